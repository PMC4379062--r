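test_that("sum ratios match hand arithmetic and are scale free", {
  qc <- apply_qc(generate_worked_fixture())
  ds <- qc$dataset   # retains Gln, Ser, PC(34:2), lysoPC(18:0)
  w <- capture_warnings(sums <- compute_sum_ratios(ds))
  expect_match(w, "tLyso/tPCae", all = FALSE)   # no retained acyl-alkyl PC
  i <- match("P1_ref", sums$sample_id)
  expect_equal(sums[["tLyso/tPC"]][i], 20 / 380)
  expect_equal(sums[["tLyso/tPCaa"]][i], 20 / 380)
  expect_null(sums[["tAA/tAC"]])     # no retained acylcarnitine
  ## doubling all concentrations of a sample leaves every ratio unchanged
  ds2 <- ds; ds2$values[i, ] <- 2 * ds2$values[i, ]
  sums2 <- suppressWarnings(compute_sum_ratios(ds2))
  expect_equal(sums2[["tLyso/tPC"]][i], sums[["tLyso/tPC"]][i])
  ## a sample with lysoPC sum 12 and PC sum 100 sits at the 0.12 cut-off scale
  ds3 <- ds
  ds3$values[i, "lysoPC(18:0)"] <- 12; ds3$values[i, "PC(34:2)"] <- 100
  s3 <- suppressWarnings(compute_sum_ratios(ds3))
  expect_equal(s3[["tLyso/tPC"]][i], 0.12)
})

test_that("quality labels follow the two published schemes", {
  ds <- generate_study(generator_config(seed = 41))
  split <- default_split(paste0("P", 1:19))
  expect_equal(length(split$train), 12)
  expect_equal(length(split$test), 7)
  expect_setequal(split$test, paste0("P", c(2, 3, 6, 8, 10, 13, 17)))

  non <- label_samples(ds, "non_stringent")
  train_lab <- non$label[non$participant %in% split$train]
  expect_equal(sum(train_lab == "good"), 48)
  expect_equal(sum(train_lab == "bad"), 24)

  str <- label_samples(ds, "stringent")
  str_train <- str$label[str$participant %in% split$train]
  expect_equal(sum(str_train == "good"), 12)
  expect_equal(sum(str_train == "bad"), 12)

  ## wet ice is unlabeled under both schemes; pools/zeros never labelled
  ann <- ds$annotations
  wet <- ann$sample_id[ann$temperature == "wet_ice"]
  expect_true(all(non$label[non$sample_id %in% wet] == "unlabeled"))
  expect_true(all(str$label[str$sample_id %in% wet] == "unlabeled"))
})

test_that("participant splits validate and reproduce under a seed", {
  ids <- paste0("P", 1:19)
  expect_error(split_participants(ids, ids[1:12], ids[10:19]), "overlap")
  expect_error(split_participants(ids, ids[1:12], ids[13:18]), "cover")
  s1 <- default_split(ids, seed = 5)
  s2 <- default_split(ids, seed = 5)
  expect_identical(s1, s2)
  expect_setequal(c(s1$train, s1$test), ids)
})

test_that("feature table combines screened ratios with the sum ratios", {
  qc <- apply_qc(generate_study(mini_config(seed = 42)))
  rr <- screen_ratios(fit_ratio_models(qc$dataset, "handling"))
  w <- capture_warnings(feat <- build_feature_table(qc$dataset, rr))
  expect_match(w, "tLyso/tPCae", all = FALSE)
  fids <- attr(feat, "feature_ids")
  expect_true(all(c("tLyso/tPC", "tLyso/tPCaa") %in% fids))
  expect_equal(sum(grepl("/", setdiff(fids, sum_ratio_names()))),
               sum(rr$passed_screen))
  expect_equal(nrow(feat), sum(qc$dataset$annotations$role %in%
                                 c("reference", "handling", "ftc")))
})

test_that("forest ranking is deterministic and rejects degenerate labels", {
  qc <- apply_qc(generate_study(mini_config(seed = 43)))
  rr <- screen_ratios(fit_ratio_models(qc$dataset, "handling"))
  suppressWarnings(feat <- build_feature_table(qc$dataset, rr))
  lab <- label_samples(qc$dataset, "stringent")
  r1 <- rank_variables(feat, lab, n_iter = 3, n_trees = 101, seed = 7)
  r2 <- rank_variables(feat, lab, n_iter = 3, n_trees = 101, seed = 7)
  expect_identical(r1, r2)
  expect_setequal(r1$variable, attr(feat, "feature_ids"))
  expect_equal(r1$rank, seq_len(nrow(r1)))
  bad_lab <- lab; bad_lab$label[bad_lab$label == "bad"] <- "unlabeled"
  expect_error(rank_variables(feat, bad_lab), "per class")
})

test_that("a pure-noise variable never outranks the implanted signals", {
  qc <- apply_qc(generate_study(mini_config(seed = 44)))
  rr <- screen_ratios(fit_ratio_models(qc$dataset, "handling"))
  suppressWarnings(feat <- build_feature_table(qc$dataset, rr))
  lab <- label_samples(qc$dataset, "stringent")
  set.seed(1); feat$noise_var <- runif(nrow(feat))
  attr(feat, "feature_ids") <- c(attr(feat, "feature_ids"), "noise_var")
  firsts <- vapply(1:20, function(s)
    rank_variables(feat, lab, n_iter = 2, n_trees = 201,
                   seed = s)$variable[1], "")
  expect_false("noise_var" %in% firsts)
})

test_that("importance averaging reduces ranking variance", {
  qc <- apply_qc(generate_study(mini_config(seed = 45)))
  rr <- screen_ratios(fit_ratio_models(qc$dataset, "handling"))
  suppressWarnings(feat <- build_feature_table(qc$dataset, rr))
  lab <- label_samples(qc$dataset, "stringent")
  rank_sd <- function(n_iter) {
    ranks <- vapply(1:8, function(s)
      with(rank_variables(feat, lab, n_iter = n_iter, n_trees = 101,
                          seed = 100 + s),
           rank[variable == "tLyso/tPC"]), 0)
    sd(ranks)
  }
  expect_lte(rank_sd(10), rank_sd(1) + 1e-9)
})

test_that("CART on cleanly separable data splits at the midpoint gap", {
  feat <- data.frame(sample_id = sprintf("s%02d", 1:24),
                     participant = rep(paste0("P", 1:6), each = 4),
                     role = "handling", temperature = "rt", delay_h = 24,
                     x = c(seq(0.8, 1.24, length.out = 12),
                           seq(1.60, 2.2, length.out = 12)))
  attr(feat, "feature_ids") <- "x"
  labels <- data.frame(sample_id = feat$sample_id,
                       participant = feat$participant,
                       label = rep(c("good", "bad"), each = 12),
                       scheme = "non_stringent")
  tree <- fit_quality_tree(feat, labels, "x")
  expect_equal(nrow(tree$splits), 1)
  expect_equal(tree$splits$variable, "x")
  expect_equal(tree$splits$threshold, (1.24 + 1.60) / 2)
  pred <- predict_quality(tree, feat)
  expect_equal(misclassification_rate(pred$predicted, labels$label)$rate, 0)
})

test_that("the published rule classifies the worked examples", {
  ## engineer training data whose CART midpoints are exactly 0.12 and 4.71:
  ## the borderline-good samples interleave with the bad cluster on the
  ## lysoPC axis (so no single lysoPC split separates them), low-amino good
  ## samples make a pure amino root strictly worse, and the amino split then
  ## isolates the interleaved goods inside the high-lysoPC branch
  lyso <- c(rep(0.08, 20), 0.11, 0.115, 0.115,             # good, low lyso
            rep(0.085, 7),                                 # good, aa-low
            0.125, 0.13, 0.135, 0.15, 0.165, 0.18, 0.195,  # bad
            0.21, 0.22, 0.23, 0.235, 0.24,                 # bad
            0.127, 0.14, 0.155, 0.17, 0.185, 0.2)          # good, interleaved
  gln_ser <- c(rep(5.5, 20), 5.4, 5.3, 5.2,
               4.02, 4.07, 4.12, 4.17, 4.22, 4.27, 4.32,
               4.0, 4.05, 4.1, 4.15, 4.2, 4.25, 4.3, 4.35, 4.36, 4.38,
               4.4, 4.42,
               5.0, 5.05, 5.1, 5.15, 5.2, 5.3)
  lab <- c(rep("good", 30), rep("bad", 12), rep("good", 6))
  feat <- data.frame(sample_id = sprintf("s%02d", seq_along(lyso)),
                     participant = rep(paste0("P", 1:12), each = 4),
                     role = "handling", temperature = "rt", delay_h = 24,
                     check.names = FALSE)
  feat[["tLyso/tPC"]] <- lyso
  feat[["Gln/Ser"]] <- gln_ser
  attr(feat, "feature_ids") <- c("tLyso/tPC", "Gln/Ser")
  labels <- data.frame(sample_id = feat$sample_id,
                       participant = feat$participant, label = lab,
                       scheme = "non_stringent")
  tree <- fit_quality_tree(feat, labels, c("tLyso/tPC", "Gln/Ser"))
  expect_equal(nrow(tree$splits), 2)
  expect_equal(tree$splits$threshold[tree$splits$variable == "tLyso/tPC"], 0.12)
  expect_equal(tree$splits$threshold[tree$splits$variable == "Gln/Ser"], 4.71)
  expect_equal(tree_rules(tree), "tLyso/tPC >= 0.12 and Gln/Ser < 4.71 -> bad")

  newdata <- feat[1:2, ]
  newdata[["tLyso/tPC"]] <- c(0.15, 0.10)
  newdata[["Gln/Ser"]] <- c(4.0, 6.0)
  pred <- predict_quality(tree, newdata)
  expect_equal(pred$predicted, c("bad", "good"))
})

test_that("misclassification handles missing features and counts honestly", {
  expect_equal(misclassification_rate(c("good", "bad", "bad"),
                                      c("good", "bad", "good"))$rate, 1 / 3)
  expect_equal(misclassification_rate(rep("good", 5), rep("good", 5))$rate, 0)
  r <- misclassification_rate(c("good", NA, "bad"),
                              c("good", "bad", "unlabeled"))
  expect_equal(r$n, 1)
  expect_equal(r$errors, 0)
})

test_that("held-out table covers wet ice and 12 h RT only", {
  qc <- apply_qc(generate_study(mini_config(seed = 46)))
  suppressWarnings(feat <- build_feature_table(qc$dataset, NULL))
  lab <- label_samples(qc$dataset, "non_stringent")
  tree <- fit_quality_tree(feat, lab, "tLyso/tPC")
  ho <- apply_to_heldout(tree, feat)
  expect_setequal(ho$condition, c("rt_12h", "wet_ice_12h", "wet_ice_24h",
                                  "wet_ice_36h"))
  expect_equal(sum(ho$n_good + ho$n_bad),
               4 * length(unique(feat$participant)))
  no_held <- feat[feat$temperature == "dry_ice", ]
  expect_equal(nrow(apply_to_heldout(tree, no_held)), 0)
})

test_that("robustness scan reports one tree per subset", {
  qc <- apply_qc(generate_study(mini_config(seed = 47)))
  rr <- screen_ratios(fit_ratio_models(qc$dataset, "handling"))
  suppressWarnings(feat <- build_feature_table(qc$dataset, rr))
  lab <- label_samples(qc$dataset, "non_stringent")
  split <- default_split(unique(feat$participant))
  fids <- attr(feat, "feature_ids")
  subsets <- list(fids[1:2], fids[c(1, length(fids))])
  tab <- robustness_scan(feat, lab, subsets, split)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$train_rate >= 0 & tab$train_rate <= 1))
  expect_error(robustness_scan(feat, lab, list(character()), split), "empty")
  expect_error(robustness_scan(feat, lab, list(), split), "no variable")
})

test_that("the decisive variables recover the reference rule shape", {
  ## with the sum ratios and Gln/Ser available, the tree roots at tLyso/tPC
  ## and classifies the held-out test participants nearly perfectly
  results <- vapply(71:75, function(s) {
    fds <- apply_qc(generate_study(generator_config(seed = s)))$dataset
    feat <- build_feature_table(fds, NULL)
    V <- fds$values[fds$annotations$role %in%
                      c("reference", "handling", "ftc"), ]
    feat[["Gln/Ser"]] <- V[, "Gln"] / V[, "Ser"]
    attr(feat, "feature_ids") <- c(attr(feat, "feature_ids"), "Gln/Ser")
    lab <- label_samples(fds, "non_stringent")
    split <- default_split(unique(fds$annotations$participant))
    tree <- fit_quality_tree(feat, lab, c(sum_ratio_names(), "Gln/Ser"),
                             participants = split$train)
    f_test <- feat[feat$participant %in% split$test, ]
    pred <- predict_quality(tree, f_test)$predicted
    truth <- lab$label[match(f_test$sample_id, lab$sample_id)]
    c(root = tree$splits$variable[1] == "tLyso/tPC",
      rate = misclassification_rate(pred, truth)$rate <= 0.05)
  }, c(root = TRUE, rate = TRUE))
  expect_gte(sum(results["root", ]), 4)
  expect_gte(sum(results["rate", ]), 4)
})
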