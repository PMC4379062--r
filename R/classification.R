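#' Names of the four sum-ratio features
#'
#' Total lysophosphatidylcholines over total phosphatidylcholines and its
#' diacyl-only / acyl-alkyl-only variants, plus total amino acids over total
#' acylcarnitines (free carnitine included in the denominator).
#'
#' @return character vector of the four feature ids.
#' @export
sum_ratio_names <- function() c("tLyso/tPC", "tLyso/tPCaa", "tLyso/tPCae",
                                "tAA/tAC")

#' Compute the sum-ratio features
#'
#' Per sample: sum of the retained lysophosphatidylcholine concentrations
#' divided by the sum of the retained phosphatidylcholines (diacyl +
#' acyl-alkyl), the two single-class denominators, and total amino acids
#' over total acylcarnitines (including free carnitine). Sums use the
#' metabolites present in the (QC-filtered) dataset; missing cells are
#' omitted from the sums. A ratio whose denominator class has no retained
#' metabolite is skipped with a warning; a zero denominator yields `NA` for
#' that sample.
#'
#' @param ds a QC-filtered `concentration_dataset`.
#' @param include_free_carnitine count free carnitine (C0) in the tAA/tAC
#'   denominator (default `TRUE`).
#' @return data.frame: `sample_id` plus one column per available sum ratio.
#' @export
compute_sum_ratios <- function(ds, include_free_carnitine = TRUE) {
  cls <- ds$panel$mclass
  ac_classes <- if (include_free_carnitine) c("acylcarnitine", "carnitine")
                else "acylcarnitine"
  sets <- list(
    `tLyso/tPC` = list(num = cls == "lyso_pc",
                       den = cls %in% c("pc_aa", "pc_ae")),
    `tLyso/tPCaa` = list(num = cls == "lyso_pc", den = cls == "pc_aa"),
    `tLyso/tPCae` = list(num = cls == "lyso_pc", den = cls == "pc_ae"),
    `tAA/tAC` = list(num = cls == "amino_acid", den = cls %in% ac_classes))
  out <- data.frame(sample_id = ds$annotations$sample_id,
                    stringsAsFactors = FALSE)
  for (nm in names(sets)) {
    s <- sets[[nm]]
    if (!any(s$num) || !any(s$den)) {
      warning("no retained metabolites for a class of ", nm, "; skipped")
      next
    }
    num <- rowSums(ds$values[, s$num, drop = FALSE], na.rm = TRUE)
    den <- rowSums(ds$values[, s$den, drop = FALSE], na.rm = TRUE)
    r <- num / den
    r[den == 0] <- NA_real_
    out[[nm]] <- r
  }
  out
}

#' Assign good/bad quality labels
#'
#' Stringent scheme (used for variable ranking): good = reference aliquots,
#' bad = 36 h at room temperature, everything else unlabeled. Non-stringent
#' scheme (used for tree construction and evaluation): good = reference or
#' any dry-ice aliquot, bad = 24 h or 36 h at room temperature.
#'
#' @param ds a `concentration_dataset` (pool/zero rows are never labelled).
#' @param scheme `"stringent"` or `"non_stringent"`.
#' @return data.frame: `sample_id`, `participant`, `label` (good / bad /
#'   unlabeled), `scheme`.
#' @export
label_samples <- function(ds, scheme = c("stringent", "non_stringent")) {
  scheme <- match.arg(scheme)
  ann <- ds$annotations
  lab <- rep("unlabeled", nrow(ann))
  if (scheme == "stringent") {
    lab[ann$role == "reference"] <- "good"
    lab[ann$role == "handling" & ann$temperature == "rt" &
          ann$delay_h == 36] <- "bad"
  } else {
    lab[ann$role == "reference" |
          (ann$role == "handling" & ann$temperature == "dry_ice")] <- "good"
    lab[ann$role == "handling" & ann$temperature == "rt" &
          ann$delay_h %in% c(24, 36)] <- "bad"
  }
  lab[ann$role %in% c("pool", "zero")] <- "unlabeled"
  data.frame(sample_id = ann$sample_id, participant = ann$participant,
             label = lab, scheme = scheme, stringsAsFactors = FALSE)
}

#' Partition participants into training and test sets
#'
#' @param participants all participant ids.
#' @param train_ids,test_ids disjoint id sets that together cover
#'   `participants`.
#' @return list with `train` and `test` character vectors.
#' @export
split_participants <- function(participants, train_ids, test_ids) {
  participants <- unique(participants)
  if (length(intersect(train_ids, test_ids)))
    stop("train and test ids overlap")
  if (!setequal(union(train_ids, test_ids), participants))
    stop("train and test ids must cover all participants exactly")
  list(train = as.character(train_ids), test = as.character(test_ids))
}

#' Default 12/7 participant split
#'
#' The fixed training/test partition used throughout: participants 1, 4, 5,
#' 7, 9, 11, 12, 14, 15, 16, 18, 19 train; 2, 3, 6, 8, 10, 13, 17 test.
#' With `seed` given, a random 12/7 split is drawn instead.
#'
#' @param participants participant ids (default `"P1"`..`"P19"`).
#' @param seed optional seed for a random split of the same sizes.
#' @return list with `train` and `test`.
#' @export
default_split <- function(participants = paste0("P", 1:19), seed = NULL) {
  if (is.null(seed)) {
    train <- paste0("P", c(1, 4, 5, 7, 9, 11, 12, 14, 15, 16, 18, 19))
    train <- intersect(train, participants)
    test <- setdiff(participants, train)
  } else {
    set.seed(seed)
    train <- sort(sample(participants, 12))
    test <- setdiff(participants, train)
  }
  split_participants(participants, train, test)
}

#' Build the classifier feature table
#'
#' One row per subject sample; feature columns are the screened single
#' metabolite ratios (`m1/m2`, raw concentration ratios) plus the four sum
#' ratios. Annotation columns (`participant`, `role`, `temperature`,
#' `delay_h`) are carried along; the feature ids are attached as attribute
#' `"feature_ids"`.
#'
#' @param ds a QC-filtered `concentration_dataset`.
#' @param ratio_results output of [screen_ratios()]; only pairs with
#'   `passed_screen` contribute features. `NULL` gives the sum ratios only.
#' @return data.frame of features and annotations.
#' @export
build_feature_table <- function(ds, ratio_results = NULL) {
  ann <- ds$annotations
  subj <- ann$role %in% c("reference", "handling", "ftc")
  sums <- compute_sum_ratios(ds)
  out <- cbind(ann[subj, c("sample_id", "participant", "role", "temperature",
                           "delay_h")],
               sums[subj, -1, drop = FALSE])
  feat <- setdiff(names(sums), "sample_id")
  if (!is.null(ratio_results)) {
    keep <- ratio_results[ratio_results$passed_screen, c("m1", "m2")]
    V <- ds$values[subj, , drop = FALSE]
    for (i in seq_len(nrow(keep))) {
      id <- paste0(keep$m1[[i]], "/", keep$m2[[i]])
      out[[id]] <- V[, keep$m1[[i]]] / V[, keep$m2[[i]]]
      feat <- c(feat, id)
    }
  }
  rownames(out) <- NULL
  attr(out, "feature_ids") <- feat
  out
}

feature_ids <- function(features) {
  f <- attr(features, "feature_ids")
  if (is.null(f))
    f <- setdiff(names(features), c("sample_id", "participant", "role",
                                    "temperature", "delay_h"))
  f
}

#' Rank variables by averaged Random-Forest permutation importance
#'
#' Trains `n_iter` independently seeded Random Forests on the labelled
#' (good/bad) samples and averages each variable's unscaled permutation
#' importance (mean decrease in out-of-bag classification accuracy). Ties in
#' the final ranking break lexicographically by variable id. The reduced
#' defaults (20 forests of 501 trees) keep routine runs fast;
#' `full_scale = TRUE` switches to 500 forests of 5001 trees.
#'
#' @param features a feature table from [build_feature_table()].
#' @param labels labels from [label_samples()] (the stringent scheme is the
#'   intended ranking input); only good/bad rows are used.
#' @param participants optional participant ids to restrict to (training set).
#' @param n_iter number of forests to average (default 20).
#' @param n_trees trees per forest (default 501).
#' @param m_try variables tried per split (default 80, capped at the number
#'   of variables).
#' @param seed master seed; each forest consumes a derived sub-seed.
#' @param full_scale use 500 iterations of 5001 trees.
#' @return data.frame `variable`, `importance`, `rank`, sorted by rank.
#' @export
rank_variables <- function(features, labels, participants = NULL,
                           n_iter = 20, n_trees = 501, m_try = 80,
                           seed = 1, full_scale = FALSE) {
  if (full_scale) { n_iter <- 500; n_trees <- 5001 }
  d <- merge(features, labels[, c("sample_id", "label")], by = "sample_id")
  if (!is.null(participants)) d <- d[d$participant %in% participants, ]
  d <- d[d$label %in% c("good", "bad"), ]
  if (length(unique(d$label)) < 2 || min(table(d$label)) < 2)
    stop("need at least two labelled samples per class")
  fids <- feature_ids(features)
  x <- as.matrix(d[, fids, drop = FALSE])
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  y <- factor(d$label[keep], levels = c("good", "bad"))
  mtry <- min(m_try, ncol(x))
  imp <- matrix(0, ncol(x), n_iter, dimnames = list(fids, NULL))
  for (i in seq_len(n_iter)) {
    set.seed(stream_seed(seed, paste0("rf", i)))
    rf <- randomForest::randomForest(x, y, ntree = n_trees, mtry = mtry,
                                     importance = TRUE)
    imp[, i] <- randomForest::importance(rf, type = 1, scale = FALSE)[fids, 1]
  }
  mean_imp <- rowMeans(imp)
  ord <- order(-mean_imp, fids)
  data.frame(variable = fids[ord], importance = unname(mean_imp[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

sanitize_vars <- function(ids) setNames(ids, paste0("V", seq_along(ids)))

#' Fit the quality classification tree
#'
#' Grows a binary CART classification tree (Gini impurity, minimum leaf size
#' 5, complexity penalty 0.01) on the labelled samples of the training
#' participants, restricted to the given candidate variables (typically the
#' top 10 of [rank_variables()]). On study-like data the expected result is
#' a two-split tree: a lysoPC/PC ratio at its transition threshold and an
#' amino-acid ratio below its threshold marking the bad region.
#'
#' @param features a feature table.
#' @param labels labels from [label_samples()] (non-stringent scheme for the
#'   final rule); only good/bad rows are used.
#' @param variables candidate feature ids.
#' @param participants optional training participant ids.
#' @param minbucket,cp rpart control (defaults 3 and 0.01; a leaf must be
#'   able to hold the four good-label aliquots of a single borderline donor,
#'   so the minimum leaf size is kept below that).
#' @return a `quality_tree`: list with the fitted `rpart` object, the
#'   variable mapping, and `splits` (data.frame `variable`, `threshold`,
#'   `left` -- the relation sending a sample to the left child).
#' @export
fit_quality_tree <- function(features, labels, variables,
                             participants = NULL, minbucket = 3, cp = 0.01) {
  if (!length(variables)) stop("no candidate variables")
  stopifnot(all(variables %in% feature_ids(features)))
  d <- merge(features, labels[, c("sample_id", "label")], by = "sample_id")
  if (!is.null(participants)) d <- d[d$participant %in% participants, ]
  d <- d[d$label %in% c("good", "bad"), ]
  if (!nrow(d)) stop("no labelled samples")
  vmap <- sanitize_vars(variables)
  dat <- d[, unname(vmap), drop = FALSE]
  names(dat) <- names(vmap)
  dat$label <- factor(d$label, levels = c("good", "bad"))
  if (nlevels(droplevels(dat$label)) < 2) stop("both classes required")
  fit <- rpart::rpart(label ~ ., data = dat, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        minsplit = 3 * minbucket, minbucket = minbucket,
                        cp = cp, maxcompete = 0, maxsurrogate = 0,
                        xval = 0))
  splits <- extract_splits(fit, vmap)
  structure(list(rpart = fit, variables = variables, vmap = vmap,
                 splits = splits), class = "quality_tree")
}

extract_splits <- function(fit, vmap) {
  fr <- fit$frame
  internal <- fr$var != "<leaf>"
  if (!any(internal))
    return(data.frame(variable = character(), threshold = numeric(),
                      left = character()))
  sp <- fit$splits
  data.frame(variable = unname(vmap[as.character(fr$var[internal])]),
             threshold = unname(sp[, "index"]),
             left = ifelse(sp[, "ncat"] < 0, "<", ">="),
             stringsAsFactors = FALSE)
}

#' @export
print.quality_tree <- function(x, ...) {
  cat("quality_tree with", nrow(x$splits), "split(s)\n")
  for (r in tree_rules(x)) cat(" ", r, "\n")
  invisible(x)
}

#' Human-readable decision rules of a quality tree
#'
#' One rule string per bad leaf, e.g.
#' `"tLyso/tPC >= 0.104 and Gln/Ser <= 4.45 -> bad"`.
#'
#' @param tree a `quality_tree`.
#' @param digits significant digits for thresholds.
#' @return character vector of rules (empty if the tree never predicts bad).
#' @export
tree_rules <- function(tree, digits = 3) {
  fit <- tree$rpart
  fr <- fit$frame
  nodes <- as.integer(rownames(fr))
  leaf_bad <- fr$var == "<leaf>" & fit$frame$yval == 2   # level 2 = bad
  if (!any(leaf_bad)) return(character())
  inv <- setNames(names(tree$vmap), tree$vmap)
  rules <- character()
  for (leaf in nodes[leaf_bad]) {
    conds <- character()
    node <- leaf
    while (node > 1) {
      parent <- node %/% 2
      pi <- which(nodes == parent)
      ki <- sum(fr$var[seq_len(pi)] != "<leaf>")
      varid <- unname(tree$splits$variable[ki])
      thr <- tree$splits$threshold[ki]
      leftop <- tree$splits$left[ki]
      is_left <- node %% 2 == 0
      op <- if (is_left) leftop else c("<" = ">=", ">=" = "<")[leftop]
      conds <- c(sprintf("%s %s %s", varid, op, signif(thr, digits)), conds)
      node <- parent
    }
    rules <- c(rules, paste(paste(conds, collapse = " and "), "-> bad"))
  }
  rules
}

#' Classify samples with a quality tree
#'
#' Deterministic application of the fitted rule. Samples missing a value of
#' any variable the tree uses are reported as unclassifiable (`NA`) and a
#' message records their count.
#'
#' @param tree a `quality_tree`.
#' @param features a feature table containing the tree's variables.
#' @return data.frame `sample_id`, `predicted` (good / bad / `NA`).
#' @export
predict_quality <- function(tree, features) {
  used <- unique(tree$splits$variable)
  dat <- features[, unname(tree$vmap), drop = FALSE]
  names(dat) <- names(tree$vmap)
  ok <- if (length(used))
    stats::complete.cases(features[, used, drop = FALSE])
  else rep(TRUE, nrow(features))
  pred <- rep(NA_character_, nrow(features))
  if (any(ok))
    pred[ok] <- as.character(predict(tree$rpart, dat[ok, , drop = FALSE],
                                     type = "class"))
  if (any(!ok))
    message(sum(!ok), " sample(s) unclassifiable (missing feature values)")
  data.frame(sample_id = features$sample_id, predicted = pred,
             stringsAsFactors = FALSE)
}

#' Misclassification rate
#'
#' Fraction of labelled (good/bad) samples whose prediction disagrees with
#' the label; unclassifiable samples (`NA` prediction) are excluded from the
#' denominator.
#'
#' @param predicted character vector of predictions (good/bad/`NA`).
#' @param truth character vector of labels (good/bad; others ignored).
#' @return list with `rate`, `errors`, `n`.
#' @export
misclassification_rate <- function(predicted, truth) {
  use <- truth %in% c("good", "bad") & !is.na(predicted)
  n <- sum(use)
  errors <- sum(predicted[use] != truth[use])
  list(rate = if (n) errors / n else NA_real_, errors = errors, n = n)
}

#' Classify the held-out handling conditions
#'
#' Applies a fitted tree to the handling conditions that carry no
#' non-stringent label (wet ice at 12/24/36 h and room temperature at 12 h)
#' and tabulates good/bad counts per condition.
#'
#' @param tree a `quality_tree`.
#' @param features a feature table (all participants).
#' @return data.frame `condition`, `n_good`, `n_bad`, `frac_good`; zero rows
#'   if the table holds no unlabeled handling samples.
#' @export
apply_to_heldout <- function(tree, features) {
  held <- features$role == "handling" &
    (features$temperature == "wet_ice" |
       (features$temperature == "rt" & features$delay_h == 12))
  if (!any(held))
    return(data.frame(condition = character(), n_good = integer(),
                      n_bad = integer(), frac_good = numeric()))
  f <- features[held, , drop = FALSE]
  pred <- predict_quality(tree, f)$predicted
  cond <- paste0(f$temperature, "_", f$delay_h, "h")
  tab <- do.call(rbind, lapply(sort(unique(cond)), function(cc) {
    p <- pred[cond == cc & !is.na(pred)]
    data.frame(condition = cc, n_good = sum(p == "good"),
               n_bad = sum(p == "bad"),
               frac_good = if (length(p)) mean(p == "good") else NA_real_)
  }))
  rownames(tab) <- NULL
  tab
}

#' Robustness scan over variable subsets
#'
#' Refits the classification tree for each candidate variable subset and
#' reports training- and test-set misclassification rates, mirroring the
#' check that any subset containing both an amino-acid variable and a
#' lysoPC/PC variable performs similarly to the full top-10 model.
#'
#' @param features a feature table.
#' @param labels non-stringent labels.
#' @param subsets list of character vectors of feature ids (non-empty).
#' @param split a participant split from [split_participants()].
#' @param ... passed to [fit_quality_tree()].
#' @return data.frame `subset`, `n_vars`, `train_rate`, `test_rate`.
#' @export
robustness_scan <- function(features, labels, subsets, split, ...) {
  if (!length(subsets)) stop("no variable subsets given")
  rows <- lapply(subsets, function(vars) {
    if (!length(vars)) stop("empty variable subset")
    tree <- fit_quality_tree(features, labels, vars,
                             participants = split$train, ...)
    rate_for <- function(ids) {
      f <- features[features$participant %in% ids, , drop = FALSE]
      pred <- predict_quality(tree, f)$predicted
      lab <- labels$label[match(f$sample_id, labels$sample_id)]
      misclassification_rate(pred, lab)$rate
    }
    data.frame(subset = paste(vars, collapse = "+"), n_vars = length(vars),
               train_rate = rate_for(split$train),
               test_rate = rate_for(split$test), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
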