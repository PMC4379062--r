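test_that("default study reproduces the experimental design", {
  ds <- generate_study(generator_config(seed = 4))
  ann <- ds$annotations
  expect_equal(nrow(ds$values), 19 * 13 + 20 + 12)  # 279
  expect_equal(sum(ann$role == "reference"), 19)
  expect_equal(sum(ann$role == "handling"), 19 * 9)
  expect_equal(sum(ann$role == "ftc"), 19 * 3)
  expect_equal(sum(ann$role == "pool"), 20)
  expect_equal(sum(ann$role == "zero"), 12)
  hand <- unique(ann[ann$role == "handling", c("temperature", "delay_h")])
  expect_equal(nrow(hand), 9)
  ## per participant: one reference, thaw counts 2:4, same plate throughout
  per <- split(ann[ann$role != "pool" & ann$role != "zero", ],
               ann$participant[!ann$role %in% c("pool", "zero")])
  expect_true(all(vapply(per, function(d) length(unique(d$plate)) == 1, TRUE)))
})

test_that("generation is deterministic given the seed and differs across seeds", {
  a <- generate_study(generator_config(seed = 9))
  b <- generate_study(generator_config(seed = 9))
  cc <- generate_study(generator_config(seed = 10))
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, cc$values))
})

test_that("an all-null configuration has equal condition means", {
  cfg <- generator_config(panel = panel_subset(build_p150_panel(),
                                               mini_panel_ids()),
                          profiles = NULL, seed = 2)
  reps <- 150
  diffs <- vapply(seq_len(reps), function(r) {
    cfg$seed <- 100 + r
    ds <- generate_study(cfg)
    ann <- ds$annotations
    rt <- ann$temperature == "rt" & ann$delay_h == 36
    dry <- ann$temperature == "dry_ice" & ann$delay_h == 36
    mean(log(ds$values[rt, "Ser"])) - mean(log(ds$values[dry, "Ser"]))
  }, 0)
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(reps))
})

test_that("choline-lipid mass balance holds with coupling on", {
  cfg <- generator_config(seed = 1)
  base <- preanalytica:::baseline_vector(cfg)
  cls <- setNames(cfg$panel$mclass, cfg$panel$id)
  pool_ids <- names(cls)[cls %in% c("lyso_pc", "pc_aa")]
  ## expectation scale: sum of baseline * multiplier is condition-invariant
  totals <- vapply(list(c("na", 0), c("dry_ice", 12), c("rt", 12),
                        c("rt", 24), c("rt", 36), c("wet_ice", 36)),
                   function(cond) {
                     lg <- preanalytica:::condition_log_multiplier(
                       cfg, cond[[1]], as.numeric(cond[[2]]))
                     sum(base[pool_ids] * exp(lg[pool_ids]))
                   }, 0)
  expect_equal(max(totals) / min(totals), 1, tolerance = 1e-10)

  ## and on simulated data, within Monte-Carlo error
  small <- generator_config(n_participants = 4, seed = 30)
  sums <- vapply(seq_len(200), function(r) {
    small$seed <- 30 + r
    ds <- generate_study(small)
    ann <- ds$annotations
    v <- ds$values[, pool_ids, drop = FALSE]
    c(ref = mean(rowSums(v[ann$role == "reference", ])),
      rt36 = mean(rowSums(v[ann$temperature == "rt" & ann$delay_h == 36, ])))
  }, c(ref = 0, rt36 = 0))
  diff <- mean(sums["rt36", ] - sums["ref", ])
  se <- sd(sums["rt36", ] - sums["ref", ]) / sqrt(ncol(sums))
  expect_lt(abs(diff), 3 * se)
})

test_that("donors dominate PCA structure, as in the study", {
  wins <- vapply(c(6, 9, 15), function(s) {
    ds <- generate_study(generator_config(seed = s))
    ann <- ds$annotations
    subj <- ann$role %in% c("reference", "handling")
    pc <- prcomp(scale(log(ds$values[subj, ])), rank. = 2)$x
    sil_donor <- mean_silhouette(pc, ann$participant[subj])
    cond <- paste(ann$temperature[subj], ann$delay_h[subj])
    sil_donor > mean_silhouette(pc, cond)
  }, TRUE)
  expect_gte(sum(wins), 2)
})

test_that("zero and pool samples behave like blanks and replicates", {
  ds <- generate_study(generator_config(seed = 8))
  ann <- ds$annotations
  lod <- compute_lod(ds)
  cv <- compute_pool_cv(ds)
  cfg <- generator_config(seed = 8)
  informative <- intersect(names(cfg$baselines), ds$panel$id)
  clean <- setdiff(informative, cfg$cv_fail_ids)
  zero_means <- colMeans(ds$values[ann$role == "zero", clean])
  expect_true(all(zero_means < lod[clean]))          # blanks sit below LOD scale
  expect_true(all(cv[clean] < 0.25))                 # replicate precision
  expect_true(all(cv[cfg$cv_fail_ids] > 0.25))       # implanted CV failures
})

test_that("implanted trajectories cross the published decision scales", {
  cfg <- generator_config(seed = 1)
  r0 <- expected_feature(cfg, "tLyso/tPC", "na", 0)
  r12 <- expected_feature(cfg, "tLyso/tPC", "rt", 12)
  r24 <- expected_feature(cfg, "tLyso/tPC", "rt", 24)
  r36 <- expected_feature(cfg, "tLyso/tPC", "rt", 36)
  expect_lt(r0, 0.12)
  expect_lt(r12, 0.12)          # crossing strictly inside (12 h, 24 h)
  expect_gt(r24, 0.12)
  expect_gt(r36, r0)
  gs24 <- expected_feature(cfg, "Gln/Ser", "rt", 24)
  expect_gt(expected_feature(cfg, "Gln/Ser", "na", 0), 4.71)
  expect_lt(gs24, 4.71)         # falls below 4.71 by 24 h
  ## wet ice: attenuated and delayed past 24 h; dry ice is null
  expect_equal(expected_feature(cfg, "tLyso/tPC", "wet_ice", 24), r0)
  wet36 <- expected_feature(cfg, "tLyso/tPC", "wet_ice", 36)
  expect_gt(wet36, r0)
  expect_lt(wet36, r12)
  expect_equal(expected_feature(cfg, "tLyso/tPC", "dry_ice", 36), r0)
})

test_that("lysoPC(18:2) is the implanted exception and dry ice is null", {
  prof <- preanalytica:::resolve_profiles(generator_config(seed = 1))
  expect_equal(prof$rt_jump[prof$id == "lysoPC(18:2)"], 0)
  expect_equal(prof$rt_slope[prof$id == "lysoPC(18:2)"], 0)
  expect_gt(prof$rt_jump[prof$id == "lysoPC(18:0)"], 0)
  lg <- preanalytica:::condition_log_multiplier(generator_config(seed = 1),
                                                "dry_ice", 36)
  expect_true(all(lg == 0))
})

test_that("worked fixture is deterministic and satisfies the invariants", {
  a <- generate_worked_fixture()
  b <- generate_worked_fixture()
  expect_identical(a$values, b$values)
  expect_s3_class(validate_dataset(a), "concentration_dataset")
  expect_equal(nrow(a$values), 2 * 13 + 4 + 3)
  qc <- apply_qc(a)
  expect_true(any(grepl("lod", qc$report$fail_reasons)))
  expect_true(any(grepl("cv", qc$report$fail_reasons)))
})
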