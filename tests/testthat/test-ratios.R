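test_that("pair enumeration is complete, unique and deterministic", {
  expect_equal(nrow(enumerate_pairs(paste0("m", 1:127))), 8001)
  expect_equal(nrow(enumerate_pairs(c("a", "b"))), 1)
  expect_equal(nrow(enumerate_pairs(paste0("m", 1:5))), 10)
  expect_equal(nrow(enumerate_pairs("a")), 0)
  p <- enumerate_pairs(c("b", "a", "c"))
  expect_equal(p$m1, c("a", "a", "b"))    # lexicographic, m1 < m2
  expect_true(all(p$m1 < p$m2))
})

test_that("screen thresholds are pure functions of the pair count", {
  expect_equal(pgain_threshold(8001, 3), 240030)
  expect_equal(pgain_threshold(8001, 1), 80010)
  expect_equal(ratio_alpha(8001, 1), 0.05 / 8001)
  expect_equal(ratio_alpha(8001, 3), 0.05 / 24003)
  for (K in c(5, 30, 127)) {
    np <- K * (K - 1) / 2
    expect_equal(pgain_threshold(np, 3), 30 * np)
    expect_equal(ratio_alpha(np, 3) * 3 * np, 0.05)
  }
})

test_that("p-gains equal brute-force recomputation from the stored fits", {
  qc <- apply_qc(generate_study(mini_config(seed = 31)))
  rr <- fit_ratio_models(qc$dataset, "handling")
  singles <- attr(rr, "singles")
  for (comp in c("time", "temp", "overall")) {
    brute <- pmin(singles[rr$m1, paste0("p_", comp)],
                  singles[rr$m2, paste0("p_", comp)]) /
      rr[[paste0("p_", comp)]]
    expect_identical(unname(rr[[paste0("pgain_", comp)]]), unname(brute))
  }
  ## a ratio p equal to the smaller single p gives p-gain 1 by definition
  expect_equal(min(pmin(singles[rr$m1, "p_temp"], singles[rr$m2, "p_temp"]) /
                     rr$p_temp / rr$pgain_temp, na.rm = TRUE), 1)
})

test_that("pair order only flips coefficient signs", {
  qc <- apply_qc(generate_study(mini_config(seed = 32)))
  fwd <- fit_ratio_models(qc$dataset, "handling",
                          pairs = data.frame(m1 = "Gln", m2 = "Ser"))
  rev <- fit_ratio_models(qc$dataset, "handling",
                          pairs = data.frame(m1 = "Ser", m2 = "Gln"))
  expect_equal(fwd$beta_temp, -rev$beta_temp)
  expect_equal(fwd$beta_time, -rev$beta_time)
  expect_identical(fwd$p_temp, rev$p_temp)
  expect_identical(fwd$p_overall, rev$p_overall)
})

test_that("rescaling one metabolite moves only the intercept", {
  qc <- apply_qc(generate_study(mini_config(seed = 33)))
  base <- fit_ratio_models(qc$dataset, "handling")
  scaled <- qc$dataset
  scaled$values[, "Ser"] <- scaled$values[, "Ser"] * 10
  again <- fit_ratio_models(scaled, "handling")
  expect_equal(again$p_temp, base$p_temp, tolerance = 1e-9)
  expect_equal(again$p_overall, base$p_overall, tolerance = 1e-9)
  expect_equal(again$beta_temp, base$beta_temp, tolerance = 1e-9)
})

test_that("screen applies both conditions and records its thresholds", {
  qc <- apply_qc(generate_study(mini_config(seed = 34)))
  rr <- screen_ratios(fit_ratio_models(qc$dataset, "handling"))
  expect_equal(attr(rr, "alpha_adj"), 0.05 / (3 * nrow(rr)))
  expect_equal(attr(rr, "pgain_min"), 30 * nrow(rr))
  expect_match(attr(rr, "note"), "n_terms")
  ## every passing pair satisfies both conditions for some component
  pass <- rr[rr$passed_screen, ]
  if (nrow(pass)) {
    ok <- mapply(function(i) {
      any(vapply(c("time", "temp", "overall"), function(cc)
        isTRUE(pass[i, paste0("p_", cc)] < attr(rr, "alpha_adj") &&
                 pass[i, paste0("pgain_", cc)] > attr(rr, "pgain_min")), TRUE))
    }, seq_len(nrow(pass)))
    expect_true(all(ok))
  }
})

test_that("opposing implanted trends generate large p-gains", {
  ## C10:2 falls while lysoPC(16:0) rises: opposite implanted trends
  hits <- 0; runs <- 20
  for (s in seq_len(runs)) {
    qc <- apply_qc(generate_study(generator_config(seed = 300 + s)))
    rr <- fit_ratio_models(qc$dataset, "handling",
                           pairs = data.frame(m1 = "C10:2",
                                              m2 = "lysoPC(16:0)"))
    hits <- hits + (rr$pgain_temp > 10)
  }
  expect_gte(hits / runs, 0.9)
})

test_that("the freeze-thaw ratio screen uses 1 df and finds nothing null", {
  qc <- apply_qc(generate_study(mini_config(seed = 36)))
  rr <- screen_ratios(fit_ratio_models(qc$dataset, "ftc"))
  expect_true(all(c("p_ftc", "pgain_ftc", "p_overall") %in% names(rr)))
  expect_equal(attr(rr, "alpha_adj"), 0.05 / nrow(rr))
  expect_equal(attr(rr, "pgain_min"), 10 * nrow(rr))
  expect_equal(sum(rr$passed_screen), 0)
})

test_that("non-positive concentrations are dropped pairwise", {
  qc <- apply_qc(generate_study(mini_config(seed = 37)))
  ds <- qc$dataset
  hand <- which(ds$annotations$role == "handling")
  ds$values[hand[1:3], "Ser"] <- 0
  rr <- fit_ratio_models(ds, "handling",
                         pairs = data.frame(m1 = c("Gln", "Gln"),
                                            m2 = c("Ser", "Orn")))
  expect_equal(rr$n_dropped, c(3L, 0L))
  expect_true(all(rr$converged))
})
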