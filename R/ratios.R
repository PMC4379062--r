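#' Enumerate all unordered metabolite pairs
#'
#' All `K * (K - 1) / 2` unordered pairs in deterministic lexicographic
#' order of the input ids (127 retained metabolites give 8001 pairs).
#'
#' @param metabolites character vector of metabolite ids.
#' @return data.frame with columns `m1`, `m2`; empty for fewer than two ids.
#' @export
enumerate_pairs <- function(metabolites) {
  ids <- sort(unique(metabolites))
  if (length(ids) < 2)
    return(data.frame(m1 = character(), m2 = character()))
  idx <- utils::combn(length(ids), 2)
  data.frame(m1 = ids[idx[1, ]], m2 = ids[idx[2, ]], stringsAsFactors = FALSE)
}

#' Ratio-screen significance threshold
#'
#' `alpha / (n_terms * n_pairs)`; with 8001 pairs and the three tested
#' components (time, temperature, overall) this is 0.05/24003 = 2.08e-6, and
#' 0.05/8001 = 6.3e-6 for the freeze-thaw scheme.
#'
#' @param n_pairs number of ratio models.
#' @param n_terms tested components per model (3 handling, 1 ftc).
#' @param alpha familywise level (default 0.05).
#' @return the per-test threshold.
#' @export
ratio_alpha <- function(n_pairs, n_terms = 3, alpha = 0.05) {
  stopifnot(n_pairs >= 1, n_terms >= 1)
  alpha / (n_terms * n_pairs)
}

#' p-gain screening threshold
#'
#' `10 * n_terms * n_pairs`: 240030 for 8001 pairs and three components
#' (handling scheme), 80010 for the freeze-thaw scheme.
#'
#' @inheritParams ratio_alpha
#' @return the p-gain bound a passing ratio must exceed.
#' @export
pgain_threshold <- function(n_pairs, n_terms = 3) {
  stopifnot(n_pairs >= 1, n_terms >= 1)
  10 * n_terms * n_pairs
}

## fixed-effect design of the ratio models (no interaction)
ratio_design <- function(ann, scheme) {
  if (scheme == "handling")
    cbind(`(Intercept)` = 1, time = ann$delay_h,
          temp = unname(temp_score(ann$temperature)))
  else
    cbind(`(Intercept)` = 1, ftc = ann$thaw_count)
}

## Single-metabolite reference fits for the p-gain: raw concentration on the
## ratio-model fixed effects (time + temperature, or thaw count), with the
## overall p from the same likelihood-ratio test used for the ratios.
fit_single_reference <- function(Y, X, g, df) {
  terms <- setdiff(colnames(X), "(Intercept)")
  complete <- !apply(is.na(Y), 2, any)
  varying <- apply(Y, 2, function(y) sd(y, na.rm = TRUE) > 1e-12)
  out <- data.frame(metabolite = colnames(Y), stringsAsFactors = FALSE)
  for (tm in terms) out[[paste0("p_", tm)]] <- NA_real_
  out$p_overall <- NA_real_
  out$converged <- FALSE
  fastcols <- complete & varying
  if (balanced_design(X, g) && any(fastcols)) {
    full <- fit_ri_lmm_multi(Y[, fastcols, drop = FALSE], X, g)
    null <- fit_ri_lmm_multi(Y[, fastcols, drop = FALSE],
                             X[, 1, drop = FALSE], g)
    po <- lrt_pvalue(full$logLik, null$logLik, df)
    idx <- which(fastcols)
    for (k in seq_along(idx)) {
      for (tm in terms) out[idx[k], paste0("p_", tm)] <- full$p[tm, k]
      out$p_overall[idx[k]] <- po[[k]]
      out$converged[idx[k]] <- full$converged[[k]] && null$converged[[k]]
    }
    rest <- which(!fastcols & varying)
  } else rest <- which(varying)
  for (j in rest) {
    y <- Y[, j]; ok <- is.finite(y)
    if (sum(ok) < ncol(X) + 2 || sd(y[ok]) <= 1e-12) next
    fullf <- fit_ri_lmm(y[ok], X[ok, , drop = FALSE], g[ok])
    nullf <- fit_ri_lmm(y[ok], X[ok, 1, drop = FALSE], g[ok])
    for (tm in terms) out[j, paste0("p_", tm)] <- fullf$p[tm]
    out$p_overall[j] <- lrt_pvalue(fullf$logLik, nullf$logLik, df)
    out$converged[j] <- isTRUE(fullf$converged)
  }
  out
}

#' Fit all metabolite-ratio mixed models and compute p-gains
#'
#' For every unordered pair of retained metabolites, fits the log-ratio
#' outcome `log(x1) - log(x2)` on the handling samples with fixed effects
#' time and temperature (no interaction) and a participant random intercept,
#' by ML. The overall p-value comes from a likelihood-ratio test against the
#' null model that keeps the intercept and the random effect (2 df; 1 df for
#' the freeze-thaw scheme, whose only fixed effect is the thaw count). The
#' p-gain of each component is the smaller of the two single-metabolite
#' p-values divided by the ratio p-value, where the single-metabolite
#' reference models regress raw concentration on the same fixed effects
#' (their overall p uses the same likelihood-ratio test).
#'
#' Rows with non-positive or missing concentrations in either member are
#' dropped pairwise; the number of dropped rows is recorded in the
#' `n_dropped` column.
#'
#' @param ds a QC-filtered `concentration_dataset`.
#' @param scheme `"handling"` (time + temperature on handling samples) or
#'   `"ftc"` (thaw count on reference + freeze-thaw samples).
#' @param null_model `"random_intercept"` (default: the LRT null keeps the
#'   participant random effect) or `"fixed_intercept"`.
#' @param pairs optional data.frame of pairs (default: all pairs of the
#'   dataset's metabolites from [enumerate_pairs()]).
#' @return data.frame with one row per pair: Wald p-values (`p_time`,
#'   `p_temp` or `p_ftc`), `p_overall`, the matching `pgain_*` columns,
#'   coefficient estimates, `n_dropped` and `converged`. The single-metabolite
#'   reference fits are attached as attribute `"singles"`.
#' @export
fit_ratio_models <- function(ds, scheme = c("handling", "ftc"),
                             null_model = c("random_intercept",
                                            "fixed_intercept"),
                             pairs = NULL) {
  scheme <- match.arg(scheme)
  null_model <- match.arg(null_model)
  ann <- ds$annotations
  keep <- if (scheme == "handling") ann$role == "handling"
          else ann$role %in% c("reference", "ftc")
  if (!any(keep)) stop("no samples for scheme ", scheme)
  ann <- ann[keep, , drop = FALSE]
  V <- ds$values[keep, , drop = FALSE]
  X <- ratio_design(ann, scheme)
  g <- factor(ann$participant)
  df <- ncol(X) - 1
  terms <- setdiff(colnames(X), "(Intercept)")
  if (is.null(pairs)) pairs <- enumerate_pairs(colnames(V))
  if (!nrow(pairs)) stop("need at least two metabolites")

  singles <- fit_single_reference(V, X, g, df)
  rownames(singles) <- singles$metabolite

  pos <- is.finite(V) & V > 0
  logV <- suppressWarnings(log(V))
  logV[!pos] <- NA_real_
  all_pos <- apply(pos, 2, all)
  clean <- all_pos[pairs$m1] & all_pos[pairs$m2]
  balanced <- balanced_design(X, g)

  nullX <- X[, 1, drop = FALSE]
  res <- vector("list", nrow(pairs))
  if (any(clean) && balanced) {
    Yp <- logV[, pairs$m1[clean], drop = FALSE] -
      logV[, pairs$m2[clean], drop = FALSE]
    full <- fit_ri_lmm_multi(Yp, X, g)
    null <- if (null_model == "random_intercept")
      fit_ri_lmm_multi(Yp, nullX, g)
    else fixed_null_loglik(Yp)
    p_overall <- lrt_pvalue(full$logLik, null$logLik, df)
    ci <- which(clean)
    for (k in seq_along(ci)) {
      row <- list(m1 = pairs$m1[ci[k]], m2 = pairs$m2[ci[k]],
                  n_dropped = 0L, converged = full$converged[[k]])
      for (tm in terms) {
        row[[paste0("beta_", tm)]] <- unname(full$beta[tm, k])
        row[[paste0("p_", tm)]] <- unname(full$p[tm, k])
      }
      row$p_overall <- p_overall[[k]]
      res[[ci[k]]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  slow <- which(!clean | !balanced)
  for (i in slow) {
    y <- logV[, pairs$m1[i]] - logV[, pairs$m2[i]]
    ok <- is.finite(y)
    row <- list(m1 = pairs$m1[i], m2 = pairs$m2[i],
                n_dropped = sum(!ok), converged = FALSE)
    for (tm in terms) {
      row[[paste0("beta_", tm)]] <- NA_real_
      row[[paste0("p_", tm)]] <- NA_real_
    }
    row$p_overall <- NA_real_
    if (sum(ok) >= ncol(X) + 2 && sd(y[ok]) > 1e-12) {
      fullf <- fit_ri_lmm(y[ok], X[ok, , drop = FALSE], g[ok])
      nullf <- if (null_model == "random_intercept")
        fit_ri_lmm(y[ok], nullX[ok, , drop = FALSE], g[ok])
      else as.list(fixed_null_loglik(matrix(y[ok], ncol = 1)))
      row$converged <- isTRUE(fullf$converged)
      for (tm in terms) {
        row[[paste0("beta_", tm)]] <- unname(fullf$beta[tm])
        row[[paste0("p_", tm)]] <- unname(fullf$p[tm])
      }
      row$p_overall <- lrt_pvalue(fullf$logLik, nullf$logLik, df)
    }
    res[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  for (tm in c(terms, "overall")) {
    pr <- out[[paste0("p_", tm)]]
    s1 <- singles[out$m1, paste0("p_", tm)]
    s2 <- singles[out$m2, paste0("p_", tm)]
    out[[paste0("pgain_", tm)]] <- pmin(s1, s2) / pr
  }
  attr(out, "singles") <- singles
  attr(out, "scheme") <- scheme
  out
}

## ML log-likelihood of the intercept-only fixed model (no random effect)
fixed_null_loglik <- function(Y) {
  n <- nrow(Y)
  ss <- colSums(scale(Y, scale = FALSE)^2)
  list(logLik = -n / 2 * (log(2 * pi) + log(ss / n) + 1))
}

#' Apply the ratio/p-gain screen
#'
#' A pair passes when some component X in {time, temp, overall} (or just the
#' thaw count for the freeze-thaw scheme) has both `p_X < alpha / (n_terms *
#' n_pairs)` and `pgain_X > 10 * n_terms * n_pairs`.
#'
#' @param results output of [fit_ratio_models()].
#' @param n_pairs number of tested pairs (default `nrow(results)`).
#' @param n_terms tested components (default 3 for the handling scheme, 1
#'   for ftc, taken from the results attribute).
#' @param alpha familywise level (default 0.05).
#' @return `results` with a logical `passed_screen` column; the applied
#'   thresholds are attached as attributes `alpha_adj` and `pgain_min`, and
#'   attribute `note` records that the threshold is computed from the
#'   formula `alpha/(n_terms*n_pairs)`.
#' @export
screen_ratios <- function(results, n_pairs = nrow(results), n_terms = NULL,
                          alpha = 0.05) {
  scheme <- attr(results, "scheme")
  if (is.null(n_terms))
    n_terms <- if (identical(scheme, "ftc")) 1L else 3L
  alpha_adj <- ratio_alpha(n_pairs, n_terms, alpha)
  pg_min <- pgain_threshold(n_pairs, n_terms)
  comp <- if (identical(scheme, "ftc")) "ftc" else c("time", "temp", "overall")
  pass <- rep(FALSE, nrow(results))
  for (tm in comp) {
    p <- results[[paste0("p_", tm)]]
    pg <- results[[paste0("pgain_", tm)]]
    pass <- pass | (!is.na(p) & !is.na(pg) & p < alpha_adj & pg > pg_min)
  }
  results$passed_screen <- pass
  attr(results, "alpha_adj") <- alpha_adj
  attr(results, "pgain_min") <- pg_min
  attr(results, "note") <-
    "alpha_adj computed as alpha/(n_terms*n_pairs); with 8001 pairs and 3 terms this is 2.08e-6"
  results
}
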