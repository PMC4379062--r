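## Per-metabolite mixed-effects screening. The handling model regresses raw
## concentration (uM) on delay time (hours), temperature and their
## interaction with a participant random intercept; temperature is an
## ordered numeric score (dry ice = 0, wet ice = 1, RT = 2) so that the
## model carries a single temperature coefficient. The freeze-thaw model
## regresses concentration on the total thaw count (1-4).

temp_score <- function(temperature) {
  c(dry_ice = 0, wet_ice = 1, rt = 2)[temperature]
}

## The interaction column is centred at the design midpoints (24 h, wet ice)
## so that `time` and `temp` are average main effects over the observed
## design rather than extrapolations to 0 h on dry ice; the model space is
## identical to the raw product coding.
handling_design <- function(ann) {
  t <- ann$delay_h
  s <- unname(temp_score(ann$temperature))
  cbind(`(Intercept)` = 1, time = t, temp = s,
        `time:temp` = (t - 24) * (s - 1))
}

#' Bonferroni-adjusted significance threshold
#'
#' `0.05 / (n_terms * n_models)`: with 127 metabolites and the three fixed
#' effects of the handling model this is 1.3e-4; the freeze-thaw screen uses
#' one term per model, giving 3.9e-4.
#'
#' @param n_models number of models (retained metabolites).
#' @param n_terms tested fixed effects per model (3 for handling, 1 for ftc).
#' @param alpha familywise level (default 0.05).
#' @return the adjusted per-test threshold.
#' @export
bonferroni_alpha <- function(n_models, n_terms = 1, alpha = 0.05) {
  stopifnot(n_models >= 1, n_terms >= 1)
  alpha / (n_terms * n_models)
}

model_result_row <- function(metabolite, fit, terms) {
  out <- data.frame(metabolite = metabolite, converged = fit$converged)
  for (tm in terms) {
    out[[paste0("beta_", sub(":.*", "_int", tm))]] <- unname(fit$beta[tm])
    out[[paste0("p_", sub(":.*", "_int", tm))]] <- unname(fit$p[tm])
  }
  out
}

#' Fit the handling mixed model for every metabolite
#'
#' For each metabolite of the (QC-filtered) dataset, fits
#' `concentration ~ time + temp + time:temp + (1 | participant)` by ML on
#' the handling-condition samples only (reference aliquots carry no
#' temperature assignment and are excluded). Returns two-sided Wald p-values
#' per fixed coefficient. Metabolites with missing cells are fitted on their
#' complete rows; zero-variance metabolites are flagged as non-converged and
#' carry `NA` p-values.
#'
#' @param ds a filtered `concentration_dataset` with handling samples from
#'   at least two participants.
#' @return data.frame with one row per metabolite: `beta_time`, `p_time`,
#'   `beta_temp`, `p_temp`, `beta_time_int`, `p_time_int` (interaction),
#'   `direction` (sign of the temperature coefficient) and `converged`.
#' @export
fit_handling_models <- function(ds) {
  ann <- ds$annotations
  keep <- ann$role == "handling"
  if (length(unique(ann$participant[keep])) < 2)
    stop("need handling samples from at least two participants")
  Y <- ds$values[keep, , drop = FALSE]
  X <- handling_design(ann[keep, ])
  g <- factor(ann$participant[keep])
  res <- fit_models_matrix(Y, X, g, terms = c("time", "temp", "time:temp"))
  res$direction <- ifelse(!res$converged, "none",
                          ifelse(res$beta_temp >= 0, "+", "-"))
  res
}

#' Fit the freeze-thaw mixed model for every metabolite
#'
#' Fits `concentration ~ thaw_count + (1 | participant)` by ML on the
#' reference (one thaw) and freeze-thaw (2-4 thaws) aliquots.
#'
#' @param ds a filtered `concentration_dataset` with reference and ftc rows.
#' @return data.frame with `beta_ftc`, `p_ftc`, `converged` per metabolite.
#' @export
fit_ftc_models <- function(ds) {
  ann <- ds$annotations
  keep <- ann$role %in% c("reference", "ftc")
  if (!any(ann$role[keep] == "ftc")) stop("no freeze-thaw samples")
  Y <- ds$values[keep, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1, ftc = ann$thaw_count[keep])
  g <- factor(ann$participant[keep])
  res <- fit_models_matrix(Y, X, g, terms = "ftc")
  res
}

## shared driver: closed-form multi-fit on complete columns, general-path
## fallback for columns with missing cells
fit_models_matrix <- function(Y, X, g, terms) {
  M <- ncol(Y)
  complete <- !apply(is.na(Y), 2, any)
  varying <- apply(Y, 2, function(y) sd(y, na.rm = TRUE) > 1e-12)
  rows <- vector("list", M)
  if (any(complete & varying) && balanced_design(X, g)) {
    mf <- fit_ri_lmm_multi(Y[, complete & varying, drop = FALSE], X, g)
    for (j in which(complete & varying)) {
      k <- sum(complete & varying & seq_len(M) <= j)
      fit <- list(beta = mf$beta[, k], p = mf$p[, k],
                  converged = mf$converged[[k]])
      rows[[j]] <- model_result_row(colnames(Y)[[j]], fit, terms)
    }
  } else {
    for (j in which(complete & varying)) {
      fit <- fit_ri_lmm(Y[, j], X, g)
      rows[[j]] <- model_result_row(colnames(Y)[[j]], fit, terms)
    }
  }
  for (j in which(!complete & varying)) {
    fit <- tryCatch(fit_ri_lmm(Y[, j], X, g), error = function(e) NULL)
    if (is.null(fit))
      fit <- list(beta = setNames(rep(NA_real_, ncol(X)), colnames(X)),
                  p = setNames(rep(NA_real_, ncol(X)), colnames(X)),
                  converged = FALSE)
    rows[[j]] <- model_result_row(colnames(Y)[[j]], fit, terms)
  }
  for (j in which(!varying)) {
    fit <- list(beta = setNames(rep(0, ncol(X)), colnames(X)),
                p = setNames(rep(NA_real_, ncol(X)), colnames(X)),
                converged = FALSE)
    rows[[j]] <- model_result_row(colnames(Y)[[j]], fit, terms)
  }
  out <- do.call(rbind, rows)
  out <- out[match(colnames(Y), out$metabolite), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bonferroni screening of the per-metabolite model results
#'
#' Applies the familywise threshold `0.05 / (3 * M)` (handling scheme; three
#' fixed effects per model) or `0.05 / M` (freeze-thaw scheme) with `M` the
#' number of fitted metabolites, and groups significant metabolites into the
#' reporting tiers: temperature only, temperature + interaction, and
#' time + temperature + interaction.
#'
#' @param results output of [fit_handling_models()] or [fit_ftc_models()].
#' @param scheme `"handling"` or `"ftc"`.
#' @param alpha familywise level (default 0.05).
#' @return data.frame with one row per metabolite: `significant_terms`
#'   (comma-separated), `significant` (any term), `tier` (handling scheme
#'   only), `direction`, and the applied `alpha_adj` as an attribute.
#' @export
screen_metabolites <- function(results, scheme = c("handling", "ftc"),
                               alpha = 0.05) {
  scheme <- match.arg(scheme)
  if (!nrow(results)) {
    out <- data.frame(metabolite = character(), significant_terms = character(),
                      significant = logical(), tier = character(),
                      direction = character())
    attr(out, "alpha_adj") <- NA_real_
    return(out)
  }
  M <- nrow(results)
  if (scheme == "handling") {
    alpha_adj <- bonferroni_alpha(M, 3, alpha)
    sig_time <- !is.na(results$p_time) & results$p_time < alpha_adj
    sig_temp <- !is.na(results$p_temp) & results$p_temp < alpha_adj
    sig_int <- !is.na(results$p_time_int) & results$p_time_int < alpha_adj
    terms <- mapply(function(a, b, c)
      paste(c("time", "temp", "interaction")[c(a, b, c)], collapse = ","),
      sig_time, sig_temp, sig_int)
    tier <- rep("none", M)
    tier[sig_temp] <- "temp"
    tier[sig_temp & sig_int] <- "temp+interaction"
    tier[sig_temp & sig_int & sig_time] <- "time+temp+interaction"
    out <- data.frame(metabolite = results$metabolite,
                      significant_terms = terms,
                      significant = sig_time | sig_temp | sig_int,
                      tier = tier,
                      direction = ifelse(sig_temp,
                                         as.character(results$direction),
                                         "none"),
                      stringsAsFactors = FALSE)
  } else {
    alpha_adj <- bonferroni_alpha(M, 1, alpha)
    sig <- !is.na(results$p_ftc) & results$p_ftc < alpha_adj
    out <- data.frame(metabolite = results$metabolite,
                      significant_terms = ifelse(sig, "ftc", ""),
                      significant = sig,
                      direction = ifelse(sig,
                                         ifelse(results$beta_ftc >= 0, "+", "-"),
                                         "none"),
                      stringsAsFactors = FALSE)
  }
  attr(out, "alpha_adj") <- alpha_adj
  out
}
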