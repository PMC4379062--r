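#' Per-metabolite limit of detection
#'
#' The LOD of a metabolite is defined as 3 times the mean concentration of
#' the blank (zero) samples; missing cells are excluded from the mean. If all
#' zero-sample cells of a metabolite are missing its LOD is undefined (`NA`)
#' and the metabolite fails the LOD criterion downstream.
#'
#' @param ds a `concentration_dataset` containing at least one zero sample.
#' @return named numeric vector of LODs (uM).
#' @export
compute_lod <- function(ds) {
  zero <- ds$annotations$role == "zero"
  if (!any(zero)) stop("dataset contains no zero samples")
  3 * colMeans(ds$values[zero, , drop = FALSE], na.rm = TRUE)
}

#' Per-metabolite coefficient of variation in the pool samples
#'
#' CV = sample standard deviation (n-1 denominator) divided by the mean over
#' the pooled-serum replicates; missing cells are excluded. A zero mean
#' leaves the CV undefined (`NA`), which counts as a failure.
#'
#' @param ds a `concentration_dataset` containing at least two pool samples.
#' @return named numeric vector of CV fractions.
#' @export
compute_pool_cv <- function(ds) {
  pool <- ds$annotations$role == "pool"
  if (sum(pool) < 2) stop("need at least two pool samples")
  v <- ds$values[pool, , drop = FALSE]
  cv <- apply(v, 2, sd, na.rm = TRUE) / colMeans(v, na.rm = TRUE)
  cv[!is.finite(cv)] <- NA_real_
  cv
}

#' Apply the kit-level quality-control filters
#'
#' A metabolite is retained when (1) its pool-sample CV is strictly smaller
#' than `cv_max` and (2) at least `frac_min` of its measured (non-missing)
#' concentrations lie strictly above the limit of detection. By default the
#' above-LOD fraction is computed over every measured sample (subject, pool
#' and zero); `lod_scope = "subject"` restricts it to subject samples.
#'
#' @param ds a `concentration_dataset` with pool and zero samples.
#' @param cv_max pool-CV bound (default 0.25; a CV equal to the bound fails).
#' @param frac_min required above-LOD fraction (default 0.5; a fraction equal
#'   to the bound passes).
#' @param lod_scope `"all"` or `"subject"`.
#' @return list with `dataset` (the filtered dataset: failing metabolites and
#'   the pool/zero rows removed, ready for the modelling stages) and `report`
#'   (a `qc_report` data.frame: `metabolite`, `lod`, `pool_cv`,
#'   `frac_above_lod`, `passed`, `fail_reasons`).
#' @examples
#' res <- apply_qc(generate_worked_fixture())
#' subset(res$report, !passed)
#' @export
apply_qc <- function(ds, cv_max = 0.25, frac_min = 0.5,
                     lod_scope = c("all", "subject")) {
  lod_scope <- match.arg(lod_scope)
  lod <- compute_lod(ds)
  cv <- compute_pool_cv(ds)
  rows <- if (lod_scope == "all") rep(TRUE, nrow(ds$values))
          else ds$annotations$role %in% c("reference", "handling", "ftc")
  v <- ds$values[rows, , drop = FALSE]
  above <- sweep(v, 2, lod, `>`)
  frac <- colSums(above, na.rm = TRUE) / colSums(!is.na(v))
  frac[is.na(lod)] <- NA_real_

  cv_ok <- !is.na(cv) & cv < cv_max
  lod_ok <- !is.na(frac) & frac >= frac_min
  passed <- cv_ok & lod_ok
  reasons <- character(length(passed))
  reasons[!cv_ok] <- "cv"
  reasons[!lod_ok] <- ifelse(nzchar(reasons[!lod_ok]), "cv,lod", "lod")
  report <- data.frame(metabolite = ds$panel$id, lod = unname(lod),
                       pool_cv = unname(cv), frac_above_lod = unname(frac),
                       passed = unname(passed), fail_reasons = reasons,
                       stringsAsFactors = FALSE)
  class(report) <- c("qc_report", "data.frame")
  filtered <- subset_metabolites(drop_qc_samples(ds),
                                 ds$panel$id[passed])
  list(dataset = filtered, report = report)
}
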