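SAMPLE_ROLES <- c("reference", "handling", "ftc", "pool", "zero")
TEMPERATURES <- c("dry_ice", "wet_ice", "rt", "na")

#' Construct a concentration dataset
#'
#' Bundles a metabolite panel, a sample sheet and a samples-by-metabolites
#' concentration matrix (micromolar). Concentrations are nonnegative; missing
#' measurements are `NA` and are never imputed.
#'
#' @param panel a `panel_definition` (see [build_p150_panel()]).
#' @param annotations data.frame with columns `sample_id`, `participant`,
#'   `role` (`reference`, `handling`, `ftc`, `pool`, `zero`), `temperature`
#'   (`dry_ice`, `wet_ice`, `rt`, `na`), `delay_h` (0/12/24/36), `thaw_count`
#'   (1--4) and `plate`.
#' @param values numeric matrix, rows matching `annotations$sample_id`,
#'   columns matching `panel$id`.
#' @return a `concentration_dataset` object.
#' @export
concentration_dataset <- function(panel, annotations, values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  ds <- structure(list(panel = panel, annotations = annotations, values = values),
                  class = "concentration_dataset")
  validate_dataset(ds)
  ds
}

#' Validate a concentration dataset
#'
#' Enforces the design invariants: row/column alignment with the sample sheet
#' and panel, nonnegative concentrations, and the role-specific annotation
#' rules (handling aliquots have a temperature and a 12/24/36 h delay,
#' reference aliquots are thawed once with no delay, freeze-thaw aliquots
#' carry 2--4 thaws at zero delay, and all aliquots of one participant sit on
#' a single plate).
#'
#' @param ds a `concentration_dataset`.
#' @return `ds` invisibly; errors describe the first violation found.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "concentration_dataset"))
  ann <- ds$annotations
  need <- c("sample_id", "participant", "role", "temperature", "delay_h",
            "thaw_count", "plate")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("sample sheet lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(ann$sample_id[duplicated(ann$sample_id)]), collapse = ", "))
  if (nrow(ds$values) != nrow(ann))
    stop("value matrix has ", nrow(ds$values), " rows but sample sheet has ",
         nrow(ann))
  if (nrow(ds$values) > 0 &&
      !identical(rownames(ds$values), as.character(ann$sample_id)))
    stop("value matrix rownames must equal sample sheet sample_id, in order")
  if (ncol(ds$values) > 0 && !identical(colnames(ds$values), ds$panel$id))
    stop("value matrix columns must equal panel ids, in order")
  if (ncol(ds$values) == 0 && nrow(ds$panel) > 0)
    stop("value matrix columns must equal panel ids, in order")
  if (any(ds$values < 0, na.rm = TRUE)) stop("negative concentration values")
  badrole <- setdiff(unique(ann$role), SAMPLE_ROLES)
  if (length(badrole)) stop("unknown role: ", paste(badrole, collapse = ", "))
  badtemp <- setdiff(unique(ann$temperature), TEMPERATURES)
  if (length(badtemp)) stop("unknown temperature: ", paste(badtemp, collapse = ", "))

  h <- ann$role == "handling"
  if (any(h & (!ann$temperature %in% c("dry_ice", "wet_ice", "rt") |
               !ann$delay_h %in% c(12, 24, 36))))
    stop("handling samples need temperature dry_ice/wet_ice/rt and delay 12/24/36 h")
  r <- ann$role == "reference"
  if (any(r & (ann$delay_h != 0 | ann$thaw_count != 1)))
    stop("reference samples must have delay_h = 0 and thaw_count = 1")
  f <- ann$role == "ftc"
  if (any(f & (!ann$thaw_count %in% 2:4 | ann$delay_h != 0)))
    stop("ftc samples must have thaw_count in 2..4 and delay_h = 0")
  subj <- ann[ann$role %in% c("reference", "handling", "ftc"), ]
  if (nrow(subj)) {
    plates <- tapply(subj$plate, subj$participant, function(p) length(unique(p)))
    if (any(plates > 1))
      stop("all samples of one participant must share one plate; violated for: ",
           paste(names(plates)[plates > 1], collapse = ", "))
  }
  invisible(ds)
}

#' @export
print.concentration_dataset <- function(x, ...) {
  cat("concentration_dataset:", nrow(x$values), "samples x",
      ncol(x$values), "metabolites\n")
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$annotations$role)),
                                table(x$annotations$role)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a concentration dataset from CSV files
#'
#' The concentration table is a CSV with a `sample_id` column followed by one
#' column per metabolite (micromolar; empty cells are missing values, not
#' zeros). The sample sheet is a CSV with the annotation columns of
#' [concentration_dataset()]. The two are joined on `sample_id`; metabolite
#' columns must be a subset of the panel.
#'
#' @param concentration_file path to the concentration CSV.
#' @param sample_sheet_file path to the sample-sheet CSV.
#' @param panel a `panel_definition`; the dataset panel is restricted to the
#'   columns present in the file, in panel order.
#' @return a validated `concentration_dataset`.
#' @export
read_dataset <- function(concentration_file, sample_sheet_file, panel) {
  conc <- read.csv(concentration_file, check.names = FALSE,
                   stringsAsFactors = FALSE)
  sheet <- read.csv(sample_sheet_file, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(conc))
    stop("concentration table lacks a sample_id column")
  mets <- setdiff(names(conc), "sample_id")
  unknown <- setdiff(mets, panel$id)
  if (length(unknown))
    stop("metabolite columns not in panel: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  if (!setequal(sheet$sample_id, conc$sample_id))
    stop("sample_id sets of concentration table and sample sheet differ")
  conc <- conc[match(sheet$sample_id, conc$sample_id), , drop = FALSE]
  keep <- panel$id[panel$id %in% mets]
  values <- as.matrix(conc[, keep, drop = FALSE])
  rownames(values) <- as.character(sheet$sample_id)
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$participant <- as.character(sheet$participant)
  sheet$plate <- as.character(sheet$plate)
  concentration_dataset(panel_subset(panel, keep), sheet, values)
}

#' Write a concentration dataset to CSV files
#'
#' Inverse of [read_dataset()]: values are written at full precision (17
#' significant digits) so a read/write round trip reproduces them exactly;
#' missing cells are written as empty fields.
#'
#' @param ds a `concentration_dataset`.
#' @param concentration_file,sample_sheet_file output paths.
#' @return the two paths, invisibly.
#' @export
write_dataset <- function(ds, concentration_file, sample_sheet_file) {
  validate_dataset(ds)
  vals <- as.data.frame(ds$values, check.names = FALSE)
  out <- cbind(sample_id = rownames(ds$values), vals)
  ## full-precision decimal text so that read(write(ds)) == ds bitwise
  for (j in seq_along(out)[-1]) {
    x <- out[[j]]
    s <- sprintf("%.17g", x)
    s[is.na(x)] <- NA_character_
    out[[j]] <- s
  }
  write.csv(out, concentration_file, row.names = FALSE, na = "", quote = TRUE)
  write.csv(ds$annotations, sample_sheet_file, row.names = FALSE, na = "",
            quote = TRUE)
  invisible(c(concentration_file, sample_sheet_file))
}

#' Drop pool and zero samples
#'
#' Returns the subject-only dataset (reference, handling and freeze-thaw
#' aliquots) used by the downstream modelling stages.
#'
#' @param ds a `concentration_dataset`.
#' @return a `concentration_dataset` without pool/zero rows.
#' @export
drop_qc_samples <- function(ds) {
  keep <- ds$annotations$role %in% c("reference", "handling", "ftc")
  subset_samples(ds, keep)
}

subset_samples <- function(ds, keep) {
  ann <- ds$annotations[keep, , drop = FALSE]
  rownames(ann) <- NULL
  concentration_dataset(ds$panel, ann, ds$values[keep, , drop = FALSE])
}

#' Restrict a dataset to a set of metabolites
#'
#' @param ds a `concentration_dataset`.
#' @param ids metabolite ids to keep (panel order is preserved).
#' @return a `concentration_dataset` with the reduced panel.
#' @export
subset_metabolites <- function(ds, ids) {
  keep <- ds$panel$id[ds$panel$id %in% ids]
  concentration_dataset(panel_subset(ds$panel, keep), ds$annotations,
                        ds$values[, keep, drop = FALSE])
}
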