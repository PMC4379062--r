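## Metabolite classes of the p150-style targeted panel. Lipid classes carry a
## carbon:double-bond annotation parsed from the short name.
PANEL_CLASSES <- c("amino_acid", "hexose", "carnitine", "acylcarnitine",
                   "sphingomyelin", "pc_aa", "pc_ae", "lyso_pc")
LIPID_CLASSES <- c("acylcarnitine", "sphingomyelin", "pc_aa", "pc_ae", "lyso_pc")

#' Parse the carbon and double-bond annotation of a lipid short name
#'
#' Lipid short names encode the total number of carbon atoms and double bonds
#' in the fatty-acid side chain(s) as `x:y`, e.g. `"PC(38:4)"` has 38 carbons
#' and 4 double bonds. Plain acylcarnitine names such as `"C4"` or `"C4-OH"`
#' have zero double bonds.
#'
#' @param id character vector of short names.
#' @return data.frame with integer columns `carbons` and `double_bonds`
#'   (`NA` where the name carries no chain annotation).
#' @examples
#' parse_chain(c("PC(38:4)", "lysoPC(18:0)", "C4-OH", "Gln"))
#' @export
parse_chain <- function(id) {
  m <- regmatches(id, regexpr("[0-9]+:[0-9]+", id))
  has <- regexpr("[0-9]+:[0-9]+", id) > 0
  carbons <- rep(NA_integer_, length(id))
  double_bonds <- rep(NA_integer_, length(id))
  if (any(has)) {
    parts <- strsplit(m, ":", fixed = TRUE)
    carbons[has] <- vapply(parts, function(p) as.integer(p[[1]]), integer(1))
    double_bonds[has] <- vapply(parts, function(p) as.integer(p[[2]]), integer(1))
  }
  ## "C4", "C4-OH": carbon count without a double-bond annotation
  plain <- !has & grepl("^C[0-9]+", id)
  if (any(plain)) {
    carbons[plain] <- as.integer(sub("^C([0-9]+).*$", "\\1", id[plain]))
    double_bonds[plain] <- 0L
  }
  data.frame(carbons = carbons, double_bonds = double_bonds)
}

p150_names <- function() {
  aa <- c(Arg = "Arginine", Gln = "Glutamine", Gly = "Glycine",
          His = "Histidine", Met = "Methionine", Orn = "Ornithine",
          Phe = "Phenylalanine", Pro = "Proline", Ser = "Serine",
          Thr = "Threonine", Trp = "Tryptophan", Tyr = "Tyrosine",
          Val = "Valine", `Leu+Ile` = "Leucine+Isoleucine")
  ac <- c("C2", "C3", "C3:1", "C3-OH", "C4", "C4:1", "C4-OH", "C5", "C5:1",
          "C5:1-DC", "C5-DC", "C5-M-DC", "C5-OH", "C6", "C6:1", "C7-DC",
          "C8", "C8:1", "C9", "C10", "C10:1", "C10:2", "C12", "C12:1",
          "C12-DC", "C14", "C14:1", "C14:1-OH", "C14:2", "C14:2-OH",
          "C16", "C16:1", "C16:1-OH", "C16:2", "C16:2-OH", "C16-OH",
          "C18", "C18:1", "C18:1-OH", "C18:2")
  sm <- c("SM(16:0)", "SM(16:1)", "SM(18:0)", "SM(18:1)", "SM(20:2)",
          "SM(22:3)", "SM(24:0)", "SM(24:1)", "SM(26:0)", "SM(26:1)",
          "SM(OH-14:1)", "SM(OH-16:1)", "SM(OH-22:1)", "SM(OH-22:2)",
          "SM(OH-24:1)")
  pc_aa <- paste0("PC(", c("24:0", "26:0", "28:1", "30:0", "30:2", "32:0",
                           "32:1", "32:2", "32:3", "34:1", "34:2", "34:3",
                           "34:4", "36:0", "36:1", "36:2", "36:3", "36:4",
                           "36:5", "36:6", "38:0", "38:1", "38:3", "38:4",
                           "38:5", "38:6", "40:1", "40:2", "40:3", "40:4",
                           "40:5", "40:6", "42:0", "42:1", "42:2", "42:4",
                           "42:5", "42:6"), ")")
  pc_ae <- paste0("PC(O-", c("30:0", "30:1", "30:2", "32:1", "32:2", "34:0",
                             "34:1", "34:2", "34:3", "36:0", "36:1", "36:2",
                             "36:3", "36:4", "36:5", "38:0", "38:1", "38:2",
                             "38:3", "38:4", "38:5", "38:6", "40:1", "40:2",
                             "40:3", "40:4", "40:5", "40:6", "40:7", "42:0",
                             "42:1", "42:2", "42:3", "42:4", "42:5", "44:3",
                             "44:4", "44:5", "44:6"), ")")
  lyso <- paste0("lysoPC(", c("6:0", "14:0", "16:0", "16:1", "17:0", "18:0",
                              "18:1", "18:2", "20:3", "20:4", "24:0", "26:0",
                              "26:1", "28:0", "28:1"), ")")
  list(aa = aa, ac = ac, sm = sm, pc_aa = pc_aa, pc_ae = pc_ae, lyso = lyso)
}

#' Build the 163-metabolite p150-style panel
#'
#' Returns the panel of 163 serum metabolites quantified by the targeted
#' FIA-MS/MS kit this package models: 14 amino acids, the hexose sum, free
#' carnitine, 40 acylcarnitines, 15 sphingomyelins, 77 phosphatidylcholines
#' (diacyl `pc_aa` plus acyl-alkyl `pc_ae`) and 15 lysophosphatidylcholines.
#' Short names follow the `x:y` carbon:double-bond convention; isobaric
#' species with equal chain sums are quantified as one measure.
#'
#' @return A `panel_definition`: data.frame with columns `id`, `full_name`,
#'   `mclass`, `carbons`, `double_bonds`, one row per metabolite.
#' @examples
#' panel <- build_p150_panel()
#' nrow(panel)           # 163
#' table(panel$mclass)
#' @export
build_p150_panel <- function() {
  nm <- p150_names()
  full_pref <- function(prefix, ids) paste(prefix, ids)
  ac_full <- full_pref("Acylcarnitine", nm$ac)
  ac_full[nm$ac == "C10:2"] <- "Decadienylcarnitine"
  rows <- rbind(
    data.frame(id = names(nm$aa), full_name = unname(nm$aa), mclass = "amino_acid"),
    data.frame(id = "H1", full_name = "Sum of hexoses", mclass = "hexose"),
    data.frame(id = "C0", full_name = "Free carnitine", mclass = "carnitine"),
    data.frame(id = nm$ac, full_name = ac_full, mclass = "acylcarnitine"),
    data.frame(id = nm$sm, full_name = full_pref("Sphingomyelin", nm$sm),
               mclass = "sphingomyelin"),
    data.frame(id = nm$pc_aa, full_name = full_pref("Diacylphosphatidylcholine", nm$pc_aa),
               mclass = "pc_aa"),
    data.frame(id = nm$pc_ae,
               full_name = full_pref("Acylalkylphosphatidylcholine", nm$pc_ae),
               mclass = "pc_ae"),
    data.frame(id = nm$lyso,
               full_name = full_pref("Lysophosphatidylcholine", nm$lyso),
               mclass = "lyso_pc")
  )
  chain <- parse_chain(rows$id)
  chain[!(rows$mclass %in% LIPID_CLASSES), ] <- NA_integer_
  panel <- cbind(rows, chain)
  rownames(panel) <- NULL
  class(panel) <- c("panel_definition", "data.frame")
  validate_panel(panel)
  panel
}

#' Validate a panel definition
#'
#' Checks id uniqueness, known classes, and that the carbon/double-bond
#' annotation is present exactly for the lipid classes.
#'
#' @param panel a `panel_definition` data.frame.
#' @return the panel, invisibly; errors on violation.
#' @export
validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("id", "full_name", "mclass", "carbons", "double_bonds")
                %in% names(panel)))
  if (anyDuplicated(panel$id))
    stop("duplicate metabolite ids in panel: ",
         paste(unique(panel$id[duplicated(panel$id)]), collapse = ", "))
  bad <- setdiff(unique(panel$mclass), PANEL_CLASSES)
  if (length(bad)) stop("unknown metabolite class: ", paste(bad, collapse = ", "))
  lipid <- panel$mclass %in% LIPID_CLASSES
  if (any(lipid & (is.na(panel$carbons) | is.na(panel$double_bonds))))
    stop("lipid-class metabolites must carry carbons/double_bonds")
  if (any(!lipid & (!is.na(panel$carbons) | !is.na(panel$double_bonds))))
    stop("non-lipid metabolites must not carry carbons/double_bonds")
  if (any(stats::na.omit(panel$carbons) < 0) ||
      any(stats::na.omit(panel$double_bonds) < 0))
    stop("carbons/double_bonds must be nonnegative")
  invisible(panel)
}

#' Subset a panel by metabolite id
#'
#' @param panel a `panel_definition`.
#' @param ids metabolite ids to keep, in the given order.
#' @return a `panel_definition` restricted to `ids`.
#' @export
panel_subset <- function(panel, ids) {
  missing <- setdiff(ids, panel$id)
  if (length(missing))
    stop("ids not in panel: ", paste(missing, collapse = ", "))
  out <- panel[match(ids, panel$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("panel_definition", "data.frame")
  out
}
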