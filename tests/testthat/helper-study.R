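# Shared fixtures: the implanted degradation signature and small builders.

implanted_metabolites <- function() {
  c("lysoPC(14:0)", "lysoPC(16:0)", "lysoPC(16:1)", "lysoPC(17:0)",
    "lysoPC(18:0)", "lysoPC(18:1)", "lysoPC(20:3)", "lysoPC(20:4)",
    "PC(30:0)", "PC(32:0)", "PC(32:1)", "PC(32:2)", "PC(34:2)",
    "PC(34:3)", "PC(34:4)", "PC(36:5)", "PC(O-34:1)",
    "Arg", "Gly", "Orn", "Phe", "Ser", "Leu+Ile", "C10:2")
}

## a small panel of QC-passing metabolites for fast ratio-stage tests
mini_panel_ids <- function() {
  c("Gln", "Ser", "Orn", "lysoPC(18:0)", "PC(34:2)", "SM(16:0)")
}

mini_config <- function(seed = 1, ...) {
  ## small panels trip the donor-dominance advisory; irrelevant here
  suppressWarnings(
    generator_config(panel = panel_subset(build_p150_panel(),
                                          mini_panel_ids()),
                     seed = seed, ...))
}

## average silhouette width of a labelled point set (euclidean)
mean_silhouette <- function(x, labels) {
  d <- as.matrix(dist(x))
  n <- nrow(x)
  widths <- vapply(seq_len(n), function(i) {
    own <- labels == labels[[i]]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(unique(labels[!own]), function(l)
      mean(d[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(widths)
}
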