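#' Pipeline run configuration
#'
#' Assembles the settings of a full analysis run. Unknown argument names are
#' rejected so that a mistyped threshold cannot silently fall back to a
#' default.
#'
#' @param generator a [generator_config()] (ignored when `concentration_file`
#'   is given).
#' @param concentration_file,sample_sheet_file optional CSV inputs; when set,
#'   simulation is skipped and the files are read with [read_dataset()].
#' @param cv_max,frac_min,lod_scope QC settings (see [apply_qc()]).
#' @param schemes which screens to run: subset of `c("handling", "ftc")`.
#' @param split_train,split_test participant id sets; `NULL` uses
#'   [default_split()] on the dataset's participants.
#' @param top_k number of top-ranked variables handed to the tree (10).
#' @param n_iter,n_trees,m_try,full_scale Random-Forest settings
#'   (see [rank_variables()]).
#' @param minbucket,cp tree settings (see [fit_quality_tree()]).
#' @param seed master seed for every stochastic stage.
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @return a `run_config` list.
#' @export
run_config <- function(generator = generator_config(),
                       concentration_file = NULL, sample_sheet_file = NULL,
                       cv_max = 0.25, frac_min = 0.5, lod_scope = "all",
                       schemes = c("handling", "ftc"),
                       split_train = NULL, split_test = NULL,
                       top_k = 10, n_iter = 20, n_trees = 501, m_try = 80,
                       full_scale = FALSE, minbucket = 5, cp = 0.01,
                       seed = 1, out_dir = NULL) {
  stopifnot(cv_max > 0, frac_min >= 0, top_k >= 1, n_iter >= 1,
            n_trees >= 1, m_try >= 1,
            all(schemes %in% c("handling", "ftc")))
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' simulate (or read) -> quality control -> per-metabolite mixed-model
#' screens -> all-pairs ratio models and p-gain screen -> two-stage
#' Random-Forest + tree classification -> held-out condition table. Returns
#' a structured run report; with `config$out_dir` set, also writes the
#' dataset CSV pair, the QC report, the association and ratio tables, the
#' importance ranking, the tree (JSON) and the per-sample classification.
#'
#' @param config a [run_config()].
#' @return a `run_report` list with per-stage results and counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  report <- list(parameters = list(seed = config$seed, cv_max = config$cv_max,
                                   frac_min = config$frac_min,
                                   top_k = config$top_k),
                 warnings = character())

  ds <- if (!is.null(config$concentration_file)) {
    read_dataset(config$concentration_file, config$sample_sheet_file,
                 config$generator$panel)
  } else {
    gen <- config$generator
    gen$seed <- stream_seed(config$seed, "generate")
    generate_study(gen)
  }
  report$n_samples <- nrow(ds$values)
  report$n_metabolites_measured <- ncol(ds$values)

  qc <- apply_qc(ds, config$cv_max, config$frac_min, config$lod_scope)
  report$qc <- qc$report
  report$n_retained <- sum(qc$report$passed)
  fds <- qc$dataset

  participants <- unique(fds$annotations$participant)
  split <- if (is.null(config$split_train)) default_split(participants)
           else split_participants(participants, config$split_train,
                                   config$split_test)
  report$split <- split

  if ("handling" %in% config$schemes) {
    assoc <- fit_handling_models(fds)
    screen <- screen_metabolites(assoc, "handling")
    report$association <- assoc
    report$assoc_screen <- screen
    report$n_significant_temp <-
      sum(grepl("temp", screen$significant_terms, fixed = TRUE))
    ratios <- screen_ratios(fit_ratio_models(fds, "handling"))
    report$ratios <- ratios
    report$n_pairs <- nrow(ratios)
    report$n_pass_ratio_screen <- sum(ratios$passed_screen, na.rm = TRUE)
    if (report$n_pairs != report$n_retained * (report$n_retained - 1) / 2)
      stop("pair count inconsistent with retained metabolite count")

    features <- build_feature_table(fds, ratios)
    lab_str <- label_samples(fds, "stringent")
    lab_non <- label_samples(fds, "non_stringent")
    ranking <- rank_variables(features, lab_str,
                              participants = split$train,
                              n_iter = config$n_iter,
                              n_trees = config$n_trees,
                              m_try = config$m_try,
                              seed = stream_seed(config$seed, "rf"),
                              full_scale = config$full_scale)
    top <- ranking$variable[seq_len(min(config$top_k, nrow(ranking)))]
    tree <- fit_quality_tree(features, lab_non, top,
                             participants = split$train,
                             minbucket = config$minbucket, cp = config$cp)
    rate_for <- function(ids) {
      f <- features[features$participant %in% ids, , drop = FALSE]
      pred <- predict_quality(tree, f)$predicted
      lab <- lab_non$label[match(f$sample_id, lab_non$sample_id)]
      misclassification_rate(pred, lab)
    }
    report$features <- features
    report$labels_nonstringent <- lab_non
    report$label_counts <- table(
      lab_non$label[lab_non$participant %in% split$train])
    report$ranking <- ranking
    report$top_variables <- top
    report$tree <- tree
    report$train_misclassification <- rate_for(split$train)
    report$test_misclassification <- rate_for(split$test)
    report$heldout <- apply_to_heldout(tree, features)
  }
  if ("ftc" %in% config$schemes) {
    ftc <- fit_ftc_models(fds)
    report$ftc <- ftc
    report$ftc_screen <- screen_metabolites(ftc, "ftc")
    report$n_significant_ftc <- sum(report$ftc_screen$significant)
    ftc_ratios <- screen_ratios(fit_ratio_models(fds, "ftc"))
    report$n_pass_ftc_ratio_screen <-
      sum(ftc_ratios$passed_screen, na.rm = TRUE)
  }
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_artifacts(report, ds, config)
  report
}

write_artifacts <- function(report, ds, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  write_dataset(ds, p("concentrations.csv"), p("sample_sheet.csv"))
  write.csv(report$qc, p("qc_report.csv"), row.names = FALSE)
  if (!is.null(report$association))
    write.csv(report$association, p("association.csv"), row.names = FALSE)
  if (!is.null(report$ratios))
    write.csv(report$ratios, p("ratios.csv"), row.names = FALSE)
  if (!is.null(report$ranking))
    write.csv(report$ranking, p("importance.csv"), row.names = FALSE)
  if (!is.null(report$tree)) {
    jsonlite::write_json(list(splits = report$tree$splits,
                              rules = tree_rules(report$tree)),
                         p("tree.json"), auto_unbox = TRUE, digits = NA)
    preds <- predict_quality(report$tree, report$features)
    write.csv(preds, p("classification.csv"), row.names = FALSE)
  }
  writeLines(make_report(report), p("run_report.md"))
  invisible(NULL)
}

#' Render a run report as markdown text
#'
#' Plain-text summary of a pipeline run: QC counts, the significance tiers
#' of the handling screen, ratio-screen counts, the top-ranked variables,
#' the fitted decision rule, misclassification rates and the held-out
#' condition table.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @return character vector of markdown lines.
#' @export
make_report <- function(report) {
  out <- c("# Pre-analytical quality pipeline run", "",
           sprintf("- samples: %d; metabolites measured: %d; retained after QC: %d",
                   report$n_samples, report$n_metabolites_measured,
                   report$n_retained))
  if (!is.null(report$assoc_screen)) {
    tiers <- table(report$assoc_screen$tier)
    out <- c(out, "", "## Handling screen",
             sprintf("- Bonferroni threshold: %.3g",
                     attr(report$assoc_screen, "alpha_adj")),
             sprintf("- significant for temperature: %d",
                     report$n_significant_temp),
             sprintf("- tiers: %s",
                     paste(sprintf("%s=%d", names(tiers), tiers),
                           collapse = ", ")),
             "", "## Ratio screen",
             sprintf("- pairs tested: %d; passing p-value and p-gain screen: %d",
                     report$n_pairs, report$n_pass_ratio_screen))
    if (report$n_pass_ratio_screen == 0)
      out <- c(out, "- zero passing pairs")
  }
  if (!is.null(report$tree)) {
    rules <- tree_rules(report$tree)
    out <- c(out, "", "## Classification",
             sprintf("- top variables: %s",
                     paste(report$top_variables, collapse = ", ")),
             if (length(rules)) paste0("- rule: ", rules)
             else "- rule: tree never predicts bad",
             sprintf("- training misclassification: %.3f (%d/%d)",
                     report$train_misclassification$rate,
                     report$train_misclassification$errors,
                     report$train_misclassification$n),
             sprintf("- test misclassification: %.3f (%d/%d)",
                     report$test_misclassification$rate,
                     report$test_misclassification$errors,
                     report$test_misclassification$n))
    if (nrow(report$heldout))
      out <- c(out, "- held-out conditions:",
               sprintf("    %s: %d good / %d bad", report$heldout$condition,
                       report$heldout$n_good, report$heldout$n_bad))
  }
  if (!is.null(report$ftc_screen)) {
    out <- c(out, "", "## Freeze-thaw screen",
             sprintf("- significant metabolites: %d", report$n_significant_ftc),
             sprintf("- ratio pairs passing the freeze-thaw screen: %d%s",
                     report$n_pass_ftc_ratio_screen,
                     if (report$n_pass_ftc_ratio_screen == 0)
                       " (none passed)" else ""))
  }
  out
}
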