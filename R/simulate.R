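## Synthetic study generator. Emulates the serum handling experiment: 19
## donors contribute 13 aliquots each (1 reference, 9 handling-condition
## aliquots = {dry ice, wet ice, RT} x {12, 24, 36 h}, 3 freeze-thaw aliquots
## with 2-4 total thaws), plus 5 pooled-serum and 3 blank (zero) samples on
## each of 4 plates. Concentrations follow a multiplicative (log-normal)
## model: log x = log baseline + donor effects + treatment(temp, delay)
##              + ftc_slope * (thaws - 1) + plate effect + noise.
## Donor effects decompose into a shared level (one factor per donor, common
## to all metabolites -- this is what makes samples cluster by donor in PCA
## and what concentration ratios cancel), a class-level component and a
## metabolite-specific component.

## deterministic per-stage RNG streams derived from one master seed
stream_seed <- function(master, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147480009
  as.integer((abs(as.numeric(master)) * 1000003 + h) %% 2147480009)
}

#' Describe the degradation behaviour of a metabolite or class
#'
#' A profile gives the room-temperature log-concentration trend of one
#' metabolite (or a whole class), how much that trend is attenuated on wet
#' ice and when the wet-ice effect begins. Dry ice is always the null
#' condition. Metabolite-level profiles override class-level ones.
#'
#' @param target metabolite id (e.g. `"Ser"`) or class name (e.g. `"lyso_pc"`).
#' @param rt_jump log-concentration change reached after 12 h at room
#'   temperature (the fast initial phase; ramps linearly over 0--12 h).
#' @param rt_slope additional per-hour change of log concentration beyond
#'   12 h at room temperature. `rt_slope = 0` gives a step that plateaus
#'   after the early phase.
#' @param wet_attenuation factor in `[0, 1]` applied to the whole trajectory
#'   on wet ice.
#' @param onset_h hours of wet-ice delay before the attenuated effect begins
#'   (the trajectory is shifted by this lag).
#' @param coupling logical; on a lysophosphatidylcholine profile, marks the
#'   increase as hydrolysis product drawn from the diacyl-PC pool; on a
#'   diacyl-PC profile, marks that species as part of the donating pool whose
#'   decrease is then derived from mass balance (its own `rt_jump`/`rt_slope`
#'   are used only when coupling is disabled in the generator).
#' @return a `degradation_profile` list.
#' @export
degradation_profile <- function(target, rt_jump = 0, rt_slope = 0,
                                wet_attenuation = 0.05, onset_h = 24,
                                coupling = FALSE) {
  stopifnot(wet_attenuation >= 0, wet_attenuation <= 1, onset_h >= 0)
  structure(list(target = target, rt_jump = rt_jump, rt_slope = rt_slope,
                 wet_attenuation = wet_attenuation, onset_h = onset_h,
                 coupling = coupling),
            class = "degradation_profile")
}

## log-effect of a profile after `hours` of its active phase
profile_trajectory <- function(jump, slope, hours) {
  jump * pmin(pmax(hours, 0) / 12, 1) + slope * pmax(hours - 12, 0)
}

#' Default degradation profiles
#'
#' Encodes the qualitative room-temperature degradation signature the
#' generator implants. Trajectories are two-phase (a fast change reaching
#' `rt_jump` by 12 h, then `rt_slope` per hour), reflecting that the
#' characteristic concentration changes are already visible after 12 h of
#' RT exposure: all lysophosphatidylcholines except lysoPC(18:2) increase; a
#' set of diacyl-phosphatidylcholines decreases (by mass balance with the
#' lysoPC gain when coupling is on); Arg, Gly, Orn, Phe, Ser and Leu+Ile
#' increase; Gln drifts slightly down (kept below single-metabolite
#' significance at the default study size); PC(O-34:1) decreases weakly;
#' C10:2 drops early and then plateaus. Wet-ice effects are strongly
#' attenuated (15% of the RT trajectory) and start only after 24 h (C10:2
#' excepted); dry ice is the null condition. With the default baselines the expected
#' tLyso/tPC trajectory at RT crosses 0.12 between 12 h and 24 h and Gln/Ser
#' falls below 4.71 by 24 h.
#'
#' @return named list of [degradation_profile()] objects.
#' @export
default_profiles <- function() {
  couple_sinks <- c("PC(30:0)", "PC(32:0)", "PC(32:1)", "PC(32:2)",
                    "PC(34:2)", "PC(34:3)", "PC(34:4)", "PC(36:5)")
  pr <- c(
    list(degradation_profile("lyso_pc", 0.20, 0.035, coupling = TRUE),
         degradation_profile("lysoPC(18:2)", 0, 0)),
    lapply(couple_sinks, degradation_profile, rt_jump = -0.10,
           rt_slope = -0.010, coupling = TRUE),
    list(degradation_profile("PC(O-34:1)", -0.15, -0.010),
         degradation_profile("Arg", 0.18, 0.009),
         degradation_profile("Gly", 0.20, 0.010),
         degradation_profile("Orn", 0.20, 0.010),
         degradation_profile("Phe", 0.22, 0.011),
         degradation_profile("Ser", 0.24, 0.012),
         degradation_profile("Leu+Ile", 0.16, 0.008),
         degradation_profile("Gln", -0.04, -0.0012),
         degradation_profile("C10:2", -0.25, 0, wet_attenuation = 0.3,
                             onset_h = 0))
  )
  names(pr) <- vapply(pr, `[[`, "", "target")
  pr
}

## Baseline serum concentrations (uM) for the metabolites that pass quality
## control, plus the two CV-failure metabolites. Panel metabolites absent
## from this table default to a trace level near the blank background and
## fail the LOD criterion by construction (emulating the kit's
## below-detection analytes).
default_baselines <- function() {
  c(Arg = 100, Gln = 560, Gly = 250, His = 80, Met = 25, Orn = 60, Phe = 60,
    Pro = 180, Ser = 110, Thr = 130, Trp = 60, Tyr = 65, Val = 230,
    `Leu+Ile` = 180,
    H1 = 4600, C0 = 35,
    C2 = 7, C3 = 0.35, C4 = 0.2, C5 = 0.12, C6 = 0.06, C8 = 0.12,
    C10 = 0.25, `C10:1` = 0.12, `C10:2` = 0.05, C12 = 0.1, C14 = 0.035,
    `C14:1` = 0.08, `C14:2` = 0.02, C16 = 0.1, `C16:1` = 0.03, C18 = 0.045,
    `C18:1` = 0.1, `C18:2` = 0.035, `C4-OH` = 0.05, `C5-OH` = 0.03,
    `SM(16:0)` = 110, `SM(16:1)` = 15, `SM(18:0)` = 25, `SM(18:1)` = 12,
    `SM(20:2)` = 15, `SM(22:3)` = 20, `SM(24:0)` = 22, `SM(24:1)` = 45,
    `SM(26:1)` = 8,
    `SM(OH-14:1)` = 6, `SM(OH-16:1)` = 3.5, `SM(OH-22:1)` = 12,
    `SM(OH-22:2)` = 10, `SM(OH-24:1)` = 1.5,
    `PC(28:1)` = 3, `PC(30:0)` = 4, `PC(30:2)` = 0.5, `PC(32:0)` = 15,
    `PC(32:1)` = 20, `PC(32:2)` = 5, `PC(32:3)` = 0.5, `PC(34:1)` = 230,
    `PC(34:2)` = 550, `PC(34:3)` = 15, `PC(34:4)` = 2.5, `PC(36:0)` = 2.5,
    `PC(36:1)` = 45, `PC(36:2)` = 150, `PC(36:3)` = 130, `PC(36:4)` = 120,
    `PC(36:5)` = 25, `PC(36:6)` = 1, `PC(38:0)` = 3, `PC(38:1)` = 1,
    `PC(38:3)` = 50, `PC(38:4)` = 120, `PC(38:5)` = 60, `PC(38:6)` = 80,
    `PC(40:1)` = 0.5, `PC(40:2)` = 0.4, `PC(40:3)` = 0.6, `PC(40:4)` = 4,
    `PC(40:5)` = 11, `PC(40:6)` = 25, `PC(42:1)` = 0.3, `PC(42:2)` = 0.3,
    `PC(42:4)` = 0.5, `PC(42:5)` = 0.5, `PC(42:6)` = 1,
    `PC(O-30:0)` = 0.4, `PC(O-30:2)` = 1, `PC(O-32:1)` = 1,
    `PC(O-32:2)` = 1.2, `PC(O-34:0)` = 1.5, `PC(O-34:1)` = 10,
    `PC(O-34:2)` = 12, `PC(O-34:3)` = 8, `PC(O-36:0)` = 1, `PC(O-36:1)` = 8,
    `PC(O-36:2)` = 12, `PC(O-36:3)` = 7, `PC(O-36:4)` = 18,
    `PC(O-36:5)` = 14, `PC(O-38:1)` = 1, `PC(O-38:2)` = 2, `PC(O-38:3)` = 5,
    `PC(O-38:4)` = 12, `PC(O-38:5)` = 15, `PC(O-38:6)` = 8,
    `PC(O-40:1)` = 1.5, `PC(O-40:2)` = 1.8, `PC(O-40:3)` = 1.5,
    `PC(O-40:4)` = 2.5, `PC(O-40:5)` = 4, `PC(O-40:6)` = 4.5,
    `PC(O-42:0)` = 0.8, `PC(O-42:1)` = 0.6, `PC(O-42:2)` = 0.9,
    `PC(O-42:3)` = 1, `PC(O-42:4)` = 1, `PC(O-42:5)` = 1.5,
    `PC(O-44:3)` = 0.2, `PC(O-44:4)` = 0.4, `PC(O-44:5)` = 0.6,
    `lysoPC(14:0)` = 12, `lysoPC(16:0)` = 30, `lysoPC(16:1)` = 12,
    `lysoPC(17:0)` = 10, `lysoPC(18:0)` = 25, `lysoPC(18:1)` = 22,
    `lysoPC(18:2)` = 22, `lysoPC(20:3)` = 10, `lysoPC(20:4)` = 15)
}

#' Generator configuration
#'
#' Collects the study design and the statistical structure of the simulated
#' data. The defaults are the study conditions every analysis stage is tested
#' against: 19 donors, 4 plates with 5 pool and 3 zero samples each, donor
#' variability dominating treatment effects, kit-like 10% analytical noise,
#' and the degradation signature of [default_profiles()].
#'
#' @param panel a `panel_definition`; defaults to the full 163-metabolite panel.
#' @param n_participants number of donors (default 19).
#' @param baselines named vector of baseline concentrations (uM); panel
#'   metabolites missing from it are simulated at a trace level
#'   (`trace_level`) with blank-like background so they fail the LOD filter.
#' @param profiles list of [degradation_profile()]s (default
#'   [default_profiles()]); `NULL` or `list()` gives an all-null study.
#' @param coupling logical; derive the diacyl-PC decrease from the lysoPC
#'   gain by choline-lipid mass balance (default `TRUE`).
#' @param sd_shared,sd_class,sd_specific log-scale SDs of the donor random
#'   effect components: a level shared across all metabolites (overall
#'   metabolic profile scale -- this is what makes samples cluster by donor
#'   and what concentration ratios cancel), a per-class level (a donor's
#'   species of one class moving together), and a metabolite-specific
#'   level. `sd_class` and `sd_specific` may be single numbers or named
#'   per-class vectors: sphingomyelins and carnitines carry strong
#'   donor-class levels (sphingolipid and fatty-acid-oxidation phenotypes),
#'   lipid species vary more between donors than amino acids, whose ratios
#'   are correspondingly tighter. The Euclidean sum is the donor
#'   (between-participant) SD.
#' @param pheno_frac,pheno_shift a minority of donors carries a constitutively
#'   elevated lysophosphatidylcholine level (probability `pheno_frac`, log-scale
#'   shift `pheno_shift` added to the donor's lyso-PC class effect). This
#'   bimodal donor structure produces the borderline participants whose
#'   reference samples sit close to the lysoPC/PC decision boundary, and it is
#'   what makes the secondary amino-acid split of the classification tree
#'   necessary.
#' @param sd_sample log-scale SD of the per-aliquot scaling factor shared by
#'   every metabolite measured in one sample (injection volume, derivatization
#'   and ionization efficiency). This error inflates single-metabolite
#'   residuals but cancels exactly in concentration ratios -- it is part of
#'   the mechanism that gives ratios their p-gain.
#' @param sd_bio per-aliquot, per-metabolite biological fluctuation of
#'   subject samples (scalar or named per-class vector). Unlike `sd_noise`
#'   it does not affect pool samples, which are replicate aliquots of one
#'   homogenized batch; subject aliquots were clotted and handled
#'   individually. This is the main residual of the raw-concentration
#'   single-metabolite models.
#' @param sd_noise residual metabolite-level log-scale SD (analytical noise).
#' @param cv_fail_ids metabolites given inflated analytical noise
#'   (`cv_fail_sd`) so they fail the pool-CV filter.
#' @param cv_fail_sd log-scale noise SD for `cv_fail_ids`.
#' @param ftc_slope named per-metabolite log change per additional thaw
#'   (default: none, the null freeze-thaw model).
#' @param n_plates,pool_per_plate,zero_per_plate plate layout (4 / 5 / 3).
#' @param zero_rel blank (zero-sample) background as a fraction of baseline
#'   for metabolites with a baseline entry.
#' @param trace_level concentration scale (uM) of metabolites without a
#'   baseline entry; their blank background equals the same level.
#' @param zero_noise_sd log-scale SD of blank measurements.
#' @param plate_effect_sd log-scale SD of plate intercepts (default 0; the
#'   study design avoided plate confounding).
#' @param seed master seed; all stages derive named sub-streams from it.
#' @return a `generator_config` list.
#' @export
generator_config <- function(panel = build_p150_panel(),
                             n_participants = 19,
                             baselines = default_baselines(),
                             profiles = default_profiles(),
                             coupling = TRUE,
                             sd_shared = 0.25,
                             sd_class = c(amino_acid = 0.025, hexose = 0.30,
                                          carnitine = 0.30,
                                          acylcarnitine = 0.30,
                                          sphingomyelin = 0.30,
                                          pc_aa = 0.025, pc_ae = 0.025,
                                          lyso_pc = 0.025),
                             sd_specific = c(amino_acid = 0.05,
                                             hexose = 0.10,
                                             carnitine = 0.20,
                                             acylcarnitine = 0.20,
                                             sphingomyelin = 0.20,
                                             pc_aa = 0.15, pc_ae = 0.15,
                                             lyso_pc = 0.15),
                             pheno_frac = 0.06, pheno_shift = 0.18,
                             sd_bio = c(amino_acid = 0.07, hexose = 0.08,
                                        carnitine = 0.10, acylcarnitine = 0.10,
                                        sphingomyelin = 0.13, pc_aa = 0.13,
                                        pc_ae = 0.13, lyso_pc = 0.13),
                             sd_sample = 0.08, sd_noise = 0.06,
                             cv_fail_ids = c("PC(O-30:2)", "SM(26:1)"),
                             cv_fail_sd = 0.45,
                             ftc_slope = NULL,
                             n_plates = 4, pool_per_plate = 5,
                             zero_per_plate = 3,
                             zero_rel = 0.005, trace_level = 0.004,
                             zero_noise_sd = 0.3,
                             plate_effect_sd = 0,
                             seed = 1) {
  validate_panel(panel)
  stopifnot(n_participants >= 2, n_plates >= 1, pool_per_plate >= 0,
            zero_per_plate >= 0, sd_shared > 0, all(sd_class > 0),
            all(sd_specific > 0), all(sd_bio >= 0), sd_sample >= 0,
            sd_noise > 0, zero_rel > 0, trace_level > 0,
            pheno_frac >= 0, pheno_frac < 1, pheno_shift >= 0)
  if (length(sd_specific) > 1 &&
      !all(unique(panel$mclass) %in% names(sd_specific)))
    stop("per-class sd_specific must name every class in the panel")
  if (length(sd_class) > 1 && !all(unique(panel$mclass) %in% names(sd_class)))
    stop("per-class sd_class must name every class in the panel")
  if (length(sd_bio) > 1 && !all(unique(panel$mclass) %in% names(sd_bio)))
    stop("per-class sd_bio must name every class in the panel")
  if (is.null(profiles)) profiles <- list()
  cfg <- structure(list(panel = panel, n_participants = n_participants,
                        baselines = baselines, profiles = profiles,
                        coupling = coupling, sd_shared = sd_shared,
                        sd_class = sd_class, sd_specific = sd_specific,
                        pheno_frac = pheno_frac, pheno_shift = pheno_shift,
                        sd_bio = sd_bio, sd_sample = sd_sample,
                        sd_noise = sd_noise,
                        cv_fail_ids = intersect(cv_fail_ids, panel$id),
                        cv_fail_sd = cv_fail_sd,
                        ftc_slope = ftc_slope, n_plates = n_plates,
                        pool_per_plate = pool_per_plate,
                        zero_per_plate = zero_per_plate, zero_rel = zero_rel,
                        trace_level = trace_level,
                        zero_noise_sd = zero_noise_sd,
                        plate_effect_sd = plate_effect_sd,
                        seed = as.integer(seed)),
                   class = "generator_config")
  ## donor clustering check: the aggregate (across-panel) donor profile
  ## distance must exceed the largest aggregate treatment displacement,
  ## otherwise PCA would separate conditions rather than donors
  sd_between <- sqrt(sd_shared^2 + max(sd_class)^2 + max(sd_specific)^2)
  M <- nrow(panel)
  shifts <- vapply(cfg$profiles, function(p)
    abs(profile_trajectory(p$rt_jump, p$rt_slope, 36)), 0)
  donor_dist <- sqrt(2 * M) * sd_between
  treat_dist <- sqrt(sum(shifts^2))
  if (donor_dist <= treat_dist)
    warning("aggregate donor profile distance (", signif(donor_dist, 3),
            ") does not exceed the largest aggregate treatment displacement (",
            signif(treat_dist, 3), "); donor clustering may not dominate")
  cfg
}

## per-metabolite slope table resolved from class- and id-level profiles
resolve_profiles <- function(config) {
  panel <- config$panel
  M <- nrow(panel)
  out <- data.frame(id = panel$id, rt_jump = 0, rt_slope = 0,
                    wet_attenuation = 0.25, onset_h = 24, coupling = FALSE,
                    stringsAsFactors = FALSE)
  apply_profile <- function(out, pr, rows) {
    out$rt_jump[rows] <- pr$rt_jump
    out$rt_slope[rows] <- pr$rt_slope
    out$wet_attenuation[rows] <- pr$wet_attenuation
    out$onset_h[rows] <- pr$onset_h
    out$coupling[rows] <- pr$coupling
    out
  }
  for (pr in config$profiles)     # class level first, then id overrides
    if (pr$target %in% PANEL_CLASSES)
      out <- apply_profile(out, pr, which(panel$mclass == pr$target))
  for (pr in config$profiles)
    if (!pr$target %in% PANEL_CLASSES)
      out <- apply_profile(out, pr, which(panel$id == pr$target))
  out
}

## expected log multiplier per metabolite for one handling condition
condition_log_multiplier <- function(config, temperature, delay_h,
                                     prof = resolve_profiles(config)) {
  logg <- numeric(nrow(prof))
  if (temperature == "rt") {
    logg <- profile_trajectory(prof$rt_jump, prof$rt_slope, delay_h)
  } else if (temperature == "wet_ice") {
    logg <- prof$wet_attenuation *
      profile_trajectory(prof$rt_jump, prof$rt_slope,
                         pmax(0, delay_h - prof$onset_h))
  }                                        # dry ice / na: 0
  if (config$coupling) {
    base <- baseline_vector(config)
    lyso <- config$panel$mclass == "lyso_pc" & prof$coupling
    sink <- config$panel$mclass == "pc_aa" & prof$coupling
    if (any(lyso) && any(sink)) {
      gain <- sum(base[lyso] * (exp(logg[lyso]) - 1))
      pool <- sum(base[sink])
      f <- 1 - gain / pool
      if (f <= 0.05)
        stop("lysoPC gain exhausts the coupled diacyl-PC pool")
      logg[sink] <- log(f)
    }
  }
  setNames(logg, config$panel$id)
}

baseline_vector <- function(config) {
  b <- config$baselines[config$panel$id]
  b[is.na(b)] <- config$trace_level
  setNames(as.numeric(b), config$panel$id)
}

## ids expected to survive QC under this configuration (used by the
## expectation helpers, not by the QC filter itself)
expected_retained_ids <- function(config) {
  ids <- intersect(config$panel$id, names(config$baselines))
  setdiff(ids, config$cv_fail_ids)
}

#' Expected value of a ratio feature under a generator configuration
#'
#' Closed-form expectation-scale value of a sum ratio (e.g. `"tLyso/tPC"`,
#' `"Gln/Ser"`) for one handling condition, computed from the configured
#' baselines and degradation profiles (noise and donor factors cancel).
#' Sums run over the metabolites expected to survive quality control. Used
#' to verify the implanted trajectories, e.g. where tLyso/tPC crosses the
#' 0.12 decision scale.
#'
#' @param config a `generator_config`.
#' @param feature feature id: `"num/den"` where each side is a metabolite id
#'   or one of `tLyso`, `tPC`, `tPCaa`, `tPCae`, `tAA`, `tAC`.
#' @param temperature `"dry_ice"`, `"wet_ice"`, `"rt"` or `"na"`.
#' @param delay_h delay hours (0 for the reference condition).
#' @return expected ratio (scalar).
#' @export
expected_feature <- function(config, feature, temperature = "na", delay_h = 0) {
  prof <- resolve_profiles(config)
  logg <- condition_log_multiplier(config, temperature, delay_h, prof)
  base <- baseline_vector(config)
  level <- base * exp(logg)
  ids <- expected_retained_ids(config)
  cls <- setNames(config$panel$mclass, config$panel$id)
  grp <- function(tag) {
    sel <- switch(tag,
                  tLyso = ids[cls[ids] == "lyso_pc"],
                  tPC   = ids[cls[ids] %in% c("pc_aa", "pc_ae")],
                  tPCaa = ids[cls[ids] == "pc_aa"],
                  tPCae = ids[cls[ids] == "pc_ae"],
                  tAA   = ids[cls[ids] == "amino_acid"],
                  tAC   = ids[cls[ids] %in% c("acylcarnitine", "carnitine")],
                  tag)
    if (!length(sel) || !all(sel %in% names(level)))
      stop("unknown feature component: ", tag)
    sum(level[sel])
  }
  parts <- strsplit(feature, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("feature must be of the form num/den")
  grp(parts[[1]]) / grp(parts[[2]])
}

#' Simulate a full pre-analytical handling study
#'
#' Draws one complete study dataset under the configured design: per donor
#' one reference aliquot, nine handling aliquots ({dry ice, wet ice, RT} x
#' {12, 24, 36 h}) and three freeze-thaw aliquots (2-4 total thaws), plus
#' pool and zero samples on every plate. Deterministic given `config$seed`.
#'
#' @param config a [generator_config()].
#' @return a validated `concentration_dataset` (default design: 19 x 13
#'   subject samples + 20 pool + 12 zero = 279 rows).
#' @examples
#' ds <- generate_study(generator_config(seed = 7))
#' nrow(ds$values)
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  panel <- config$panel
  M <- nrow(panel)
  nP <- config$n_participants
  participants <- paste0("P", seq_len(nP))
  plate_of <- paste0("plate", ((seq_len(nP) - 1) %% config$n_plates) + 1)

  subj <- do.call(rbind, lapply(seq_len(nP), function(i) {
    p <- participants[[i]]
    hand <- expand.grid(temperature = c("dry_ice", "wet_ice", "rt"),
                        delay_h = c(12, 24, 36), stringsAsFactors = FALSE)
    rbind(
      data.frame(sample_id = paste0(p, "_ref"), participant = p,
                 role = "reference", temperature = "na", delay_h = 0,
                 thaw_count = 1, plate = plate_of[[i]]),
      data.frame(sample_id = paste0(p, "_", hand$temperature, "_",
                                    hand$delay_h, "h"),
                 participant = p, role = "handling",
                 temperature = hand$temperature, delay_h = hand$delay_h,
                 thaw_count = 1, plate = plate_of[[i]]),
      data.frame(sample_id = paste0(p, "_ftc", 2:4), participant = p,
                 role = "ftc", temperature = "na", delay_h = 0,
                 thaw_count = 2:4, plate = plate_of[[i]])
    )
  }))
  plates <- paste0("plate", seq_len(config$n_plates))
  qcrow <- function(role, k) {
    if (k == 0) return(NULL)
    do.call(rbind, lapply(plates, function(pl)
      data.frame(sample_id = paste0(role, "_", pl, "_", seq_len(k)),
                 participant = role, role = role, temperature = "na",
                 delay_h = 0, thaw_count = 1, plate = pl)))
  }
  ann <- rbind(subj, qcrow("pool", config$pool_per_plate),
               qcrow("zero", config$zero_per_plate))
  rownames(ann) <- NULL

  prof <- resolve_profiles(config)
  base <- baseline_vector(config)
  logb <- log(base)
  conds <- unique(ann[ann$role != "zero", c("temperature", "delay_h")])
  lg <- lapply(seq_len(nrow(conds)), function(i)
    condition_log_multiplier(config, conds$temperature[[i]],
                             conds$delay_h[[i]], prof))
  names(lg) <- paste(conds$temperature, conds$delay_h)

  noise_sd <- rep(config$sd_noise, M)
  noise_sd[panel$id %in% config$cv_fail_ids] <- config$cv_fail_sd
  ftc_slope <- rep(0, M)
  if (!is.null(config$ftc_slope)) {
    hit <- match(names(config$ftc_slope), panel$id)
    ftc_slope[hit[!is.na(hit)]] <- config$ftc_slope[!is.na(hit)]
  }

  set.seed(stream_seed(config$seed, "donor"))
  shared <- rnorm(nP, sd = config$sd_shared)
  classes <- unique(panel$mclass)
  class_sd <- if (length(config$sd_class) > 1)
    unname(config$sd_class[classes]) else rep(config$sd_class, length(classes))
  class_eff <- matrix(rnorm(nP * length(classes)), nP,
                      dimnames = list(NULL, classes)) %*% diag(class_sd)
  colnames(class_eff) <- classes
  if (config$pheno_frac > 0 && "lyso_pc" %in% classes) {
    high <- stats::runif(nP) < config$pheno_frac
    class_eff[, "lyso_pc"] <- class_eff[, "lyso_pc"] +
      high * config$pheno_shift
  }
  spec_sd <- if (length(config$sd_specific) > 1)
    unname(config$sd_specific[panel$mclass]) else rep(config$sd_specific, M)
  specific <- matrix(rnorm(nP * M), nP) %*% diag(spec_sd)
  set.seed(stream_seed(config$seed, "plate"))
  plate_eff <- setNames(
    if (config$plate_effect_sd > 0)
      rnorm(config$n_plates, sd = config$plate_effect_sd)
    else rep(0, config$n_plates), plates)

  n <- nrow(ann)
  logx <- matrix(NA_real_, n, M, dimnames = list(ann$sample_id, panel$id))
  is_subj <- ann$role %in% c("reference", "handling", "ftc")
  pidx <- match(ann$participant, participants)
  condkey <- paste(ann$temperature, ann$delay_h)

  set.seed(stream_seed(config$seed, "aliquot"))
  aliquot <- rnorm(n, sd = config$sd_sample)
  bio_sd <- if (length(config$sd_bio) > 1)
    unname(config$sd_bio[panel$mclass]) else rep(config$sd_bio, M)
  set.seed(stream_seed(config$seed, "bio"))
  bio_subj <- matrix(rnorm(sum(is_subj) * M), sum(is_subj)) %*% diag(bio_sd)
  set.seed(stream_seed(config$seed, "noise"))
  eps_subj <- matrix(rnorm(sum(is_subj) * M), sum(is_subj)) %*% diag(noise_sd) +
    bio_subj
  ridx <- 0
  for (i in which(is_subj)) {
    ridx <- ridx + 1
    logx[i, ] <- logb + shared[pidx[[i]]] +
      class_eff[pidx[[i]], panel$mclass] + specific[pidx[[i]], ] +
      lg[[condkey[[i]]]] + ftc_slope * (ann$thaw_count[[i]] - 1) +
      plate_eff[[ann$plate[[i]]]] + aliquot[[i]] + eps_subj[ridx, ]
  }
  set.seed(stream_seed(config$seed, "pool"))
  for (i in which(ann$role == "pool"))
    logx[i, ] <- logb + plate_eff[[ann$plate[[i]]]] + aliquot[[i]] +
      rnorm(M) * noise_sd
  set.seed(stream_seed(config$seed, "zero"))
  zero_mean <- ifelse(panel$id %in% names(config$baselines),
                      base * config$zero_rel, config$trace_level)
  for (i in which(ann$role == "zero"))
    logx[i, ] <- log(zero_mean) + rnorm(M, sd = config$zero_noise_sd)

  concentration_dataset(panel, ann, exp(logx))
}

#' Tiny deterministic worked-example dataset
#'
#' A hand-constructed 6-metabolite, 2-participant dataset (all sample roles,
#' 4 pool and 3 zero samples) with exactly known quality-control outcomes:
#' `C3` fails the LOD criterion (blank background as high as serum) and
#' `SM(16:0)` fails the pool-CV criterion; the remaining four metabolites
#' pass. Values carry simple exact treatment multipliers and no noise, so
#' LODs, CVs and sum ratios can be verified by hand arithmetic.
#'
#' @return a validated `concentration_dataset` (26 subject + 7 QC rows).
#' @export
generate_worked_fixture <- function() {
  panel <- panel_subset(build_p150_panel(),
                        c("Gln", "Ser", "C3", "SM(16:0)", "PC(34:2)",
                          "lysoPC(18:0)"))
  base <- c(Gln = 500, Ser = 100, C3 = 0.9, `SM(16:0)` = 100,
            `PC(34:2)` = 380, `lysoPC(18:0)` = 20)
  pfac <- c(P1 = 1, P2 = 1.2)
  mult <- function(temp, d) {
    m <- c(Gln = 1, Ser = 1, C3 = 1, `SM(16:0)` = 1, `PC(34:2)` = 1,
           `lysoPC(18:0)` = 1)
    if (temp == "rt") {
      m["Gln"] <- 1 - 0.002 * d; m["Ser"] <- 1 + 0.005 * d
      m["PC(34:2)"] <- 1 - 0.005 * d; m["lysoPC(18:0)"] <- 1 + 0.01 * d
    } else if (temp == "wet_ice" && d == 36) {
      m["Gln"] <- 0.976; m["Ser"] <- 1.06
      m["PC(34:2)"] <- 0.94; m["lysoPC(18:0)"] <- 1.12
    }
    m
  }
  rows <- list(); vals <- list()
  add <- function(id, part, role, temp, d, thaw, v) {
    rows[[length(rows) + 1]] <<- data.frame(
      sample_id = id, participant = part, role = role, temperature = temp,
      delay_h = d, thaw_count = thaw, plate = "plate1")
    vals[[length(vals) + 1]] <<- v
  }
  for (p in c("P1", "P2")) {
    add(paste0(p, "_ref"), p, "reference", "na", 0, 1, base * pfac[[p]])
    for (temp in c("dry_ice", "wet_ice", "rt"))
      for (d in c(12, 24, 36))
        add(paste0(p, "_", temp, "_", d, "h"), p, "handling", temp, d, 1,
            base * pfac[[p]] * mult(temp, d))
    for (k in 2:4)
      add(paste0(p, "_ftc", k), p, "ftc", "na", 0, k, base * pfac[[p]])
  }
  sm_pool <- c(60, 100, 160, 100)
  for (j in 1:4) {
    v <- base * 1.1
    v["SM(16:0)"] <- sm_pool[[j]]
    add(paste0("pool_plate1_", j), "pool", "pool", "na", 0, 1, v)
  }
  zero <- c(Gln = 1, Ser = 0.5, C3 = 0.9, `SM(16:0)` = 0.2,
            `PC(34:2)` = 0.5, `lysoPC(18:0)` = 0.1)
  for (j in 1:3)
    add(paste0("zero_plate1_", j), "zero", "zero", "na", 0, 1, zero)
  ann <- do.call(rbind, rows)
  values <- do.call(rbind, vals)[, panel$id, drop = FALSE]
  rownames(values) <- ann$sample_id
  concentration_dataset(panel, ann, values)
}
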