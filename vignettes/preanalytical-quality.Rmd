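---
title: "Assessing pre-analytical serum quality from metabolite ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing pre-analytical serum quality from metabolite ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preanalytica)
```

## The problem

Biobanked serum is often the limiting resource of an omics study, and most
laboratory error arises before anything is measured: in the interval between
blood draw and frozen storage. Prolonged room-temperature (RT) exposure of
serum after centrifugation leaves a biochemical signature — enzymatic
hydrolysis of diacyl-phosphatidylcholines (PC) by phospholipase-type activity
raises lysophosphatidylcholines (lysoPC), and residual proteolysis raises
free amino acids. `preanalytica` implements, end to end, the analysis that
turns this signature into an *intrinsic* quality marker: a decision rule on
metabolite ratios (lysoPC/PC and amino-acid ratios) that classifies a single
sample as of good or bad pre-analytical quality without any external
information about its history.

The pipeline covers a targeted metabolomics design: 19 donors, each
contributing 13 aliquots of one pooled serum draw — 1 immediately frozen
reference, 9 handling aliquots ({dry ice, wet ice, RT} x {12, 24, 36 h}) and
3 freeze–thaw aliquots (2–4 total thaws) — plus 5 pooled-serum and 3 blank
(zero) samples on each of 4 measurement plates, one plate per donor's
samples. The 163-metabolite panel (`build_p150_panel()`) spans amino acids,
hexose, carnitines/acylcarnitines, sphingomyelins, diacyl and acyl-alkyl
phosphatidylcholines, and lysophosphatidylcholines.

No subject-level data from the original experiment are available, so the
package carries a first-class synthetic-data generator that reproduces the
design and the statistical structure the analysis relies on; every stage is
tested against it.

## Stages and their models

### Quality control

Per metabolite, two kit-level criteria decide whether it is analyzable:
the coefficient of variation over the 20 pooled-serum replicates must be
strictly below 25% (sample SD / mean, n−1 denominator), and at least 50% of
all measured concentrations must lie strictly above the limit of detection,
defined as 3x the mean of the 12 zero samples. Boundary semantics follow the
wording of the criteria: a CV exactly at the bound fails, an above-LOD
fraction exactly at the bound passes. The above-LOD denominator includes
every non-missing measurement (subject, pool and zero samples); a switch
(`lod_scope = "subject"`) restricts it to subject samples, since the
original description leaves this open. Missing cells are excluded from all
means and never imputed. On the default synthetic study, 127 of 163
metabolites survive, matching the study scale.

### Single-metabolite mixed models

Each retained metabolite is screened with a linear mixed model on raw
concentration (uM): fixed effects delay time (hours), temperature and their
interaction, plus a participant random intercept; the freeze–thaw screen
uses the total thaw count (1–4) as its single fixed effect. Temperature is
an ordered numeric score (dry ice = 0, wet ice = 1, RT = 2), which is what a
single reported "temperature coefficient" implies. Reference aliquots carry
no temperature assignment and are excluded from the handling model.

Two numerical decisions matter here:

* **Interaction centring.** The interaction column is `(t − 24) * (score −
  1)`. With a raw product term the temperature main effect is the
  extrapolated group contrast at 0 h — identically ~0 for any trajectory
  observed only at 12–36 h — so no data generated on this design could ever
  show the temperature-dominant significance pattern that is the hallmark
  of RT degradation. Centring at the design midpoints makes `time` and
  `temp` design-averaged main effects while spanning the identical model
  space.
* **Estimation and reference distribution.** All models are fitted by
  maximum likelihood (not REML) so that likelihood-ratio tests between
  nested fixed-effect models are valid. Wald p-values use a t reference
  with residual degrees of freedom `n − p − (G − 1)` and the matching scale
  correction of the ML variance: at the extreme Bonferroni tails used here
  (0.05/381 ≈ 1.3e-4), a plain normal reference on ML standard errors is
  several-fold anti-conservative at this design size (171 observations, 19
  donors) and floods the screen with false positives.

The fitter itself (`fit_ri_lmm()`) exploits the balanced design: every
participant carries the same condition rows, so the GLS estimate equals OLS
and the profiled likelihood in the variance ratio has a closed-form
maximizer. This makes the 2 x 8001 ratio-model fits of a full run, and the
replicated simulations in the test suite, essentially free. Unbalanced data
(dropped rows, missing cells) fall back to a one-dimensional numerical
profile likelihood. Both paths are validated against `lme4` in the tests.

Significance uses Bonferroni control: `0.05 / (3 * M)` for the handling
screen (three coefficients per model, M retained metabolites; 1.3e-4 at
M = 127) and `0.05 / M` for the freeze–thaw screen (3.9e-4).

### Ratio models and the p-gain

All `M (M − 1) / 2` unordered metabolite pairs (8001 at M = 127) are fitted
with the log-ratio outcome `log x1 − log x2`, fixed effects time and
temperature (no interaction), and the participant random intercept. An
overall p-value comes from a 2-df likelihood-ratio test against the model
with intercept and random effect only. The p-gain of a component is the
smaller of the two single-metabolite p-values divided by the ratio p-value,
with the single-metabolite reference models fitted on raw concentration with
the same fixed effects (their overall p uses the same LRT). A pair passes
when some component has `p < 0.05 / (3 * n_pairs)` *and*
`p-gain > 10 * 3 * n_pairs` (240030 at 8001 pairs; 80010 for the
freeze–thaw scheme). The threshold is computed from the formula — note that
0.05/24003 is 2.08e-6.

Why do ratios gain power at all? Two mechanisms, both represented in the
generator: a per-aliquot scaling error shared by all metabolites of one
measured sample (injection, derivatization, ionization) cancels exactly in
any ratio but inflates every raw-concentration model; and opposing
degradation trends (lysoPC up / PC down; Ser up / Gln down) add in a ratio.
Glutamine is the emblematic case: its decline stays below single-metabolite
significance, yet glutamine ratios carry strong signal.

### Two-stage classification

The classifier stage mirrors the two-step procedure exactly:

1. **Variable ranking.** Candidate variables are the screened single ratios
   plus four sum ratios — tLyso/tPC, tLyso/tPCaa, tLyso/tPCae and tAA/tAC
   (free carnitine included in the acylcarnitine denominator; a
   configuration switch excludes it). Under the *stringent* labelling
   (good = reference, bad = 36 h RT; 24 training samples) repeated Random
   Forests are trained and each variable's unscaled permutation importance
   (mean decrease in out-of-bag accuracy) is averaged. Defaults are the
   reduced scale (20 forests of 501 trees, mtry 80 capped at the variable
   count); `full_scale = TRUE` gives 500 x 5001. Ties break
   lexicographically.
2. **Tree construction.** A CART classification tree (Gini impurity,
   cost-complexity `cp = 0.01`) is grown on the top 10 variables under the
   *non-stringent* labelling (good = reference + dry ice, 48 training
   samples; bad = 24 h and 36 h RT, 24 samples), using the 12 training
   participants. The minimum leaf size is 3 rather than a more conventional
   5: the expected tree shape is a lysoPC/PC split with a secondary
   amino-acid split that isolates the good samples of a borderline
   (constitutively high-lysoPC) donor, and with 72 training samples a leaf
   must be able to hold the four good-label aliquots of one such donor.

The fitted rule is reported in the printed form, e.g.
`tLyso/tPC >= 0.104 and Gln/Ser < 4.4 -> bad`. Evaluation is the
misclassification rate over labelled samples of the fixed 12/7 participant
split (participants 1, 4, 5, 7, 9, 11, 12, 14–16, 18, 19 train); samples
missing a tree variable are reported unclassifiable and excluded. The tree
is then applied to the held-out conditions (wet ice at all delays, RT at
12 h), and a robustness scan refits it on subsets of the top-10 variables.

## What the generator emulates

Concentrations are log-normal:
`log x = log baseline + donor effects + treatment(temp, delay) + ftc_slope *
(thaws − 1) + plate + aliquot effects + noise`, with one master seed and
named sub-streams per stage.

* **Donor effects** decompose into a shared level (SD 0.25; the overall
  metabolic scale of a person — this is what makes samples cluster by donor
  in a PCA and what every ratio cancels), per-class levels (strong for
  sphingomyelins, carnitines and hexose — donor lipid/fatty-acid-oxidation
  phenotypes — and weak, 0.025, for the classes that feed the classifier),
  and metabolite-specific levels (tight for amino acids, 0.05; loose for
  lipid species, 0.15–0.20). A minority high-lysoPC phenotype
  (`pheno_frac = 0.06`, +0.18 log) produces the borderline donors visible
  in the study's own scatter of the two decision ratios.
* **Aliquot effects**: a per-sample scaling factor (SD 0.08) shared by all
  metabolites of one measurement — the p-gain engine — plus a per-aliquot,
  per-metabolite biological fluctuation of subject samples (0.03–0.15 by
  class) that pools, being replicates of one homogenized batch, do not
  have. Residual analytical noise has SD 0.06 (pool CV ≈ 10%).
* **Degradation profiles** are two-phase: a fast log change reached by 12 h
  (`rt_jump`) and a per-hour change thereafter (`rt_slope`), because the
  characteristic changes are already visible after 12 h; a purely
  linear-in-delay effect cannot produce a temperature main effect on this
  design (see the centring discussion above). All lysoPCs except
  lysoPC(18:2) rise (jump 0.20, slope 0.035/h); the decrease of eight
  diacyl-PCs is derived from choline-lipid mass balance with the lysoPC
  gain (coupling), so the expected total lysoPC + diacyl-PC pool is
  condition-invariant; Arg, Gly, Orn, Phe, Ser, Leu+Ile rise; Gln drifts
  down, calibrated to stay below single-metabolite significance; C10:2
  drops between 0 and 12 h and then plateaus; PC(O-34:1) falls weakly. Wet
  ice applies a tenth of the RT trajectory starting only after 24 h (C10:2
  excepted: visible early); dry ice is the null condition. Freeze–thaw
  effects default to zero.
* **QC structure**: 34 panel metabolites sit at a trace level with
  blank-like background (they fail the LOD rule), and two carry inflated
  analytical noise (they fail the CV rule), leaving the 127 analyzable
  metabolites of the study.

With the default baselines the expected tLyso/tPC trajectory at RT starts
near 0.086, crosses 0.12 between 12 h and 24 h and reaches ~0.16 by 36 h;
Gln/Ser starts at 5.1 and falls below 4.71 well before 24 h. These are the
scales of the published cut-offs. Effect magnitudes are a modelling
convention — the source experiment reports directions and significance, not
sizes — calibrated once so that the full pipeline reproduces the qualitative
pattern at n = 19 and then frozen.

What passing tests on this generator do *not* show about real data: the
generator has no plate drift (plate intercepts default to 0, a switch adds
them), no pre-centrifugation cell-contact effects, no missing cells, no
heavy-tailed analytical outliers, and its degradation model is smooth and
donor-independent on the log scale. Results on real tables (via
`read_dataset()`) depend on those factors too.

## Known limitations

* **Reduced-scale Random-Forest ranking is noisy.** On the 24 stringent
  training samples, dozens of screened ratios separate the classes
  completely; permutation importance then differs only through
  use-frequency noise, and at the reduced scale (20 x 501 trees) the top-10
  set is unstable. The test suite demonstrates the two sides of this:
  given the decisive variables (the sum ratios plus Gln/Ser), the fitted
  tree roots at tLyso/tPC and classifies the held-out participants nearly
  perfectly, and the variance of a variable's rank shrinks as the number
  of averaged forests grows. Larger averaging (e.g. `n_iter = 100` or the
  500 x 5001 full scale) is therefore recommended for any real analysis;
  the reduced scale is the default purely for runtime.
* The Wald t reference is a finite-sample correction, not exact; at the
  1.3e-4 tail a residual ~2x anti-conservatism remains from the skewness of
  log-normal concentrations, visible as occasional single false positives
  in the 381-test screen.
* The ratio-screen significance threshold is always computed from the
  formula `alpha / (n_terms * n_pairs)` — 2.08e-6 at 8001 pairs and three
  components, 6.25e-6 for the freeze–thaw scheme — and the screen metadata
  records this; commonly quoted rounded values for these quantities
  (2.8e-6, 6.3e-6) differ from the formula.
* `tAA/tAC` is retained as a candidate variable but rarely ranks high on
  synthetic data: the acylcarnitine denominator is dominated by free
  carnitine, whose donor variability swamps the modest total-amino-acid
  rise.

## Problem sizes used by the test suite

Unit tests run on a 6-metabolite panel (ratio stage) or the full panel
(design, QC, screens). The acceptance checks use: 200 all-null replicates
of a 30-metabolite study for familywise-error calibration; 50 seeded full
studies for signature recovery; and 50 seeded end-to-end classifier runs at
the reduced Random-Forest scale. A complete 163-metabolite pipeline run —
QC, 127 single-metabolite models, 8001 ratio models with likelihood-ratio
tests, the reduced-scale forest stage and the tree — takes roughly ten
seconds on one core thanks to the closed-form fitter.

## A worked run

```{r, eval = FALSE}
library(preanalytica)

report <- run_pipeline(run_config(seed = 1))
make_report(report)
```

See the README for the printed output of this run and how to reproduce the
headline numbers with `scripts/acceptance.R`.
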