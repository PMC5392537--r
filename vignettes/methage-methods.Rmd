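---
title: "Methylation-based age prediction with methage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-based age prediction with methage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methage)
```

## The problem

DNA methylation at a modest set of CpG sites drifts with chronological
age in a reproducible way, which makes a blood (or saliva) stain a
usable age witness: measure the methylation fraction (beta value, 0–1)
of each marker CpG, feed the vector into a trained model, and read off
an age in years. `methage` implements the full desk-side counterpart of
such a workflow: a synthetic cohort generator that stands in for pooled
public array data, marker screening and selection, a linear baseline, a
generalised regression neural network (GRNN) predictor with staged
optimisation, and a bisulfite amplicon sequencing layer (read
simulation, per-CpG C/T calling, conversion correction, standard-curve
and cross-platform normalization) that feeds sequencing measurements
into an array-trained model.

## The GRNN age model

The predictor is Specht-style kernel regression. Training cases are
stored as exemplars $(x_i, y_i)$ (beta vector, age); a query $x$ is
predicted as

$$\hat y(x) \;=\; \frac{\sum_i y_i\, e^{-\lVert x - x_i\rVert^2 / 2\sigma^2}}
                        {\sum_i e^{-\lVert x - x_i\rVert^2 / 2\sigma^2}},$$

a convex combination of training ages, so predictions can never leave
the training age range. There is one pattern unit per training case and
a numerator/denominator summation pair, hence the
inputs–cases–2–1 architecture reported by `print.grnn()`. Inputs are
standardized to zero mean and unit variance over the training exemplars
before distances are computed: marker beta ranges differ by more than an
order of magnitude, and unstandardized Euclidean distance would let the
widest-range CpGs dominate the kernel. As $\sigma \to 0$ the model
returns the nearest exemplar's age; as $\sigma \to \infty$ it returns
the training mean. The exponent is stabilised by subtracting the
per-query maximum, so tiny widths do not underflow.

The single isotropic $\sigma$ (in standardized units) is the only tuned
hyperparameter. It is chosen by golden-section search over
$[0.01, 10]$, minimising verification-set mean absolute error (MAE); a
solution within 1% of either bracket end raises a boundary warning.
Per-input widths are supported (`sigma` as a vector) but off by
default: with 14–16 correlated inputs a shared width is markedly more
stable at these sample sizes.

### Staged optimisation and replicates

Model selection mirrors how such networks are tuned in practice and is
split into three stages:

1. **Stage 1** (`stage1_split_search`) draws random
   training/verification/blind partitions for each candidate training
   proportion in $[0.5, 0.7]$ (verification and blind split the
   remainder equally), tunes $\sigma$, and picks the proportion with
   the lowest mean blind MAE. Partition sizes follow
   `round(p*n)` / `round(p*n)` / remainder, which maps 60:20:20 of
   1156 cases to 694/231/231.
2. **Stage 2** (`stage2_fixed_blind`) keeps the winning blind cases
   frozen and resamples only the train/verify assignment, choosing the
   best model by verification MAE so the blind set stays untouched.
3. **Stage 3** (`stage3_replicates`) fixes all three subsets and
   trains `k = 10` replicates, each on a bootstrap resample of the
   training exemplars. The base fit is deterministic given a split, so
   the bootstrap is the package's source of replicate-to-replicate
   variability; subset errors are always evaluated on the original
   fixed subsets and summarised as mean ± SD.

### Sensitivity analysis

`sensitivity_analysis()` removes one input at a time from each
replicate model (exemplars unchanged, remaining standardization kept)
and reports the error ratio
$\mathrm{MAE}_{\text{without}} / \mathrm{MAE}_{\text{all}}$ on the
blind set. Ratios above 1 mean the input contributes to accuracy;
inputs are ranked by mean ratio across replicates. Pure-noise inputs
hover within a few percent of 1. Collinear inputs are deliberately
retained (removing either member of a correlated pair degrades
prediction); `vif_markers()` quantifies the collinearity so that
rankings among high-VIF inputs are read with care.

## The linear baseline and the marker funnel

`screen_markers()` fits per-CpG ordinary least squares of beta on age
(slope in fraction/year, Pearson r, two-sided slope p, observed
methylation range). No multiplicity correction is applied by default —
screening 45 candidates at raw p < 0.05 is the convention this panel
size uses — with Benjamini–Hochberg available as an option.
`stepwise_select()` is classic forward selection on the multiple
regression of age on betas: at each step the candidate with the
smallest partial-F p enters (ties broken by candidate order), stopping
when the best p reaches `alpha_enter` (0.05) or the R² gain falls
below `r2_tol` (1e-4, "no statistical improvement"). The R²-gain stop
matters: with a strong model already in hand, marginally "significant"
noise candidates add R² of order $10^{-5}$ and are correctly refused.
`fit_linear_age_model()`/`predict()` provide the multiple-linear-
regression baseline the GRNN is compared against, and
`evaluate_predictions()` computes the reporting set used throughout:
MAE, SD of absolute error, R² (squared Pearson correlation of
predicted vs true), ±5/±10-year band fractions, the 75th percentile of
absolute error and the skewness of signed errors.

`covariate_association()` tests whether sex, ethnicity or study
labels structure the methylation matrix beyond age: a multivariate
regression (Pillai trace) of all betas on age plus the covariate
factors, one pooled p per covariate. The generator builds sex and
ethnicity as exact nulls, so this test doubles as a calibration check
(its null p-values are uniform).

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` stands in for a pooled collection of public
whole-blood array profiles: 1156 samples aged 2–90 by default, drawn
stratified-uniform per decade (about 130 per decade), pooled from seven
"studies" whose only systematic difference is an additive batch offset
(up to ±0.05 beta) that is constant within a study — exactly the
structure a per-CpG mean-shift normalization removes. Sex (51.6%
female) and a three-level ethnicity label are generated with zero
effect on every CpG. Noise is additive Gaussian on the beta scale
(default SD 0.035, a typical array technical+biological spread for a
single CpG), truncated to [0, 1]; trend specs are validated so the
noiseless trajectory never touches the clamp.

The default 45-CpG candidate panel encodes the marker-selection funnel
the analysis is designed around: 16 informative CpGs, 7 weak CpGs with
real but tiny slopes (detectable individually in a large cohort,
negligible on top of the informative set), and 22 pure-noise CpGs, one
of which has the widest methylation range of the panel — a reminder
that range and age-information are different things. The informative
trends mix signs and curvature: linear, quadratic, cubic and
saturating-logistic trajectories whose transition midpoints are
staggered across the life span (20–85 years). The staggering is the
panel's key design idea: each marker drifts fastest during a different
life phase, so each carries age information the others lack — which is
what lets forward selection recover essentially the whole informative
set — while the strong curvature is what gives a nonlinear model a
genuine, reproducible advantage over the linear baseline. All
coefficients are package fixtures chosen once at design time; they are
not estimates from any real cohort.

Twin cohorts (`generate_twin_cohort`) share one age and one per-CpG
deviation per pair (default SD 0.03) plus an independent individual
deviation (default SD 0.015), so within-pair prediction differences are
driven only by the individual term. Disease cohorts
(`generate_disease_cohort`) add an independent per-sample shift at the
affected CpGs, with blood-related conditions defaulting to a 2.5×
larger shift SD (0.05 vs 0.02) because the assayed tissue is perturbed
directly.

Not emulated: probe chemistry and detection p-values, cell-composition
heterogeneity, age-dependent (heteroscedastic) noise, and real
epigenetic drift structure. Passing tests on this generator therefore
demonstrate that the pipeline's statistics and plumbing are correct
under the stated assumptions — not that any particular accuracy will
be attained on real cohorts, where all of the above inflate error.

## The sequencing layer

`simulate_reads()` draws per-fragment methylation states per CpG
(probability = true beta), converts unmethylated and control cytosines
with the given conversion rate, applies uniform substitution errors and
emits 150 bp paired-end reads from both amplicon ends.
`assign_reads()` scores every read against every panel reference by
exhaustive ungapped alignment anchored at either amplicon end, in both
orientations; reference CpG and conversion-control positions match C
and T at zero cost (the IUPAC Y convention used throughout), and reads
below 80% identity or tied across markers go to the unassigned bin.
Ungapped scoring is exact here because amplicon reads at this scale
carry no indels (indel realignment is out of scope); identical reads
are collapsed before scoring, which changes nothing in the result and
makes deep-coverage runs cheap. `call_methylation()` counts C/T per
interrogated offset, counting overlapping mate bases once (first mate
wins — double-counting would halve the apparent sampling variance),
estimates the conversion rate from the pooled non-CpG cytosine
controls, corrects raw betas by inverting the conversion process
(`corrected = (raw − (1 − rate)) / rate`, clamped; rates ≤ 0.5 are
refused as assay failures), and flags offsets below the minimum
coverage (default 1000 reads). Replicate callsets are averaged after
coverage filtering.

Two further normalization layers close the loop to array-trained
models. Standard curves (`fit_standard_curve`) regress observed on
known methylation across the 0/25/50/75/100% standards — linear by
default, cubic only when it improves residual SD by >20%, with
monotonicity checked on a 0.001 grid and non-monotone fits falling
back to linear — and are inverted numerically (bisection to 1e-6).
`ngs_to_array_normalize()` then treats the sequencing batch as one
extra dataset and mean-shifts it per CpG toward the array reference,
the same operation `cross_dataset_normalize()` applies between array
studies. The shift is a batch statistic: harmonising a very small
batch estimates it noisily, which is why the convergence checks in the
test suite use the donors' own array rows as the reference.

## Numerical choices and degenerate inputs

* Partition rounding (round/round/remainder) is fixed so that split
  sizes are reproducible integers.
* Golden-section $\sigma$ search tolerance is 1e-3 on log-$\sigma$
  (0.05 inside the subset search, where thousands of tunings occur).
* Constant inputs standardize with unit scale and a warning; identical
  exemplar sets predict a constant with a warning; `k = 1` replicates
  report SD 0 with a warning.
* Ties in read assignment and in stepwise entry are broken
  deterministically (unassigned bin; candidate order).
* Missing model CpGs at prediction time are refused by default
  (forensic caution); training-mean imputation is opt-in.
* All randomness flows through explicit integer seeds; pipeline runs
  write a manifest (config, seeds, artifact checksums) sufficient to
  reproduce outputs bit-identically.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full study-scale
cohort (n = 1156, 45 CpGs) for selection and GRNN stages, 10-seed
repeats for the funnel/nonlinearity properties, a 33-cell
beta × conversion grid at 1000 fragments for the sequencing round
trip, and 4 donors at 20,000–50,000 fragments/marker for the
array-vs-sequencing convergence check; the subset search is exercised
at n = 400 with a 400-evaluation budget. These sizes were chosen so
each property is measured with comfortable statistical margin.

## Known limitations

* The GRNN underestimates at the oldest ages when old training cases
  are sparse — kernel averaging shrinks toward the bulk of the data.
  This is a property of the estimator, visible in residual-vs-age
  tables, not a bug.
* The error-ratio ranking is only as stable as the collinearity
  structure allows; inputs with VIF above ~5 should be interpreted
  jointly.
* The subset search optimises verification MAE, which at realistic
  noise prefers subsets somewhat smaller than the full informative
  set; it is a model-building tool, not a marker-discovery oracle.
* `in_silico_bisulfite_pcr` searches a supplied region, not a genome:
  primer uniqueness is checked within the template only.
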