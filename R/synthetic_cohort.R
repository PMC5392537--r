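# Synthetic whole-blood methylation cohorts.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: a panel of candidate CpGs whose mean methylation follows smooth
# monotone trends with age (linear to cubic, or saturating logistic), with
# additive Gaussian noise on the beta scale, per-study batch offsets that
# are constant within a study, null sex/ethnicity effects, twin-pair shared
# deviations, and disease perturbations of selected CpGs.

VALID_TREND_FORMS <- c("linear", "quadratic", "cubic", "logistic-clamped")

#' Specify the age trend of one CpG
#'
#' Describes how the expected beta value of a CpG changes with age.
#' Polynomial forms use intercept-first coefficients on the
#' methylation-fraction scale per year of age; the `logistic-clamped` form
#' uses coefficients `(baseline, amplitude, midpoint, scale)` giving
#' `baseline + amplitude / (1 + exp(-(age - midpoint)/scale))`.
#'
#' The noiseless trend must stay inside \[0, 1\] over the ages 2–90 so that
#' clamping never distorts it; this is validated at construction.
#'
#' @param cpg_id CpG identifier (Illumina-style `cg...`).
#' @param form one of `"linear"`, `"quadratic"`, `"cubic"`,
#'   `"logistic-clamped"`.
#' @param coefficients numeric vector of trend coefficients (see above).
#' @param noise_sd standard deviation of additive Gaussian noise on the
#'   beta scale, in `[0, 0.2]`. Zero gives a deterministic trend.
#' @param direction `"increasing"`, `"decreasing"` or `"none"`.
#'   `direction = "none"` requires all non-intercept coefficients to be 0.
#' @param role optional label used by the default panel:
#'   `"informative"`, `"weak"` or `"null"`.
#' @return an object of class `age_trend_spec`.
#' @export
age_trend_spec <- function(cpg_id, form, coefficients, noise_sd = 0.035,
                           direction = c("increasing", "decreasing", "none"),
                           role = NA_character_) {
  direction <- match.arg(direction)
  if (!form %in% VALID_TREND_FORMS)
    stop("unknown trend form '", form, "' for ", cpg_id)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0 ||
      noise_sd > 0.2)
    stop("noise_sd must be a single value in [0, 0.2] (got ", noise_sd,
         ") for ", cpg_id)
  if (direction == "none" && any(coefficients[-1] != 0))
    stop("direction 'none' requires all non-intercept coefficients to be 0",
         " for ", cpg_id)
  spec <- structure(
    list(cpg_id = cpg_id, form = form, coefficients = coefficients,
         noise_sd = noise_sd, direction = direction, role = role),
    class = "age_trend_spec")
  vals <- trend_value(spec, seq(2, 90, by = 0.5))
  if (any(vals < 0 | vals > 1))
    stop("trend for ", cpg_id, " leaves [0,1] over ages 2-90 (range ",
         signif(min(vals), 3), "..", signif(max(vals), 3), ")")
  if (direction == "increasing" && vals[length(vals)] <= vals[1L])
    stop("trend for ", cpg_id, " declared increasing but is not")
  if (direction == "decreasing" && vals[length(vals)] >= vals[1L])
    stop("trend for ", cpg_id, " declared decreasing but is not")
  spec
}

#' Evaluate a noiseless age trend
#'
#' @param spec an [age_trend_spec()].
#' @param age numeric vector of ages in years.
#' @return expected beta values (no noise, no batch offset).
#' @export
trend_value <- function(spec, age) {
  co <- spec$coefficients
  switch(spec$form,
    "linear" = co[1] + co[2] * age,
    "quadratic" = co[1] + co[2] * age + co[3] * age^2,
    "cubic" = co[1] + co[2] * age + co[3] * age^2 + co[4] * age^3,
    "logistic-clamped" =
      clamp01(co[1] + co[2] / (1 + exp(-(age - co[3]) / co[4]))))
}

#' Default 45-CpG candidate trend panel
#'
#' A fixture panel mirroring the marker-selection funnel the analysis is
#' designed around: 16 informative CpGs with monotone trends of mixed sign
#' and mixed curvature (linear, quadratic, cubic and saturating logistic
#' trajectories whose transition midpoints are staggered across the life
#' span), 7 "weak" CpGs with real but very small slopes (individually
#' detectable in a large cohort yet contributing almost nothing on top of
#' the informative set), and 22 pure-noise CpGs. One high-variance null CpG
#' (`cg07455279`) has the largest methylation range of the panel without
#' any age association. All coefficients are package fixtures, not
#' estimates from any real cohort.
#'
#' @param noise_sd noise standard deviation applied to every CpG with the
#'   default noise (the high-variance null CpG keeps its own larger value).
#' @return list of [age_trend_spec()]; attributes `informative`, `weak`
#'   and `null` give the CpG ids in each group.
#' @export
default_trend_panel <- function(noise_sd = 0.035) {
  inf <- list(
    # id, form, coefficients (intercept first), direction. Saturating
    # trends have staggered midpoints (20..85 yr): each marker drifts
    # fastest during a different life phase, so every marker carries
    # age information the others do not.
    list("cg19761273", "logistic-clamped", c(0.90, -0.45, 20,  9), "decreasing"),
    list("cg27544190", "logistic-clamped", c(0.08,  0.40, 30,  9), "increasing"),
    list("cg03286783", "linear",    c(0.30,  0.0015),              "increasing"),
    list("cg01511567", "logistic-clamped", c(0.85, -0.42, 40,  9), "decreasing"),
    list("cg07158339", "logistic-clamped", c(0.80, -0.40, 50,  9), "decreasing"),
    list("cg05442902", "logistic-clamped", c(0.36, -0.26, 60,  9), "decreasing"),
    list("cg24450312", "logistic-clamped", c(0.10,  0.38, 70,  9), "increasing"),
    list("cg17274064", "logistic-clamped", c(0.75, -0.40, 80, 10), "decreasing"),
    list("cg02085507", "cubic",     c(0.12,  0.0130, -1.7e-4, 8.0e-7), "increasing"),
    list("cg20692569", "linear",    c(0.12,  0.0045),              "increasing"),
    list("cg04528819", "quadratic", c(0.05,  0.0002,  4.5e-5),     "increasing"),
    list("cg08370996", "logistic-clamped", c(0.65, -0.35, 55, 16), "decreasing"),
    list("cg04084157", "linear",    c(0.25,  0.0040),              "increasing"),
    list("cg22736354", "logistic-clamped", c(0.10,  0.58, 45, 13), "increasing"),
    list("cg06493994", "quadratic", c(0.04,  0.0105, -6.0e-5),     "increasing"),
    list("cg02479575", "logistic-clamped", c(0.22,  0.32, 35, 15), "increasing"))
  specs <- lapply(inf, function(z)
    age_trend_spec(z[[1]], z[[2]], z[[3]], noise_sd, z[[4]],
                   role = "informative"))
  weak_ids <- sprintf("cg9%07d", 1:7)
  weak_slopes <- c(4e-4, -4e-4, 5e-4, -5e-4, 3e-4, -3e-4, 2.5e-4)
  for (i in seq_along(weak_ids)) {
    specs[[length(specs) + 1L]] <- age_trend_spec(
      weak_ids[i], "linear", c(if (weak_slopes[i] > 0) 0.3 else 0.6,
                               weak_slopes[i]),
      noise_sd, if (weak_slopes[i] > 0) "increasing" else "decreasing",
      role = "weak")
  }
  # high-variance null CpG: widest observed range, no age association
  specs[[length(specs) + 1L]] <- age_trend_spec(
    "cg07455279", "linear", c(0.5, 0), 0.2, "none", role = "null")
  null_ids <- sprintf("cg9%07d", 8:28)
  for (id in null_ids) {
    specs[[length(specs) + 1L]] <- age_trend_spec(
      id, "linear", c(0.4, 0), noise_sd, "none", role = "null")
  }
  ids <- vapply(specs, `[[`, "", "cpg_id")
  roles <- vapply(specs, `[[`, "", "role")
  structure(specs,
            informative = ids[roles == "informative"],
            weak = ids[roles == "weak"],
            null = ids[roles == "null"])
}

#' Specify a synthetic cohort
#'
#' @param n_samples number of samples.
#' @param age_range numeric length-2, minimum and maximum age in years.
#' @param age_distribution `"uniform-per-decade"` (stratified uniform with
#'   near-equal samples per decade, the design the pooled training set
#'   aims for), `"uniform"`, or a numeric vector of per-year weights over
#'   the integer ages in `age_range`.
#' @param datasets `data.frame` with columns `label`, `batch_offset`
#'   (additive constant on the beta scale, identical across ages within a
#'   dataset) and `n` (samples per dataset; must sum to `n_samples`).
#' @param sex_ratio fraction of female samples.
#' @param trend_specs list of [age_trend_spec()].
#' @param seed integer seed; the generated cohort is deterministic given
#'   the spec.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples, age_range = c(2, 90),
                        age_distribution = "uniform-per-decade",
                        datasets = NULL, sex_ratio = 0.516,
                        trend_specs = default_trend_panel(), seed = 1L) {
  if (!is.numeric(n_samples) || n_samples < 1)
    stop("n_samples must be a positive integer")
  if (length(age_range) != 2L || age_range[1] >= age_range[2] ||
      age_range[1] < 0)
    stop("invalid age range [", age_range[1], ", ", age_range[2], "]")
  if (is.null(datasets))
    datasets <- data.frame(label = "ds1", batch_offset = 0, n = n_samples)
  if (sum(datasets$n) != n_samples)
    stop("dataset shares (", sum(datasets$n), ") must sum to n_samples (",
         n_samples, ")")
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must be in [0,1]")
  structure(list(n_samples = as.integer(n_samples), age_range = age_range,
                 age_distribution = age_distribution, datasets = datasets,
                 sex_ratio = sex_ratio, trend_specs = trend_specs,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default study-scale cohort specification
#'
#' 1156 whole-blood samples aged 2–90 with roughly equal representation
#' per decade, pooled from seven synthetic "studies" with constant batch
#' offsets up to ±0.05 on the beta scale, a near-balanced sex ratio
#' (597/1156 female) and the default 45-CpG candidate panel.
#'
#' @param seed integer seed.
#' @param noise_sd per-CpG noise standard deviation for the default panel.
#' @return a [cohort_spec()].
#' @export
default_cohort_spec <- function(seed = 1L, noise_sd = 0.035) {
  offsets <- c(-0.05, -0.03, -0.015, 0, 0.015, 0.03, 0.05)
  n_ds <- rep(1156 %/% 7, 7)
  n_ds[seq_len(1156 %% 7)] <- n_ds[seq_len(1156 %% 7)] + 1L
  cohort_spec(
    n_samples = 1156,
    datasets = data.frame(label = sprintf("geo%02d", 1:7),
                          batch_offset = offsets, n = n_ds),
    sex_ratio = 597 / 1156,
    trend_specs = default_trend_panel(noise_sd),
    seed = seed)
}

sample_ages <- function(n, age_range, distribution) {
  lo <- age_range[1]; hi <- age_range[2]
  if (is.numeric(distribution)) {
    ages <- seq(lo, hi)
    if (length(distribution) != length(ages))
      stop("custom age weights must have one weight per integer age in range")
    return(sample(ages, n, replace = TRUE, prob = distribution) + runif(n))
  }
  if (identical(distribution, "uniform"))
    return(runif(n, lo, hi))
  if (identical(distribution, "uniform-per-decade")) {
    breaks <- unique(c(seq(floor(lo / 10) * 10, hi, by = 10), hi))
    breaks[1] <- lo
    k <- length(breaks) - 1L
    per <- rep(n %/% k, k)
    extra <- sample.int(k, n %% k)
    per[extra] <- per[extra] + 1L
    ages <- unlist(lapply(seq_len(k), function(i)
      runif(per[i], breaks[i], breaks[i + 1])))
    return(sample(ages))
  }
  stop("unknown age_distribution: ", distribution)
}

#' Generate a synthetic beta-value cohort
#'
#' Draws ages, sex, ethnicity and dataset labels per the spec, evaluates
#' every CpG trend, adds the dataset batch offset and Gaussian noise on
#' the beta scale, and clamps to \[0, 1\]. Sex and ethnicity have no effect
#' on any CpG (null covariates). Deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return a `data.frame` (class `beta_matrix`) with columns `sample_id`,
#'   `age`, `sex`, `ethnicity`, `dataset`, `tissue`, then one column per
#'   CpG. The attribute `ground_truth` holds the trend table.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples
    age <- sample_ages(n, spec$age_range, spec$age_distribution)
    sex <- ifelse(runif(n) < spec$sex_ratio, "F", "M")
    ethnicity <- sample(c("eur", "afr", "asn"), n, replace = TRUE)
    dataset <- sample(rep(spec$datasets$label, spec$datasets$n))
    offset <- spec$datasets$batch_offset[match(dataset, spec$datasets$label)]
    out <- data.frame(
      sample_id = sprintf("S%05d", seq_len(n)), age = age, sex = sex,
      ethnicity = ethnicity, dataset = dataset, tissue = "blood",
      stringsAsFactors = FALSE)
    for (ts in spec$trend_specs) {
      mu <- trend_value(ts, age) + offset
      noise <- if (ts$noise_sd > 0) rnorm(n, 0, ts$noise_sd) else 0
      out[[ts$cpg_id]] <- clamp01(mu + noise)
    }
    attr(out, "ground_truth") <- trend_table(spec$trend_specs)
    class(out) <- c("beta_matrix", "data.frame")
    out
  })
}

trend_table <- function(trend_specs) {
  data.frame(
    cpg_id = vapply(trend_specs, `[[`, "", "cpg_id"),
    form = vapply(trend_specs, `[[`, "", "form"),
    direction = vapply(trend_specs, `[[`, "", "direction"),
    role = vapply(trend_specs, `[[`, "", "role"),
    noise_sd = vapply(trend_specs, `[[`, 0, "noise_sd"),
    coefficients = vapply(trend_specs, function(z)
      paste(z$coefficients, collapse = ","), ""),
    stringsAsFactors = FALSE)
}

#' Specify a monozygotic twin cohort
#'
#' @param n_pairs number of twin pairs.
#' @param shared_deviation_sd SD of the per-pair shared beta deviation
#'   (both twins get the same draw: shared genetics/early environment).
#' @param individual_deviation_sd SD of the per-individual deviation; the
#'   only driver of within-pair beta differences.
#' @param age_range ages (both members of a pair share one age).
#' @return object of class `twin_cohort_spec`.
#' @export
twin_cohort_spec <- function(n_pairs, shared_deviation_sd = 0.03,
                             individual_deviation_sd = 0.015,
                             age_range = c(33, 77)) {
  if (n_pairs < 1) stop("n_pairs must be positive")
  structure(list(n_pairs = as.integer(n_pairs),
                 shared_deviation_sd = shared_deviation_sd,
                 individual_deviation_sd = individual_deviation_sd,
                 age_range = age_range),
            class = "twin_cohort_spec")
}

#' Generate a monozygotic twin cohort
#'
#' Pairs share one age and one per-CpG shared deviation; members add an
#' independent individual deviation. With
#' `individual_deviation_sd = 0` the within-pair beta difference is
#' exactly zero at every CpG.
#'
#' @param spec a [twin_cohort_spec()].
#' @param trends list of [age_trend_spec()] (trend `noise_sd` is ignored;
#'   the twin spec's deviations replace it).
#' @param seed integer seed.
#' @return a `beta_matrix` with an extra `pair_id` column.
#' @export
generate_twin_cohort <- function(spec, trends = default_trend_panel(),
                                 seed = 1L) {
  stopifnot(inherits(spec, "twin_cohort_spec"))
  with_seed(seed, {
    np <- spec$n_pairs
    pair_age <- runif(np, spec$age_range[1], spec$age_range[2])
    age <- rep(pair_age, each = 2L)
    n <- 2L * np
    out <- data.frame(
      sample_id = sprintf("T%04d_%d", rep(seq_len(np), each = 2L), 1:2),
      pair_id = sprintf("P%04d", rep(seq_len(np), each = 2L)),
      age = age, sex = "F", ethnicity = "eur", dataset = "twins",
      tissue = "blood", stringsAsFactors = FALSE)
    for (ts in trends) {
      shared <- rep(rnorm(np, 0, spec$shared_deviation_sd), each = 2L)
      indiv <- if (spec$individual_deviation_sd > 0)
        rnorm(n, 0, spec$individual_deviation_sd) else 0
      out[[ts$cpg_id]] <- clamp01(trend_value(ts, age) + shared + indiv)
    }
    attr(out, "ground_truth") <- trend_table(trends)
    class(out) <- c("beta_matrix", "data.frame")
    out
  })
}

#' Specify a disease perturbation
#'
#' @param label cohort label.
#' @param affected_cpgs CpG ids whose betas are perturbed; empty vector
#'   means no perturbation.
#' @param shift_sd SD of the per-sample, per-CpG beta shift. Defaults to
#'   0.05 for blood-related disease and 0.02 otherwise (blood-related
#'   conditions act directly on the assayed tissue).
#' @param blood_related logical.
#' @return object of class `disease_perturbation_spec`.
#' @export
disease_perturbation_spec <- function(label, affected_cpgs,
                                      shift_sd = NULL,
                                      blood_related = FALSE) {
  if (is.null(shift_sd)) shift_sd <- if (blood_related) 0.05 else 0.02
  if (shift_sd < 0) stop("shift_sd must be >= 0")
  structure(list(label = label, affected_cpgs = affected_cpgs,
                 shift_sd = shift_sd, blood_related = blood_related),
            class = "disease_perturbation_spec")
}

#' Generate a disease-perturbed cohort
#'
#' Generates the base cohort, then adds an independent Gaussian shift
#' (`shift_sd`) to each sample at each affected CpG. With `shift_sd = 0`
#' or no affected CpGs the cohort is identical to the healthy one.
#'
#' @param dspec a [disease_perturbation_spec()].
#' @param base a [cohort_spec()] for the underlying healthy cohort.
#' @return a `beta_matrix` with a `condition` column set to the disease
#'   label.
#' @export
generate_disease_cohort <- function(dspec, base) {
  stopifnot(inherits(dspec, "disease_perturbation_spec"),
            inherits(base, "cohort_spec"))
  out <- generate_cohort(base)
  bad <- setdiff(dspec$affected_cpgs, beta_cols(out))
  if (length(bad))
    stop("affected CpGs absent from panel: ", paste(bad, collapse = ", "))
  out$condition <- dspec$label
  if (dspec$shift_sd > 0 && length(dspec$affected_cpgs)) {
    with_seed(base$seed + 104729L, {
      for (cg in dspec$affected_cpgs)
        out[[cg]] <- clamp01(out[[cg]] + rnorm(nrow(out), 0, dspec$shift_sd))
    })
  }
  out
}

#' Write / read a beta matrix as TSV
#'
#' Annotation columns first (`sample_id`, `age`, `sex`, ...), then the
#' `cg*` columns; missing values encoded as `NA`.
#'
#' @param x a `beta_matrix`.
#' @param path output file.
#' @return `write_beta_matrix` returns `path` invisibly;
#'   `read_beta_matrix` returns a `beta_matrix`.
#' @export
write_beta_matrix <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_beta_matrix
#' @export
read_beta_matrix <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(x) || !"age" %in% names(x))
    stop("not a beta matrix TSV (needs sample_id and age columns): ", path)
  class(x) <- c("beta_matrix", "data.frame")
  x
}

#' Write cohort ground truth as JSON
#'
#' @param x a generated cohort with a `ground_truth` attribute.
#' @param path output JSON file.
#' @export
write_ground_truth <- function(x, path) {
  gt <- attr(x, "ground_truth")
  if (is.null(gt)) stop("no ground_truth attribute on this matrix")
  jsonlite::write_json(gt, path, dataframe = "rows", digits = NA)
  invisible(path)
}
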