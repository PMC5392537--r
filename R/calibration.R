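# Normalization layers.
#
# Three distinct corrections share this file because they are all shifts
# or inversions on the beta scale:
#  * standard curves map assay-observed methylation back to the known
#    level of calibration standards (polynomial fit + numeric inversion);
#  * cross-dataset normalization removes constant between-study offsets
#    by per-CpG mean shifting without touching within-study variation;
#  * NGS-to-array harmonisation treats a sequencing batch as one extra
#    dataset and applies the same mean shift toward the array reference.

#' Fit a standard curve from methylation standards
#'
#' Least-squares polynomial of observed methylation on known methylation.
#' With `degree = NULL` a linear fit is compared against a cubic and the
#' cubic is kept only when it improves the residual SD by more than 20%
#' (assay distortions are usually mild, so the simpler curve is preferred
#' unless the curvature is real). Monotonicity is checked on a 0.001 grid;
#' a non-monotone polynomial falls back to the linear fit with
#' `monotone_ok = FALSE`.
#'
#' @param known known methylation fractions of the standards; must span
#'   \[0, 1\] (i.e. include 0% and 100% standards).
#' @param observed assay-observed fractions, same length.
#' @param degree polynomial degree 1–3, or `NULL` for automatic choice.
#' @param cpg_id optional marker id carried into the result.
#' @return object of class `standard_curve` with elements `degree`,
#'   `coefficients` (intercept first), `r_squared`, `residual_sd`,
#'   `monotone_ok`.
#' @export
fit_standard_curve <- function(known, observed, degree = NULL,
                               cpg_id = NA_character_) {
  if (length(known) != length(observed))
    stop("known and observed must have equal length")
  if (min(known) > 1e-9 || max(known) < 1 - 1e-9)
    stop("known standards must span [0, 1] (include 0% and 100% levels)")
  fit1 <- function(d) {
    if (length(known) < d + 2)
      stop("insufficient points: degree ", d, " needs at least ", d + 2,
           " standards, got ", length(known))
    fit <- stats::lm(observed ~ stats::poly(known, d, raw = TRUE))
    co <- unname(stats::coef(fit))
    rss <- sum(stats::residuals(fit)^2)
    tss <- sum((observed - mean(observed))^2)
    list(degree = d, coefficients = co,
         residual_sd = sqrt(rss / length(observed)),
         r_squared = if (tss > 0) 1 - rss / tss else NA_real_)
  }
  if (is.null(degree)) {
    f1 <- fit1(1L)
    f <- f1
    if (length(known) >= 5 && f1$residual_sd > 1e-8) {
      f3 <- fit1(3L)
      if (f3$residual_sd < 0.8 * f1$residual_sd) f <- f3
    }
  } else {
    if (!degree %in% 1:3) stop("degree must be 1, 2 or 3")
    f <- fit1(as.integer(degree))
  }
  mono <- curve_is_monotone(f$coefficients)
  if (!mono && f$degree > 1L) {
    f <- fit1(1L)  # fall back to linear when the polynomial wiggles
    mono <- curve_is_monotone(f$coefficients)
  }
  structure(c(f, list(monotone_ok = mono, cpg_id = cpg_id)),
            class = "standard_curve")
}

eval_poly <- function(coefficients, x) {
  y <- 0
  for (i in rev(seq_along(coefficients))) y <- y * x + coefficients[i]
  y
}

curve_is_monotone <- function(coefficients) {
  g <- eval_poly(coefficients, seq(0, 1, by = 0.001))
  all(diff(g) >= -1e-12)
}

#' Normalize an observed beta through a standard curve
#'
#' Numerically inverts the monotone fitted curve (bisection to 1e-6) and
#' clamps: observed values below the curve at 0 map to 0, above the curve
#' at 1 map to 1.
#'
#' @param curve a [fit_standard_curve()] result.
#' @param observed_beta numeric vector of observed fractions.
#' @return normalized fractions in \[0, 1\].
#' @export
apply_standard_curve <- function(curve, observed_beta) {
  stopifnot(inherits(curve, "standard_curve"))
  co <- curve$coefficients
  y0 <- eval_poly(co, 0); y1 <- eval_poly(co, 1)
  vapply(observed_beta, function(y) {
    if (is.na(y)) return(NA_real_)
    if (y <= y0) return(0)
    if (y >= y1) return(1)
    stats::uniroot(function(x) eval_poly(co, x) - y, c(0, 1),
                   tol = 1e-6)$root
  }, 0)
}

#' Remove between-dataset batch offsets by per-CpG mean shifting
#'
#' For each CpG, every dataset's values are shifted by
#' (grand mean − dataset mean), so dataset means coincide with the pooled
#' overall mean while within-dataset variation (including the age signal)
#' is untouched. Values pushed outside \[0, 1\] are clamped and counted.
#' The alternative `mode = "global"` applies one shift per dataset
#' computed across all CpGs jointly.
#'
#' @param x a `beta_matrix` with a `dataset` column.
#' @param mode `"per-cpg"` (default) or `"global"`.
#' @return the normalized `beta_matrix`; attribute `normalization_report`
#'   is a `data.frame` (dataset, cpg, shift, clamped_n), attribute
#'   `normalization_mode` records the mode.
#' @export
cross_dataset_normalize <- function(x, mode = c("per-cpg", "global")) {
  mode <- match.arg(mode)
  if (!"dataset" %in% names(x)) stop("beta matrix has no dataset column")
  cgs <- beta_cols(x)
  ds <- factor(x$dataset)
  report <- list()
  if (mode == "per-cpg") {
    for (cg in cgs) {
      v <- x[[cg]]
      grand <- mean(v, na.rm = TRUE)
      mu <- tapply(v, ds, mean, na.rm = TRUE)
      shift <- grand - mu[as.character(ds)]
      out <- v + shift
      clamped <- sum(out < 0 | out > 1, na.rm = TRUE)
      x[[cg]] <- clamp01(out)
      report[[cg]] <- data.frame(dataset = levels(ds), cpg = cg,
                                 shift = as.numeric(grand - mu),
                                 clamped_n = clamped, row.names = NULL)
    }
  } else {
    m <- as.matrix(x[, cgs, drop = FALSE])
    grand <- mean(m, na.rm = TRUE)
    mu <- tapply(rowMeans(m, na.rm = TRUE), ds, mean, na.rm = TRUE)
    shift <- grand - mu[as.character(ds)]
    clamped <- 0L
    for (cg in cgs) {
      out <- x[[cg]] + shift
      clamped <- clamped + sum(out < 0 | out > 1, na.rm = TRUE)
      x[[cg]] <- clamp01(out)
    }
    report[["all"]] <- data.frame(dataset = levels(ds), cpg = "all",
                                  shift = as.numeric(grand - mu),
                                  clamped_n = clamped, row.names = NULL)
  }
  attr(x, "normalization_report") <- do.call(rbind, report)
  attr(x, "normalization_mode") <- mode
  x
}

#' Harmonise NGS-derived betas to an array reference
#'
#' Treats the NGS batch as one extra dataset: per CpG, the batch values
#' are shifted by (reference grand mean − batch mean) and clamped. The
#' shift is a batch-level statistic, so the batch should contain several
#' samples for it to be meaningful.
#'
#' @param ngs_betas `data.frame`/matrix of NGS betas (samples x CpGs), or
#'   a single named vector (treated as a 1-sample batch, with a warning).
#' @param reference_matrix the array `beta_matrix` the model was trained
#'   on (or any matrix with the same CpG columns).
#' @return harmonised betas, same shape as `ngs_betas`; attribute
#'   `shifts` holds the applied per-CpG shift.
#' @export
ngs_to_array_normalize <- function(ngs_betas, reference_matrix) {
  single <- is.null(dim(ngs_betas))
  if (single) {
    warning("normalising a single-sample NGS batch; the mean shift is ",
            "estimated from one value")
    ngs_betas <- as.data.frame(as.list(ngs_betas))
  }
  cgs <- colnames(ngs_betas)
  missing <- setdiff(cgs, colnames(reference_matrix))
  if (length(missing))
    stop("CpGs absent from reference: ", paste(missing, collapse = ", "))
  shifts <- numeric(length(cgs)); names(shifts) <- cgs
  for (cg in cgs) {
    shifts[cg] <- mean(reference_matrix[[cg]], na.rm = TRUE) -
      mean(ngs_betas[[cg]], na.rm = TRUE)
    ngs_betas[[cg]] <- clamp01(ngs_betas[[cg]] + shifts[cg])
  }
  if (single) ngs_betas <- unlist(ngs_betas[1L, ])
  attr(ngs_betas, "shifts") <- shifts
  ngs_betas
}
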