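# Marker screening and the linear baseline.
#
# Per-CpG ordinary least squares against age, pooled covariate tests,
# forward stepwise selection by partial F, a multiple-linear-regression
# age model, prediction evaluation metrics and VIF collinearity.

#' Screen markers by per-CpG linear regression on age
#'
#' For each CpG column, fits `beta ~ age` by OLS and reports the slope
#' (beta fraction per year), Pearson r, R², the two-sided p-value for the
#' slope, and the observed methylation range (max − min). Constant CpGs
#' are flagged and excluded from significance calls.
#'
#' @param x a `beta_matrix`.
#' @param age ages in years; defaults to `x$age`.
#' @param alpha significance cut-off (raw p-values, no multiplicity
#'   correction by default).
#' @param adjust `"none"` (default) or `"BH"` for Benjamini–Hochberg.
#' @return `data.frame` with one row per CpG: `cpg_id`, `slope`,
#'   `intercept`, `r`, `r_squared`, `p_value`, `meth_range`,
#'   `significant`, `flagged`.
#' @export
screen_markers <- function(x, age = x$age, alpha = 0.05,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  cgs <- beta_cols(x)
  res <- lapply(cgs, function(cg) {
    v <- x[[cg]]
    ok <- is.finite(v) & is.finite(age)
    v <- v[ok]; a <- age[ok]
    n <- length(v)
    rng <- if (n) max(v) - min(v) else NA_real_
    if (n < 3L || stats::sd(v) == 0 || stats::sd(a) == 0) {
      return(data.frame(cpg_id = cg, slope = 0, intercept = mean(v),
                        r = NA_real_, r_squared = NA_real_,
                        p_value = NA_real_, meth_range = rng,
                        significant = NA, flagged = TRUE))
    }
    sxx <- sum((a - mean(a))^2)
    slope <- stats::cov(v, a) * (n - 1) / sxx
    intercept <- mean(v) - slope * mean(a)
    r <- stats::cor(v, a)
    rss <- sum((v - intercept - slope * a)^2)
    se <- sqrt(rss / (n - 2) / sxx)
    p <- 2 * stats::pt(abs(slope / se), n - 2, lower.tail = FALSE)
    data.frame(cpg_id = cg, slope = slope, intercept = intercept, r = r,
               r_squared = r^2, p_value = p, meth_range = rng,
               significant = NA, flagged = FALSE)
  })
  res <- do.call(rbind, res)
  p_use <- if (adjust == "BH") stats::p.adjust(res$p_value, "BH")
           else res$p_value
  res$significant <- !res$flagged & !is.na(p_use) & p_use < alpha
  res$significant[res$flagged] <- NA
  res
}

#' Test covariates against age-adjusted methylation
#'
#' Multivariate regression (Pillai trace) of the beta matrix on age plus
#' the requested covariate factors, returning one pooled p-value per
#' covariate. Age enters first so each covariate is tested on top of the
#' age association; a null covariate (e.g. sex in the generator) yields a
#' uniform p-value.
#'
#' @param x a `beta_matrix`.
#' @param age ages in years.
#' @param covariates column names of factors to test (default
#'   `c("sex", "dataset")`; any of `sex`, `ethnicity`, `dataset`).
#' @return named numeric vector of p-values, one per covariate.
#' @export
covariate_association <- function(x, age = x$age,
                                  covariates = c("sex", "dataset")) {
  missing <- setdiff(covariates, names(x))
  if (length(missing))
    stop("covariates absent from matrix: ", paste(missing, collapse = ", "))
  for (cv in covariates) {
    if (length(unique(x[[cv]])) < 2L)
      stop("covariate '", cv, "' has a single level; cannot test")
  }
  Y <- as.matrix(x[, beta_cols(x), drop = FALSE])
  df <- data.frame(age = age, lapply(x[covariates], factor))
  fit <- stats::manova(stats::as.formula(
    paste("Y ~ age +", paste(covariates, collapse = " + "))), data = df)
  st <- summary(fit, test = "Pillai")$stats
  p <- st[covariates, "Pr(>F)"]
  names(p) <- covariates
  p
}

#' Forward stepwise selection of age-predictive CpGs
#'
#' At each step the candidate with the smallest partial-F p-value is
#' added to the multiple regression of age on the selected CpGs; ties are
#' broken by candidate order. Selection stops when the best entry p-value
#' is at or above `alpha_enter` or when the R² improvement falls below
#' `r2_tol` ("no statistical improvement").
#'
#' @param x a `beta_matrix` (rows with missing candidate values are
#'   dropped).
#' @param age ages in years.
#' @param candidates candidate CpG columns (default: all `cg*` columns).
#' @param alpha_enter entry significance threshold.
#' @param r2_tol minimum R² gain to keep adding markers.
#' @return object of class `stepwise_result`: `selected` (in entry
#'   order), `r2_trajectory`, `entry_p`, `stop_reason`, `n_used`.
#' @export
stepwise_select <- function(x, age = x$age, candidates = beta_cols(x),
                            alpha_enter = 0.05, r2_tol = 1e-4) {
  X <- as.matrix(x[, candidates, drop = FALSE])
  ok <- stats::complete.cases(X) & is.finite(age)
  X <- X[ok, , drop = FALSE]; y <- age[ok]
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  selected <- character(0)
  r2_traj <- numeric(0)
  entry_p <- numeric(0)
  D <- matrix(1, n, 1)  # current design: intercept + selected
  rss0 <- tss
  stop_reason <- "exhausted candidates"
  remaining <- candidates
  while (length(remaining)) {
    k <- ncol(D)  # parameters in current model
    stats_cand <- vapply(remaining, function(cg) {
      Dc <- cbind(D, X[, cg])
      qrD <- qr(Dc)
      if (qrD$rank < ncol(Dc)) return(c(NA_real_, NA_real_))
      rss1 <- sum(qr.resid(qrD, y)^2)
      df2 <- n - k - 1L
      Fv <- (rss0 - rss1) / (rss1 / df2)
      c(stats::pf(Fv, 1, df2, lower.tail = FALSE), rss1)
    }, c(0, 0))
    ps <- stats_cand[1L, ]
    if (all(is.na(ps))) { stop_reason <- "all candidates collinear"; break }
    best <- which.min(ps)  # first minimum wins: deterministic tie-break
    if (ps[best] >= alpha_enter) {
      stop_reason <- sprintf("best entry p %.3g >= alpha_enter %.3g",
                             ps[best], alpha_enter)
      break
    }
    rss1 <- unname(stats_cand[2L, best])
    dr2 <- (rss0 - rss1) / tss
    if (dr2 < r2_tol) {
      stop_reason <- sprintf("delta R-squared %.3g < r2_tol %.3g",
                             dr2, r2_tol)
      break
    }
    cg <- remaining[best]
    selected <- c(selected, cg)
    entry_p <- c(entry_p, ps[best])
    D <- cbind(D, X[, cg])
    rss0 <- rss1
    r2_traj <- c(r2_traj, 1 - rss0 / tss)
    remaining <- remaining[-best]
  }
  structure(list(selected = selected, r2_trajectory = r2_traj,
                 entry_p = entry_p, stop_reason = stop_reason, n_used = n),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("Forward stepwise selection:", length(x$selected), "CpGs",
      "(n =", x$n_used, ")\n")
  if (length(x$selected))
    cat("  order:", paste(x$selected, collapse = ", "), "\n",
        " final R-squared:", round(utils::tail(x$r2_trajectory, 1), 4), "\n")
  cat("  stopped:", x$stop_reason, "\n")
  invisible(x)
}

#' Multiple-linear-regression age model
#'
#' Ordinary least squares of age on the selected CpG betas. Rows with
#' missing values in the model CpGs are dropped from fitting (and
#' counted); prediction refuses samples with missing model CpGs.
#'
#' @param x a `beta_matrix`.
#' @param age ages in years.
#' @param cpgs model CpG columns.
#' @return object of class `linear_age_model` with `intercept`,
#'   `coefficients`, `cpgs`, `training` (an [evaluate_predictions()]
#'   report) and `n_dropped`.
#' @export
fit_linear_age_model <- function(x, age = x$age, cpgs) {
  missing <- setdiff(cpgs, names(x))
  if (length(missing))
    stop("model CpGs absent from matrix: ", paste(missing, collapse = ", "))
  X <- as.matrix(x[, cpgs, drop = FALSE])
  ok <- stats::complete.cases(X) & is.finite(age)
  fit <- stats::lm.fit(cbind(1, X[ok, , drop = FALSE]), age[ok])
  co <- fit$coefficients
  model <- structure(
    list(intercept = unname(co[1]),
         coefficients = stats::setNames(unname(co[-1]), cpgs),
         cpgs = cpgs, n_dropped = sum(!ok)),
    class = "linear_age_model")
  model$training <- evaluate_predictions(age[ok], fit$fitted.values)
  model
}

#' Predict ages from a linear age model
#'
#' @param object a `linear_age_model`.
#' @param newdata a `beta_matrix` or matrix containing the model CpGs.
#' @param ... unused.
#' @return numeric vector of predicted ages.
#' @export
predict.linear_age_model <- function(object, newdata, ...) {
  missing <- setdiff(object$cpgs, colnames(newdata))
  if (length(missing))
    stop("prediction refused; missing model CpGs: ",
         paste(missing, collapse = ", "))
  X <- as.matrix(as.data.frame(newdata)[, object$cpgs, drop = FALSE])
  if (anyNA(X)) {
    bad <- object$cpgs[colSums(is.na(X)) > 0]
    stop("prediction refused; NA values in model CpGs: ",
         paste(bad, collapse = ", "))
  }
  drop(object$intercept + X %*% object$coefficients)
}

#' Evaluate age predictions
#'
#' Summarises prediction performance the way age-model studies report it:
#' mean absolute error, SD of the absolute error, R² (squared Pearson
#' correlation of predicted vs true), the fractions of samples within
#' ±5 and ±10 years, the 75th percentile of absolute error, and the
#' skewness of the signed errors (predicted − true).
#'
#' @param true_ages numeric vector.
#' @param predicted_ages numeric vector.
#' @return object of class `evaluation_report` (a list; the `residuals`
#'   element is a per-sample table of true age, prediction and error).
#' @export
evaluate_predictions <- function(true_ages, predicted_ages) {
  if (length(true_ages) != length(predicted_ages))
    stop("true and predicted lengths differ")
  err <- predicted_ages - true_ages
  abs_err <- abs(err)
  r2 <- if (length(err) > 2L && stats::sd(predicted_ages) > 0 &&
            stats::sd(true_ages) > 0)
    stats::cor(true_ages, predicted_ages)^2 else NA_real_
  structure(list(
    n = length(err),
    mae = mean(abs_err),
    sd_abs_error = stats::sd(abs_err),
    r_squared = r2,
    frac_within_5 = mean(abs_err <= 5),
    frac_within_10 = mean(abs_err <= 10),
    q75_abs_error = unname(stats::quantile(abs_err, 0.75)),
    skewness = sample_skewness(err),
    residuals = data.frame(true_age = true_ages,
                           predicted_age = predicted_ages, error = err)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "Age prediction (n = %d): MAE %.2f yr (SD %.2f), R2 %.3f\n",
    x$n, x$mae, x$sd_abs_error, x$r_squared))
  cat(sprintf("  within +/-5 yr: %.1f%%  within +/-10 yr: %.1f%%  q75 |err|: %.2f yr  skew: %.2f\n",
              100 * x$frac_within_5, 100 * x$frac_within_10,
              x$q75_abs_error, x$skewness))
  invisible(x)
}

#' Variance inflation factors for a set of CpGs
#'
#' VIF of each CpG against the others: `1 / (1 - R²_j)` where `R²_j` is
#' from regressing CpG j on the remaining CpGs. Values above `cap`
#' (numerically collinear inputs, e.g. duplicated columns) are reported
#' as `cap` with `capped = TRUE`.
#'
#' @param x a `beta_matrix` or matrix.
#' @param cpgs columns to assess.
#' @param cap finite ceiling for reported VIFs.
#' @return `data.frame` with `cpg_id`, `vif`, `capped`.
#' @export
vif_markers <- function(x, cpgs = beta_cols(x), cap = 1e6) {
  X <- as.matrix(as.data.frame(x)[, cpgs, drop = FALSE])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  out <- lapply(seq_along(cpgs), function(j) {
    yj <- X[, j]
    others <- cbind(1, X[, -j, drop = FALSE])
    res <- stats::lm.fit(others, yj)$residuals
    tssj <- sum((yj - mean(yj))^2)
    r2 <- if (tssj > 0) 1 - sum(res^2) / tssj else 1
    v <- if (r2 >= 1 - 1 / cap) cap else 1 / (1 - r2)
    data.frame(cpg_id = cpgs[j], vif = v, capped = v >= cap)
  })
  do.call(rbind, out)
}
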