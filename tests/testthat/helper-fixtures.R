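# shared fixtures, all built in code

# tiny trend set: one strongly informative CpG, one weak, one null
tiny_trends <- function(noise_sd = 0.035) {
  list(
    age_trend_spec("cg00000001", "linear", c(0.2, 0.005), noise_sd,
                   "increasing", role = "informative"),
    age_trend_spec("cg00000002", "linear", c(0.6, -0.0005), noise_sd,
                   "decreasing", role = "weak"),
    age_trend_spec("cg00000003", "linear", c(0.4, 0), noise_sd, "none",
                   role = "null"))
}

tiny_cohort <- function(n = 200, seed = 1, noise_sd = 0.035,
                        trends = tiny_trends(noise_sd), datasets = NULL) {
  generate_cohort(cohort_spec(n, datasets = datasets,
                              trend_specs = trends, seed = seed))
}

# the packaged synthetic 16-marker panel, loaded once per test run
fixture_panel <- local({
  panel <- NULL
  function() {
    if (is.null(panel)) panel <<- example_panel()
    panel
  }
})

# single-marker subset of a panel
subset_panel <- function(panel, ids) {
  marker_panel(unclass(panel)[ids])
}

# brute-force GRNN oracle: direct double-loop kernel average on
# standardized inputs (independent of the package's vectorised path)
grnn_oracle <- function(X, y, Q, sigma, center, scale) {
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  Qs <- sweep(sweep(Q, 2, center), 2, scale, "/")
  out <- numeric(nrow(Qs))
  for (i in seq_len(nrow(Qs))) {
    num <- 0; den <- 0
    for (j in seq_len(nrow(Xs))) {
      w <- exp(-sum((Qs[i, ] - Xs[j, ])^2) / (2 * sigma^2))
      num <- num + w * y[j]
      den <- den + w
    }
    out[i] <- num / den
  }
  out
}

# exact binomial 99% interval for a proportion
binom_ci99 <- function(n, p) {
  stats::qbinom(c(0.005, 0.995), n, p) / n
}
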