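# per-CpG screening, covariate tests, stepwise selection, linear
# baseline, evaluation metrics, VIF

test_that("screening recovers perfect, null and constant markers", {
  x <- data.frame(sample_id = sprintf("s%d", 1:200),
                  age = seq(2, 90, length.out = 200))
  x$cg00000001 <- 0.2 + 0.005 * x$age
  set.seed(41)
  x$cg00000002 <- runif(200, 0.3, 0.5)
  x$cg00000003 <- 0.4
  class(x) <- c("beta_matrix", "data.frame")
  sc <- screen_markers(x)
  expect_equal(sc$r[1], 1, tolerance = 1e-12)
  expect_lt(sc$p_value[1], 1e-100)
  expect_true(sc$significant[1])
  expect_false(sc$significant[2])
  expect_true(sc$flagged[3])
  expect_true(is.na(sc$significant[3]))
  expect_equal(sc$meth_range[1], 0.005 * 88, tolerance = 1e-12)
})

test_that("null markers rarely reach |r| > 0.1 at n = 1000", {
  withr::local_seed(17)
  rs <- vapply(1:50, function(i) {
    x <- data.frame(sample_id = as.character(1:1000),
                    age = runif(1000, 2, 90),
                    cg00000001 = runif(1000))
    class(x) <- c("beta_matrix", "data.frame")
    abs(screen_markers(x)$r)
  }, 0)
  expect_gte(mean(rs < 0.1), 0.98)
})

test_that("null sex effects give uniform covariate p-values; real effects are detected", {
  tr <- tiny_trends(0.05)
  withr::local_seed(23)
  ps <- vapply(1:400, function(s) {
    co <- generate_cohort(cohort_spec(100, trend_specs = tr, seed = s))
    covariate_association(co, covariates = "sex")[["sex"]]
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # injected sex shift of 0.1 at one CpG is found at n = 500
  co <- generate_cohort(cohort_spec(500, trend_specs = tr, seed = 77))
  co$cg00000001 <- clamp01(co$cg00000001 + 0.1 * (co$sex == "F"))
  expect_lt(covariate_association(co, covariates = "sex")[["sex"]],
            0.001)
  co$onelevel <- "a"
  expect_error(covariate_association(co, covariates = "onelevel"),
               "single level")
})

test_that("stepwise selects the true predictor and ignores noise", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    age <- runif(500, 2, 90)
    x <- data.frame(sample_id = as.character(1:500), age = age,
                    cg00000001 = clamp01(0.1 + 0.005 * age +
                                           rnorm(500, 0, 0.02)),
                    cg00000002 = runif(500, 0.2, 0.8))
    class(x) <- c("beta_matrix", "data.frame")
    identical(stepwise_select(x)$selected, "cg00000001")
  }, TRUE)
  expect_true(all(hits))
})

test_that("a perfect predictor is selected in one step with R-squared 1", {
  age <- seq(2, 90, length.out = 100)
  x <- data.frame(sample_id = as.character(1:100), age = age,
                  cg00000001 = 0.1 + 0.009 * age)
  class(x) <- c("beta_matrix", "data.frame")
  sw <- stepwise_select(x)
  expect_equal(sw$selected, "cg00000001")
  expect_equal(sw$r2_trajectory, 1, tolerance = 1e-12)
})

test_that("all-noise candidates: empty-selection rate matches the order-statistic oracle", {
  # oracle: with m independent null candidates the selection stays empty
  # when min p >= alpha (prob ~ (1-alpha)^m) or the best candidate's
  # R-squared gain falls under r2_tol; the observed empty rate must sit
  # inside a binomial 99% band around the oracle simulation
  m <- 10; n <- 100; alpha <- 0.05; runs <- 200
  withr::local_seed(31)
  oracle_empty <- mean(vapply(seq_len(runs), function(i) {
    ps <- vapply(seq_len(m), function(j) {
      yy <- rnorm(n); xx <- rnorm(n)
      summary(stats::lm(yy ~ xx))$coefficients[2, 4]
    }, 0)
    min(ps) >= alpha
  }, TRUE))
  observed <- mean(vapply(seq_len(runs), function(i) {
    x <- data.frame(sample_id = as.character(1:n),
                    age = runif(n, 2, 90))
    for (j in seq_len(m))
      x[[sprintf("cg%08d", j)]] <- runif(n)
    class(x) <- c("beta_matrix", "data.frame")
    length(stepwise_select(x)$selected) == 0L
  }, TRUE))
  band <- binom_ci99(runs, oracle_empty)
  expect_gte(observed, band[1] - 0.05)
  expect_lte(observed, band[2] + 0.05)
})

test_that("stepwise is invariant to candidate column permutation", {
  co <- tiny_cohort(n = 400, seed = 19)
  sw1 <- stepwise_select(co)
  perm <- rev(beta_cols(co))
  sw2 <- stepwise_select(co, candidates = perm)
  expect_setequal(sw1$selected, sw2$selected)
})

test_that("stepwise picks only individually significant CpGs on synthetic data", {
  co <- cross_dataset_normalize(generate_cohort(default_cohort_spec(1)))
  sw <- stepwise_select(co)
  sc <- screen_markers(co)
  sig <- sc$cpg_id[!is.na(sc$significant) & sc$significant]
  expect_true(all(sw$selected %in% sig))
})

test_that("linear model fits noiseless data exactly and guards inputs", {
  tr <- list(age_trend_spec("cg00000001", "linear", c(0.2, 0.005), 0,
                            "increasing"),
             age_trend_spec("cg00000002", "linear", c(0.7, -0.004), 0,
                            "decreasing"))
  co <- generate_cohort(cohort_spec(100, trend_specs = tr, seed = 2))
  lm1 <- fit_linear_age_model(co, cpgs = beta_cols(co))
  expect_lt(lm1$training$mae, 1e-8)
  expect_error(fit_linear_age_model(co, cpgs = c("cg00000001", "cgXX")),
               "cgXX")
  expect_error(predict(lm1, co[, "cg00000001", drop = FALSE]),
               "cg00000002")
  co2 <- co
  co2$cg00000002[3] <- NA
  expect_error(predict(lm1, co2), "NA values")
})

test_that("linear-model error sits at the noise-implied analytic floor", {
  # closed form: with p independent linear markers of slope b and noise
  # sd s, the age information is p (b/s)^2, so the best achievable
  # absolute error is sqrt(2/pi) / sqrt(p) / (b/s)
  b <- 0.004; s <- 0.035; p <- 8
  tr <- lapply(seq_len(p), function(j)
    age_trend_spec(sprintf("cg%08d", j), "linear", c(0.2, b), s,
                   "increasing"))
  co <- generate_cohort(cohort_spec(1156, trend_specs = tr, seed = 4))
  fit <- fit_linear_age_model(co, cpgs = beta_cols(co))
  floor_mae <- sqrt(2 / pi) / sqrt(p * (b / s)^2)
  expect_lt(abs(fit$training$mae - floor_mae), 0.5)
})

test_that("evaluation metrics match hand-computed values", {
  ev <- evaluate_predictions(c(10, 20, 30), c(11, 18, 33))
  expect_equal(ev$mae, 2)
  ev2 <- evaluate_predictions(1:50, 1:50)
  expect_equal(ev2$frac_within_5, 1)
  expect_equal(ev2$frac_within_10, 1)
  expect_equal(ev2$skewness, 0)
  expect_equal(ev2$mae, 0)
  ev3 <- evaluate_predictions(rep(0, 4), c(-6, 4, 4, 4))
  expect_equal(ev3$frac_within_5, 0.75)
  expect_equal(ev3$frac_within_10, 1)
  expect_error(evaluate_predictions(1:3, 1:4), "lengths differ")
  # band ordering is structural
  set.seed(50)
  ev4 <- evaluate_predictions(runif(100, 2, 90),
                              runif(100, 2, 90))
  expect_lte(ev4$frac_within_5, ev4$frac_within_10)
})

test_that("VIF flags collinearity and respects orthogonality", {
  n <- 64
  x1 <- rep(c(0.4, 0.6), each = n / 2)
  x2 <- rep(c(0.4, 0.6), times = n / 2)
  x <- data.frame(cg00000001 = x1, cg00000002 = x2)
  v <- vif_markers(x, c("cg00000001", "cg00000002"))
  expect_equal(v$vif, c(1, 1), tolerance = 1e-10)
  set.seed(60)
  x$cg00000003 <- x$cg00000001
  v2 <- vif_markers(x)
  expect_true(all(v2$capped[v2$cpg_id != "cg00000002"]))
  x$cg00000003 <- clamp01(x1 + x2 - 0.4 + rnorm(n, 0, 0.01))
  v3 <- vif_markers(x)
  expect_gt(v3$vif[v3$cpg_id == "cg00000003"], 10)
})
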