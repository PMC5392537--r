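# GRNN kernel regression: oracle equivalence, limits, staged
# optimisation, sensitivity, subset search, serialization

make_xy <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p,
              dimnames = list(NULL, sprintf("cg%08d", seq_len(p))))
  list(X = X, y = runif(n, 2, 90))
}

test_that("degenerate and symmetric exemplar sets behave exactly", {
  one <- grnn_fit(matrix(0.5, 1, 1, dimnames = list(NULL, "cg1")),
                  40, input_cpgs = "cg1", sigma = 0.7,
                  standardize = FALSE)
  expect_equal(predict(one, matrix(c(0.1, 0.9, 0.5), 3, 1,
                                   dimnames = list(NULL, "cg1"))),
               rep(40, 3))
  two <- grnn_fit(matrix(c(0, 1), 2, 1, dimnames = list(NULL, "cg1")),
                  c(20, 60), input_cpgs = "cg1", sigma = 0.4,
                  standardize = FALSE)
  expect_equal(predict(two, matrix(0.5, 1, 1,
                                   dimnames = list(NULL, "cg1"))), 40)
})

test_that("vectorised prediction equals the brute-force kernel average", {
  d <- make_xy(10, 4, 1)
  q <- make_xy(5, 4, 2)
  m <- grnn_fit(d$X, d$y, input_cpgs = colnames(d$X), sigma = 0.6)
  expect_equal(predict(m, q$X),
               grnn_oracle(d$X, d$y, q$X, 0.6, m$center, m$scale),
               tolerance = 1e-10)
})

test_that("predictions are convex combinations of training ages", {
  d <- make_xy(60, 6, 3)
  q <- make_xy(40, 6, 4)
  for (sg in c(0.05, 0.5, 3)) {
    m <- grnn_fit(d$X, d$y, input_cpgs = colnames(d$X), sigma = sg)
    p <- predict(m, q$X)
    expect_true(all(p >= min(d$y) & p <= max(d$y)))
  }
})

test_that("sigma limits recover the mean and the nearest neighbour", {
  d <- make_xy(30, 3, 5)
  q <- make_xy(7, 3, 6)
  m_inf <- grnn_fit(d$X, d$y, input_cpgs = colnames(d$X), sigma = 1e6)
  expect_equal(predict(m_inf, q$X), rep(mean(d$y), 7),
               tolerance = 1e-6)
  m_0 <- grnn_fit(d$X, d$y, input_cpgs = colnames(d$X), sigma = 1e-8)
  Xs <- sweep(sweep(d$X, 2, m_0$center), 2, m_0$scale, "/")
  Qs <- sweep(sweep(q$X, 2, m_0$center), 2, m_0$scale, "/")
  nn <- apply(Qs, 1, function(qq)
    which.min(colSums((t(Xs) - qq)^2)))
  expect_equal(predict(m_0, q$X), d$y[nn])
})

test_that("prediction guards dimensionality and missing values", {
  d <- make_xy(20, 3, 7)
  m <- grnn_fit(d$X, d$y, input_cpgs = colnames(d$X), sigma = 1)
  expect_error(predict(m, d$X[, 1:2]), "missing model inputs")
  bad <- d$X; bad[1, 2] <- NA
  expect_error(predict(m, bad), "missing input values")
  expect_error(grnn_fit(d$X, d$y[-1]), "sizes differ")
  expect_error(grnn_fit(d$X, d$y, sigma = -1), "sigma")
})

test_that("sigma tuning reaches low verification error on dense noiseless data", {
  tr <- list(age_trend_spec("cg00000001", "linear", c(0.1, 0.008), 0,
                            "increasing"),
             age_trend_spec("cg00000002", "linear", c(0.9, -0.008), 0,
                            "decreasing"))
  co <- generate_cohort(cohort_spec(600, trend_specs = tr, seed = 8))
  spl <- make_split(600, split_spec(0.6, seed = 1))
  m <- grnn_fit(co[spl$train, ], co$age[spl$train])
  m <- tune_sigma(m, co[spl$verify, ], co$age[spl$verify])
  expect_lt(m$verify_mae, 0.5)
  expect_false(m$sigma_boundary)
  # cramped interval forces a boundary warning
  expect_warning(tune_sigma(m, co[spl$verify, ], co$age[spl$verify],
                            interval = c(5, 10)), "boundary")
  # identical exemplars: constant prediction, warning
  flat <- co[rep(1, 20), ]
  mflat <- suppressWarnings(grnn_fit(flat, rep(50, 20)))
  expect_warning(tune_sigma(mflat, co[1:10, ], co$age[1:10]),
                 "degenerate")
})

test_that("split sizes follow the rounding convention", {
  expect_equal(split_sizes(1156, 0.6),
               c(train = 694, verify = 231, blind = 231))
  expect_equal(split_sizes(1156, 0.5),
               c(train = 578, verify = 289, blind = 289))
  expect_error(split_sizes(1156, 0.45), "0.5, 0.7")
  expect_error(split_sizes(1156, 0.75), "0.5, 0.7")
  expect_error(split_spec(0.8), "0.5, 0.7")
})

test_that("splits are deterministic and honour fixed blind cases", {
  s1 <- make_split(100, split_spec(0.6, seed = 5))
  s2 <- make_split(100, split_spec(0.6, seed = 5))
  expect_identical(s1, s2)
  expect_length(intersect(s1$train, s1$verify), 0)
  expect_length(intersect(s1$train, s1$blind), 0)
  expect_equal(sort(c(s1$train, s1$verify, s1$blind)), 1:100)
  blind <- 91:100
  s3 <- make_split(100, split_spec(0.6, seed = 6,
                                   fixed_blind_ids = blind))
  expect_equal(sort(s3$blind), blind)
  expect_length(intersect(s3$train, blind), 0)
})

test_that("stage 1 is reproducible and rejects bad proportions", {
  co <- tiny_cohort(n = 150, seed = 10)
  a <- stage1_split_search(co, co$age, p_grid = c(0.5, 0.6),
                           repeats = 2, seed = 3)
  b <- stage1_split_search(co, co$age, p_grid = c(0.5, 0.6),
                           repeats = 2, seed = 3)
  expect_equal(a$results, b$results)
  expect_equal(a$best_p, b$best_p)
  expect_error(stage1_split_search(co, co$age, p_grid = c(0.4, 0.6)),
               "0.5, 0.7")
})

test_that("stage 3 replicate variability grows with generator noise", {
  sd_at <- function(noise) {
    tr <- list(age_trend_spec("cg00000001", "linear", c(0.1, 0.008),
                              noise, "increasing"),
               age_trend_spec("cg00000002", "linear", c(0.9, -0.008),
                              noise, "decreasing"))
    co <- generate_cohort(cohort_spec(240, trend_specs = tr, seed = 21))
    spl <- make_split(240, split_spec(0.6, seed = 2))
    reps <- stage3_replicates(co, co$age, beta_cols(co), spl, k = 8,
                              seed = 31)
    reps$summary$sd_mae[reps$summary$subset == "blind"]
  }
  sds <- vapply(c(0.005, 0.04, 0.12), sd_at, 0)
  expect_lt(sds[1], sds[3])
  expect_lt(sds[1], 0.2)
  # k = 1 warns and reports zero spread
  co <- tiny_cohort(n = 100, seed = 11)
  spl <- make_split(100, split_spec(0.6, seed = 1))
  expect_warning(r1 <- stage3_replicates(co, co$age, beta_cols(co),
                                         spl, k = 1, seed = 1),
                 "SD reported as 0")
  expect_equal(unique(r1$summary$sd_mae), 0)
})

test_that("sensitivity ratios separate informative from irrelevant inputs", {
  # one informative input + one constant input: removing the constant
  # leaves predictions untouched (ratio exactly 1); removing the sole
  # informative input collapses the model (ratio > 2)
  set.seed(12)
  n <- 300
  age <- runif(n, 2, 90)
  x <- data.frame(sample_id = as.character(1:n), age = age,
                  cg00000001 = clamp01(0.1 + 0.009 * age +
                                         rnorm(n, 0, 0.01)),
                  cg00000002 = 0.5)
  class(x) <- c("beta_matrix", "data.frame")
  spl <- make_split(n, split_spec(0.6, seed = 3))
  m <- suppressWarnings(
    grnn_fit(x[spl$train, ], age[spl$train]))
  m <- tune_sigma(m, x[spl$verify, ], age[spl$verify])
  sens <- sensitivity_analysis(list(m), x, age, blind_ids = spl$blind)
  r <- sens$summary
  expect_equal(r$mean[r$cpg_id == "cg00000002"], 1, tolerance = 1e-12)
  expect_gt(r$mean[r$cpg_id == "cg00000001"], 2)
  expect_equal(r$rank[r$cpg_id == "cg00000001"], 1)
})

test_that("pure-noise inputs have error ratios near one across replicates", {
  tr <- c(tiny_trends(0.035),
          list(age_trend_spec("cg00000004", "linear", c(0.45, 0), 0.035,
                              "none", role = "null")))
  co <- generate_cohort(cohort_spec(400, trend_specs = tr, seed = 14))
  spl <- make_split(400, split_spec(0.6, seed = 4))
  reps <- stage3_replicates(co, co$age, beta_cols(co), spl, k = 6,
                            seed = 15)
  sens <- sensitivity_analysis(reps, co, co$age)
  noise_mean <- sens$summary$mean[sens$summary$cpg_id == "cg00000004"]
  expect_lt(abs(noise_mean - 1), 0.05)
  expect_equal(sens$summary$rank[sens$summary$cpg_id == "cg00000001"], 1)
})

test_that("input subset search edge cases and recovery", {
  co <- tiny_cohort(n = 120, seed = 16)
  spl <- make_split(120, split_spec(0.6, seed = 5))
  expect_warning(all_in <- input_subset_search(co, co$age, split = spl,
                                               budget = 0),
                 "budget 0")
  expect_setequal(all_in$selected, beta_cols(co))
  one <- input_subset_search(co, co$age, candidates = "cg00000001",
                             split = spl, budget = 10)
  expect_equal(one$selected, "cg00000001")
  # on a reduced cohort the search keeps informative inputs, rejects
  # null CpGs and never scores worse than the all-input model
  spec <- default_cohort_spec(seed = 41)
  spec$n_samples <- 400L
  nds <- rep(400 %/% 7, 7); nds[seq_len(400 %% 7)] <- nds[seq_len(400 %% 7)] + 1L
  spec$datasets$n <- nds
  co <- generate_cohort(spec)
  spl <- make_split(400, split_spec(0.6, seed = 1))
  got <- input_subset_search(co, co$age, split = spl, budget = 400,
                             seed = 1)
  tr <- default_trend_panel()
  expect_length(intersect(got$selected, attr(tr, "null")), 0)
  expect_gte(mean(got$selected %in% attr(tr, "informative")), 0.5)
  m_all <- grnn_fit(co[spl$train, ], co$age[spl$train])
  m_all <- suppressWarnings(tune_sigma(m_all, co[spl$verify, ],
                                       co$age[spl$verify]))
  expect_lte(got$verify_mae, m_all$verify_mae)
})

test_that("GRNN serialization round trips", {
  d <- make_xy(25, 4, 18)
  m <- grnn_fit(d$X, d$y, input_cpgs = colnames(d$X), sigma = 0.8)
  js <- withr::local_tempfile(fileext = ".json")
  write_grnn(m, js)
  back <- read_grnn(js)
  q <- make_xy(6, 4, 19)
  expect_equal(predict(back, q$X), predict(m, q$X), tolerance = 1e-12)
  expect_false(is.null(back$training_data_md5))
})
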