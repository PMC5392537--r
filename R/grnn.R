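# Generalised regression neural network (GRNN) age model.
#
# A GRNN is Specht-style kernel regression: one pattern unit per training
# case, a Gaussian radial basis of width sigma on standardized inputs,
# and a numerator/denominator summation pair
#
#   yhat(x) = sum_i y_i exp(-||x - x_i||^2 / (2 sigma^2))
#           / sum_i     exp(-||x - x_i||^2 / (2 sigma^2)).
#
# Predictions are convex combinations of training ages, hence bounded by
# the training age range. sigma -> 0 recovers the nearest exemplar's age;
# sigma -> Inf the training mean. The exponent is stabilised by
# subtracting the per-query maximum so tiny sigmas do not underflow.
#
# The staged optimisation mirrors how such models are tuned in practice:
# Stage 1 searches training/verification/blind proportions with fully
# random splits; Stage 2 fixes the blind cases and resamples the
# train/verify assignment; Stage 3 assesses reproducibility over k
# replicate models on the fixed split (here: bootstrap resamples of the
# training exemplars, since the base fit is otherwise deterministic).

#' Fit a GRNN age model
#'
#' Stores the training exemplars and targets, the per-input
#' standardization (mean/SD over the training exemplars; beta ranges
#' differ ~50-fold across CpGs, so unstandardized Euclidean distance
#' would be dominated by the widest-range inputs), and the smoothing
#' width.
#'
#' @param x training inputs: `beta_matrix`, `data.frame` or matrix.
#' @param y training ages in years.
#' @param input_cpgs input columns (default: all `cg*` columns of `x`).
#' @param sigma smoothing width in standardized units (scalar isotropic,
#'   or one value per input); may be `NULL` and set later via
#'   [tune_sigma()].
#' @param standardize standardize inputs before distance computation.
#' @return object of class `grnn`.
#' @export
grnn_fit <- function(x, y, input_cpgs = NULL, sigma = NULL,
                     standardize = TRUE) {
  df <- as.data.frame(x)
  if (is.null(input_cpgs))
    input_cpgs <- grep("^cg", colnames(df), value = TRUE)
  if (!length(input_cpgs)) stop("no input columns")
  missing <- setdiff(input_cpgs, colnames(df))
  if (length(missing))
    stop("inputs absent from training data: ",
         paste(missing, collapse = ", "))
  X <- as.matrix(df[, input_cpgs, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X) || anyNA(y)) stop("training data contain missing values")
  if (nrow(X) != length(y)) stop("x and y sizes differ")
  if (!is.null(sigma) && any(sigma <= 0)) stop("sigma must be > 0")
  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    if (any(scale == 0)) {
      warning("constant input(s): ",
              paste(input_cpgs[scale == 0], collapse = ", "),
              "; standardized with unit scale")
      scale[scale == 0] <- 1
    }
  } else {
    center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
  }
  structure(list(
    exemplars = X, targets = as.numeric(y), input_cpgs = input_cpgs,
    sigma = sigma, center = stats::setNames(center, input_cpgs),
    scale = stats::setNames(scale, input_cpgs)),
    class = "grnn")
}

# kernel-average prediction on already-standardized matrices
grnn_kernel_average <- function(Xs, y, Qs, sigma) {
  if (length(sigma) > 1L) {  # per-input widths: rescale axes, sigma = 1
    Qs <- sweep(Qs, 2, sigma, "/")
    Xs <- sweep(Xs, 2, sigma, "/")
    sigma <- 1
  }
  d2 <- outer(rowSums(Qs^2), rowSums(Xs^2), "+") - 2 * tcrossprod(Qs, Xs)
  d2[d2 < 0] <- 0
  E <- -d2 / (2 * sigma^2)
  Emax <- E[cbind(seq_len(nrow(E)), max.col(E, ties.method = "first"))]
  W <- exp(E - Emax)
  drop(W %*% y) / rowSums(W)
}

#' Predict ages with a GRNN
#'
#' @param object a fitted `grnn` (with `sigma` set).
#' @param newdata matrix/`data.frame` containing the model's input CpGs,
#'   or a single named vector.
#' @param ... unused.
#' @return predicted ages (years); always within the training age range.
#' @export
predict.grnn <- function(object, newdata, ...) {
  if (is.null(object$sigma))
    stop("model has no sigma; run tune_sigma() first")
  if (is.null(dim(newdata))) {
    if (is.null(names(newdata)))
      stop("query dimensionality mismatch: unnamed vector")
    newdata <- as.data.frame(as.list(newdata))
  }
  df <- as.data.frame(newdata)
  missing <- setdiff(object$input_cpgs, colnames(df))
  if (length(missing))
    stop("query missing model inputs: ", paste(missing, collapse = ", "))
  Q <- as.matrix(df[, object$input_cpgs, drop = FALSE])
  storage.mode(Q) <- "double"
  if (anyNA(Q)) stop("query contains missing input values")
  Qs <- sweep(sweep(Q, 2, object$center), 2, object$scale, "/")
  Xs <- sweep(sweep(object$exemplars, 2, object$center), 2,
              object$scale, "/")
  grnn_kernel_average(Xs, object$targets, Qs, object$sigma)
}

#' Tune the GRNN smoothing width on a verification set
#'
#' Golden-section search (via [stats::optimize()]) of log-sigma over
#' `interval`, minimising verification-set mean absolute error. A chosen
#' sigma within 1% of either interval end triggers a boundary warning.
#'
#' @param model a `grnn` fitted on the training cases.
#' @param x_verify,y_verify verification inputs and ages.
#' @param interval search interval for sigma in standardized units.
#' @param tol relative tolerance of the search.
#' @return the model with `sigma` set; also carries `verify_mae` and
#'   `sigma_boundary`.
#' @export
tune_sigma <- function(model, x_verify, y_verify,
                       interval = c(0.01, 10), tol = 1e-3) {
  stopifnot(inherits(model, "grnn"))
  Xs <- sweep(sweep(model$exemplars, 2, model$center), 2, model$scale, "/")
  if (all(apply(Xs, 2, stats::sd) == 0) || nrow(Xs) == 1L) {
    warning("degenerate training set (identical exemplars); ",
            "predictions are constant and sigma is irrelevant")
    model$sigma <- mean(interval)
    model$verify_mae <- mae(y_verify,
                            rep(mean(model$targets), length(y_verify)))
    model$sigma_boundary <- FALSE
    return(model)
  }
  df <- as.data.frame(x_verify)
  Q <- as.matrix(df[, model$input_cpgs, drop = FALSE])
  storage.mode(Q) <- "double"
  Qs <- sweep(sweep(Q, 2, model$center), 2, model$scale, "/")
  f <- function(ls)
    mae(y_verify, grnn_kernel_average(Xs, model$targets, Qs, exp(ls)))
  opt <- stats::optimize(f, log(interval), tol = tol)
  model$sigma <- exp(opt$minimum)
  model$verify_mae <- opt$objective
  rel <- (opt$minimum - log(interval[1])) / diff(log(interval))
  model$sigma_boundary <- rel < 0.01 || rel > 0.99
  if (model$sigma_boundary)
    warning(sprintf("tuned sigma %.4g is at the search boundary [%g, %g]",
                    model$sigma, interval[1], interval[2]))
  model
}

#' Train/verification/blind partition sizes
#'
#' Rounding convention: `train = round(p_train * n)`,
#' `verify = round(p_verify * n)`, blind takes the remainder. For
#' n = 1156 at 60:20:20 this yields 694/231/231.
#'
#' @param n number of cases.
#' @param p_train training proportion (must lie in \[0.5, 0.7\]).
#' @param p_verify verification proportion; default splits the remainder
#'   equally between verification and blind test.
#' @return named integer vector `(train, verify, blind)`.
#' @export
split_sizes <- function(n, p_train, p_verify = (1 - p_train) / 2) {
  if (p_train < 0.5 || p_train > 0.7)
    stop("p_train must be in [0.5, 0.7], got ", p_train)
  tr <- round(p_train * n)
  ve <- round(p_verify * n)
  bl <- n - tr - ve
  if (bl < 1) stop("proportions leave no blind cases")
  c(train = as.integer(tr), verify = as.integer(ve), blind = as.integer(bl))
}

#' Specify a random data split
#'
#' @param p_train,p_verify proportions (see [split_sizes()]).
#' @param seed integer seed for the random assignment.
#' @param fixed_blind_ids optional indices to hold fixed as the blind set
#'   (Stage 2/3 style).
#' @return object of class `split_spec`.
#' @export
split_spec <- function(p_train, p_verify = (1 - p_train) / 2, seed = 1L,
                       fixed_blind_ids = NULL) {
  if (p_train < 0.5 || p_train > 0.7)
    stop("p_train must be in [0.5, 0.7], got ", p_train)
  structure(list(p_train = p_train, p_verify = p_verify,
                 seed = as.integer(seed),
                 fixed_blind_ids = fixed_blind_ids),
            class = "split_spec")
}

#' Draw a train/verify/blind partition
#'
#' @param n number of cases.
#' @param spec a [split_spec()].
#' @return list of integer index vectors `train`, `verify`, `blind`.
#' @export
make_split <- function(n, spec) {
  sizes <- split_sizes(n, spec$p_train, spec$p_verify)
  with_seed(spec$seed, {
    if (is.null(spec$fixed_blind_ids)) {
      ids <- sample.int(n)
      list(train = ids[seq_len(sizes["train"])],
           verify = ids[sizes["train"] + seq_len(sizes["verify"])],
           blind = ids[(sizes["train"] + sizes["verify"] + 1L):n])
    } else {
      blind <- spec$fixed_blind_ids
      rest <- sample(setdiff(seq_len(n), blind))
      ntr <- min(sizes["train"], length(rest) - 1L)
      list(train = rest[seq_len(ntr)],
           verify = rest[(ntr + 1L):length(rest)],
           blind = blind)
    }
  })
}

train_on_split <- function(x, age, inputs, split, interval = c(0.01, 10),
                           tol = 1e-3) {
  m <- grnn_fit(x[split$train, , drop = FALSE], age[split$train],
                input_cpgs = inputs)
  m <- tune_sigma(m, x[split$verify, , drop = FALSE], age[split$verify],
                  interval = interval, tol = tol)
  m$split <- split
  m$blind_mae <- mae(age[split$blind],
                     predict(m, x[split$blind, , drop = FALSE]))
  m
}

#' Stage 1: search training/verification proportions
#'
#' For each candidate training proportion, cases are randomly partitioned
#' `repeats` times; each time a GRNN is fitted, sigma tuned on the
#' verification set and the blind-set MAE recorded. The proportion with
#' the lowest mean blind MAE wins, and the best-performing repeat at that
#' proportion is returned.
#'
#' @param x a `beta_matrix`.
#' @param age ages.
#' @param inputs model input CpGs.
#' @param p_grid candidate training proportions, each in \[0.5, 0.7\].
#' @param repeats random re-partitions per proportion.
#' @param seed integer seed (each partition derives its own sub-seed).
#' @return list: `best_spec` ([split_spec()] of the winning run),
#'   `model`, `results` (per-run table), `best_p`.
#' @export
stage1_split_search <- function(x, age, inputs = beta_cols(x),
                                p_grid = c(0.5, 0.55, 0.6, 0.65, 0.7),
                                repeats = 3L, seed = 1L) {
  if (any(p_grid < 0.5 | p_grid > 0.7))
    stop("p_train must be in [0.5, 0.7]")
  runs <- list(); models <- list()
  for (i in seq_along(p_grid)) {
    for (r in seq_len(repeats)) {
      sp <- split_spec(p_grid[i], seed = seed + 1000L * i + r)
      m <- train_on_split(x, age, inputs, make_split(nrow(x), sp))
      runs[[length(runs) + 1L]] <- data.frame(
        p_train = p_grid[i], rep = r, sigma = m$sigma,
        verify_mae = m$verify_mae, blind_mae = m$blind_mae)
      models[[length(models) + 1L]] <- list(model = m, spec = sp)
    }
  }
  results <- do.call(rbind, runs)
  mean_blind <- tapply(results$blind_mae, results$p_train, mean)
  best_p <- as.numeric(names(mean_blind)[which.min(mean_blind)])
  at_p <- which(results$p_train == best_p)
  best <- at_p[which.min(results$blind_mae[at_p])]
  list(best_spec = models[[best]]$spec, model = models[[best]]$model,
       results = results, best_p = best_p)
}

#' Stage 2: resample train/verify with the blind set fixed
#'
#' Keeps the winning Stage-1 blind cases fixed and redraws the
#' train/verify assignment `resamples` times; the model with the lowest
#' verification MAE wins (the blind set stays untouched for final
#' evaluation).
#'
#' @param x,age,inputs as in [stage1_split_search()].
#' @param p_train winning training proportion.
#' @param blind_ids fixed blind-case indices.
#' @param resamples number of redraws.
#' @param seed integer seed.
#' @return list: `model` (best by verification MAE), `results` table.
#' @export
stage2_fixed_blind <- function(x, age, inputs, p_train, blind_ids,
                               resamples = 5L, seed = 1L) {
  runs <- list(); models <- list()
  for (r in seq_len(resamples)) {
    sp <- split_spec(p_train, seed = seed + r,
                     fixed_blind_ids = blind_ids)
    m <- train_on_split(x, age, inputs, make_split(nrow(x), sp))
    runs[[r]] <- data.frame(rep = r, sigma = m$sigma,
                            verify_mae = m$verify_mae,
                            blind_mae = m$blind_mae)
    models[[r]] <- m
  }
  results <- do.call(rbind, runs)
  best <- which.min(results$verify_mae)
  list(model = models[[best]], results = results)
}

#' Stage 3: replicate models on a fixed split
#'
#' With all three subsets fixed, trains `k` replicate GRNNs, each on a
#' bootstrap resample of the training exemplars (the replicate-to-
#' replicate stochasticity; verification and blind cases never move), and
#' summarises the variability of the subset errors as mean ± SD.
#'
#' @param x,age,inputs as in [stage1_split_search()].
#' @param split fixed list of `train`/`verify`/`blind` indices.
#' @param k number of replicates (default 10).
#' @param seed integer seed.
#' @param bootstrap resample training exemplars per replicate; `FALSE`
#'   makes all replicates identical.
#' @return object of class `grnn_replicates`: `models`, `errors`
#'   (k x 3 MAE table), `summary` (mean and SD per subset), `split`.
#' @export
stage3_replicates <- function(x, age, inputs, split, k = 10L, seed = 1L,
                              bootstrap = TRUE) {
  if (k < 2L) warning("k = ", k, " replicates: SD reported as 0")
  models <- vector("list", k)
  errs <- matrix(NA_real_, k, 3,
                 dimnames = list(NULL, c("train", "verify", "blind")))
  for (r in seq_len(k)) {
    tr <- if (bootstrap)
      with_seed(seed + r, sample(split$train, replace = TRUE))
    else split$train
    rs <- list(train = tr, verify = split$verify, blind = split$blind)
    m <- train_on_split(x, age, inputs, rs)
    # subset errors are always measured on the original fixed subsets
    errs[r, "train"] <- mae(age[split$train],
                            predict(m, x[split$train, , drop = FALSE]))
    errs[r, "verify"] <- m$verify_mae
    errs[r, "blind"] <- m$blind_mae
    models[[r]] <- m
  }
  summ <- data.frame(
    subset = colnames(errs),
    mean_mae = colMeans(errs),
    sd_mae = if (k >= 2L) apply(errs, 2, stats::sd) else rep(0, 3),
    row.names = NULL)
  structure(list(models = models, errors = errs, summary = summ,
                 split = split),
            class = "grnn_replicates")
}

#' Variable-removal sensitivity analysis
#'
#' For every input of every replicate model, the blind-set MAE is
#' re-evaluated with that input removed (remaining inputs keep their
#' standardization; exemplars unchanged) and expressed as the error ratio
#' MAE(without input) / MAE(all inputs). Ratios above 1 mean the input
#' contributes to accuracy; inputs are ranked by mean ratio across
#' replicates (rank 1 = largest = most depended upon).
#'
#' @param replicates a [stage3_replicates()] result, or a list of `grnn`
#'   models.
#' @param x a `beta_matrix`.
#' @param age ages.
#' @param blind_ids blind-set indices (defaults to the replicates' fixed
#'   split).
#' @return object of class `sensitivity_report`: `ratios` (k x p matrix)
#'   and `summary` (per input: mean, median, q25, q75, rank).
#' @export
sensitivity_analysis <- function(replicates, x, age, blind_ids = NULL) {
  models <- if (inherits(replicates, "grnn_replicates")) {
    if (is.null(blind_ids)) blind_ids <- replicates$split$blind
    replicates$models
  } else replicates
  if (is.null(blind_ids)) stop("blind_ids required")
  xb <- x[blind_ids, , drop = FALSE]
  yb <- age[blind_ids]
  inputs <- models[[1L]]$input_cpgs
  ratios <- matrix(NA_real_, length(models), length(inputs),
                   dimnames = list(NULL, inputs))
  for (r in seq_along(models)) {
    m <- models[[r]]
    base <- mae(yb, predict(m, xb))
    for (j in seq_along(inputs)) {
      mj <- m
      keep <- setdiff(inputs, inputs[j])
      mj$exemplars <- m$exemplars[, keep, drop = FALSE]
      mj$center <- m$center[keep]; mj$scale <- m$scale[keep]
      mj$input_cpgs <- keep
      ratios[r, j] <- mae(yb, predict(mj, xb)) / base
    }
  }
  mean_r <- colMeans(ratios)
  summ <- data.frame(
    cpg_id = inputs, mean = mean_r,
    median = apply(ratios, 2, stats::median),
    q25 = apply(ratios, 2, stats::quantile, 0.25),
    q75 = apply(ratios, 2, stats::quantile, 0.75),
    rank = rank(-mean_r, ties.method = "first"), row.names = NULL)
  structure(list(ratios = ratios, summary = summ),
            class = "sensitivity_report")
}

#' Search for a well-performing input subset
#'
#' Greedy forward selection scored by verification-set MAE, followed by
#' random add/drop/swap moves, under a finite budget of subset
#' evaluations. A budget of 0 returns all inputs with a warning.
#'
#' @param x a `beta_matrix`.
#' @param age ages.
#' @param candidates candidate input CpGs.
#' @param split list of `train`/`verify` indices (a `blind` element, if
#'   present, is never consulted).
#' @param budget maximum number of subset evaluations.
#' @param seed integer seed for the random phase.
#' @param tol sigma-search tolerance (coarse by default; each evaluation
#'   re-tunes sigma).
#' @return list: `selected` inputs, `verify_mae`, `evaluations` used,
#'   `trace` of best scores.
#' @export
input_subset_search <- function(x, age, candidates = beta_cols(x), split,
                                budget = 2000L, seed = 1L, tol = 0.05) {
  if (budget <= 0L) {
    warning("budget 0: returning all candidate inputs unsearched")
    return(list(selected = candidates, verify_mae = NA_real_,
                evaluations = 0L, trace = numeric(0)))
  }
  if (length(candidates) == 1L) {
    m <- train_on_split(x, age, candidates,
                        c(split, list(blind = split$verify)), tol = tol)
    return(list(selected = candidates, verify_mae = m$verify_mae,
                evaluations = 1L, trace = m$verify_mae))
  }
  evals <- 0L
  score <- function(subset) {
    evals <<- evals + 1L
    m <- grnn_fit(x[split$train, , drop = FALSE], age[split$train],
                  input_cpgs = subset)
    m <- suppressWarnings(
      tune_sigma(m, x[split$verify, , drop = FALSE],
                 age[split$verify], tol = tol))
    m$verify_mae
  }
  current <- character(0); current_mae <- Inf
  trace <- numeric(0)
  repeat {  # greedy forward
    remaining <- setdiff(candidates, current)
    if (!length(remaining) || evals + length(remaining) > budget) break
    scores <- vapply(remaining, function(cg) score(c(current, cg)), 0)
    best <- which.min(scores)
    if (scores[best] >= current_mae) break
    current <- c(current, remaining[best])
    current_mae <- scores[best]
    trace <- c(trace, current_mae)
  }
  with_seed(seed, {
    while (evals < budget) {  # random neighbourhood moves
      prop <- current
      move <- sample(c("add", "drop", "swap"), 1L)
      rem <- setdiff(candidates, prop)
      if (move == "add" && length(rem)) prop <- c(prop, sample(rem, 1L))
      else if (move == "drop" && length(prop) > 1L)
        prop <- setdiff(prop, sample(prop, 1L))
      else if (move == "swap" && length(rem) && length(prop))
        prop <- c(setdiff(prop, sample(prop, 1L)), sample(rem, 1L))
      if (identical(sort(prop), sort(current))) next
      s <- score(prop)
      if (s < current_mae) {
        current <- prop; current_mae <- s
        trace <- c(trace, current_mae)
      }
    }
  })
  list(selected = current, verify_mae = current_mae, evaluations = evals,
       trace = trace)
}

#' Serialize / restore a GRNN model as JSON
#'
#' Stores exemplars, targets, sigma, input ids, standardization and a
#' provenance hash of the training exemplars.
#'
#' @param model a `grnn`.
#' @param path JSON file path.
#' @return `write_grnn` returns `path` invisibly; `read_grnn` a `grnn`.
#' @export
write_grnn <- function(model, path) {
  stopifnot(inherits(model, "grnn"))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  utils::write.table(cbind(model$exemplars, .y = model$targets), tmp,
                     sep = "\t", row.names = FALSE)
  obj <- list(
    type = "grnn", input_cpgs = model$input_cpgs, sigma = model$sigma,
    center = as.list(model$center), scale = as.list(model$scale),
    targets = model$targets,
    exemplars = as.data.frame(model$exemplars),
    training_data_md5 = unname(tools::md5sum(tmp)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grnn
#' @export
read_grnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "grnn")) stop("not a serialized grnn: ", path)
  X <- as.matrix(as.data.frame(obj$exemplars))[, obj$input_cpgs,
                                               drop = FALSE]
  dimnames(X) <- list(NULL, obj$input_cpgs)
  structure(list(
    exemplars = X, targets = as.numeric(obj$targets),
    input_cpgs = obj$input_cpgs, sigma = as.numeric(obj$sigma),
    center = unlist(obj$center)[obj$input_cpgs],
    scale = unlist(obj$scale)[obj$input_cpgs],
    training_data_md5 = obj$training_data_md5),
    class = "grnn")
}

#' @export
print.grnn <- function(x, ...) {
  cat(sprintf("GRNN age model: %d-%d-2-1 (inputs-pattern units-summation-output)\n",
              length(x$input_cpgs), nrow(x$exemplars)))
  cat("  sigma:", if (is.null(x$sigma)) "untuned"
      else signif(x$sigma, 4), "\n")
  invisible(x)
}
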