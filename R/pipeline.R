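# Pipeline orchestration and cohort-level evaluation.
#
# run_pipeline() chains the stages -- cohort generation (or loading),
# cross-dataset normalization, marker screening, stepwise selection,
# the linear baseline, staged GRNN optimisation and sensitivity
# analysis -- writing stage artifacts and a machine-readable manifest
# sufficient to re-execute deterministically. The evaluate_* functions
# apply a trained model to twin, disease and other labelled cohorts, and
# ngs_validation_loop() closes the loop from FASTQ replicates back into
# an array-trained model.

#' Build a pipeline run configuration
#'
#' @param cohort a [cohort_spec()] to generate, or `NULL` when
#'   `input_path` is given.
#' @param input_path optional beta-matrix TSV to use instead of
#'   generating a cohort.
#' @param out_dir output directory for artifacts (created if needed);
#'   `NULL` keeps everything in memory.
#' @param seed master seed; stage seeds derive from it.
#' @param normalization_mode `"per-cpg"` or `"global"` (see
#'   [cross_dataset_normalize()]).
#' @param p_grid Stage-1 training-proportion grid.
#' @param stage1_repeats,stage2_resamples,stage3_k staged-optimisation
#'   effort knobs.
#' @param min_reads NGS coverage threshold carried into manifests.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = default_cohort_spec(), input_path = NULL,
                       out_dir = NULL, seed = 1L,
                       normalization_mode = "per-cpg",
                       p_grid = c(0.5, 0.6, 0.7), stage1_repeats = 2L,
                       stage2_resamples = 3L, stage3_k = 10L,
                       min_reads = 1000L) {
  if (is.null(cohort) && is.null(input_path))
    stop("stage dependency unmet: no cohort spec and no input_path; ",
         "the pipeline has nothing to run on")
  structure(list(cohort = cohort, input_path = input_path,
                 out_dir = out_dir, seed = as.integer(seed),
                 normalization_mode = normalization_mode,
                 p_grid = p_grid, stage1_repeats = stage1_repeats,
                 stage2_resamples = stage2_resamples,
                 stage3_k = stage3_k, min_reads = min_reads),
            class = "run_config")
}

#' Run the full array-data pipeline
#'
#' Executes, in order: cohort generation/loading, cross-dataset
#' normalization, per-CpG screening, forward stepwise selection, the
#' multiple-linear-regression baseline, Stage 1–3 GRNN optimisation on
#' the stepwise-selected inputs, and sensitivity analysis. Artifacts are
#' written under `config$out_dir` (when set) together with
#' `manifest.json` recording the configuration, seeds, package version
#' and artifact checksums; identical configs yield identical outputs.
#'
#' @param config a [run_config()].
#' @return list with elements `matrix` (normalized cohort), `screen`,
#'   `stepwise`, `linear_model`, `linear_eval`, `stage1`, `stage2`,
#'   `replicates`, `sensitivity`, `grnn` (the final model),
#'   `grnn_eval` (per-subset reports) and `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  x <- if (!is.null(config$input_path)) {
    if (!file.exists(config$input_path))
      stop("stage dependency unmet: input matrix not found at ",
           config$input_path)
    read_beta_matrix(config$input_path)
  } else generate_cohort(config$cohort)
  x <- cross_dataset_normalize(x, mode = config$normalization_mode)
  screen <- screen_markers(x)
  sw <- stepwise_select(x)
  if (!length(sw$selected))
    stop("stepwise selection chose no markers; cannot train models")
  lin <- fit_linear_age_model(x, cpgs = sw$selected)
  lin_eval <- evaluate_predictions(x$age, predict(lin, x))
  s1 <- stage1_split_search(x, x$age, inputs = sw$selected,
                            p_grid = config$p_grid,
                            repeats = config$stage1_repeats,
                            seed = config$seed)
  s2 <- stage2_fixed_blind(x, x$age, sw$selected, s1$best_p,
                           s1$model$split$blind,
                           resamples = config$stage2_resamples,
                           seed = config$seed + 7L)
  reps <- stage3_replicates(x, x$age, sw$selected, s2$model$split,
                            k = config$stage3_k,
                            seed = config$seed + 13L)
  best_rep <- which.min(reps$errors[, "verify"])
  grnn <- reps$models[[best_rep]]
  sens <- sensitivity_analysis(reps, x, x$age)
  split <- s2$model$split
  grnn_eval <- lapply(split, function(ids)
    evaluate_predictions(x$age[ids], predict(grnn,
                                             x[ids, , drop = FALSE])))
  res <- list(matrix = x, screen = screen, stepwise = sw,
              linear_model = lin, linear_eval = lin_eval, stage1 = s1,
              stage2 = s2, replicates = reps, sensitivity = sens,
              grnn = grnn, grnn_eval = grnn_eval)
  res$manifest <- write_run_artifacts(res, config)
  res
}

write_run_artifacts <- function(res, config) {
  manifest <- list(
    package = "methage",
    version = as.character(utils::packageVersion("methage")),
    seed = config$seed, normalization_mode = config$normalization_mode,
    p_grid = config$p_grid, stage1_repeats = config$stage1_repeats,
    stage2_resamples = config$stage2_resamples,
    stage3_k = config$stage3_k, min_reads = config$min_reads,
    cohort_seed = if (!is.null(config$cohort)) config$cohort$seed,
    input_path = config$input_path,
    selected_cpgs = res$stepwise$selected,
    sigma = res$grnn$sigma,
    split_sizes = vapply(res$grnn$split, length, 0L))
  if (is.null(config$out_dir)) return(manifest)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    matrix = file.path(config$out_dir, "normalized_matrix.tsv"),
    screen = file.path(config$out_dir, "marker_screen.tsv"),
    model = file.path(config$out_dir, "grnn_model.json"),
    report = file.path(config$out_dir, "evaluation.json"))
  write_beta_matrix(res$matrix, paths["matrix"])
  utils::write.table(res$screen, paths["screen"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_grnn(res$grnn, paths["model"])
  jsonlite::write_json(
    list(linear = unclass(res$linear_eval)[
           c("n", "mae", "sd_abs_error", "r_squared", "frac_within_5",
             "frac_within_10", "q75_abs_error", "skewness")],
         grnn = lapply(res$grnn_eval, function(e) unclass(e)[
           c("n", "mae", "sd_abs_error", "r_squared")]),
         replicate_summary = res$replicates$summary,
         sensitivity = res$sensitivity$summary),
    paths["report"], auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest$artifacts <- as.list(tools::md5sum(paths))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Evaluate a model on a monozygotic twin cohort
#'
#' Predicts every twin, reports the blind-test error, the within-pair
#' prediction differences (mean ± SD) and a paired t-test of member-1 vs
#' member-2 predictions. Identical within-pair predictions make the
#' t-test degenerate; it is then reported as p = 1 with a flag.
#'
#' @param model a `grnn` or `linear_age_model`.
#' @param twins a twin `beta_matrix` with `pair_id` (every pair complete).
#' @return list: `eval` ([evaluate_predictions()]), `pair_diff_mean`,
#'   `pair_diff_sd`, `paired_t_p`, `degenerate_t`, `n_pairs`.
#' @export
evaluate_twins <- function(model, twins) {
  if (!"pair_id" %in% names(twins)) stop("twin matrix needs pair_id")
  tab <- table(twins$pair_id)
  if (any(tab != 2L))
    stop("unpaired sample(s) in pairs: ",
         paste(names(tab)[tab != 2L], collapse = ", "))
  ord <- order(twins$pair_id)
  twins <- twins[ord, , drop = FALSE]
  pred <- predict(model, twins)
  ev <- evaluate_predictions(twins$age, pred)
  p1 <- pred[seq(1, length(pred), by = 2L)]
  p2 <- pred[seq(2, length(pred), by = 2L)]
  d <- p1 - p2
  degenerate <- stats::sd(d) == 0
  pt <- if (degenerate) 1 else stats::t.test(p1, p2, paired = TRUE)$p.value
  list(eval = ev, pair_diff_mean = mean(abs(d)),
       pair_diff_sd = stats::sd(abs(d)), paired_t_p = pt,
       degenerate_t = degenerate, n_pairs = length(d))
}

#' Evaluate a model across labelled cohorts
#'
#' @param model a `grnn` or `linear_age_model`.
#' @param cohorts named list of `beta_matrix` objects (e.g. healthy,
#'   blood-related disease, non-blood disease, saliva-like). Empty
#'   cohorts are skipped with a warning; cohorts missing model CpGs
#'   raise an error naming them.
#' @return `data.frame`: cohort, n, mae, sd_abs_error, r_squared.
#' @export
evaluate_cohorts <- function(model, cohorts) {
  stopifnot(is.list(cohorts), !is.null(names(cohorts)))
  rows <- lapply(names(cohorts), function(nm) {
    x <- cohorts[[nm]]
    if (is.null(x) || !nrow(x)) {
      warning("cohort '", nm, "' is empty; skipped")
      return(NULL)
    }
    ev <- evaluate_predictions(x$age, predict(model, x))
    data.frame(cohort = nm, n = ev$n, mae = ev$mae,
               sd_abs_error = ev$sd_abs_error,
               r_squared = ev$r_squared, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' NGS validation loop: FASTQ replicates into an array-trained model
#'
#' Quantifies each replicate read batch against the panel, filters by
#' coverage, conversion-corrects, averages corrected target betas over
#' passing replicates, optionally normalizes through per-marker standard
#' curves and then to the array reference, and predicts age with the
#' array-trained model. Markers with no passing replicate abort the
#' prediction (forensic caution) unless `on_missing = "impute"`, which
#' substitutes the training-exemplar mean.
#'
#' @param model a trained `grnn` (or `linear_age_model`).
#' @param replicate_batches list (one element per sample) of lists of
#'   `read_batch` replicates (e.g. triplicates).
#' @param panel a `marker_panel`.
#' @param standard_curves optional named list of `standard_curve`s per
#'   marker (from sequencing the 0–100% methylation standards).
#' @param reference_matrix optional array `beta_matrix` for
#'   [ngs_to_array_normalize()]; `NULL` skips harmonisation.
#' @param true_ages optional ages for reporting.
#' @param min_reads coverage threshold per marker.
#' @param on_missing `"refuse"` (default) or `"impute"`.
#' @return list: `betas` (samples x markers, after all normalization),
#'   `predictions`, and `eval` when `true_ages` given.
#' @export
ngs_validation_loop <- function(model, replicate_batches, panel,
                                standard_curves = NULL,
                                reference_matrix = NULL,
                                true_ages = NULL, min_reads = 1000L,
                                on_missing = c("refuse", "impute")) {
  on_missing <- match.arg(on_missing)
  betas <- t(vapply(replicate_batches, function(reps) {
    calls <- lapply(reps, quantify_reads, panel = panel,
                    min_reads = min_reads)
    average_replicates(calls)
  }, numeric(length(panel))))
  colnames(betas) <- names(panel)
  if (!is.null(standard_curves)) {
    for (mk in colnames(betas)) {
      if (!is.null(standard_curves[[mk]]))
        betas[, mk] <- apply_standard_curve(standard_curves[[mk]],
                                            betas[, mk])
    }
  }
  if (anyNA(betas)) {
    bad <- colnames(betas)[colSums(is.na(betas)) > 0]
    if (on_missing == "refuse")
      stop("all replicates failed coverage for marker(s): ",
           paste(bad, collapse = ", "),
           "; prediction refused (use on_missing = 'impute' to override)")
    for (mk in bad) {
      fill <- if (inherits(model, "grnn"))
        mean(model$exemplars[, mk]) else NA_real_
      if (is.na(fill)) stop("cannot impute marker ", mk)
      betas[is.na(betas[, mk]), mk] <- fill
      warning("imputed training-mean beta for marker ", mk)
    }
  }
  if (!is.null(reference_matrix))
    betas <- ngs_to_array_normalize(as.data.frame(betas),
                                    reference_matrix)
  betas <- as.matrix(as.data.frame(betas))
  predictions <- predict(model, betas)
  out <- list(betas = betas, predictions = predictions)
  if (!is.null(true_ages))
    out$eval <- evaluate_predictions(true_ages, predictions)
  out
}
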