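#' Default pipeline configuration
#'
#' One nested configuration drives every pipeline stage; it serialises to
#' YAML round-trip and unknown keys are rejected on read. `scale` presets:
#' `"full"` mirrors the study design (48 samples per group, full grid);
#' `"small"` is a desk-scale preset (8 per group, stronger emission
#' decimation, smaller/shorter attention model) used by the end-to-end
#' reproduction run.
#'
#' @param scale `"full"` or `"small"`.
#' @param seed Global integer seed.
#' @return Nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(scale = c("full", "small"), seed = 1) {
  scale <- match.arg(scale)
  small <- scale == "small"
  cfg <- list(
    seed = as.integer(seed),
    scale = scale,
    grid = list(ex_start = 220, ex_stop = 550, ex_step = 5,
                em_start = 240, em_stop = 750, em_step = 1),
    synthetic = list(n_per_group = if (small) 8L else 48L,
                     sample_lognormal_sigma = 0.08,
                     additive_gaussian_sigma = 10,
                     scatter = TRUE),
    scatter = list(rayleigh1_halfwidth = 15, rayleigh2_halfwidth = 15,
                   raman_shift = 3400, raman_halfwidth = 10,
                   smoothing_window = 11, nonphysical_margin = 0),
    peaks = list(statistic = "mean"),
    parafac = list(n_components = 5L, F_range = c(3L, 6L),
                   decimate_em = if (small) 8L else 4L,
                   n_restarts = 3L, n_splits = 3L,
                   tol = 1e-8, max_iter = if (small) 200L else 500L,
                   split_threshold = 95, cc_threshold = 60),
    model = list(embed_dim = if (small) 32L else 64L,
                 n_heads = 4L, depth = if (small) 1L else 2L,
                 mlp_hidden = if (small) 64L else 128L,
                 dropout_rate = 0.1,
                 learning_rate = if (small) 5e-3 else 1e-3,
                 epochs = if (small) 80L else 150L,
                 batch_size = 16L,
                 patch_size_1d = 16L, patch_size_2d = c(8L, 32L)),
    evaluation = list(calibration_ratio = 2 / 3, k_folds = 5L),
    shapley = list(n_permutations = 200L)
  )
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a validated `pipeline_config`;
#'   unknown keys (top-level or within a section) raise an error.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ref <- unclass(default_pipeline_config())
  bad <- setdiff(names(raw), names(ref))
  if (length(bad)) stop(sprintf("unknown config key: %s", bad[1]), call. = FALSE)
  for (sec in names(raw)) {
    if (is.list(ref[[sec]]) && is.list(raw[[sec]])) {
      bad <- setdiff(names(raw[[sec]]), names(ref[[sec]]))
      if (length(bad)) {
        stop(sprintf("unknown config key: %s$%s", sec, bad[1]), call. = FALSE)
      }
      ref[[sec]][names(raw[[sec]])] <- raw[[sec]]
    } else {
      ref[[sec]] <- raw[[sec]]
    }
  }
  class(ref) <- c("pipeline_config", "list")
  ref
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_grid <- function(config) do.call(eem_grid, config$grid)

config_scatter <- function(config) do.call(scatter_config, config$scatter)

#' Build an [attention_config()] from a pipeline configuration
#' @param config A `pipeline_config`.
#' @param seed_offset Added to the global seed.
#' @return An `attention_config`.
#' @export
config_attention <- function(config, seed_offset = 0) {
  m <- config$model
  attention_config(patch_size_2d = m$patch_size_2d,
                   patch_size_1d = m$patch_size_1d,
                   embed_dim = m$embed_dim, n_heads = m$n_heads,
                   depth = m$depth, mlp_hidden = m$mlp_hidden,
                   dropout_rate = m$dropout_rate,
                   learning_rate = m$learning_rate, epochs = m$epochs,
                   batch_size = m$batch_size,
                   seed = config$seed + seed_offset)
}

#' Pipeline stages
#'
#' Each `pipeline_*` function runs one stage of the end-to-end analysis,
#' reading and writing the documented CSV/JSON artifacts under `out_dir`.
#' [pipeline_reproduce()] chains
#' simulate -> preprocess -> features -> train/evaluate -> explain and
#' writes a metrics report.
#'
#' @param config A [default_pipeline_config()].
#' @param out_dir Output directory.
#' @return `pipeline_simulate` returns (invisibly) the generated dataset
#'   bundle and writes per-sample CSVs plus `manifest.json` and the
#'   ground-truth scores.
#' @export
pipeline_simulate <- function(config = default_pipeline_config(), out_dir) {
  grid <- config_grid(config)
  gen <- generate_eem_dataset(
    noise = noise_model(
      sample_lognormal_sigma = config$synthetic$sample_lognormal_sigma,
      additive_gaussian_sigma = config$synthetic$additive_gaussian_sigma),
    n_per_group = config$synthetic$n_per_group,
    grid = grid, seed = config$seed,
    scatter = isTRUE(config$synthetic$scatter))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_eem_dataset(gen$dataset, file.path(out_dir, "raw"))
  utils::write.csv(
    data.frame(sample_id = gen$dataset$manifest$sample_id, gen$truth$scores),
    file.path(out_dir, "truth_scores.csv"), row.names = FALSE)
  invisible(gen)
}

#' @rdname pipeline_simulate
#' @param dataset An `eem_dataset` (from [pipeline_simulate()] or
#'   [read_eem_dataset()]).
#' @return `pipeline_preprocess` returns the preprocessed dataset and
#'   writes it under `out_dir/preprocessed`.
#' @export
pipeline_preprocess <- function(dataset, config = default_pipeline_config(),
                                out_dir = NULL) {
  pp <- preprocess_dataset(dataset, config_scatter(config))
  if (!is.null(out_dir)) write_eem_dataset(pp, file.path(out_dir, "preprocessed"))
  pp
}

#' @rdname pipeline_simulate
#' @return `pipeline_peaks` returns the peak table and (optionally) writes
#'   `peaks.csv`.
#' @export
pipeline_peaks <- function(dataset, config = default_pipeline_config(),
                           out_dir = NULL) {
  pt <- build_peak_table(dataset, statistic = config$peaks$statistic)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(pt, file.path(out_dir, "peaks.csv"), row.names = FALSE)
  }
  pt
}

#' @rdname pipeline_simulate
#' @param rank_selection Run [select_rank()] over `config$parafac$F_range`
#'   (slower) instead of fitting only `n_components`.
#' @return `pipeline_parafac` returns a list with the fitted `model`,
#'   `scores` table and (if requested) `rank` diagnostics; writes the
#'   model CSVs and a diagnostics JSON.
#' @export
pipeline_parafac <- function(dataset, config = default_pipeline_config(),
                             out_dir = NULL, rank_selection = FALSE) {
  pc <- config$parafac
  X <- dataset_tensor(dataset, decimate_em = pc$decimate_em)
  rank <- NULL
  F <- pc$n_components
  if (rank_selection) {
    rank <- select_rank(X, seq(pc$F_range[1], pc$F_range[2]),
                        split_threshold = pc$split_threshold,
                        cc_threshold = pc$cc_threshold, seed = config$seed,
                        n_restarts = pc$n_restarts, n_splits = pc$n_splits,
                        tol = pc$tol, max_iter = pc$max_iter)
    F <- rank$chosen
  }
  model <- fit_parafac(X, F, n_restarts = pc$n_restarts, tol = pc$tol,
                       max_iter = pc$max_iter, seed = config$seed)
  cc <- core_consistency(model, X)
  scores <- data.frame(sample_id = dataset$manifest$sample_id,
                       model$sample_scores,
                       polymer = dataset$manifest$polymer,
                       concentration = dataset$manifest$concentration)
  colnames(scores)[seq_len(F) + 1] <- paste0("C", seq_len(F))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(scores, file.path(out_dir, "parafac_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(ex_nm = model$ex, model$ex_loadings),
                     file.path(out_dir, "parafac_ex_loadings.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(em_nm = model$em, model$em_loadings),
                     file.path(out_dir, "parafac_em_loadings.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(n_components = F, fit_error = model$fit_error,
           core_consistency = as.numeric(cc),
           rank_diagnostics = rank$diagnostics),
      file.path(out_dir, "parafac_diagnostics.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(model = model, scores = scores, core_consistency = as.numeric(cc),
       rank = rank)
}

# train + evaluate one polymer's 3-class task on a feature table
evaluate_polymer <- function(features_table, polymer, config, trainer_name) {
  rows <- features_table$polymer %in% c("CONTROL", polymer)
  tab <- features_table[rows, , drop = FALSE]
  feats <- feature_matrix(tab)
  labels <- tab$concentration
  split <- split_dataset(labels,
                         ratios = c(config$evaluation$calibration_ratio,
                                    1 - config$evaluation$calibration_ratio),
                         k_folds = min(config$evaluation$k_folds,
                                       min(table(labels))),
                         seed = config$seed)
  trainer <- switch(
    trainer_name,
    attention = function(x, y) train_attention_classifier(
      x, y, config_attention(config), type = "features"),
    KNN = function(x, y) train_baseline(x, y, "KNN", seed = config$seed),
    RF = function(x, y) train_baseline(x, y, "RF", seed = config$seed))
  res <- evaluate_classifier(feats, labels, split, trainer)
  res$split <- split
  res$features <- feats
  res$labels <- labels
  res
}

#' @rdname pipeline_simulate
#' @param features_table Peak table (or PARAFAC score table) with
#'   `polymer` / `concentration` columns.
#' @param trainer One of `"attention"`, `"KNN"`, `"RF"`.
#' @return `pipeline_evaluate` returns per-polymer confusion matrices and
#'   metrics for the 3-class concentration task and writes
#'   `metrics.json` / `metrics.csv`.
#' @export
pipeline_evaluate <- function(features_table,
                              config = default_pipeline_config(),
                              trainer = "attention", out_dir = NULL) {
  out <- list()
  for (p in c("PET", "PS", "PVC")) {
    if (!p %in% features_table$polymer) next
    out[[p]] <- evaluate_polymer(features_table, p, config, trainer)
  }
  metrics <- do.call(rbind, lapply(names(out), function(p) {
    m <- out[[p]]$metrics
    data.frame(polymer = p, accuracy = m$accuracy,
               t(m$sensitivity), t(m$specificity), check.names = FALSE)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(out, function(r) list(confusion = unclass(r$confusion),
                                   accuracy = r$metrics$accuracy,
                                   sensitivity = as.list(r$metrics$sensitivity),
                                   specificity = as.list(r$metrics$specificity))),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  list(results = out, metrics = metrics)
}

#' @rdname pipeline_simulate
#' @param evaluation Result of [pipeline_evaluate()].
#' @return `pipeline_explain` returns the mean-|phi| importance summary of
#'   each polymer's trained model over its validation samples, explaining
#'   the predicted probability of each sample's true class.
#' @export
pipeline_explain <- function(evaluation, config = default_pipeline_config(),
                             out_dir = NULL) {
  summaries <- list()
  for (p in names(evaluation$results)) {
    r <- evaluation$results[[p]]
    background <- colMeans(r$features[r$split$calibration, , drop = FALSE])
    val <- r$split$validation
    atts <- lapply(val, function(i) {
      f <- class_prob_fn(r$model, as.character(r$labels[i]))
      exact_shapley(f, r$features[i, ], background)
    })
    summaries[[p]] <- importance_summary(atts, r$labels[val])
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    flat <- do.call(rbind, lapply(names(summaries), function(p) {
      cbind(polymer = p, summaries[[p]])
    }))
    utils::write.csv(flat, file.path(out_dir, "shap_importance.csv"),
                     row.names = FALSE)
  }
  summaries
}

#' @rdname pipeline_simulate
#' @param scale Overrides the config preset (`"small"` keeps the run to a
#'   few minutes on one CPU).
#' @param seed Global seed.
#' @return `pipeline_reproduce` runs the full chain and returns a report
#'   list (`metrics`, `parafac`, `shap`, `min_validation_accuracy`);
#'   artifacts and `report.json` land under `out_dir`.
#' @export
pipeline_reproduce <- function(scale = "small", seed = 1, out_dir = tempfile("eemrun"),
                               rank_selection = FALSE) {
  config <- default_pipeline_config(scale = scale, seed = seed)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    s <- Sys.time()
    val <- force(expr)
    message(sprintf("[%s] %s (%.1fs)", format(Sys.time(), "%H:%M:%S"), name,
                    as.numeric(difftime(Sys.time(), s, units = "secs"))))
    val
  }
  gen <- stage("simulate", pipeline_simulate(config, out_dir))
  pp <- stage("preprocess", pipeline_preprocess(gen$dataset, config, out_dir))
  peaks <- stage("peaks", pipeline_peaks(pp, config, out_dir))
  pf <- stage("parafac", pipeline_parafac(pp, config, out_dir,
                                          rank_selection = rank_selection))
  ev <- stage("evaluate", pipeline_evaluate(peaks, config, "attention", out_dir))
  shap <- stage("explain", pipeline_explain(ev, config, out_dir))
  report <- list(
    scale = scale, seed = seed,
    n_samples = length(gen$dataset$samples),
    parafac = list(n_components = pf$model$n_components,
                   fit_error = pf$model$fit_error,
                   core_consistency = pf$core_consistency),
    metrics = ev$metrics,
    min_validation_accuracy = min(ev$metrics$accuracy),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(c(report, list(shap = shap)),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(c(report, list(shap = shap, evaluation = ev)))
}
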