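# Experiment orchestration: configuration, staged (resumable) execution of
# the full pipeline at a chosen scale, and summary report tables.

#' Configure an end-to-end learning experiment
#'
#' Defaults mirror the reference experimental conditions (3-minute stimulus,
#' K = 400 filters, 250-ms/5-ms patches, 60 channels, 95% variance capture,
#' at most 30 optimizer iterations, a grid of correlation intervals); see
#' [desk_config()] for a reduced-scale profile suitable for interactive use.
#'
#' @param recipe A [stimulus_recipe()].
#' @param objectives A list of [objective_config()]s to fit.
#' @param K Ensemble size per fit.
#' @param mode `"response"` or `"shape"` constraints.
#' @param win_ms Patch window length in ms (default 250).
#' @param var_fraction Whitening variance-capture target.
#' @param mu,max_iter,tol Optimizer settings (see [fit_ensemble()]).
#' @param n_clusters,spi_threshold,q_threshold Clustering/merging settings.
#' @param seed Master seed.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(recipe = stimulus_recipe(),
                              objectives = c(
                                lapply(c(10, 25, 50, 125, 250, 500, 1000, 2000),
                                       function(N) objective_config("sustained", N)),
                                list(objective_config("sparse"))),
                              K = 400, mode = "response", win_ms = 250,
                              var_fraction = 0.95,
                              mu = 1, max_iter = 30, tol = 1e-4,
                              n_clusters = 12, spi_threshold = 0.5,
                              q_threshold = 0.69, seed = 1) {
  stopifnot(inherits(recipe, "stimulus_recipe"))
  if (!length(objectives) ||
      !all(vapply(objectives, inherits, logical(1), "objective_config"))) {
    stop_param("`objectives` must be a list of objective_config objects")
  }
  mode <- match.arg(mode, c("response", "shape"))
  check_scalar(K, "K", lower = 1)
  structure(list(recipe = recipe, objectives = objectives, K = as.integer(K),
                 mode = mode, win_ms = win_ms, var_fraction = var_fraction,
                 mu = mu,
                 max_iter = max_iter, tol = tol,
                 n_clusters = as.integer(n_clusters),
                 spi_threshold = spi_threshold, q_threshold = q_threshold,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Reduced-scale experiment profile
#'
#' A desk-scale configuration (short stimulus, small ensemble, two
#' correlation intervals, fewer iterations) that exercises every stage of
#' the pipeline in minutes rather than hours.
#'
#' @param total_duration_s Stimulus length (default 30 s).
#' @param K Ensemble size (default 50).
#' @param N_ms_grid Sustained correlation intervals (default 10 and 125 ms).
#' @param max_iter Optimizer iteration cap (default 15).
#' @param seed Master seed.
#' @param ... Further overrides passed to [experiment_config()].
#' @return An `experiment_config`.
#' @export
desk_config <- function(total_duration_s = 30, K = 50,
                        N_ms_grid = c(10, 125), max_iter = 15, seed = 1, ...) {
  experiment_config(
    recipe = stimulus_recipe(total_duration_s = total_duration_s, seed = seed),
    objectives = c(lapply(N_ms_grid,
                          function(N) objective_config("sustained", N)),
                   list(objective_config("sparse"))),
    K = K, max_iter = max_iter, seed = seed, ...)
}

stage_file <- function(out_dir, name) file.path(out_dir, paste0(name, ".rds"))

run_stage <- function(name, out_dir, resume, fun) {
  path <- stage_file(out_dir, name)
  if (resume && file.exists(path)) {
    message(sprintf("[%s] reusing cached artifact", name))
    return(readRDS(path))
  }
  message(sprintf("[%s] computing", name))
  value <- fun()
  saveRDS(value, path)
  value
}

#' Run a full experiment
#'
#' Executes stimulus synthesis, the peripheral model, patch extraction and
#' whitening, ensemble learning over the objective grid, per-STRF metrics,
#' clustering with merging, and the summary report. Every stage's artifact
#' is persisted under `out_dir` (RDS for R objects, CSV/JSON for tables) and
#' reused on rerun when `resume = TRUE`, so any stage can be rerun from
#' persisted upstream artifacts. The configuration is serialized alongside
#' the artifacts for provenance.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created if needed).
#' @param resume Reuse cached stage artifacts when present (default TRUE)?
#' @return A list with the stage artifacts (`stimulus`, `spectrogram`,
#'   `whitening`, `ensembles`, `metrics`, `labels`, `report`).
#' @export
run_experiment <- function(config, out_dir, resume = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(serialize_config(config), cfg_json, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  wav <- run_stage("stimulus", out_dir, resume,
                   function() gen_stimulus_ensemble(config$recipe))
  spec <- run_stage("spectrogram", out_dir, resume,
                    function() compute_spectrogram(wav))
  prep <- run_stage("patches", out_dir, resume, function() {
    preprocess_patches(extract_patches(spec, win_ms = config$win_ms))
  })
  wm <- run_stage("whitening", out_dir, resume,
                  function() fit_whitening(prep, config$var_fraction))
  data_mat <- if (config$mode == "response") apply_whitening(prep, wm) else prep
  fit_seeds <- derive_seeds(config$seed, length(config$objectives))
  ensembles <- run_stage("ensembles", out_dir, resume, function() {
    out <- list()
    for (i in seq_along(config$objectives)) {
      obj <- config$objectives[[i]]
      nm <- objective_name(obj)
      out[[nm]] <- fit_ensemble(
        data_mat, K = config$K, objective = obj, mode = config$mode,
        mu = config$mu, max_iter = config$max_iter, tol = config$tol,
        seed = fit_seeds[i],
        whitening = if (config$mode == "response") wm else NULL)
    }
    out
  })
  metrics <- run_stage("metrics", out_dir, resume, function() {
    tabs <- lapply(names(ensembles), function(nm) {
      cbind(ensemble = nm, strf_metrics(ensembles[[nm]],
                                        patch_shape = ensembles[[nm]]$patch_shape))
    })
    do.call(rbind, tabs)
  })
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  labels <- run_stage("clusters", out_dir, resume, function() {
    all_strfs <- do.call(cbind, lapply(ensembles, function(e) e$strfs))
    W <- similarity_matrix(all_strfs,
                           patch_shape = ensembles[[1]]$patch_shape)
    k <- min(config$n_clusters, nrow(W) - 1L)
    init <- spectral_cluster(W, k = k, seed = config$seed)
    merge_clusters(init, metrics$spi, metrics$compactness,
                   config$spi_threshold, config$q_threshold)
  })
  report <- summary_report(metrics, labels)
  utils::write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       dataframe = "rows", pretty = TRUE, digits = NA)
  list(stimulus = wav, spectrogram = spec, whitening = wm,
       ensembles = ensembles, metrics = metrics, labels = labels,
       report = report, out_dir = out_dir)
}

objective_name <- function(obj) {
  if (obj$kind == "sustained") sprintf("sustained_N%g", obj$N_ms) else "sparse"
}

serialize_config <- function(config) {
  list(recipe = unclass(config$recipe),
       objectives = lapply(config$objectives, function(o)
         list(kind = o$kind, N_ms = o$N_ms)),
       K = config$K, mode = config$mode, win_ms = config$win_ms,
       var_fraction = config$var_fraction,
       mu = config$mu, max_iter = config$max_iter, tol = config$tol,
       n_clusters = config$n_clusters, spi_threshold = config$spi_threshold,
       q_threshold = config$q_threshold, seed = config$seed)
}

#' Summary report of ensemble statistics
#'
#' One row per ensemble: mean separability, best rate/scale, directionality,
#' compactness and 6-dB cutoffs, plus the class entropy of each ensemble's
#' STRFs under the pooled (merged) clustering.
#'
#' @param metrics A metrics table from [strf_metrics()] with an `ensemble`
#'   column (as produced by [run_experiment()]).
#' @param labels Optional merged class labels aligned with `metrics` rows.
#' @return A data.frame of per-ensemble summary statistics.
#' @export
summary_report <- function(metrics, labels = NULL) {
  needed <- c("ensemble", "spi", "br_hz", "bs_cpo", "dsi", "compactness",
              "rate_cutoff6dB_hz", "scale_cutoff6dB_cpo")
  missing_cols <- setdiff(needed, names(metrics))
  if (length(missing_cols)) {
    stop_param("metrics table lacks column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  if (!is.null(labels) && length(labels) != nrow(metrics)) {
    stop_param("`labels` must align with the metrics rows")
  }
  groups <- split(seq_len(nrow(metrics)), metrics$ensemble)
  rows <- lapply(names(groups), function(nm) {
    idx <- groups[[nm]]
    m <- metrics[idx, ]
    data.frame(ensemble = nm, n = length(idx),
               mean_spi = mean(m$spi, na.rm = TRUE),
               mean_br_hz = mean(m$br_hz, na.rm = TRUE),
               mean_bs_cpo = mean(m$bs_cpo, na.rm = TRUE),
               mean_dsi = mean(m$dsi, na.rm = TRUE),
               mean_compactness = mean(m$compactness, na.rm = TRUE),
               mean_rate_cutoff6dB_hz = mean(m$rate_cutoff6dB_hz, na.rm = TRUE),
               mean_scale_cutoff6dB_cpo = mean(m$scale_cutoff6dB_cpo,
                                               na.rm = TRUE),
               entropy_bits = if (is.null(labels)) NA_real_ else
                 class_entropy(labels[idx]))
  })
  do.call(rbind, rows)
}
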