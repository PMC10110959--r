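#' Default pipeline configuration
#'
#' Flat, serializable configuration for [run_pipeline()]: every tunable
#' of the simulate / preprocess / features / discover / annotate /
#' transitions stages with its default.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `"run_config"`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    # simulate
    n_tracks = 50, duration = 1440, dt = 1,
    transition_matrix = matrix(c(0.8, 0.15, 0.05,
                                 0.15, 0.8, 0.05,
                                 0.2, 0.2, 0.6),
                               3, 3, byrow = TRUE,
                               dimnames = list(MODE_LEVELS, MODE_LEVELS)),
    initial_distribution = rep(1 / 3, 3),
    # preprocess
    max_gap = 10, split_threshold = 10,
    min_mean_speed = 1.5, min_duration = 60, min_max_displacement = 20,
    window = 60, min_points = 50,
    # discover
    k = NULL, k_range = 2:8, train_fraction = 0.366, train_count = NULL,
    # stats
    fit_lags = c(10, 30), heatmap_lags = 1:30, zigzag_lag = 3
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  structure(cfg, class = c("run_config", "list"))
}

#' Run the full mode-discovery pipeline
#'
#' Executes the requested stages in order on either an input track CSV or
#' (by default) freshly simulated mode-switching trajectories, writing
#' tidy CSV artifacts plus the effective configuration into `out_dir`.
#' Re-running with an identical configuration reproduces identical
#' outputs.
#'
#' @param config A [default_config()] (or modified copy).
#' @param out_dir Output directory (created if absent).
#' @param input Optional path to a track CSV; `NULL` simulates instead.
#' @param stages Stages to run, a subset of
#'   `c("preprocess", "discover", "annotate", "stats", "transitions")`.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir = ".",
                         input = NULL,
                         stages = c("preprocess", "discover", "annotate",
                                    "stats", "transitions")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_flat <- config
  cfg_flat$transition_matrix <- as.vector(config$transition_matrix)
  jsonlite::write_json(cfg_flat, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  res <- list(config = config)

  if (is.null(input)) {
    sim <- simulate_switching_tracks(
      n_tracks = config$n_tracks,
      cfg = switching_config(config$transition_matrix,
                             config$initial_distribution,
                             duration = config$duration, dt = config$dt),
      seed = config$seed)
    tracks <- sim$tracks
    readr::write_csv(sim$labels, file.path(out_dir, "true_modes.csv"))
    res$true_modes <- sim$labels
  } else {
    tracks <- read_tracks(input)
  }

  if ("preprocess" %in% stages) {
    tracks <- split_on_long_gaps(tracks, threshold = config$split_threshold)
    tracks <- interpolate_gaps(tracks, max_gap = config$max_gap,
                               dt = config$dt)
    filt <- filter_tracks(tracks,
                          filter_criteria(config$min_mean_speed,
                                          config$min_duration,
                                          config$min_max_displacement))
    tracks <- filt$kept
    readr::write_csv(filt$removed, file.path(out_dir, "removed_tracks.csv"))
  }
  readr::write_csv(tracks, file.path(out_dir, "tracks.csv"))
  res$tracks <- tracks

  segs <- segment_tracks(tracks, window = config$window,
                         min_points = config$min_points)
  feats <- track_features(segs)
  readr::write_csv(feats, file.path(out_dir, "features.csv"))
  res$features <- feats

  if ("discover" %in% stages) {
    model <- fit_modes(feats, k = config$k,
                       train_fraction = config$train_fraction,
                       train_count = config$train_count,
                       seed = config$seed)
    readr::write_csv(tidy(model), file.path(out_dir, "mode_centers.csv"))
    readr::write_csv(glance(model), file.path(out_dir, "model_summary.csv"))
    res$model <- model
  }

  if ("annotate" %in% stages && !is.null(res$model)) {
    modes <- annotate_modes(res$model, tracks, window = config$window,
                            min_points = config$min_points)
    write_annotated(tracks, file.path(out_dir, "annotated_tracks.csv"),
                    modes = modes)
    readr::write_csv(modes, file.path(out_dir, "mode_sequences.csv"))
    res$modes <- modes
  }

  if ("stats" %in% stages) {
    msd_tbl <- msd(tracks, max_lag = config$fit_lags[2])
    readr::write_csv(msd_tbl, file.path(out_dir, "msd.csv"))
    readr::write_csv(fit_alpha(msd_tbl, config$fit_lags),
                     file.path(out_dir, "alpha.csv"))
    readr::write_csv(turning_angle_heatmap(tracks, config$heatmap_lags),
                     file.path(out_dir, "angle_heatmap.csv"))
    readr::write_csv(zigzag_fraction(tracks, lag = config$zigzag_lag),
                     file.path(out_dir, "zigzag.csv"))
  }

  if ("transitions" %in% stages && !is.null(res$modes) &&
      nrow(res$modes) > 0) {
    tm <- transition_matrix(res$modes)
    readr::write_csv(tidy(tm), file.path(out_dir, "transition_matrix.csv"))
    readr::write_csv(mode_fractions(res$modes),
                     file.path(out_dir, "mode_fractions.csv"))
    readr::write_csv(homogeneity_fraction(res$modes),
                     file.path(out_dir, "homogeneity.csv"))
    lt <- mode_lifetimes(res$modes)
    readr::write_csv(lt, file.path(out_dir, "lifetimes.csv"))
    readr::write_csv(pathway_summary(res$modes),
                     file.path(out_dir, "pathways.csv"))
    res$transition_matrix <- tm
  }
  invisible(res)
}
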