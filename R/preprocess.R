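#' Track-filtering criteria
#'
#' Thresholds of the three admission criteria applied after gap handling:
#' mean track speed, observed duration, and maximal displacement from the
#' starting position.
#'
#' @param min_mean_speed Minimum mean step speed, um/min (default 1.5).
#' @param min_duration Minimum observed duration, minutes (default 60).
#' @param min_max_displacement Minimum of
#'   \eqn{\max_t |r(t) - r(t_0)|}, um (default 20).
#' @return A list of class `"filter_criteria"`.
#' @export
filter_criteria <- function(min_mean_speed = 1.5, min_duration = 60,
                            min_max_displacement = 20) {
  stopifnot(min_mean_speed > 0, min_duration > 0, min_max_displacement > 0)
  structure(list(min_mean_speed = min_mean_speed,
                 min_duration = min_duration,
                 min_max_displacement = min_max_displacement),
            class = "filter_criteria")
}

#' Fill short tracking gaps by cubic-spline interpolation
#'
#' Missing timepoints inside gaps shorter than `max_gap` are filled on the
#' 1-minute grid (spacing `dt`, anchored at the sample before the gap) by
#' a per-coordinate cubic spline through the observed points. Observed
#' samples are never altered; gaps of `max_gap` or longer are left
#' untouched and are the business of [split_on_long_gaps()].
#'
#' Spline end conditions follow Forsythe–Malcolm–Moler
#' (`stats::spline(method = "fmm")`), which reproduces cubic position data
#' exactly.
#'
#' @param tracks A track table (possibly with absent rows where tracking
#'   failed).
#' @param max_gap Gaps of at least this many minutes are not interpolated
#'   (default 10).
#' @param dt Sampling grid spacing in minutes (default 1).
#' @return A track table including the interpolated rows.
#' @export
interpolate_gaps <- function(tracks, max_gap = 10, dt = 1) {
  validate_tracks(tracks)
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$time_min)
      n <- nrow(df)
      if (n < 4) {
        abort(paste0("track ", key$track_id,
                     " has fewer than 4 points; cannot spline-interpolate"),
              class = "modewalk_size_error")
      }
      gaps <- diff(df$time_min)
      fill_after <- which(gaps > dt & gaps < max_gap)
      if (length(fill_after) == 0) return(df)
      new_t <- unlist(lapply(fill_after, function(i) {
        grid <- seq(df$time_min[i] + dt, df$time_min[i + 1], by = dt)
        grid[grid < df$time_min[i + 1] - 1e-9]
      }))
      if (length(new_t) == 0) return(df)
      fx <- spline(df$time_min, df$x_um, xout = new_t, method = "fmm")$y
      fy <- spline(df$time_min, df$y_um, xout = new_t, method = "fmm")$y
      add <- df[rep(1, length(new_t)), , drop = FALSE]
      add$time_min <- new_t
      add$x_um <- fx
      add$y_um <- fy
      dplyr::arrange(dplyr::bind_rows(df, add), .data$time_min)
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("track_id")
}

#' Split trajectories at long tracking gaps
#'
#' Wherever a track has an untracked period of `threshold` minutes or
#' more, it is split into independent pieces before and after the gap.
#' When a track is split, children are deterministically renamed
#' `"<id>.1"`, `"<id>.2"`, ...; unsplit tracks keep their id. The output
#' rows partition the input rows exactly.
#'
#' @param tracks A track table.
#' @param threshold Gap length (minutes) at or above which to split
#'   (default 10).
#' @return A track table with split tracks renamed.
#' @export
split_on_long_gaps <- function(tracks, threshold = 10) {
  validate_tracks(tracks)
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$time_min)
      piece <- cumsum(c(0, diff(df$time_min) >= threshold))
      if (max(piece) > 0) {
        df$track_id_new <- paste0(key$track_id, ".", piece + 1)
      } else {
        df$track_id_new <- key$track_id
      }
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(track_id = .data$track_id_new) |>
    dplyr::select(-"track_id_new") |>
    dplyr::relocate("track_id")
}

#' Filter tracks by speed, duration and maximal displacement
#'
#' A track is kept iff its mean step speed, observed duration and maximal
#' displacement from the starting position all meet the thresholds in
#' `criteria`. Removed tracks are tagged with every criterion they
#' violate, so filtering is auditable and monotone in each threshold.
#'
#' @param tracks A gap-free track table.
#' @param criteria A [filter_criteria()].
#' @return A list with `kept` (track table) and `removed` (tibble of
#'   `track_id`, the three measured quantities, and a comma-joined
#'   `reasons` string).
#' @export
filter_tracks <- function(tracks, criteria = filter_criteria()) {
  validate_tracks(tracks)
  stats_tbl <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$time_min, .by_group = TRUE) |>
    dplyr::summarise(
      mean_speed = mean(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2) /
                          diff(.data$time_min)),
      duration = max(.data$time_min) - min(.data$time_min),
      max_displacement = max(sqrt((.data$x_um - .data$x_um[1])^2 +
                                    (.data$y_um - .data$y_um[1])^2)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fail_speed = .data$mean_speed < criteria$min_mean_speed,
      fail_duration = .data$duration < criteria$min_duration,
      fail_displacement = .data$max_displacement < criteria$min_max_displacement
    )
  removed <- stats_tbl |>
    dplyr::filter(.data$fail_speed | .data$fail_duration |
                    .data$fail_displacement) |>
    dplyr::rowwise() |>
    dplyr::mutate(reasons = paste(
      c("mean_speed", "duration", "max_displacement")[
        c(.data$fail_speed, .data$fail_duration, .data$fail_displacement)],
      collapse = ",")) |>
    dplyr::ungroup() |>
    dplyr::select("track_id", "mean_speed", "duration",
                  "max_displacement", "reasons")
  kept_ids <- setdiff(stats_tbl$track_id, removed$track_id)
  list(kept = dplyr::filter(tracks, .data$track_id %in% kept_ids),
       removed = removed)
}

#' Cut trajectories into fixed-duration classification windows
#'
#' Segments each track into consecutive non-overlapping windows of
#' `window` minutes anchored at the track's first timestamp. Windows with
#' fewer than `min_points` samples (e.g. trailing remainders) are
#' dropped; at the nominal 1-minute sampling an admissible window holds
#' between `min_points` and `window` points.
#'
#' @param tracks A gap-free track table.
#' @param window Window length in minutes (default 60).
#' @param min_points Minimum samples per admissible window (default 50).
#' @return A segmented track table: the input rows of admissible windows
#'   plus `window_start_min` and `window_end_min` key columns.
#' @export
segment_tracks <- function(tracks, window = 60, min_points = 50) {
  validate_tracks(tracks)
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(
      window_start_min = min(.data$time_min) +
        floor((.data$time_min - min(.data$time_min)) / window) * window,
      window_end_min = .data$window_start_min + window
    ) |>
    dplyr::group_by(.data$track_id, .data$window_start_min,
                    .data$window_end_min) |>
    dplyr::filter(dplyr::n() >= min_points) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$track_id, .data$time_min)
}
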