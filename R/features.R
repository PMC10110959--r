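#' Gyration tensor of a 2D point set
#'
#' The centered second-moment tensor of a segment's positions,
#' \eqn{R_{ij} = \frac{1}{N}\sum_l (r_i(t_l) - \langle r_i\rangle)(r_j(t_l) - \langle r_j\rangle)},
#' whose eigenvalues \eqn{\lambda_1 \ge \lambda_2} describe the spread of
#' the trajectory along its principal axes. Equivalently (and used as a
#' regression oracle in the tests) each element equals the half mean of
#' pairwise coordinate differences,
#' \eqn{\frac{1}{2N^2}\sum_{l,m}(r_i(t_l)-r_i(t_m))(r_j(t_l)-r_j(t_m))}.
#'
#' @param x,y Coordinate vectors in micrometers (equal length, >= 2).
#' @return A list of class `"gyration_tensor"` with elements `rxx`, `rxy`,
#'   `ryy` (um^2) and sorted eigenvalues `lambda1 >= lambda2`.
#' @export
#' @examples
#' gyration_tensor(c(0, 2), c(0, 0)) # rxx = 1, rest 0
gyration_tensor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) {
    abort("gyration tensor needs at least 2 points", class = "modewalk_size_error")
  }
  dx <- x - mean(x)
  dy <- y - mean(y)
  rxx <- mean(dx^2)
  ryy <- mean(dy^2)
  rxy <- mean(dx * dy)
  half_diff <- (rxx - ryy) / 2
  disc <- sqrt(half_diff^2 + rxy^2)
  mid <- (rxx + ryy) / 2
  structure(
    list(rxx = rxx, rxy = rxy, ryy = ryy,
         lambda1 = mid + disc, lambda2 = max(mid - disc, 0)),
    class = "gyration_tensor"
  )
}

#' Radius of gyration
#'
#' Square root of the gyration-tensor trace,
#' \eqn{R_g = \sqrt{\lambda_1 + \lambda_2}}: the root-mean-square spread of
#' the segment about its centroid, in micrometers.
#'
#' @param g A [gyration_tensor()], or an `x` coordinate vector when `y` is
#'   given.
#' @param y Optional `y` coordinates (then `g` is taken as `x`).
#' @return Radius of gyration in micrometers.
#' @export
radius_of_gyration <- function(g, y = NULL) {
  if (!is.null(y)) g <- gyration_tensor(g, y)
  sqrt(g$rxx + g$ryy)
}

#' Asphericity of a trajectory segment
#'
#' Normalized eigenvalue anisotropy of the gyration tensor,
#' \eqn{A = (\lambda_1-\lambda_2)^2 / (\lambda_1+\lambda_2)^2 \in [0, 1]}:
#' 0 for an isotropic (perfectly circular) point cloud, 1 for collinear
#' points.
#'
#' @inheritParams radius_of_gyration
#' @return Asphericity in `[0, 1]`.
#' @export
asphericity <- function(g, y = NULL) {
  if (!is.null(y)) g <- gyration_tensor(g, y)
  tr <- g$lambda1 + g$lambda2
  if (tr <= 0) {
    abort("asphericity undefined for a degenerate (stationary) segment",
          class = "modewalk_shape_error")
  }
  ((g$lambda1 - g$lambda2) / tr)^2
}

#' Kinetic energy proxy of a segment
#'
#' Mean squared step speed,
#' \eqn{E = \frac{1}{N-1}\sum_n V_D(t_n)^2} with
#' \eqn{V_D(t_n) = |r(t_{n+1}) - r(t_n)| / (t_{n+1} - t_n)}, in
#' (um/min)^2. No mass factor is applied; this is exactly the mean squared
#' speed.
#'
#' @param time Strictly increasing times in minutes.
#' @param x,y Coordinates in micrometers.
#' @return Mean squared step speed, (um/min)^2.
#' @export
step_energy <- function(time, x, y) {
  n <- length(time)
  stopifnot(length(x) == n, length(y) == n)
  if (n < 2) abort("energy needs at least 2 points", class = "modewalk_size_error")
  dt <- diff(time)
  if (any(dt <= 0)) {
    abort("times must be strictly increasing", class = "modewalk_validation_error")
  }
  v2 <- (diff(x)^2 + diff(y)^2) / dt^2
  mean(v2)
}

#' End-to-end distance of a segment
#'
#' Euclidean distance between the first and last positions, in
#' micrometers.
#'
#' @param x,y Coordinates in micrometers (>= 2 points).
#' @return End-to-end distance, um.
#' @export
end_to_end <- function(x, y) {
  n <- length(x)
  if (n < 2) abort("end-to-end needs at least 2 points", class = "modewalk_size_error")
  sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
}

#' Signed turning angles along a trajectory
#'
#' Angles between consecutive displacement vectors
#' \eqn{D(t_n; \Delta t) = r(t_n + \Delta t) - r(t_n)} taken at
#' non-overlapping lags (\eqn{t_n = n\Delta t}, i.e. positions are
#' subsampled every `lag` samples). Angles are signed via the 2D cross
#' product — positive counterclockwise in a y-up frame — and lie in
#' `[-pi, pi)`, an exact reversal mapping to `-pi`. Zero-length
#' displacement vectors (stationary frames) carry no direction and are
#' skipped.
#'
#' @param x,y Coordinates at uniform sampling.
#' @param lag Lag in samples between the positions defining each
#'   displacement vector (default 1).
#' @return Numeric vector of signed angles in radians (possibly empty).
#' @export
#' @examples
#' # repeated 90-degree left turns: all angles +pi/2
#' turning_angles(c(0, 1, 1, 0), c(0, 0, 1, 1))
turning_angles <- function(x, y, lag = 1) {
  stopifnot(length(x) == length(y), lag >= 1)
  idx <- seq(1, length(x), by = lag)
  if (length(idx) < 3) return(numeric(0))
  dx <- diff(x[idx])
  dy <- diff(y[idx])
  keep <- (dx != 0 | dy != 0)
  dx <- dx[keep]
  dy <- dy[keep]
  if (length(dx) < 2) return(numeric(0))
  n <- length(dx)
  dot <- dx[-n] * dx[-1] + dy[-n] * dy[-1]
  crs <- dx[-n] * dy[-1] - dy[-n] * dx[-1]
  ang <- atan2(crs, dot)
  # atan2 returns (-pi, pi]; fold the reversal boundary onto -pi
  ang[ang >= pi] <- -pi
  ang
}

#' Variance of turning angles
#'
#' Population variance of the lag-1 signed turning angles of a segment,
#' \eqn{\mathrm{Var}[\theta] = \frac{1}{N-2}\sum_i (\theta_i - \langle\theta\rangle)^2}
#' (the divisor is the number of angles; steps with zero displacement are
#' skipped and the divisor adjusted).
#'
#' @param x,y Coordinates at uniform sampling (>= 3 points).
#' @return Variance in radians^2; `NA` if fewer than one angle survives.
#' @export
var_theta <- function(x, y) {
  if (length(x) < 3) {
    abort("turning-angle variance needs at least 3 points",
          class = "modewalk_size_error")
  }
  th <- turning_angles(x, y, lag = 1)
  if (length(th) < 1) return(NA_real_)
  mean((th - mean(th))^2)
}

#' Five-feature descriptors for trajectory segments
#'
#' Computes, for every segment in a segmented track table (see
#' [segment_tracks()]), the five per-segment descriptors used for mode
#' discovery: radius of gyration `rg` (um), `asphericity` (unitless),
#' kinetic `energy` ((um/min)^2), end-to-end distance `rete` (um) and
#' turning-angle variance `var_theta` (rad^2).
#'
#' @param segments A segmented track table: a track table with
#'   `window_start_min` / `window_end_min` columns, as returned by
#'   [segment_tracks()]. A plain track table is accepted and treated as
#'   one segment per track.
#' @return A tibble with one row per segment: `track_id`,
#'   `window_start_min`, `window_end_min`, `n_points` and the five
#'   features.
#' @export
#' @examples
#' trk <- fixture_track("ballistic", speed = 2, duration = 59)
#' track_features(segment_tracks(trk))
track_features <- function(segments) {
  if (!"window_start_min" %in% names(segments)) {
    segments <- segments |>
      dplyr::group_by(.data$track_id) |>
      dplyr::mutate(window_start_min = min(.data$time_min),
                    window_end_min = max(.data$time_min)) |>
      dplyr::ungroup()
  }
  segments |>
    dplyr::group_by(.data$track_id, .data$window_start_min,
                    .data$window_end_min) |>
    dplyr::arrange(.data$time_min, .by_group = TRUE) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      rg = radius_of_gyration(.data$x_um, .data$y_um),
      asphericity = asphericity(gyration_tensor(.data$x_um, .data$y_um)),
      energy = step_energy(.data$time_min, .data$x_um, .data$y_um),
      rete = end_to_end(.data$x_um, .data$y_um),
      var_theta = var_theta(.data$x_um, .data$y_um),
      .groups = "drop"
    )
}

feature_names <- function() c("rg", "asphericity", "energy", "rete", "var_theta")
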