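#' Time-averaged mean squared displacement
#'
#' For each track, the discrete time-averaged MSD
#' \eqn{\mathrm{MSD}(k\delta) = \frac{1}{N-k}\sum_i |r_{i+k} - r_i|^2}
#' over all overlapping start times, for lags up to `max_lag` minutes.
#' Sampling must be uniform (post-preprocessing).
#'
#' @param tracks A track table with uniform sampling.
#' @param max_lag Largest lag in minutes; must be smaller than each
#'   track's duration. Defaults to half the shortest track duration.
#' @return A tibble of class `"msd_tbl"`: `track_id`, `lag_min`, `msd`
#'   (um^2), `n_pairs`.
#' @export
#' @examples
#' msd(fixture_track("ballistic", speed = 2, duration = 30), max_lag = 10)
msd <- function(tracks, max_lag = NULL) {
  validate_tracks(tracks)
  if (is.null(max_lag)) {
    dur <- tracks |>
      dplyr::group_by(.data$track_id) |>
      dplyr::summarise(d = max(.data$time_min) - min(.data$time_min))
    max_lag <- floor(min(dur$d) / 2)
  }
  out <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$time_min, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      dt <- diff(df$time_min)
      step <- dt[1]
      if (any(abs(dt - step) > 1e-6)) {
        abort(paste0("track ", key$track_id, " is not uniformly sampled"),
              class = "modewalk_validation_error")
      }
      k_max <- floor(max_lag / step)
      if (k_max >= n) {
        abort("max_lag must be smaller than the track duration",
              class = "modewalk_range_error")
      }
      ks <- seq_len(k_max)
      tibble::tibble(
        lag_min = ks * step,
        msd = vapply(ks, function(k) {
          i <- seq_len(n - k)
          mean((df$x_um[i + k] - df$x_um[i])^2 +
                 (df$y_um[i + k] - df$y_um[i])^2)
        }, numeric(1)),
        n_pairs = n - ks
      )
    }) |>
    dplyr::ungroup()
  class(out) <- c("msd_tbl", class(out))
  out
}

#' Average MSD curves across tracks
#'
#' Ensemble mean of per-track time-averaged MSD curves at each lag
#' (lags present in every contributing track are averaged with equal
#' per-track weight).
#'
#' @param msd_tbl Output of [msd()].
#' @return A one-track `msd_tbl` with `track_id = "ensemble"`.
#' @export
ensemble_msd <- function(msd_tbl) {
  out <- msd_tbl |>
    dplyr::group_by(.data$lag_min) |>
    dplyr::summarise(msd = mean(.data$msd),
                     n_pairs = sum(.data$n_pairs), .groups = "drop") |>
    dplyr::mutate(track_id = "ensemble", .before = 1)
  class(out) <- c("msd_tbl", class(out))
  out
}

#' Anomalous exponent from an MSD curve
#'
#' Least-squares slope of `log(msd)` versus `log(lag)` over the fit
#' window: the anomalous exponent \eqn{\alpha}
#' (\eqn{\mathrm{MSD} \propto \Delta t^\alpha}; 1 = normal diffusion,
#' <1 sub-diffusive, 1–2 super-diffusive, 2 ballistic).
#'
#' @param msd_tbl Output of [msd()] or [ensemble_msd()].
#' @param fit_lags Length-2 numeric, inclusive lag window in minutes
#'   (default `c(10, 30)`, the long-time window).
#' @return Tibble with `track_id`, `alpha`, `n_lags`.
#' @export
fit_alpha <- function(msd_tbl, fit_lags = c(10, 30)) {
  msd_tbl |>
    dplyr::filter(.data$lag_min >= fit_lags[1],
                  .data$lag_min <= fit_lags[2]) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::filter(df, .data$msd > 0)
      if (nrow(df) < 3) {
        abort(paste0("track ", key$track_id,
                     ": need >= 3 positive-MSD lags in the fit window"),
              class = "modewalk_fit_error")
      }
      fit <- lm(log(msd) ~ log(lag_min), data = df)
      tibble::tibble(alpha = unname(coef(fit)[2]), n_lags = nrow(df))
    }) |>
    dplyr::ungroup()
}

#' Per-track distribution of anomalous exponents
#'
#' Fits the anomalous exponent track by track (or segment by segment) and
#' summarizes the spread of the resulting empirical distribution
#' \eqn{P(\alpha)}, the quantitative handle on cell-to-cell dynamic
#' heterogeneity.
#'
#' @param tracks A track table (each segment as its own track id).
#' @param fit_lags Lag window for [fit_alpha()].
#' @param max_lag Largest MSD lag (default `fit_lags[2]`).
#' @return Tibble of per-track `alpha` with a `"summary"` attribute
#'   holding the 5/25/50/75/95% quantiles.
#' @export
alpha_distribution <- function(tracks, fit_lags = c(10, 30),
                               max_lag = fit_lags[2]) {
  out <- fit_alpha(msd(tracks, max_lag = max_lag), fit_lags = fit_lags)
  attr(out, "summary") <- quantile(out$alpha,
                                   c(0.05, 0.25, 0.5, 0.75, 0.95))
  out
}

#' One-dimensional displacement distribution
#'
#' Normalized histogram of x-displacements
#' \eqn{x = x(t + \Delta t) - x(t)} pooled over all start times and
#' tracks at one lag (the self part of the van Hove function). The
#' density integrates to 1 over the binned range.
#'
#' @param tracks A track table with uniform sampling.
#' @param lag Lag in minutes.
#' @param breaks Histogram breaks: a number, a vector, or `NULL` for
#'   Freedman–Diaconis.
#' @return Tibble of class `"displacement_pdf"`: `bin_lo`, `bin_hi`,
#'   `bin_mid`, `count`, `density`; lag stored as attribute `"lag_min"`.
#' @export
displacement_pdf <- function(tracks, lag, breaks = NULL) {
  validate_tracks(tracks)
  disp <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$time_min, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      step <- diff(df$time_min)[1]
      k <- round(lag / step)
      if (k < 1 || k >= nrow(df)) return(tibble::tibble(dx = numeric(0)))
      i <- seq_len(nrow(df) - k)
      tibble::tibble(dx = df$x_um[i + k] - df$x_um[i])
    }) |>
    dplyr::ungroup()
  if (nrow(disp) == 0) {
    abort("no displacement pairs at this lag", class = "modewalk_nodata_error")
  }
  if (is.null(breaks)) breaks <- "FD"
  h <- graphics::hist(disp$dx, breaks = breaks, plot = FALSE)
  out <- tibble::tibble(bin_lo = head(h$breaks, -1), bin_hi = h$breaks[-1],
                        bin_mid = h$mids, count = h$counts,
                        density = h$density)
  attr(out, "lag_min") <- lag
  class(out) <- c("displacement_pdf", class(out))
  out
}

#' Turning-angle distributions as a function of lag time
#'
#' For each lag, signed turning angles between consecutive
#' non-overlapping displacement vectors (\eqn{t_n = n\Delta t}) are
#' pooled over all trajectories and histogrammed; each lag column is
#' normalized to sum to 1.
#'
#' @param tracks A track table with uniform sampling.
#' @param lags Lags in minutes (default `1:30`).
#' @param n_bins Number of angle bins over `[-pi, pi)` (default 61).
#' @return Tibble of class `"angle_heatmap"`: `lag_min`, `theta_mid`,
#'   `prob` (per-lag normalized), `count`.
#' @export
turning_angle_heatmap <- function(tracks, lags = 1:30, n_bins = 61) {
  validate_tracks(tracks)
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  mids <- (head(edges, -1) + edges[-1]) / 2
  by_track <- split(tracks[c("time_min", "x_um", "y_um")], tracks$track_id)
  out <- purrr::map(lags, function(lag) {
    th <- unlist(purrr::map(by_track, function(df) {
      df <- df[order(df$time_min), ]
      step <- diff(df$time_min)[1]
      k <- round(lag / step)
      if (k < 1) return(numeric(0))
      turning_angles(df$x_um, df$y_um, lag = k)
    }), use.names = FALSE)
    counts <- if (length(th) == 0) rep(0L, n_bins) else {
      tabulate(findInterval(th, edges, rightmost.closed = TRUE),
               nbins = n_bins)
    }
    tibble::tibble(lag_min = lag, theta_mid = mids, count = counts,
                   prob = if (sum(counts) > 0) counts / sum(counts)
                          else rep(NA_real_, n_bins))
  }) |> purrr::list_rbind()
  class(out) <- c("angle_heatmap", class(out))
  out
}

#' Angular/radial phase-space series of a trajectory pool
#'
#' From non-overlapping displacement vectors at one lag, returns for each
#' consecutive angle pair the turning angles \eqn{\theta_n},
#' \eqn{\theta_{n+1}}, their raw (un-rewrapped) difference
#' \eqn{\Delta\theta_n = \theta_{n+1} - \theta_n \in (-2\pi, 2\pi)} — the
#' extended range is what makes alternating-turn peaks at
#' \eqn{\pm 2\pi} visible — and the radial rate
#' \eqn{V_n = (|D(t_{n+1})| - |D(t_n)|)/\Delta t}.
#'
#' @param tracks A track table with uniform sampling.
#' @param lag Lag in minutes.
#' @return Tibble: `track_id`, `theta`, `theta_next`, `delta_theta`,
#'   `v_radial` (um/min).
#' @export
phase_space <- function(tracks, lag = 3) {
  validate_tracks(tracks)
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$time_min, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      step <- diff(df$time_min)[1]
      k <- round(lag / step)
      idx <- seq(1, nrow(df), by = max(k, 1))
      if (length(idx) < 4) {
        return(tibble::tibble(theta = numeric(0), theta_next = numeric(0),
                              delta_theta = numeric(0),
                              v_radial = numeric(0)))
      }
      dx <- diff(df$x_um[idx])
      dy <- diff(df$y_um[idx])
      m <- length(dx)
      norms <- sqrt(dx^2 + dy^2)
      # angles computed in place (zero-length vectors give theta = 0) so
      # that theta_n, V_n stay index-aligned
      dot <- dx[-m] * dx[-1] + dy[-m] * dy[-1]
      crs <- dx[-m] * dy[-1] - dy[-m] * dx[-1]
      th <- atan2(crs, dot)
      th[th >= pi] <- -pi
      nth <- length(th)
      if (nth < 2) {
        return(tibble::tibble(theta = numeric(0), theta_next = numeric(0),
                              delta_theta = numeric(0),
                              v_radial = numeric(0)))
      }
      vr <- (norms[-1] - norms[-m]) / lag
      tibble::tibble(theta = th[-nth], theta_next = th[-1],
                     delta_theta = th[-1] - th[-nth],
                     v_radial = vr[seq_len(nth - 1)])
    }) |>
    dplyr::ungroup()
}

#' Successive turning-angle pairs
#'
#' Ordered pairs \eqn{(\theta_n, \theta_{n+1})} of consecutive signed
#' turning angles at one lag, the raw material of the successive-angle
#' density map; quadrant counts are attached as attribute
#' `"quadrant_counts"` (named `pp`, `pn`, `np`, `nn`; zero angles
#' excluded).
#'
#' @inheritParams phase_space
#' @return Tibble: `track_id`, `theta`, `theta_next`.
#' @export
successive_angles <- function(tracks, lag = 3) {
  ps <- phase_space(tracks, lag = lag)
  out <- dplyr::select(ps, "track_id", "theta", "theta_next")
  nz <- out$theta != 0 & out$theta_next != 0
  attr(out, "quadrant_counts") <- c(
    pp = sum(nz & out$theta > 0 & out$theta_next > 0),
    pn = sum(nz & out$theta > 0 & out$theta_next < 0),
    np = sum(nz & out$theta < 0 & out$theta_next > 0),
    nn = sum(nz & out$theta < 0 & out$theta_next < 0)
  )
  out
}

#' Zigzag fraction of turning-angle sequences
#'
#' Ratio of opposite-sign to same-sign successive turning-angle pairs at
#' one lag. Values above 1 indicate alternating (zigzag) turning; below
#' 1, same-direction (curly) turning. Pairs in which either angle is
#' exactly zero are excluded; with no same-sign pairs the ratio is
#' `Inf`.
#'
#' @inheritParams phase_space
#' @param pooled Pool pairs across all tracks into a single ratio
#'   (default `TRUE`); otherwise one row per track.
#' @return Tibble with `n_opposite`, `n_same`, `zigzag_fraction` (and
#'   `track_id` when `pooled = FALSE`).
#' @export
zigzag_fraction <- function(tracks, lag = 3, pooled = TRUE) {
  pairs <- successive_angles(tracks, lag = lag) |>
    dplyr::filter(.data$theta != 0, .data$theta_next != 0) |>
    dplyr::mutate(opposite = sign(.data$theta) != sign(.data$theta_next))
  if (nrow(pairs) == 0) {
    abort("no nonzero successive-angle pairs at this lag",
          class = "modewalk_nodata_error")
  }
  grouped <- if (pooled) pairs else dplyr::group_by(pairs, .data$track_id)
  grouped |>
    dplyr::summarise(
      n_opposite = sum(.data$opposite),
      n_same = sum(!.data$opposite),
      zigzag_fraction = ifelse(.data$n_same > 0,
                               .data$n_opposite / .data$n_same, Inf),
      .groups = "drop"
    )
}
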