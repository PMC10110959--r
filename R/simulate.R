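#' Parameters of one synthetic migration mode
#'
#' Describes a single mode's walker. Three turn models are available:
#' `"persistent"` (heading plus small Gaussian turns — fast-persistent
#' motion), `"zigzag"` (turn magnitudes whose sign alternates with
#' probability `p_alternate` — slow-persistent zigzag motion) and
#' `"anti_persistent"` (an anchored, mean-reverting walk whose heading
#' carries a persistent per-segment curl — slow-diffusive motion with
#' heading reversals at multi-minute lags).
#'
#' Default speeds follow the three reported modes: SD 2.58 +- 1.90, SP
#' 2.21 +- 1.61, FP 6.27 +- 2.66 um/min.
#'
#' @param mode_name One of `"SD"`, `"SP"`, `"FP"` (or any label).
#' @param mean_speed,speed_sd Step-speed distribution, um/min; speeds are
#'   drawn from a normal truncated to positive values.
#' @param turn_model `"persistent"`, `"zigzag"` or `"anti_persistent"`.
#' @param turn_scale Scale of heading changes, radians: the per-step turn
#'   standard deviation (persistent/anti-persistent) or the magnitude
#'   scale of zigzag turn events.
#' @param anchor_stiffness Mean-reversion rate toward the segment anchor,
#'   1/min (anti-persistent model only).
#' @param curl_rate Persistent angular drift of the heading, rad/min
#'   (anti-persistent model only); its sign is drawn once per segment.
#' @param p_alternate Probability that consecutive zigzag turn events
#'   have opposite sign (zigzag model only).
#' @param zig_period Minutes between zigzag turn events (zigzag model
#'   only); between events the heading carries only small noise
#'   (`heading_noise`).
#' @param heading_noise Per-step heading noise between zigzag turn
#'   events, radians.
#' @return A list of class `"mode_params"`.
#' @export
mode_params <- function(mode_name, mean_speed, speed_sd,
                        turn_model = c("persistent", "zigzag",
                                       "anti_persistent"),
                        turn_scale = 0.25, anchor_stiffness = 0.08,
                        curl_rate = 0.8, p_alternate = 0.9,
                        zig_period = 3, heading_noise = 0.15) {
  turn_model <- match.arg(turn_model)
  stopifnot(mean_speed > 0, speed_sd >= 0,
            turn_scale > 0, turn_scale <= pi, zig_period >= 1)
  structure(list(mode_name = mode_name, mean_speed = mean_speed,
                 speed_sd = speed_sd, turn_model = turn_model,
                 turn_scale = turn_scale,
                 anchor_stiffness = anchor_stiffness,
                 curl_rate = curl_rate, p_alternate = p_alternate,
                 zig_period = zig_period, heading_noise = heading_noise),
            class = "mode_params")
}

#' Default parameters of the three migration modes
#'
#' Slow-diffusive (SD, anchored curly walk), slow-persistent (SP, zigzag
#' walker) and fast-persistent (FP, persistent walker) with the reported
#' mode speeds.
#'
#' @return A named list of three [mode_params()] objects.
#' @export
default_mode_params <- function() {
  list(
    SD = mode_params("SD", mean_speed = 2.58, speed_sd = 1.90,
                     turn_model = "anti_persistent", turn_scale = 0.25,
                     anchor_stiffness = 0.05, curl_rate = 0.6),
    SP = mode_params("SP", mean_speed = 2.21, speed_sd = 1.61,
                     turn_model = "zigzag", turn_scale = 2.0,
                     p_alternate = 0.9, zig_period = 3, heading_noise = 0.15),
    FP = mode_params("FP", mean_speed = 6.27, speed_sd = 2.66,
                     turn_model = "persistent", turn_scale = 0.40)
  )
}

# Positive-truncated normal speeds.
draw_speeds <- function(n, mean, sd) {
  v <- rnorm(n, mean, sd)
  while (any(bad <- v <= 0)) v[bad] <- rnorm(sum(bad), mean, sd)
  v
}

# Core walker: advances n_pts - 1 steps from `start` using the current
# RNG stream. Returns a matrix of positions (n_pts x 2).
walk_positions <- function(params, n_pts, dt = 1, start = c(0, 0)) {
  n_steps <- n_pts - 1
  pos <- matrix(0, n_pts, 2)
  pos[1, ] <- start
  heading <- runif(1, -pi, pi)
  speeds <- draw_speeds(n_steps, params$mean_speed, params$speed_sd)
  if (params$turn_model == "persistent") {
    turns <- rnorm(n_steps, 0, params$turn_scale)
    headings <- heading + cumsum(c(0, turns[-n_steps]))
    steps <- speeds * dt * cbind(cos(headings), sin(headings))
    pos[-1, ] <- start[c(1, 1)] + apply(steps, 2, cumsum)
  } else if (params$turn_model == "zigzag") {
    # left-right turn events every zig_period minutes with alternating
    # sign; small heading noise within runs
    turns <- rnorm(n_steps, 0, params$heading_noise)
    event_steps <- which(seq_len(n_steps) %% round(params$zig_period / dt) == 0)
    n_ev <- length(event_steps)
    if (n_ev > 0) {
      mags <- abs(rnorm(n_ev, params$turn_scale, params$turn_scale / 4))
      sign0 <- sample(c(-1, 1), 1)
      flips <- runif(n_ev) < params$p_alternate
      signs <- sign0 * cumprod(ifelse(flips, -1, 1))
      turns[event_steps] <- turns[event_steps] + signs * mags
    }
    headings <- heading + cumsum(c(0, turns[-n_steps]))
    steps <- speeds * dt * cbind(cos(headings), sin(headings))
    pos[-1, ] <- start[c(1, 1)] + apply(steps, 2, cumsum)
  } else if (params$turn_model == "anti_persistent") {
    curl_sign <- sample(c(-1, 1), 1)
    cnoise <- cumsum(rnorm(n_steps, 0, params$turn_scale))
    anchor <- start
    r <- start
    for (i in seq_len(n_steps)) {
      h <- heading + curl_sign * params$curl_rate * dt * i + cnoise[i]
      step <- speeds[i] * dt * c(cos(h), sin(h)) +
        params$anchor_stiffness * (anchor - r) * dt
      r <- r + step
      pos[i + 1, ] <- r
    }
  } else {
    abort(paste0("unknown turn model: ", params$turn_model),
          class = "modewalk_config_error")
  }
  pos
}

#' Simulate one single-mode trajectory segment
#'
#' Generates an `n_steps`-point trajectory at spacing `dt` from a single
#' mode's walker. Identical seeds reproduce identical trajectories.
#'
#' @param params A [mode_params()].
#' @param n_steps Number of trajectory points (>= 2).
#' @param dt Sampling interval, minutes (default 1).
#' @param seed Integer seed.
#' @param track_id Track identifier for the output table.
#' @return A track table with one trajectory.
#' @export
#' @examples
#' simulate_mode_segment(default_mode_params()$FP, n_steps = 60, seed = 1)
simulate_mode_segment <- function(params, n_steps, dt = 1, seed = 1,
                                  track_id = params$mode_name) {
  stopifnot(n_steps >= 2)
  pos <- with_seed(seed, walk_positions(params, n_steps, dt))
  tibble::tibble(track_id = as.character(track_id),
                 time_min = (seq_len(n_steps) - 1) * dt,
                 x_um = pos[, 1], y_um = pos[, 2])
}

#' Mode-switching configuration
#'
#' A first-order Markov chain over the three modes at one-window
#' (60-minute) granularity: the mode is constant within each window and
#' the next window's mode is drawn from the row of `transition_matrix`
#' for the current mode (self-transitions included).
#'
#' @param transition_matrix 3x3 row-stochastic matrix of per-window mode
#'   transition probabilities, rows/columns ordered `SD, SP, FP`.
#' @param initial_distribution Length-3 probability vector for the first
#'   window's mode.
#' @param duration Trajectory duration in minutes (>= 60).
#' @param dt Sampling interval, minutes.
#' @param window Window length, minutes.
#' @return A list of class `"switching_config"`.
#' @export
switching_config <- function(transition_matrix,
                             initial_distribution = rep(1 / 3, 3),
                             duration = 1440, dt = 1, window = 60) {
  transition_matrix <- as.matrix(transition_matrix)
  stopifnot(all(dim(transition_matrix) == c(3, 3)),
            all(transition_matrix >= 0),
            all(abs(rowSums(transition_matrix) - 1) < 1e-12),
            length(initial_distribution) == 3,
            abs(sum(initial_distribution) - 1) < 1e-12)
  if (duration < window) {
    abort("duration must cover at least one window",
          class = "modewalk_size_error")
  }
  structure(list(transition_matrix = transition_matrix,
                 initial_distribution = initial_distribution,
                 duration = duration, dt = dt, window = window),
            class = "switching_config")
}

#' Simulate trajectories with Markov mode switching
#'
#' Generates `n_tracks` trajectories whose migration mode is constant
#' within each 60-minute window and switches window-to-window according
#' to the configured Markov chain. Position is continuous across window
#' boundaries. Per-trajectory random streams are derived from the global
#' seed by counter-based splitting, so trajectory `k` is reproducible in
#' isolation.
#'
#' @param n_tracks Number of trajectories.
#' @param cfg A [switching_config()].
#' @param params Named list of three [mode_params()] (default
#'   [default_mode_params()]).
#' @param seed Global integer seed.
#' @return A list with `tracks` (track table) and `labels` (ground-truth
#'   mode per window: `track_id`, `window_start_min`, `window_end_min`,
#'   `mode`).
#' @export
simulate_switching_tracks <- function(n_tracks, cfg,
                                      params = default_mode_params(),
                                      seed = 1) {
  stopifnot(length(params) == 3)
  modes <- names(params)
  n_windows <- floor(cfg$duration / cfg$window)
  pts_per_window <- round(cfg$window / cfg$dt)
  out <- purrr::map(seq_len(n_tracks), function(k) {
    id <- sprintf("sim%04d", k)
    with_seed(derive_seed(seed, k), {
      mode_idx <- integer(n_windows)
      mode_idx[1] <- sample.int(3, 1, prob = cfg$initial_distribution)
      for (w in seq_len(n_windows)[-1]) {
        mode_idx[w] <- sample.int(3, 1,
                                  prob = cfg$transition_matrix[mode_idx[w - 1], ])
      }
      segs <- vector("list", n_windows)
      cur <- c(0, 0)
      for (w in seq_len(n_windows)) {
        if (w == 1) {
          seg <- walk_positions(params[[mode_idx[w]]], pts_per_window,
                                cfg$dt, cur)
        } else {
          seg <- walk_positions(params[[mode_idx[w]]], pts_per_window + 1,
                                cfg$dt, cur)[-1, , drop = FALSE]
        }
        cur <- seg[nrow(seg), ]
        segs[[w]] <- seg
      }
      pos <- do.call(rbind, segs)
      n_pts_total <- nrow(pos)
      list(
        tracks = tibble::tibble(track_id = id,
                                time_min = (seq_len(n_pts_total) - 1) * cfg$dt,
                                x_um = pos[, 1], y_um = pos[, 2]),
        labels = tibble::tibble(
          track_id = id,
          window_start_min = (seq_len(n_windows) - 1) * cfg$window,
          window_end_min = seq_len(n_windows) * cfg$window,
          mode = modes[mode_idx])
      )
    })
  })
  list(tracks = purrr::list_rbind(purrr::map(out, "tracks")),
       labels = purrr::list_rbind(purrr::map(out, "labels")))
}

#' Simulate a pool of single-mode trajectory segments
#'
#' Generates `n_segments` one-hour (60-point, 1-minute-sampled) segments
#' whose true mode is drawn from `proportions` — the default training
#' mixture for the hybrid kernel. Each segment is an independent track
#' with a counter-derived seed.
#'
#' @param n_segments Number of segments.
#' @param proportions Length-3 mode mixture over `params` (default equal
#'   thirds).
#' @param params Named list of three [mode_params()].
#' @param n_steps Points per segment (default 60).
#' @param dt Sampling interval, minutes.
#' @param seed Global integer seed.
#' @return A list with `tracks` (track table, one track per segment) and
#'   `labels` (tibble `track_id`, `mode`).
#' @export
simulate_segment_pool <- function(n_segments, proportions = rep(1 / 3, 3),
                                  params = default_mode_params(),
                                  n_steps = 60, dt = 1, seed = 1) {
  stopifnot(length(params) == 3, abs(sum(proportions) - 1) < 1e-9)
  modes <- names(params)
  mode_idx <- with_seed(derive_seed(seed, 0),
                        sample.int(3, n_segments, replace = TRUE,
                                   prob = proportions))
  tracks <- purrr::map(seq_len(n_segments), function(k) {
    simulate_mode_segment(params[[mode_idx[k]]], n_steps = n_steps, dt = dt,
                          seed = derive_seed(seed, k),
                          track_id = sprintf("seg%05d", k))
  }) |> purrr::list_rbind()
  list(tracks = tracks,
       labels = tibble::tibble(track_id = sprintf("seg%05d",
                                                  seq_len(n_segments)),
                               mode = modes[mode_idx]))
}

#' Remove tracked points inside specified gap intervals
#'
#' Deletes rows whose time falls inside half-open gap intervals
#' `[start_min, start_min + length_min)`, emulating tracking dropouts;
#' used to exercise gap interpolation and splitting.
#'
#' @param tracks A track table.
#' @param gaps Tibble with `start_min`, `length_min` and optionally
#'   `track_id` (absent: gaps apply to every track).
#' @return The degraded track table.
#' @export
degrade <- function(tracks, gaps) {
  if (nrow(gaps) == 0) return(tracks)
  gaps <- dplyr::arrange(gaps, .data$start_min)
  if (!"track_id" %in% names(gaps)) {
    ids <- unique(tracks$track_id)
    gaps <- tidyr::crossing(track_id = ids, gaps)
  }
  by_track <- split(gaps, gaps$track_id)
  for (g in by_track) {
    ends <- g$start_min + g$length_min
    if (nrow(g) > 1 && any(g$start_min[-1] < ends[-nrow(g)])) {
      abort("overlapping gap intervals", class = "modewalk_spec_error")
    }
  }
  drop <- rep(FALSE, nrow(tracks))
  for (i in seq_len(nrow(gaps))) {
    drop <- drop | (tracks$track_id == gaps$track_id[i] &
                      tracks$time_min >= gaps$start_min[i] &
                      tracks$time_min < gaps$start_min[i] + gaps$length_min[i])
  }
  tracks[!drop, , drop = FALSE]
}

#' Analytic fixture trajectories
#'
#' Small trajectories with known statistical signatures, used as oracles:
#' `"ballistic"` (constant velocity; MSD exactly \eqn{v^2\Delta t^2},
#' asphericity 1), `"brownian"` (i.i.d. Gaussian increments; MSD slope 1),
#' `"circle"` (equally spaced points on a circle; asphericity 0),
#' `"zigzag"` (alternating exact +-`turn` turns) and `"stationary"`.
#'
#' @param kind Fixture kind.
#' @param speed Step speed, um/min (ballistic/zigzag).
#' @param sigma Per-coordinate step standard deviation, um (brownian).
#' @param radius Circle radius, um.
#' @param turn Zigzag turn magnitude, radians (default pi/2).
#' @param heading Initial heading, radians.
#' @param duration Duration in minutes (the track has `duration/dt + 1`
#'   points).
#' @param dt Sampling interval, minutes.
#' @param n_points For `"circle"`: number of equally spaced points.
#' @param seed Seed (brownian only).
#' @param track_id Track identifier.
#' @return A track table with one trajectory.
#' @export
#' @examples
#' fixture_track("circle", radius = 10, n_points = 60)
fixture_track <- function(kind = c("ballistic", "brownian", "circle",
                                   "zigzag", "stationary"),
                          speed = 2, sigma = 1, radius = 10, turn = pi / 2,
                          heading = 0, duration = 60, dt = 1, n_points = 60,
                          seed = 1, track_id = kind[1]) {
  kind <- match.arg(kind)
  n <- round(duration / dt) + 1
  t <- (seq_len(n) - 1) * dt
  pos <- switch(
    kind,
    ballistic = cbind(speed * t * cos(heading), speed * t * sin(heading)),
    brownian = with_seed(seed, {
      cbind(cumsum(c(0, rnorm(n - 1, 0, sigma))),
            cumsum(c(0, rnorm(n - 1, 0, sigma))))
    }),
    circle = {
      t <- (seq_len(n_points) - 1) * dt
      ang <- 2 * pi * (seq_len(n_points) - 1) / n_points
      cbind(radius * cos(ang), radius * sin(ang))
    },
    zigzag = {
      turns <- rep(c(turn, -turn), length.out = n - 1)
      headings <- heading + cumsum(c(0, turns[-(n - 1)]))
      steps <- speed * dt * cbind(cos(headings), sin(headings))
      rbind(c(0, 0), apply(steps, 2, cumsum))
    },
    stationary = matrix(0, n, 2)
  )
  tibble::tibble(track_id = as.character(track_id), time_min = t,
                 x_um = pos[, 1], y_um = pos[, 2])
}
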