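as_mode_sequence_tbl <- function(modes, mode_levels = MODE_LEVELS) {
  needed <- c("track_id", "window_start_min", "mode")
  missing <- setdiff(needed, names(modes))
  if (length(missing) > 0) {
    abort(paste0("mode sequence is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "modewalk_format_error")
  }
  extra <- setdiff(unique(modes$mode), mode_levels)
  if (length(extra) > 0) {
    abort(paste0("unknown mode label(s): ", paste(extra, collapse = ", ")),
          class = "modewalk_format_error")
  }
  dplyr::arrange(modes, .data$track_id, .data$window_start_min)
}

#' Mode-transition matrix
#'
#' Counts every ordered pair of consecutive windows (self-transitions
#' included) pooled over all mode sequences, and row-normalizes into
#' transition probabilities \eqn{P_{ij}}. Rows with no observed
#' transitions are `NA` (undefined), never silently zero. The total count
#' equals \eqn{\sum_{\mathrm{tracks}} (\mathrm{windows} - 1)}.
#'
#' @param modes A mode sequence tibble (`track_id`, `window_start_min`,
#'   `window_end_min`, `mode`), e.g. from [annotate_modes()].
#' @param mode_levels Mode alphabet (default `c("SD", "SP", "FP")`).
#' @return An object of class `"transition_matrix"`: list with `counts`,
#'   `probs` (both `length(mode_levels)` square), `n_transitions`.
#' @export
transition_matrix <- function(modes, mode_levels = MODE_LEVELS) {
  modes <- as_mode_sequence_tbl(modes, mode_levels)
  pairs <- modes |>
    dplyr::group_by(.data$track_id) |>
    dplyr::reframe(from = head(.data$mode, -1), to = tail(.data$mode, -1))
  if (nrow(pairs) == 0) {
    abort("no consecutive window pairs in the pool",
          class = "modewalk_nodata_error")
  }
  counts <- table(factor(pairs$from, mode_levels),
                  factor(pairs$to, mode_levels))
  counts <- matrix(as.integer(counts), length(mode_levels),
                   dimnames = list(from = mode_levels, to = mode_levels))
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs > 0, rs, NA_real_)
  structure(list(counts = counts, probs = probs,
                 n_transitions = sum(counts)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Mode-transition matrix (", x$n_transitions, "transitions )\n")
  print(round(x$probs, 3))
  invisible(x)
}

#' @describeIn transition_matrix Long tidy form: one row per ordered mode
#'   pair with `n` and `prob`.
#' @param x A `transition_matrix`.
#' @param ... Unused.
#' @export
tidy.transition_matrix <- function(x, ...) {
  lev <- rownames(x$counts)
  tidyr::expand_grid(from = lev, to = lev) |>
    dplyr::mutate(n = as.vector(t(x$counts)),
                  prob = as.vector(t(x$probs)))
}

#' Per-mode window fractions
#'
#' Fraction of classified windows spent in each mode (occurrence
#' frequency); fractions sum to 1.
#'
#' @inheritParams transition_matrix
#' @return Tibble: `mode`, `n_windows`, `fraction`.
#' @export
mode_fractions <- function(modes, mode_levels = MODE_LEVELS) {
  modes <- as_mode_sequence_tbl(modes, mode_levels)
  tibble::tibble(mode = mode_levels) |>
    dplyr::left_join(dplyr::count(modes, .data$mode, name = "n_windows"),
                     by = "mode") |>
    tidyr::replace_na(list(n_windows = 0L)) |>
    dplyr::mutate(fraction = .data$n_windows / sum(.data$n_windows))
}

#' Single-mode versus multi-mode track fractions
#'
#' A track migrates homogeneously (single-mode) iff all its windows share
#' one mode. Fractions over tracks sum to 1.
#'
#' @inheritParams transition_matrix
#' @return Tibble: `class` (`"single_mode"`, `"multi_mode"`), `n_tracks`,
#'   `fraction`.
#' @export
homogeneity_fraction <- function(modes, mode_levels = MODE_LEVELS) {
  modes <- as_mode_sequence_tbl(modes, mode_levels)
  per_track <- modes |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(single = dplyr::n_distinct(.data$mode) == 1)
  tibble::tibble(class = c("single_mode", "multi_mode"),
                 n_tracks = c(sum(per_track$single),
                              sum(!per_track$single))) |>
    dplyr::mutate(fraction = .data$n_tracks / sum(.data$n_tracks))
}

#' Mode lifetimes (consecutive-window dwell times)
#'
#' Extracts maximal constant-mode runs from each sequence. Runs touching
#' a track boundary are censored (the true dwell is at least as long);
#' they are flagged but retained, since dropping them would bias against
#' long dwells. Run lengths are in windows (hours at the default
#' 60-minute window).
#'
#' @inheritParams transition_matrix
#' @return Tibble: `track_id`, `mode`, `run_windows`, `censored_left`,
#'   `censored_right`, `censored`.
#' @export
mode_lifetimes <- function(modes, mode_levels = MODE_LEVELS) {
  modes <- as_mode_sequence_tbl(modes, mode_levels)
  modes |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) {
      r <- rle(df$mode)
      k <- length(r$lengths)
      tibble::tibble(mode = r$values, run_windows = r$lengths,
                     censored_left = seq_len(k) == 1,
                     censored_right = seq_len(k) == k)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(censored = .data$censored_left | .data$censored_right)
}

#' Empirical CDF of mode lifetimes
#'
#' @param lifetimes Output of [mode_lifetimes()].
#' @return Tibble: `mode`, `run_windows`, `cdf`.
#' @export
lifetime_cdf <- function(lifetimes) {
  lifetimes |>
    dplyr::count(.data$mode, .data$run_windows) |>
    dplyr::group_by(.data$mode) |>
    dplyr::arrange(.data$run_windows, .by_group = TRUE) |>
    dplyr::mutate(cdf = cumsum(.data$n) / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select("mode", "run_windows", "cdf")
}

#' One-step versus two-step cross-transition pathways
#'
#' Each sequence is collapsed to its run-mode order (self-transitions
#' removed). For every ordered mode pair \eqn{(i, j)}, \eqn{i \ne j}:
#' one-step transitions are adjacent \eqn{(i, j)} occurrences in the
#' collapsed sequence; two-step transitions are \eqn{(i, k, j)}
#' occurrences via the third mode \eqn{k}. Fractions are normalized
#' within each pair (routes of three or more steps are not counted).
#'
#' @inheritParams transition_matrix
#' @return Tibble: `from`, `to`, `one_step`, `two_step`, `frac_one_step`,
#'   `frac_two_step`.
#' @export
pathway_summary <- function(modes, mode_levels = MODE_LEVELS) {
  modes <- as_mode_sequence_tbl(modes, mode_levels)
  collapsed <- modes |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(seq = list(rle(.data$mode)$values))
  pairs_grid <- tidyr::expand_grid(from = mode_levels, to = mode_levels) |>
    dplyr::filter(.data$from != .data$to)
  one <- matrix(0L, length(mode_levels), length(mode_levels),
                dimnames = list(mode_levels, mode_levels))
  two <- one
  for (s in collapsed$seq) {
    n <- length(s)
    if (n >= 2) {
      for (i in seq_len(n - 1)) one[s[i], s[i + 1]] <- one[s[i], s[i + 1]] + 1L
    }
    if (n >= 3) {
      for (i in seq_len(n - 2)) {
        if (s[i] != s[i + 2]) two[s[i], s[i + 2]] <- two[s[i], s[i + 2]] + 1L
      }
    }
  }
  pairs_grid |>
    dplyr::mutate(
      one_step = purrr::map2_int(.data$from, .data$to, ~ one[.x, .y]),
      two_step = purrr::map2_int(.data$from, .data$to, ~ two[.x, .y]),
      total = .data$one_step + .data$two_step,
      frac_one_step = ifelse(.data$total > 0,
                             .data$one_step / .data$total, NA_real_),
      frac_two_step = ifelse(.data$total > 0,
                             .data$two_step / .data$total, NA_real_)
    ) |>
    dplyr::select(-"total")
}
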