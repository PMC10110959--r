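#' Column dialect for track tables
#'
#' Describes how an on-disk delimited file maps onto the canonical track
#' table columns (`track_id`, `time_min`, `x_um`, `y_um`, optional
#' `condition`). Unit factors convert the file's time and length units to
#' minutes and micrometers; both conversions are linear and invertible.
#'
#' @param track_id,time,x,y Column names in the source file.
#' @param condition Optional condition column name, or `NULL`.
#' @param time_factor Multiplier taking source time units to minutes
#'   (e.g. `1/60` for seconds).
#' @param length_factor Multiplier taking source length units to
#'   micrometers (e.g. `1000` for millimeters).
#' @param delim Field delimiter.
#' @return A list of class `"track_dialect"`.
#' @export
#' @examples
#' track_dialect(track_id = "TRACK_ID", time = "T", x = "X", y = "Y")
track_dialect <- function(track_id = "track_id", time = "time_min",
                          x = "x_um", y = "y_um", condition = NULL,
                          time_factor = 1, length_factor = 1, delim = ",") {
  structure(
    list(track_id = track_id, time = time, x = x, y = y,
         condition = condition, time_factor = time_factor,
         length_factor = length_factor, delim = delim),
    class = "track_dialect"
  )
}

#' Validate a track table
#'
#' Checks the structural invariants every downstream verb assumes: the four
#' canonical columns are present, coordinates and times are finite, and
#' within each track timestamps are unique and therefore strictly
#' increasing once sorted.
#'
#' @param tracks A track table (tibble with `track_id`, `time_min`,
#'   `x_um`, `y_um`).
#' @return `tracks`, invisibly, sorted by track and time.
#' @export
validate_tracks <- function(tracks) {
  needed <- c("track_id", "time_min", "x_um", "y_um")
  missing <- setdiff(needed, names(tracks))
  if (length(missing) > 0) {
    abort(paste0("track table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "modewalk_format_error")
  }
  num <- c("time_min", "x_um", "y_um")
  bad_num <- num[!vapply(tracks[num], is.numeric, logical(1))]
  if (length(bad_num) > 0) {
    abort(paste0("non-numeric column(s): ", paste(bad_num, collapse = ", ")),
          class = "modewalk_format_error")
  }
  if (any(!is.finite(as.matrix(tracks[num])))) {
    abort("track table contains missing or non-finite values; gaps must be absent rows, not placeholders",
          class = "modewalk_validation_error")
  }
  dup <- tracks |>
    dplyr::count(.data$track_id, .data$time_min) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicated (track_id, time_min) rows in track(s): ",
                 paste(unique(dup$track_id), collapse = ", ")),
          class = "modewalk_validation_error")
  }
  invisible(dplyr::arrange(tracks, .data$track_id, .data$time_min))
}

#' Read a delimited track table
#'
#' Reads 2D cell-track data (one row per cell per timepoint) from
#' delimited text, renames columns according to a [track_dialect()], and
#' converts times to minutes and positions to micrometers. Rows are
#' returned sorted by track and time.
#'
#' @param file Path or connection understood by [readr::read_delim()].
#' @param dialect A [track_dialect()] describing the file's columns and
#'   units.
#' @return A tibble with columns `track_id` (character), `time_min`,
#'   `x_um`, `y_um`, and `condition` if declared in the dialect.
#' @export
read_tracks <- function(file, dialect = track_dialect()) {
  raw <- readr::read_delim(file, delim = dialect$delim,
                           show_col_types = FALSE, progress = FALSE)
  needed <- c(track_id = dialect$track_id, time = dialect$time,
              x = dialect$x, y = dialect$y)
  missing <- needed[!needed %in% names(raw)]
  if (length(missing) > 0) {
    abort(paste0("input is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "modewalk_format_error")
  }
  out <- tibble::tibble(
    track_id = as.character(raw[[dialect$track_id]]),
    time_min = as.numeric(raw[[dialect$time]]) * dialect$time_factor,
    x_um = as.numeric(raw[[dialect$x]]) * dialect$length_factor,
    y_um = as.numeric(raw[[dialect$y]]) * dialect$length_factor
  )
  if (!is.null(dialect$condition) && dialect$condition %in% names(raw)) {
    out$condition <- as.character(raw[[dialect$condition]])
  }
  validate_tracks(out)
  dplyr::arrange(out, .data$track_id, .data$time_min)
}

#' Write a track table, optionally annotated with migration modes
#'
#' Writes the canonical track columns plus, when a mode sequence is
#' supplied, the window each point falls in and the mode assigned to that
#' window (`window_start_min`, `window_end_min`, `mode`; `NA` for points
#' outside any classified window). Coordinates survive a write/read
#' round trip exactly at decimal-text precision.
#'
#' @param tracks A track table.
#' @param file Output path.
#' @param modes Optional mode sequence (tibble with `track_id`,
#'   `window_start_min`, `window_end_min`, `mode`), e.g. from
#'   [annotate_modes()].
#' @return `file`, invisibly.
#' @export
write_annotated <- function(tracks, file, modes = NULL) {
  validate_tracks(tracks)
  out <- dplyr::arrange(tracks, .data$track_id, .data$time_min)
  if (!is.null(modes) && nrow(modes) > 0) {
    unknown <- setdiff(unique(modes$track_id), unique(tracks$track_id))
    if (length(unknown) > 0) {
      abort(paste0("mode labels reference unknown track(s): ",
                   paste(unknown, collapse = ", ")),
            class = "modewalk_consistency_error")
    }
    out <- out |>
      dplyr::left_join(
        dplyr::select(modes, "track_id", "window_start_min",
                      "window_end_min", "mode"),
        by = dplyr::join_by("track_id",
                            "time_min" >= "window_start_min",
                            "time_min" < "window_end_min")
      )
  } else {
    out$window_start_min <- NA_real_
    out$window_end_min <- NA_real_
    out$mode <- NA_character_
  }
  readr::write_csv(out, file, progress = FALSE)
  invisible(file)
}
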