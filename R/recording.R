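#' Spike recordings as tidy tables
#'
#' A recording is stored as a tibble with one row per sorted spike —
#' columns `electrode_id` (character) and `time_s` (seconds from recording
#' start) — carrying the recording id, condition label and duration as
#' attributes. Analysis begins at sorted spike times; raw voltage traces,
#' filtering and spike sorting are upstream of this package.
#'
#' @param spikes Data frame with columns `electrode_id` and `time_s`.
#' @param duration Recording duration in seconds.
#' @param condition One of `"no_stim"`, `"hfs5"`, `"hfs40"`: spontaneous
#'   activity before stimulation, after a 5-pulse 100 Hz theta-patterned
#'   train, or after a 40-pulse train.
#' @param recording_id Free-text identifier.
#'
#' @return A tibble of class `mea_recording`, sorted by electrode then time,
#'   with exact duplicate (electrode, time) rows collapsed.
#' @export
mea_recording <- function(spikes, duration,
                          condition = c("no_stim", "hfs5", "hfs40"),
                          recording_id = "recording") {
  condition <- match.arg(condition)
  stopifnot(is.numeric(duration), length(duration) == 1, duration > 0)
  spikes <- tibble::as_tibble(spikes)
  stopifnot(all(c("electrode_id", "time_s") %in% names(spikes)))
  spikes <- spikes |>
    dplyr::mutate(electrode_id = as.character(.data$electrode_id),
                  time_s = as.numeric(.data$time_s)) |>
    dplyr::distinct(.data$electrode_id, .data$time_s) |>
    dplyr::arrange(.data$electrode_id, .data$time_s)
  if (nrow(spikes) && any(spikes$time_s < 0)) {
    stop("spike times must be >= 0", call. = FALSE)
  }
  if (nrow(spikes) && any(spikes$time_s > duration)) {
    stop("spike time exceeds recording duration (", duration, " s)",
         call. = FALSE)
  }
  structure(spikes,
            class = c("mea_recording", class(spikes)),
            duration = duration, condition = condition,
            recording_id = recording_id)
}

#' @rdname mea_recording
#' @param x An `mea_recording`.
#' @export
recording_duration <- function(x) attr(x, "duration")

#' @rdname mea_recording
#' @export
recording_condition <- function(x) attr(x, "condition")

#' Extract one electrode's spike train
#'
#' @param recording An [mea_recording()].
#' @param electrode_id Electrode to extract.
#' @return Numeric vector of strictly ascending spike times in seconds
#'   (length 0 if the electrode fired no spikes).
#' @export
spike_train <- function(recording, electrode_id) {
  recording$time_s[recording$electrode_id == electrode_id]
}

#' Read / write a spike table
#'
#' Spike tables are plain delimited text (CSV) with header columns
#' `electrode_id,time_s`. Times are seconds; duplicate (electrode, time)
#' rows are collapsed and times are sorted on read.
#'
#' @param path CSV file path.
#' @param duration Recording duration in seconds; any spike time beyond it
#'   is a validation error.
#' @inheritParams mea_recording
#' @return `read_spike_table()` returns an [mea_recording()];
#'   `write_spike_table()` returns `path` invisibly.
#' @export
read_spike_table <- function(path, duration, condition = "no_stim",
                             recording_id = basename(path)) {
  raw <- utils::read.csv(path, colClasses = "character",
                         col.names = c("electrode_id", "time_s"))
  raw$time_s <- suppressWarnings(as.numeric(raw$time_s))
  bad <- which(!is.finite(raw$time_s))
  if (length(bad)) {
    stop("malformed spike time at data line ", bad[1], " of ", path,
         call. = FALSE)
  }
  mea_recording(raw, duration = duration, condition = condition,
                recording_id = recording_id)
}

#' @rdname read_spike_table
#' @param recording An `mea_recording`.
#' @export
write_spike_table <- function(recording, path) {
  utils::write.csv(as.data.frame(recording)[, c("electrode_id", "time_s")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.mea_recording <- function(x, ...) {
  cat("<mea_recording '", attr(x, "recording_id"), "'> ",
      nrow(x), " spikes / ", length(unique(x$electrode_id)),
      " electrodes; ", recording_duration(x), " s; condition ",
      recording_condition(x), "\n", sep = "")
  NextMethod()
}
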