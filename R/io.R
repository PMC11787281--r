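#' Column mapping for delimited IMU recordings
#'
#' Describes how the columns of a delimited recording file map onto the
#' timestamp, the three acceleration axes (units G) and the three
#' angular-velocity axes (units dps). The default dialect has a header row
#' naming `t, ax, ay, az, gx, gy, gz`.
#'
#' @param time Name of the timestamp column (seconds).
#' @param acc Character vector of length 3: X, Y, Z acceleration columns.
#' @param gyr Character vector of length 3: X, Y, Z angular-velocity columns.
#' @return A named list used by [read_imu_recording()].
#' @export
imu_schema <- function(time = "t",
                       acc = c("ax", "ay", "az"),
                       gyr = c("gx", "gy", "gz")) {
  stopifnot(length(time) == 1, length(acc) == 3, length(gyr) == 3)
  list(time = time, acc = acc, gyr = gyr)
}

imu_axis_cols <- c("ax", "ay", "az", "gx", "gy", "gz")

#' Construct a validated IMU recording
#'
#' A recording is a tibble with one row per sample and columns `t` (seconds
#' from the recording origin), `ax, ay, az` (acceleration, G) and
#' `gx, gy, gz` (angular velocity, dps), sampled at a fixed rate with no
#' gaps. Metadata (`subject_id`, `sample_rate`, `start_time`) travel as
#' attributes.
#'
#' @param data Data frame with the six axis columns (`t` optional; rebuilt
#'   from the sample rate when absent).
#' @param subject_id Subject identifier.
#' @param sample_rate Sampling rate in Hz (default 60).
#' @param start_time Recording origin in seconds.
#' @return A tibble of class `imu_recording`.
#' @export
imu_recording <- function(data, subject_id = "subject",
                          sample_rate = 60, start_time = 0) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    abort("`sample_rate` must be a single positive number.", class = "somnimu_format_error")
  }
  missing_cols <- setdiff(imu_axis_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Recording is missing axis column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "somnimu_format_error")
  }
  n <- nrow(data)
  if (n < 2) abort("Recording must contain at least 2 samples.", class = "somnimu_data_error")
  out <- tibble::tibble(t = seq(0, by = 1 / sample_rate, length.out = n))
  for (col in imu_axis_cols) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      abort(paste0("Column `", col, "` must be numeric."), class = "somnimu_format_error")
    }
    if (anyNA(v)) {
      abort(paste0("Column `", col, "` contains missing samples."),
            class = "somnimu_data_error")
    }
    out[[col]] <- v
  }
  structure(out,
            class = c("imu_recording", class(tibble::tibble())),
            subject_id = subject_id,
            sample_rate = sample_rate,
            start_time = start_time)
}

#' @export
print.imu_recording <- function(x, ...) {
  fs <- attr(x, "sample_rate")
  cat(sprintf("<imu_recording> subject %s: %d samples at %g Hz (%.1f s)\n",
              attr(x, "subject_id"), nrow(x), fs, nrow(x) / fs))
  NextMethod()
}

#' Duration of a recording in seconds
#' @param recording An [imu_recording()].
#' @return Duration in seconds (samples / sample rate).
#' @export
recording_duration <- function(recording) {
  nrow(recording) / attr(recording, "sample_rate")
}

#' Read a wrist IMU recording from delimited text
#'
#' Reads a CSV with a header row, maps columns through `schema`, checks that
#' the timestamps are regular and consistent with the declared sampling rate
#' (within 1%), and returns a validated [imu_recording()]. A missing column
#' is a format error; a timestamp gap beyond half a sample period is a data
#' error.
#'
#' @param path Path to the CSV file.
#' @param schema Column mapping from [imu_schema()].
#' @param subject_id Subject identifier (defaults to the file stem).
#' @param sample_rate Declared sampling rate in Hz; when `NULL` (default 60
#'   assumed absent timestamps) it is taken as 60.
#' @param offset Synchronisation offset in seconds added to `start_time`
#'   (one scalar per subject; no drift model).
#' @return An [imu_recording()].
#' @export
read_imu_recording <- function(path, schema = imu_schema(),
                               subject_id = NULL, sample_rate = 60,
                               offset = 0) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  want <- c(schema$time, schema$acc, schema$gyr)
  missing_cols <- setdiff(want, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("File is missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "somnimu_format_error")
  }
  tt <- raw[[schema$time]]
  dt <- diff(tt)
  if (length(dt) == 0) abort("Recording has fewer than 2 samples.", class = "somnimu_data_error")
  dt_med <- median(dt)
  if (dt_med <= 0) abort("Timestamps are not increasing.", class = "somnimu_data_error")
  implied_rate <- 1 / dt_med
  if (abs(implied_rate - sample_rate) / sample_rate > 0.01) {
    abort(sprintf("Declared sample rate %g Hz does not match timestamp spacing (%.4g Hz).",
                  sample_rate, implied_rate),
          class = "somnimu_data_error")
  }
  if (any(abs(dt - dt_med) > 0.5 * dt_med)) {
    abort("Irregular sampling: timestamp gap beyond half a sample period.",
          class = "somnimu_data_error")
  }
  dat <- tibble::tibble(
    ax = raw[[schema$acc[1]]], ay = raw[[schema$acc[2]]], az = raw[[schema$acc[3]]],
    gx = raw[[schema$gyr[1]]], gy = raw[[schema$gyr[2]]], gz = raw[[schema$gyr[3]]]
  )
  imu_recording(dat,
                subject_id = subject_id %||% sub("\\.[^.]*$", "", basename(path)),
                sample_rate = sample_rate,
                start_time = tt[1] + offset)
}

#' Write a recording to the CSV dialect [read_imu_recording()] reads
#'
#' @param recording An [imu_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imu_recording <- function(recording, path) {
  readr::write_csv(tibble::as_tibble(recording), path, progress = FALSE)
  invisible(path)
}

#' Respiratory-event annotation categories
#' @return Character vector of the four admissible event types.
#' @export
annotation_types <- function() {
  c("obstructive_apnea", "central_apnea", "mixed_apnea", "hypopnea")
}

#' Read respiratory-event annotations
#'
#' Annotations stand in for polysomnographic scoring: one row per
#' apnea/hypopnea episode with columns `event_type`, `onset_s`, `duration_s`
#' (times in seconds relative to the recording start). Events are returned
#' sorted by onset. Unknown event types, negative onsets or non-positive
#' durations are format errors.
#'
#' @param path Path to the annotation CSV.
#' @return Tibble with columns `event_type`, `onset`, `duration`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) {
    return(tibble::tibble(event_type = character(), onset = numeric(),
                          duration = numeric()))
  }
  want <- c("event_type", "onset_s", "duration_s")
  missing_cols <- setdiff(want, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Annotation file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "somnimu_format_error")
  }
  events <- tibble::tibble(event_type = as.character(raw$event_type),
                           onset = as.numeric(raw$onset_s),
                           duration = as.numeric(raw$duration_s))
  validate_events(events)
  dplyr::arrange(events, .data$onset)
}

validate_events <- function(events) {
  bad <- setdiff(unique(events$event_type), annotation_types())
  if (length(bad) > 0) {
    abort(paste0("Unknown event type(s): ", paste(bad, collapse = ", ")),
          class = "somnimu_format_error")
  }
  if (any(events$duration <= 0)) {
    abort("Event durations must be positive.", class = "somnimu_format_error")
  }
  if (any(events$onset < 0)) {
    abort("Event onsets must be non-negative.", class = "somnimu_format_error")
  }
  invisible(events)
}

#' Write annotations in the dialect [read_annotations()] reads
#' @param events Tibble with `event_type`, `onset`, `duration`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(events, path) {
  out <- tibble::tibble(event_type = events$event_type,
                        onset_s = events$onset,
                        duration_s = events$duration)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' The 30-second epoch grid of a recording
#'
#' Epoch `i` spans `[origin + 30 (i - 1), origin + 30 i)` (half-open,
#' 1-based). Trailing samples that do not fill a whole epoch are discarded.
#'
#' @param recording An [imu_recording()] (or anything with a duration via
#'   `recording_duration()`).
#' @param epoch_length Epoch length in seconds (30).
#' @return An `epoch_grid` object.
#' @export
make_epoch_grid <- function(recording, epoch_length = 30) {
  duration <- recording_duration(recording)
  n_epochs <- floor(duration / epoch_length)
  if (n_epochs < 1) {
    abort(sprintf("Recording (%.1f s) is shorter than one %g-s epoch.",
                  duration, epoch_length),
          class = "somnimu_data_error")
  }
  structure(list(epoch_length = epoch_length, n_epochs = n_epochs, origin = 0),
            class = "epoch_grid")
}

#' @export
print.epoch_grid <- function(x, ...) {
  cat(sprintf("<epoch_grid> %d epochs of %g s from t = %g s\n",
              x$n_epochs, x$epoch_length, x$origin))
  invisible(x)
}

#' @export
as_tibble.epoch_grid <- function(x, ...) {
  i <- seq_len(x$n_epochs)
  tibble::tibble(epoch = i,
                 start = x$origin + x$epoch_length * (i - 1),
                 end = x$origin + x$epoch_length * i)
}

#' Epoch containing a time point
#'
#' Maps times onto 1-based epoch indices of a grid (half-open epochs).
#' Times beyond the grid return `NA`.
#'
#' @param time Numeric vector of times in seconds.
#' @param grid An `epoch_grid`.
#' @return Integer vector of epoch indices (`NA` outside the grid).
#' @export
epoch_index <- function(time, grid) {
  i <- floor((time - grid$origin) / grid$epoch_length) + 1L
  i[i < 1L | i > grid$n_epochs] <- NA_integer_
  as.integer(i)
}

# sample indices (1-based) of epoch `epoch` at sampling rate fs
epoch_samples <- function(epoch, grid, fs) {
  if (epoch < 1 || epoch > grid$n_epochs) {
    abort("Epoch index outside the grid.", class = "somnimu_data_error")
  }
  start <- (epoch - 1) * grid$epoch_length
  i0 <- round(start * fs) + 1L
  i1 <- round((start + grid$epoch_length) * fs)
  seq.int(i0, i1)
}
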