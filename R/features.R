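#' Names of the fifteen per-epoch features
#'
#' Two frequency-stability features (`mcg_fsi`, `rm_fsi`), the body-movement
#' maximum (`bm`), and six dip features per sensor (width `w`, relative area
#' between envelopes `rabe`, boundary height `h_max` and ratio `h_ratio`,
#' absolute and relative maximum depth `ad`, `rd`), suffixed `_acc` / `_gyr`.
#'
#' @return Character vector of length 15 in the canonical column order.
#' @export
somnimu_features <- function() {
  dipf <- c("w", "rabe", "h_max", "h_ratio", "ad", "rd")
  c("mcg_fsi", "rm_fsi", "bm",
    paste0(dipf, "_acc"), paste0(dipf, "_gyr"))
}

dip_feature_cols <- function(suffix) {
  paste0(c("w", "rabe", "h_max", "h_ratio", "ad", "rd"), "_", suffix)
}

#' Label epochs from respiratory-event annotations
#'
#' Under the default `"end"` rule an epoch is RE-positive iff at least one
#' event's end time (`onset + duration`) falls within it — the epoch
#' containing the end of the event, where breathing resumes and the signal
#' disturbance concentrates. The `"overlap"` rule instead marks every epoch
#' an event overlaps, for sensitivity analysis. Events ending beyond the
#' grid are assigned to the last epoch with a warning.
#'
#' @param events Tibble of annotations (`event_type`, `onset`, `duration`),
#'   as from [read_annotations()]; may have zero rows.
#' @param grid Epoch grid from [make_epoch_grid()].
#' @param rule `"end"` (default) or `"overlap"`.
#' @return Tibble with columns `epoch` and `label` (factor with levels
#'   `RE_negative`, `RE_positive`).
#' @export
label_epochs <- function(events, grid, rule = c("end", "overlap")) {
  rule <- match.arg(rule)
  positive <- logical(grid$n_epochs)
  if (nrow(events) > 0) {
    validate_events(events)
    if (rule == "end") {
      ends <- events$onset + events$duration
      ep <- floor((ends - grid$origin) / grid$epoch_length) + 1
      if (any(ep > grid$n_epochs)) {
        warn("Event(s) ending beyond the epoch grid assigned to the last epoch.")
        ep[ep > grid$n_epochs] <- grid$n_epochs
      }
      positive[ep[ep >= 1]] <- TRUE
    } else {
      for (i in seq_len(nrow(events))) {
        from <- max(1, floor((events$onset[i] - grid$origin) / grid$epoch_length) + 1)
        to <- min(grid$n_epochs,
                  floor((events$onset[i] + events$duration[i] - grid$origin) /
                          grid$epoch_length) + 1)
        if (from <= to) positive[from:to] <- TRUE
      }
    }
  }
  tibble::tibble(
    epoch = seq_len(grid$n_epochs),
    label = factor(ifelse(positive, "RE_positive", "RE_negative"),
                   levels = c("RE_negative", "RE_positive"))
  )
}

#' Assign dips to epochs
#'
#' A dip belongs to the epoch containing its end time; among several dips
#' ending in the same epoch the one with the greatest absolute area between
#' envelopes (`abe`) is kept (ties break toward the earliest dip). Dips
#' ending in the discarded trailing partial epoch are dropped.
#'
#' @param dips Featurised dip tibble from [find_dips()].
#' @param grid Epoch grid from [make_epoch_grid()].
#' @return Tibble with one row per epoch that received a dip: `epoch` plus
#'   the dip's feature columns.
#' @export
assign_dips <- function(dips, grid) {
  if (nrow(dips) == 0) {
    return(tibble::tibble(epoch = integer()))
  }
  dips$epoch <- epoch_index(pmin(dips$end,
                                 grid$origin + grid$n_epochs * grid$epoch_length -
                                   1e-9),
                            grid)
  dips$epoch[dips$end > grid$origin + grid$n_epochs * grid$epoch_length] <- NA
  dips <- dips[!is.na(dips$epoch), ]
  dips |>
    dplyr::arrange(.data$epoch, dplyr::desc(.data$abe), .data$start) |>
    dplyr::distinct(.data$epoch, .keep_all = TRUE) |>
    dplyr::select("epoch", dplyr::everything())
}

# Per-epoch dip feature block for one sensor: assigned dips spread onto the
# full grid, zero-filled where no dip ended in the epoch.
epoch_dip_block <- function(dips, grid, suffix) {
  assigned <- assign_dips(dips, grid)
  out <- tibble::tibble(epoch = seq_len(grid$n_epochs))
  src <- c("w", "rabe", "h_max", "h_ratio", "ad", "rd")
  if (nrow(assigned) == 0) {
    for (col in dip_feature_cols(suffix)) out[[col]] <- 0
    return(out)
  }
  sel <- assigned[, c("epoch", src)]
  names(sel) <- c("epoch", dip_feature_cols(suffix))
  out <- dplyr::left_join(out, sel, by = "epoch")
  out[is.na(out)] <- 0
  out
}

#' Build the per-epoch feature table for one recording
#'
#' Runs the whole per-subject pipeline: band decomposition, per-epoch
#' cardiac and respiratory FSI, the body-movement maximum, dip detection on
#' the accelerometer and gyroscope respiratory scalars, dip-to-epoch
#' assignment with zero-fill, and (when annotations are given) ground-truth
#' labelling. The result has one row per whole 30-s epoch with the fifteen
#' features of [somnimu_features()], no missing values.
#'
#' @param recording An [imu_recording()].
#' @param events Optional annotation tibble; when `NULL` no `label` column
#'   is produced.
#' @param label_rule Passed to [label_epochs()].
#' @return Tibble with `subject_id`, `epoch`, the 15 feature columns and
#'   (if labelled) `label` last.
#' @export
build_feature_table <- function(recording, events = NULL, label_rule = "end") {
  grid <- make_epoch_grid(recording)
  comp <- decompose(recording)
  fs <- attr(comp, "sample_rate")
  tbl <- tibble::tibble(subject_id = attr(recording, "subject_id"),
                        epoch = seq_len(grid$n_epochs)) |>
    dplyr::left_join(epoch_mcg_fsi(comp, grid)[, c("epoch", "mcg_fsi")], by = "epoch") |>
    dplyr::left_join(epoch_rm_fsi(comp, grid)[, c("epoch", "rm_fsi")], by = "epoch") |>
    dplyr::left_join(epoch_bm(comp, grid), by = "epoch") |>
    dplyr::left_join(epoch_dip_block(find_dips(comp$rms_acc, fs), grid, "acc"),
                     by = "epoch") |>
    dplyr::left_join(epoch_dip_block(find_dips(comp$rms_gyr, fs), grid, "gyr"),
                     by = "epoch")
  if (!is.null(events)) {
    tbl <- dplyr::left_join(tbl, label_epochs(events, grid, rule = label_rule),
                            by = "epoch")
  }
  if (anyNA(tbl)) abort("Feature table contains missing values.", class = "somnimu_data_error")
  tbl
}

#' Write / read a feature table as CSV
#'
#' Fixed column order: `subject_id`, `epoch`, the fifteen features of
#' [somnimu_features()], then `label` (when present) last.
#'
#' @param table Feature table from [build_feature_table()].
#' @param path Output path.
#' @return `path` invisibly (writer); the table (reader).
#' @export
write_feature_table <- function(table, path) {
  cols <- intersect(c("subject_id", "epoch", somnimu_features(), "label"),
                    names(table))
  readr::write_csv(table[, cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("label" %in% names(tbl)) {
    tbl$label <- factor(tbl$label, levels = c("RE_negative", "RE_positive"))
  }
  tbl
}
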