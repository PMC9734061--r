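# CSV I/O for hypnograms, event tables and spike trains.

#' Read a hypnogram from CSV
#'
#' Expects columns `epoch_index` (0-based, contiguous) and `label`
#' (Wake / NREM / REM / Artifact).
#'
#' @param path CSV file path.
#' @param epoch_s Epoch length in seconds (default 1).
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_s = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "label") %in% names(df))) {
    stop("hypnogram CSV must have columns epoch_index,label")
  }
  idx <- df$epoch_index
  if (length(idx) == 0) stop("empty hypnogram file")
  if (!identical(as.integer(idx), seq_len(length(idx)) - 1L)) {
    stop("epoch_index must be contiguous 0..n-1; found gaps or reordering")
  }
  hypnogram(df$label, epoch_s = epoch_s) # label validation in constructor
}

#' Write a hypnogram to CSV
#'
#' @param hyp A [hypnogram()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  df <- data.frame(epoch_index = seq_along(hyp$labels) - 1L, label = hyp$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an event table (spindles, bursts or episodes) to CSV
#'
#' One row per event in the schema's stable column order; times are written
#' at full floating precision (well beyond millisecond resolution). The
#' table must be homogeneous: its columns must match exactly one known
#' event schema.
#'
#' @param events Data frame of events of one kind.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  if (!is.data.frame(events)) stop("events must be a data.frame of one event kind")
  kind <- event_kind(events)
  utils::write.csv(events[, EVENT_SCHEMAS[[kind]], drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event table written by [write_events()]
#'
#' @param path CSV file path.
#' @return Data frame of events; kind inferred from the columns.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  kind <- event_kind(df)
  df <- df[, EVENT_SCHEMAS[[kind]], drop = FALSE]
  if (nrow(df) == 0) return(empty_events(kind))
  df
}

#' Read spike times from CSV
#'
#' Expects columns `unit_id`, `region`, `time_s`; returns one
#' [spike_train()] per unit.
#'
#' @param path CSV file path.
#' @return Named list of `spike_train` objects (by unit id).
#' @export
read_spike_trains <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "region", "time_s") %in% names(df))) {
    stop("spike CSV must have columns unit_id,region,time_s")
  }
  out <- lapply(split(df, df$unit_id), function(d) {
    spike_train(sort(d$time_s), unit_id = d$unit_id[1], region = d$region[1])
  })
  out[order(names(out))]
}

#' Write spike trains to CSV
#'
#' @param trains A `spike_train` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  df <- do.call(rbind, lapply(trains, function(tr) {
    if (!length(tr$times_s)) return(NULL)
    data.frame(unit_id = tr$unit_id, region = tr$region, time_s = tr$times_s)
  }))
  if (is.null(df)) df <- data.frame(unit_id = character(0), region = character(0),
                                    time_s = numeric(0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
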