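#' Write simulation outputs to plain-text files
#'
#' `write_event_log()` writes the typed event stream as CSV with columns
#' `time_s`, `event_type`, `compartment_id`, `position`, `detail`.
#' `write_timeseries()` writes the sampled species counts as TSV
#' (`time_s` then one column per species). `write_kymograph()` writes
#' per-entity position samples as CSV.
#'
#' @param sim A `txsim`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(sim, path) {
  ev <- sim$events
  out <- data.frame(time_s = ev$time, event_type = ev$event,
                    compartment_id = ev$comp_id, position = ev$position,
                    detail = ev$value)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
write_timeseries <- function(sim, path) {
  ts <- sim$timeseries
  names(ts)[names(ts) == "time"] <- "time_s"
  utils::write.table(ts, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an interval histogram as CSV
#'
#' Bins the consecutive-event intervals of one event type and writes
#' `bin_left`, `bin_right`, `count` rows.
#'
#' @inheritParams event_intervals
#' @param path Output CSV path.
#' @param breaks Passed to [graphics::hist()] (`plot = FALSE`); default 40.
#' @return `path`, invisibly.
#' @export
write_interval_histogram <- function(events, type, path, breaks = 40) {
  iv <- event_intervals(events, type)
  h <- graphics::hist(iv, breaks = breaks, plot = FALSE)
  out <- data.frame(bin_left = utils::head(h$breaks, -1),
                    bin_right = utils::tail(h$breaks, -1),
                    count = h$counts)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
write_kymograph <- function(sim, path) {
  ky <- sim$kymograph
  names(ky)[names(ky) == "time"] <- "time_s"
  utils::write.csv(ky, path, row.names = FALSE)
  invisible(path)
}
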