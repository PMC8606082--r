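#' Construct a fluorescence trace with injection events
#'
#' A raw assay recording: NBD fluorescence sampled on a regular grid
#' (nominally every 0.5 s) with an ordered list of injection events.
#' Traces are `dequench` when the signal rises on transfer (the PS
#' two-population assay, sensor NBD-C2Lact moving away from the quencher)
#' or `quench` when it falls (PI(4)P assays with NBD-PHFAPP, and the
#' three-population PS routing assay).
#'
#' @param time_s sampling times (s), strictly increasing
#' @param f fluorescence (arbitrary units)
#' @param events data.frame with columns `label`, `time_s`; labels such as
#'   `"liposome_b"`, `"liposome_c"`, `"protein"`
#' @param channel sensor identity
#' @param direction `"dequench"` or `"quench"`
#' @return An object of class `ord_trace`.
#' @export
fluorescence_trace <- function(time_s, f,
                               events = data.frame(label = character(),
                                                   time_s = numeric()),
                               channel = c("NBD-C2Lact", "NBD-PHFAPP",
                                           "NBD-PHPLCd1"),
                               direction = c("dequench", "quench")) {
  channel <- match.arg(channel)
  direction <- match.arg(direction)
  stopifnot(length(time_s) == length(f),
            all(c("label", "time_s") %in% names(events)))
  if (length(time_s) > 1L && is.unsorted(time_s, strictly = TRUE))
    stop("trace times must be strictly increasing", call. = FALSE)
  if (nrow(events) > 0 &&
      (min(events$time_s) < min(time_s) || max(events$time_s) > max(time_s)))
    stop("event times must lie within the trace span", call. = FALSE)
  structure(data.frame(time_s = time_s, f = f),
            class = c("ord_trace", "data.frame"),
            events = events, channel = channel, direction = direction)
}

#' @export
print.ord_trace <- function(x, ...) {
  ev <- attr(x, "events")
  cat("<ord_trace> ", nrow(x), " samples over ",
      round(max(x$time_s) - min(x$time_s), 1), " s; channel ",
      attr(x, "channel"), " (", attr(x, "direction"), ")\n", sep = "")
  if (nrow(ev)) cat("events:", paste0(ev$label, "@", ev$time_s, "s",
                                      collapse = ", "), "\n")
  invisible(x)
}

event_time <- function(trace, label) {
  ev <- attr(trace, "events")
  hit <- ev$time_s[ev$label == label]
  if (length(hit) == 0L)
    stop(structural_error(label))
  hit[1]
}

has_event <- function(trace, label) {
  label %in% attr(trace, "events")$label
}

structural_error <- function(label) {
  structure(
    class = c("ordflux_missing_event", "error", "condition"),
    list(message = paste0("required injection event '", label,
                          "' is missing from the trace"),
         call = NULL, label = label))
}

#' Read a fluorescence trace from CSV files
#'
#' @param path trace CSV with columns `time_s`, `fluorescence`
#' @param events_path sidecar CSV with columns `label`, `time_s`
#' @param channel,direction see [fluorescence_trace()]
#' @return An `ord_trace`.
#' @export
read_trace_csv <- function(path, events_path = NULL,
                           channel = "NBD-C2Lact", direction = "dequench") {
  d <- utils::read.csv(path)
  ev <- if (is.null(events_path)) {
    data.frame(label = character(), time_s = numeric())
  } else {
    utils::read.csv(events_path, colClasses = c(label = "character"))
  }
  fluorescence_trace(d$time_s, d$fluorescence, ev, channel, direction)
}

#' Write a fluorescence trace (and its events) to CSV
#'
#' @param trace an `ord_trace`
#' @param path trace CSV path
#' @param events_path events CSV path (optional)
#' @export
write_trace_csv <- function(trace, path, events_path = NULL) {
  utils::write.csv(data.frame(time_s = trace$time_s, fluorescence = trace$f),
                   path, row.names = FALSE)
  if (!is.null(events_path))
    utils::write.csv(attr(trace, "events"), events_path, row.names = FALSE)
  invisible(path)
}
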