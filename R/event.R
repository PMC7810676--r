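#' Construct an event
#'
#' An event is one contiguous window of a four-channel recording during
#' which a single insect transits the beam.  Sample indices are 0-based
#' and half-open: the event covers samples \code{start} to
#' \code{end - 1} of its source recording, so its length is
#' \code{end - start} samples.
#'
#' @param segment 4 x L numeric matrix (channels x samples, detector
#'   units).
#' @param sample_rate Sampling frequency in Hz.
#' @param start,end 0-based half-open sample interval in the source
#'   recording (both 0 and L for free-standing events).
#' @param label Optional species label.
#' @param peak_snr Optional peak signal-to-noise ratio recorded at
#'   detection time.
#' @return An object of class \code{wb_event} with fields
#'   \code{segment}, \code{sample_rate}, \code{start}, \code{end},
#'   \code{duration} (seconds), \code{label}, \code{peak_snr}.
#' @export
new_event <- function(segment, sample_rate, start = 0L, end = ncol(segment),
                      label = NA_character_, peak_snr = NA_real_) {
  if (!is.matrix(segment) || nrow(segment) != 4L)
    stop("segment must be a 4 x L matrix", call. = FALSE)
  if (ncol(segment) < 1L) stop("empty segment", call. = FALSE)
  start <- as.integer(start); end <- as.integer(end)
  if (start < 0L || end <= start)
    stop("need 0 <= start < end", call. = FALSE)
  if (end - start != ncol(segment))
    stop("segment length must equal end - start", call. = FALSE)
  structure(list(segment = segment,
                 sample_rate = sample_rate,
                 start = start, end = end,
                 duration = ncol(segment) / sample_rate,
                 label = label,
                 peak_snr = peak_snr),
            class = "wb_event")
}

#' @export
print.wb_event <- function(x, ...) {
  cat(sprintf("<wb_event> [%d, %d) %.1f ms, label = %s\n",
              x$start, x$end, 1000 * x$duration,
              ifelse(is.na(x$label), "<none>", x$label)))
  invisible(x)
}

#' Construct a labeled event set
#'
#' @param events List of [new_event()] objects.
#' @param labels Character vector, one species label per event.
#' @param sensor The [sensor_config()] the events were recorded with.
#' @return An object of class \code{wb_event_set}.
#' @export
event_set <- function(events, labels, sensor = sensor_config()) {
  if (length(events) != length(labels))
    stop("one label per event required", call. = FALSE)
  structure(list(events = events,
                 labels = as.character(labels),
                 sensor = sensor),
            class = "wb_event_set")
}

#' @export
length.wb_event_set <- function(x) length(x$events)

#' @export
print.wb_event_set <- function(x, ...) {
  cat("<wb_event_set>", length(x$events), "events,",
      length(unique(x$labels)), "species\n")
  print(table(x$labels))
  invisible(x)
}

#' Per-species event counts
#' @param x A \code{wb_event_set}.
#' @return Named integer vector of event counts per species label.
#' @export
species_counts <- function(x) {
  stopifnot(inherits(x, "wb_event_set"))
  tab <- table(x$labels)
  setNames(as.integer(tab), names(tab))
}
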