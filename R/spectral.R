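# Spectral processing: zero-padded Fourier magnitudes and the
# fixed-length classifier input vector.

utils::globalVariables(c("freq", "q25", "q75"))

PAD_LENGTH <- 20000L   # zero-padded transform length: 1 s at 20 kHz -> 1 Hz bins
BAND_BINS <- 1000L     # bins below 1 kHz used downstream
VECTOR_POINTS <- 512L  # per-channel points in the classifier vector

#' Zero-padded magnitude spectrum of an event
#'
#' Per channel: the channel mean is subtracted (otherwise the DC
#' body/baseline term dominates bin 0 and leaks into neighbours), the
#' segment is zero padded to 20,000 samples (1 s at 20 kHz, so the bin
#' spacing is exactly \code{sample_rate / 20000} = 1 Hz at the default
#' rate) and the magnitude of the discrete Fourier transform is taken.
#' No taper is applied (rectangular window).  Events longer than
#' 20,000 samples are centre-truncated, preserving the transit peak.
#'
#' @param event A \code{wb_event}.
#' @return An object of class \code{wb_spectrum}: list with
#'   \code{magnitudes} (4 x 20000 non-negative matrix),
#'   \code{bin_hz} (bin spacing), \code{sample_rate},
#'   \code{duration} (seconds of real data), \code{channel_names}.
#' @export
power_spectrum <- function(event) {
  stopifnot(inherits(event, "wb_event"))
  seg <- event$segment
  if (ncol(seg) == 0L) stop("empty segment", call. = FALSE)
  L <- ncol(seg)
  if (L > PAD_LENGTH) {
    drop <- L - PAD_LENGTH
    a <- drop %/% 2L + 1L
    seg <- seg[, a:(a + PAD_LENGTH - 1L), drop = FALSE]
    L <- PAD_LENGTH
  }
  x <- seg - rowMeans(seg)
  padded <- matrix(0, PAD_LENGTH, 4L)
  padded[seq_len(L), ] <- t(x)
  mag <- t(Mod(mvfft(padded)))
  rownames(mag) <- rownames(seg)
  structure(list(magnitudes = mag,
                 bin_hz = event$sample_rate / PAD_LENGTH,
                 sample_rate = event$sample_rate,
                 duration = L / event$sample_rate,
                 channel_names = rownames(seg)),
            class = "wb_spectrum")
}

#' @export
print.wb_spectrum <- function(x, ...) {
  cat(sprintf("<wb_spectrum> 4 x %d bins, %.3g Hz spacing\n",
              ncol(x$magnitudes), x$bin_hz))
  invisible(x)
}

# frequencies (Hz) of the first `n` bins of a spectrum
spectrum_freqs <- function(spectrum, n = ncol(spectrum$magnitudes)) {
  (seq_len(n) - 1) * spectrum$bin_hz
}

#' Fixed-length spectral vector for classification
#'
#' Per channel, the 1000 magnitude bins below 1 kHz are downsampled to
#' 512 points, and the four channels are concatenated in fixed order
#' (co_l1, de_l1, co_l2, de_l2) into a length-2048 vector.
#' Downsampling is linear interpolation onto a uniform grid by default
#' (the 1000:512 ratio is non-integer); \code{method = "average"}
#' block-averages instead.  The vector is L2-normalized by default,
#' removing the amplitude confound of insect size and range.
#'
#' @param spectrum A [power_spectrum()] result.
#' @param normalize \code{"l2"} (unit Euclidean norm) or \code{"none"}.
#' @param method \code{"interpolate"} or \code{"average"}.
#' @return Numeric vector of length 2048 with attributes
#'   \code{channel_order} and \code{normalization}.
#' @export
spectral_vector <- function(spectrum,
                            normalize = c("l2", "none"),
                            method = c("interpolate", "average")) {
  stopifnot(inherits(spectrum, "wb_spectrum"))
  normalize <- match.arg(normalize)
  method <- match.arg(method)
  mag <- spectrum$magnitudes[, seq_len(BAND_BINS), drop = FALSE]
  per_channel <- apply(mag, 1, function(m) {
    if (method == "interpolate") {
      approx(x = seq_len(BAND_BINS), y = m,
             xout = seq(1, BAND_BINS, length.out = VECTOR_POINTS))$y
    } else {
      grp <- ceiling(seq_len(BAND_BINS) / (BAND_BINS / VECTOR_POINTS))
      as.vector(tapply(m, grp, mean))
    }
  })  # BAND->512 x 4 matrix, columns in channel order
  v <- as.vector(per_channel)
  if (normalize == "l2") {
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
  }
  structure(v,
            channel_order = spectrum$channel_names,
            normalization = normalize)
}

#' Average spectrum of a set of events with interquartile band
#'
#' For each event the magnitude spectrum is averaged over the four
#' channels; the pointwise mean and 25th/75th percentiles across
#' events are then taken on the sub-kHz grid.  This is the standard
#' per-group spectral summary showing the harmonic structure (1H, 2H,
#' ...) of a species.
#'
#' @param events List of \code{wb_event}, or a \code{wb_event_set}.
#' @return An object of class \code{wb_average_spectrum}: list with
#'   \code{freq} (Hz), \code{mean}, \code{q25}, \code{q75}, \code{n}.
#' @export
average_spectrum <- function(events) {
  if (inherits(events, "wb_event_set")) events <- events$events
  if (length(events) == 0L) stop("no events", call. = FALSE)
  mat <- vapply(events, function(ev) {
    ps <- power_spectrum(ev)
    colMeans(ps$magnitudes[, seq_len(BAND_BINS), drop = FALSE])
  }, numeric(BAND_BINS))   # BAND_BINS x n_events
  bin_hz <- power_spectrum(events[[1]])$bin_hz
  structure(list(freq = (seq_len(BAND_BINS) - 1) * bin_hz,
                 mean = rowMeans(mat),
                 q25 = apply(mat, 1, quantile, probs = 0.25, names = FALSE),
                 q75 = apply(mat, 1, quantile, probs = 0.75, names = FALSE),
                 n = length(events)),
            class = "wb_average_spectrum")
}

#' Plot an average spectrum
#'
#' Mean channel-averaged magnitude with the interquartile range as a
#' shaded band, on a log magnitude axis.
#'
#' @param x A [average_spectrum()] result, or a named list of them
#'   (one facet per name).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_average_spectrum <- function(x, ...) {
  if (inherits(x, "wb_average_spectrum")) x <- list(spectrum = x)
  df <- do.call(rbind, lapply(names(x), function(nm) {
    s <- x[[nm]]
    data.frame(group = nm, freq = s$freq, mean = s$mean,
               q25 = s$q25, q75 = s$q75)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = freq)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = q25, ymax = q75),
                         fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = mean)) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::labs(x = "Frequency (Hz)", y = "Magnitude (a.u.)")
}
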