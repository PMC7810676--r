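# Scalar feature extraction for the WBF and Features classifiers.

#' Canonical feature names
#'
#' The fixed, ordered 12-feature set used by the Features classifier:
#' the dominant (wingbeat) frequency, the harmonic amplitudes at f0,
#' 2 f0 and 3 f0 and their ratios to the fundamental, the spectral
#' centroid, event duration and total energy, the band-integrated
#' de-/co-polarized amplitude ratio at each wavelength, and the
#' wavelength-1 / wavelength-2 band ratio.
#'
#' @return Character vector of length 12.
#' @export
feature_names <- function() {
  c("wbf", "amp_1h", "amp_2h", "amp_3h",
    "ratio_2h_1h", "ratio_3h_1h",
    "spectral_centroid", "duration", "total_energy",
    "depol_ratio_l1", "depol_ratio_l2", "wavelength_ratio")
}

# channel-averaged magnitude over the first BAND_BINS bins
channel_mean_band <- function(spectrum) {
  colMeans(spectrum$magnitudes[, seq_len(BAND_BINS), drop = FALSE])
}

#' Dominant frequency of an event spectrum
#'
#' The argmax of the channel-averaged magnitude inside the search
#' band, taken as the wingbeat frequency.  No harmonic correction is
#' applied: when the second harmonic is stronger than the fundamental
#' the returned value is 2 f0, a documented failure mode that the
#' downstream classifiers learn to accommodate.
#'
#' @param spectrum A [power_spectrum()] result.
#' @param band Numeric length-2 search band in Hz, within (0, 1000].
#' @return Frequency in Hz (a bin centre).
#' @export
dominant_frequency <- function(spectrum, band = c(30, 1000)) {
  stopifnot(inherits(spectrum, "wb_spectrum"))
  freqs <- spectrum_freqs(spectrum, BAND_BINS)
  sel <- which(freqs >= band[1] & freqs <= band[2])
  if (length(sel) == 0L) stop("empty search band", call. = FALSE)
  m <- channel_mean_band(spectrum)
  freqs[sel[which.max(m[sel])]]
}

#' Harmonic amplitudes and ratios
#'
#' Amplitude at the k-th harmonic is the maximum channel-averaged
#' magnitude within one intrinsic resolution width (1/duration) of
#' k f0; harmonics beyond the 1 kHz band are reported as 0.  Ratios
#' are relative to the fundamental amplitude (0 if that is 0).
#'
#' @param spectrum A [power_spectrum()] result.
#' @param f0 Fundamental frequency in Hz.
#' @return Named list: \code{amp_1h}, \code{amp_2h}, \code{amp_3h},
#'   \code{ratio_2h_1h}, \code{ratio_3h_1h}.
#' @export
harmonic_features <- function(spectrum, f0) {
  stopifnot(inherits(spectrum, "wb_spectrum"))
  if (!is.numeric(f0) || f0 <= 0) stop("f0 must be positive", call. = FALSE)
  m <- channel_mean_band(spectrum)
  freqs <- spectrum_freqs(spectrum, BAND_BINS)
  w <- max(1 / spectrum$duration, spectrum$bin_hz)
  amp_at <- function(f) {
    sel <- which(freqs >= f - w & freqs <= f + w)
    if (length(sel) == 0L) 0 else max(m[sel])
  }
  a1 <- amp_at(f0); a2 <- amp_at(2 * f0); a3 <- amp_at(3 * f0)
  list(amp_1h = a1, amp_2h = a2, amp_3h = a3,
       ratio_2h_1h = if (a1 > 0) a2 / a1 else 0,
       ratio_3h_1h = if (a1 > 0) a3 / a1 else 0)
}

# band-integrated magnitude of one channel over [band] Hz
band_integral <- function(spectrum, channel, band) {
  freqs <- spectrum_freqs(spectrum, BAND_BINS)
  sel <- which(freqs >= band[1] & freqs <= band[2])
  sum(spectrum$magnitudes[channel, sel])
}

#' Full scalar feature set of an event
#'
#' Computes the canonical 12 features (see [feature_names()]).
#' Polarization and wavelength ratios are band-integrated over the
#' search band, excluding the DC/body region below 30 Hz.  Feature
#' extraction is total: degenerate cases (zero denominators, silent
#' channels) are encoded as 0 and flagged in the \code{"degenerate"}
#' attribute rather than erroring.
#'
#' @param event A \code{wb_event}.
#' @param spectrum Optional precomputed [power_spectrum()] of the
#'   event (saves the transform when already available).
#' @param band Search band in Hz for the WBF and band integrals.
#' @return Named numeric vector of length 12 in canonical order, with
#'   attribute \code{"degenerate"} (logical).
#' @examples
#' ev <- simulate_event(default_species_library()$sawfly, seed = 1)
#' full_feature_set(ev)
#' @export
full_feature_set <- function(event, spectrum = NULL, band = c(30, 1000)) {
  stopifnot(inherits(event, "wb_event"))
  if (is.null(spectrum)) spectrum <- power_spectrum(event)
  degenerate <- FALSE

  wbf <- dominant_frequency(spectrum, band)
  h <- harmonic_features(spectrum, wbf)

  m <- channel_mean_band(spectrum)
  freqs <- spectrum_freqs(spectrum, BAND_BINS)
  sel <- which(freqs >= band[1] & freqs <= band[2])
  tot <- sum(m[sel])
  centroid <- if (tot > 0) sum(freqs[sel] * m[sel]) / tot else {
    degenerate <- TRUE; 0
  }

  energy <- sum(event$segment^2) / event$sample_rate

  bi <- vapply(1:4, function(ch) band_integral(spectrum, ch, band),
               numeric(1))
  safe_ratio <- function(num, den) {
    if (den > 0) num / den else { degenerate <<- TRUE; 0 }
  }
  depol_l1 <- safe_ratio(bi[2], bi[1])
  depol_l2 <- safe_ratio(bi[4], bi[3])
  wl_ratio <- safe_ratio(bi[1], bi[3])

  out <- c(wbf = wbf,
           amp_1h = h$amp_1h, amp_2h = h$amp_2h, amp_3h = h$amp_3h,
           ratio_2h_1h = h$ratio_2h_1h, ratio_3h_1h = h$ratio_3h_1h,
           spectral_centroid = centroid,
           duration = event$duration,
           total_energy = energy,
           depol_ratio_l1 = depol_l1,
           depol_ratio_l2 = depol_l2,
           wavelength_ratio = wl_ratio)
  attr(out, "degenerate") <- degenerate
  out
}

#' Feature matrix of an event set
#'
#' @param dataset A \code{wb_event_set}.
#' @param band Search band passed to [full_feature_set()].
#' @return Numeric matrix, one row per event, columns in
#'   [feature_names()] order.
#' @export
feature_matrix <- function(dataset, band = c(30, 1000)) {
  stopifnot(inherits(dataset, "wb_event_set"))
  t(vapply(dataset$events,
           function(ev) as.numeric(full_feature_set(ev, band = band)),
           numeric(12L))) |>
    `colnames<-`(feature_names())
}
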