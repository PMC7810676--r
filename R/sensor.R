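#' Sensor configuration
#'
#' Describes the four-channel optical sensor: co- and de-polarized
#' detection at each of two laser wavelengths, uniformly sampled.
#' Defaults match the prototype the pipeline is modelled on: 20 kHz
#' sampling, 5 kHz analogue bandwidth, 808 and 980 nm lasers.
#'
#' The channel order is fixed and used everywhere downstream
#' (recordings, spectral vectors, feature ratios):
#' \code{co_l1, de_l1, co_l2, de_l2}, i.e. co-polarized then
#' de-polarized at wavelength 1, then the same at wavelength 2.
#'
#' @param sample_rate Sampling frequency in Hz.
#' @param bandwidth Analogue detection bandwidth in Hz; must satisfy
#'   \code{sample_rate > 2 * bandwidth}.
#' @param wavelengths Numeric length-2 vector of laser wavelengths (nm).
#' @param channel_names Character length-4 vector of channel labels.
#' @return An object of class \code{wb_sensor}.
#' @examples
#' sensor_config()
#' @export
sensor_config <- function(sample_rate = 20000,
                          bandwidth = 5000,
                          wavelengths = c(808, 980),
                          channel_names = c("co_l1", "de_l1", "co_l2", "de_l2")) {
  stop_if_not_scalar_pos(sample_rate, "sample_rate")
  stop_if_not_scalar_pos(bandwidth, "bandwidth")
  if (sample_rate <= 2 * bandwidth)
    stop("sample_rate must exceed twice the bandwidth", call. = FALSE)
  if (length(wavelengths) != 2L)
    stop("exactly two wavelengths required", call. = FALSE)
  if (length(channel_names) != 4L || anyDuplicated(channel_names))
    stop("exactly 4 distinct channel names required", call. = FALSE)
  structure(list(sample_rate = sample_rate,
                 bandwidth = bandwidth,
                 wavelengths = wavelengths,
                 channel_names = channel_names),
            class = "wb_sensor")
}

#' @export
print.wb_sensor <- function(x, ...) {
  cat("<wb_sensor> fs =", x$sample_rate, "Hz, bandwidth =", x$bandwidth,
      "Hz\n  wavelengths:", paste(x$wavelengths, collapse = ", "), "nm\n",
      " channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}
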