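#' Species signal profile
#'
#' Parameters of the generative wingbeat-signal model for one insect
#' group.  A \emph{flyer} produces a periodic signal: a fundamental
#' wingbeat frequency (WBF) drawn per individual from
#' \code{N(f0_mean, f0_sd)} plus a geometrically decaying harmonic
#' series.  A \emph{jumper} (e.g. a flea beetle caught mid-leap)
#' produces an aperiodic envelope-shaped transient with no WBF peak.
#' Both ride on a low-frequency body-reflection component and are
#' split across the four sensor channels by fixed amplitude ratios.
#'
#' @param name Species/group label.
#' @param f0_mean,f0_sd Mean and between-individual standard deviation
#'   of the fundamental WBF (Hz).  Ignored for jumpers.
#' @param n_harmonics Number of harmonics in the series (fundamental
#'   included).
#' @param harmonic_decay Amplitude ratio between successive harmonics
#'   (amplitude at (k+1) f0 divided by amplitude at k f0).
#' @param body_fraction Fraction of signal energy in the low-frequency
#'   body-reflection component, in [0, 1].
#' @param depol_ratio Length-2 vector: de-/co-polarized amplitude ratio
#'   at wavelength 1 and wavelength 2.
#' @param wavelength_ratio Amplitude ratio wavelength-1 / wavelength-2
#'   (co-polarized channels).
#' @param duration_mean,duration_sd Mean and sd of event (beam transit)
#'   duration in milliseconds.
#' @param behaviour \code{"flyer"} or \code{"jumper"}.
#' @return An object of class \code{wb_species}.
#' @seealso [default_species_library()]
#' @export
species_profile <- function(name,
                            f0_mean = NA_real_, f0_sd = 0,
                            n_harmonics = 4L,
                            harmonic_decay = 0.5,
                            body_fraction = 0.2,
                            depol_ratio = c(0.4, 0.4),
                            wavelength_ratio = 1,
                            duration_mean = 85, duration_sd = 20,
                            behaviour = c("flyer", "jumper")) {
  behaviour <- match.arg(behaviour)
  if (behaviour == "flyer") {
    stop_if_not_scalar_pos(f0_mean, "f0_mean")
    if (f0_sd < 0) stop("f0_sd must be >= 0", call. = FALSE)
  }
  if (body_fraction < 0 || body_fraction > 1)
    stop("body_fraction must lie in [0, 1]", call. = FALSE)
  if (length(depol_ratio) != 2L || any(depol_ratio < 0))
    stop("depol_ratio must be two non-negative values", call. = FALSE)
  stop_if_not_scalar_pos(wavelength_ratio, "wavelength_ratio")
  stop_if_not_scalar_pos(duration_mean, "duration_mean")
  structure(list(name = name,
                 f0_mean = f0_mean, f0_sd = f0_sd,
                 n_harmonics = as.integer(n_harmonics),
                 harmonic_decay = harmonic_decay,
                 body_fraction = body_fraction,
                 depol_ratio = depol_ratio,
                 wavelength_ratio = wavelength_ratio,
                 duration_mean = duration_mean,
                 duration_sd = duration_sd,
                 behaviour = behaviour),
            class = "wb_species")
}

#' Default nine-group synthetic species library
#'
#' A fixed library of nine insect groups typical of the oilseed rape
#' agro-ecosystem: four coleopteran pests, a pod midge, two sciarid
#' midge genera, a sawfly and a parasitoid wasp group.  Two groups
#' (the flea beetles) are \emph{jumpers} with no wingbeat periodicity;
#' the two sciarid midges form a deliberately \emph{overlapping} WBF
#' pair (their fundamental-frequency distributions overlap strongly),
#' so that WBF alone cannot separate them and harmonic/polarization
#' structure must be used.
#'
#' All numeric parameter values are \strong{synthetic defaults} chosen
#' to be biologically plausible (larger, heavier taxa beat slower;
#' small midges faster) and to reproduce the qualitative difficulty
#' structure of a field-realistic mix.  They are not measurements of
#' the named taxa.
#'
#' @return A named list of nine [species_profile()] objects.  The
#'   function is pure: repeated calls return identical values.
#' @examples
#' lib <- default_species_library()
#' names(lib)
#' sum(vapply(lib, function(p) p$behaviour == "jumper", logical(1)))
#' @export
default_species_library <- function() {
  profiles <- list(
    species_profile("pollen_beetle",
                    f0_mean = 120, f0_sd = 14, harmonic_decay = 0.65,
                    body_fraction = 0.30, depol_ratio = c(0.55, 0.40),
                    wavelength_ratio = 1.25, duration_mean = 95,
                    duration_sd = 22),
    species_profile("seed_weevil",
                    f0_mean = 88, f0_sd = 11, harmonic_decay = 0.75,
                    body_fraction = 0.35, depol_ratio = c(0.70, 0.55),
                    wavelength_ratio = 0.85, duration_mean = 100,
                    duration_sd = 24),
    species_profile("pod_midge",
                    f0_mean = 480, f0_sd = 45, harmonic_decay = 0.35,
                    body_fraction = 0.10, depol_ratio = c(0.25, 0.20),
                    wavelength_ratio = 1.05, duration_mean = 65,
                    duration_sd = 15),
    species_profile("midge_corynoptera",
                    f0_mean = 340, f0_sd = 38, harmonic_decay = 0.45,
                    body_fraction = 0.12, depol_ratio = c(0.30, 0.35),
                    wavelength_ratio = 0.95, duration_mean = 70,
                    duration_sd = 16),
    species_profile("midge_zygoneura",
                    f0_mean = 355, f0_sd = 40, harmonic_decay = 0.60,
                    body_fraction = 0.15, depol_ratio = c(0.45, 0.25),
                    wavelength_ratio = 1.15, duration_mean = 72,
                    duration_sd = 16),
    species_profile("sawfly",
                    f0_mean = 165, f0_sd = 16, harmonic_decay = 0.50,
                    body_fraction = 0.25, depol_ratio = c(0.35, 0.60),
                    wavelength_ratio = 1.40, duration_mean = 110,
                    duration_sd = 25),
    species_profile("parasitoid_wasp",
                    f0_mean = 255, f0_sd = 26, harmonic_decay = 0.40,
                    body_fraction = 0.18, depol_ratio = c(0.20, 0.30),
                    wavelength_ratio = 0.75, duration_mean = 80,
                    duration_sd = 18),
    species_profile("flea_beetle_phyllotreta",
                    behaviour = "jumper",
                    body_fraction = 0.60, depol_ratio = c(0.65, 0.50),
                    wavelength_ratio = 1.10, duration_mean = 70,
                    duration_sd = 20),
    species_profile("flea_beetle_psylliodes",
                    behaviour = "jumper",
                    body_fraction = 0.45, depol_ratio = c(0.40, 0.70),
                    wavelength_ratio = 0.80, duration_mean = 90,
                    duration_sd = 22)
  )
  names(profiles) <- vapply(profiles, `[[`, character(1), "name")
  profiles
}
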