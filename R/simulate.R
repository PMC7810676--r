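# Synthetic-data module: generative model of wingbeat events.
#
# A flyer event is
#   x(t) = env(t) * [ sqrt(1-b) * wing(t) + sqrt(b) ]        (per channel gain)
# with env a Gaussian taper (sigma = T/6; smooth transit through a
# collimated beam), wing a harmonic series at the individual's f0 with
# geometric amplitude decay and random phases, and b the body-energy
# fraction (the envelope itself is the low-frequency body reflection:
# its spectrum sits below ~30 Hz for transit-scale durations).
# A jumper event replaces wing() with smoothed aperiodic noise, giving
# a transient with no spectral peak in the wingbeat band.
# Channel gains are (1, d1, 1/w, d2/w) for (co_l1, de_l1, co_l2, de_l2)
# with d = depol_ratio and w = wavelength_ratio.

channel_gains <- function(profile) {
  c(1,
    profile$depol_ratio[1],
    1 / profile$wavelength_ratio,
    profile$depol_ratio[2] / profile$wavelength_ratio)
}

# Zero-mean white Gaussian noise low-passed to the sensor bandwidth,
# rescaled so each channel's sample sd equals `sd` exactly.
band_limited_noise <- function(n_channels, n, sd, sensor) {
  if (sd <= 0 || n < 2L)
    return(matrix(0, n_channels, n))
  x <- matrix(rnorm(n_channels * n), n_channels, n)
  wc <- sensor$bandwidth / (sensor$sample_rate / 2)
  if (wc < 1 && n > 30L) {
    bf <- signal::butter(4, wc, type = "low")
    for (ch in seq_len(n_channels))
      x[ch, ] <- signal::filtfilt(bf, x[ch, ])
  }
  for (ch in seq_len(n_channels)) {
    s <- stats::sd(x[ch, ])
    if (s > 0) x[ch, ] <- x[ch, ] * (sd / s)
  }
  x
}

# Draw a transit duration (seconds) from the profile, truncated below.
draw_duration <- function(profile) {
  d <- rnorm(1, profile$duration_mean, profile$duration_sd)
  max(d, profile$duration_mean / 4, 25) / 1000
}

#' Simulate a single noiseless insect event
#'
#' Generates the four-channel signal of one beam transit for a species
#' profile: a Gaussian amplitude envelope (sigma = duration/6)
#' modulating, for flyers, a harmonic wingbeat series (fundamental
#' drawn from the profile's f0 distribution, geometric amplitude decay,
#' random phases) plus a low-frequency body-reflection term, and for
#' jumpers an aperiodic smoothed transient with no periodic component.
#' The four channels are exact scalar multiples of one waveform, with
#' gains set by the profile's depolarization and wavelength ratios.
#' The output is peak-normalized to unit maximum absolute amplitude
#' across channels.
#'
#' @param profile A [species_profile()].
#' @param sensor A [sensor_config()].
#' @param duration Event duration in seconds; if \code{NULL}, drawn
#'   from the profile's duration distribution.
#' @param seed Integer seed; the function is a pure function of
#'   \code{(profile, sensor, duration, seed)}.
#' @return A [new_event()] with the drawn fundamental stored in
#'   attribute \code{"f0"} (NA for jumpers) and the profile name as
#'   label.
#' @examples
#' ev <- simulate_event(default_species_library()$sawfly, seed = 1)
#' dim(ev$segment)
#' @export
simulate_event <- function(profile, sensor = sensor_config(),
                           duration = NULL, seed = 1L) {
  stopifnot(inherits(profile, "wb_species"))
  fs <- sensor$sample_rate
  withr::with_seed(seed, {
    if (is.null(duration)) duration <- draw_duration(profile)
    if (!is.numeric(duration) || duration <= 0)
      stop("duration must be positive", call. = FALSE)
    n <- max(8L, as.integer(round(duration * fs)))
    tt <- (seq_len(n) - 1) / fs
    env <- exp(-0.5 * ((tt - duration / 2) / (duration / 6))^2)

    f0 <- NA_real_
    if (profile$behaviour == "flyer") {
      f0 <- rnorm(1, profile$f0_mean, profile$f0_sd)
      f0 <- max(f0, profile$f0_mean / 4, 10)
      k <- seq_len(profile$n_harmonics)
      amps <- profile$harmonic_decay^(k - 1)
      phases <- runif(profile$n_harmonics, 0, 2 * pi)
      wing <- as.vector(sin(outer(2 * pi * f0 * tt, k) +
                              rep(phases, each = n)) %*% amps)
    } else {
      # aperiodic transient: gently smoothed broadband noise, so the
      # wingbeat band (30-1000 Hz) shows no discrete peak
      kw <- max(3L, as.integer(round(0.0002 * fs)))
      ker <- dnorm(seq(-2, 2, length.out = 2L * kw + 1L))
      ker <- ker / sum(ker)
      raw <- rnorm(n + 2L * kw)
      wing <- as.vector(stats::filter(raw, ker, sides = 2))[(kw + 1L):(kw + n)]
    }
    wing <- env * wing
    if (rms(wing) > 0) wing <- wing / rms(wing)
    body <- env / rms(env)
    b <- profile$body_fraction
    mono <- sqrt(1 - b) * wing + sqrt(b) * body
    mono <- mono / max(abs(mono))

    seg <- outer(channel_gains(profile), mono)
    rownames(seg) <- sensor$channel_names
    ev <- new_event(seg, fs, label = profile$name)
    attr(ev, "f0") <- f0
    ev
  })
}

#' Simulate a continuous multi-event recording
#'
#' Builds a four-channel recording of stated length: band-limited white
#' Gaussian background noise on every channel, with insect events
#' inserted at Poisson-distributed times (overlapping placements are
#' rejected and redrawn, so each truth interval holds a single insect).
#' Event amplitudes are scaled so the peak absolute amplitude over
#' channels equals \code{peak_snr * noise_sd}, making detectability
#' directly controllable.
#'
#' @param profiles List of [species_profile()]; the species of each
#'   event is drawn uniformly from this list.
#' @param event_rate Expected number of events per second.
#' @param total_duration Recording length in seconds.
#' @param noise_sd Background noise standard deviation (detector
#'   units); 0 gives a noiseless recording with unit-peak events.
#' @param seed Integer seed (full determinism).
#' @param sensor A [sensor_config()].
#' @param peak_snr Peak amplitude of each inserted event in units of
#'   \code{noise_sd}.
#' @return An object of class \code{wb_recording}: list with
#'   \code{samples} (4 x N matrix), \code{sensor}, and \code{truth}
#'   (data.frame \code{start}, \code{end} -- 0-based half-open sample
#'   indices -- and \code{species}), sorted by start.
#' @export
simulate_recording <- function(profiles, event_rate, total_duration,
                               noise_sd = 1, seed = 1L,
                               sensor = sensor_config(), peak_snr = 50) {
  stop_if_not_scalar_pos(total_duration, "total_duration")
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (inherits(profiles, "wb_species")) profiles <- list(profiles)
  fs <- sensor$sample_rate
  n_total <- as.integer(round(total_duration * fs))
  withr::with_seed(seed, {
    samples <- band_limited_noise(4L, n_total, noise_sd, sensor)
    rownames(samples) <- sensor$channel_names
    n_events <- rpois(1, event_rate * total_duration)
    truth <- data.frame(start = integer(0), end = integer(0),
                        species = character(0))
    margin <- as.integer(round(0.08 * fs))   # keep events clear of edges
    amp <- if (noise_sd > 0) peak_snr * noise_sd else 1
    placed <- 0L
    attempts <- 0L
    while (placed < n_events && attempts < n_events * 60L) {
      attempts <- attempts + 1L
      i_prof <- sample.int(length(profiles), 1L)
      prof <- profiles[[i_prof]]
      dur <- draw_duration(prof)
      len <- as.integer(round(dur * fs))
      if (len + 2L * margin >= n_total) next
      start0 <- sample.int(n_total - len - 2L * margin, 1L) + margin  # 0-based
      end0 <- start0 + len
      clash <- any(start0 < truth$end + margin & end0 > truth$start - margin)
      if (clash) next
      ev <- simulate_event(prof, sensor, dur,
                           seed = derive_seed(seed, "event", attempts))
      seg <- ev$segment * (amp / max(abs(ev$segment)))
      idx <- (start0 + 1L):end0
      samples[, idx] <- samples[, idx] + seg
      truth <- rbind(truth, data.frame(start = start0, end = end0,
                                       species = prof$name))
      placed <- placed + 1L
    }
    truth <- truth[order(truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    structure(list(samples = samples, sensor = sensor, truth = truth),
              class = "wb_recording")
  })
}

#' @export
print.wb_recording <- function(x, ...) {
  cat(sprintf("<wb_recording> 4 x %d samples (%.2f s at %g Hz), %d truth events\n",
              ncol(x$samples), ncol(x$samples) / x$sensor$sample_rate,
              x$sensor$sample_rate, nrow(x$truth)))
  invisible(x)
}

#' Simulate a labeled event dataset
#'
#' Generates \code{n_per_species} events for every profile, each a
#' simulated transit with additive band-limited sensor noise, peak
#' amplitude \code{peak_snr * noise_sd}.  By default each event is
#' windowed directly (the generated segment plus noise); with
#' \code{embed = TRUE} each event is instead inserted into a short
#' noise recording and re-extracted with [detect_events()], exercising
#' the full detection path at generation cost.
#'
#' @param profiles List of [species_profile()].
#' @param n_per_species Events to generate per profile.
#' @param sensor A [sensor_config()].
#' @param noise_sd Additive noise sd (detector units).
#' @param seed Integer seed (full determinism).
#' @param peak_snr Event peak amplitude in units of \code{noise_sd}.
#' @param embed If \code{TRUE}, re-extract each event through the
#'   detector instead of windowing it directly.
#' @return A [event_set()] with labels correct by construction.
#' @examples
#' lib <- default_species_library()
#' ds <- simulate_labeled_dataset(lib[1:2], n_per_species = 3, seed = 1)
#' species_counts(ds)
#' @export
simulate_labeled_dataset <- function(profiles, n_per_species,
                                     sensor = sensor_config(),
                                     noise_sd = 1, seed = 1L,
                                     peak_snr = 50, embed = FALSE) {
  if (n_per_species < 1L) stop("n_per_species must be >= 1", call. = FALSE)
  if (inherits(profiles, "wb_species")) profiles <- list(profiles)
  amp <- if (noise_sd > 0) peak_snr * noise_sd else 1
  events <- vector("list", length(profiles) * n_per_species)
  labels <- character(length(events))
  i <- 0L
  for (prof in profiles) {
    for (j in seq_len(n_per_species)) {
      i <- i + 1L
      ev_seed <- derive_seed(seed, prof$name, j)
      if (embed) {
        ev <- embed_and_extract(prof, sensor, noise_sd, amp, ev_seed)
      } else {
        ev <- simulate_event(prof, sensor, seed = ev_seed)
        seg <- ev$segment * (amp / max(abs(ev$segment)))
        if (noise_sd > 0) {
          seg <- seg + withr::with_seed(
            derive_seed(ev_seed, "noise"),
            band_limited_noise(4L, ncol(seg), noise_sd, sensor))
        }
        rownames(seg) <- sensor$channel_names
        ev <- new_event(seg, sensor$sample_rate, label = prof$name)
      }
      events[[i]] <- ev
      labels[i] <- prof$name
    }
  }
  event_set(events, labels, sensor)
}

# Insert one event into a short noise recording and recover it with the
# detector; falls back to direct windowing if detection fails (possible
# at low peak_snr).
embed_and_extract <- function(prof, sensor, noise_sd, amp, ev_seed) {
  fs <- sensor$sample_rate
  ev <- simulate_event(prof, sensor, seed = ev_seed)
  seg <- ev$segment * (amp / max(abs(ev$segment)))
  len <- ncol(seg)
  pad <- as.integer(round(0.15 * fs))
  n <- len + 2L * pad
  samples <- withr::with_seed(derive_seed(ev_seed, "noise"),
                              band_limited_noise(4L, n, noise_sd, sensor))
  samples[, (pad + 1L):(pad + len)] <- samples[, (pad + 1L):(pad + len)] + seg
  rownames(samples) <- sensor$channel_names
  rec <- structure(list(samples = samples, sensor = sensor,
                        truth = data.frame(start = pad, end = pad + len,
                                           species = prof$name)),
                   class = "wb_recording")
  det <- tryCatch(detect_events(rec), error = function(e) list())
  if (length(det) == 0L)
    return(new_event(seg, fs, label = prof$name))
  best <- det[[which.max(vapply(det, function(d) d$end - d$start, numeric(1)))]]
  best$label <- prof$name
  best
}
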