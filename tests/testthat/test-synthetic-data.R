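test_that("default species library has the documented structure", {
  lib <- default_species_library()
  expect_length(lib, 9L)
  behaviours <- vapply(lib, `[[`, character(1), "behaviour")
  expect_identical(sum(behaviours == "jumper"), 2L)
  # at least one flyer pair with overlapping f0 distributions
  flyers <- lib[behaviours == "flyer"]
  f0 <- vapply(flyers, `[[`, numeric(1), "f0_mean")
  sds <- vapply(flyers, `[[`, numeric(1), "f0_sd")
  overlapping <- FALSE
  for (i in seq_along(flyers)) for (j in seq_along(flyers)) {
    if (i < j && abs(f0[i] - f0[j]) < sds[i] + sds[j]) overlapping <- TRUE
  }
  expect_true(overlapping)
  # pure function: repeated calls identical
  expect_identical(lib, default_species_library())
})

test_that("flyer events put the spectral peak at the drawn fundamental", {
  prof <- species_profile("probe", f0_mean = 200, f0_sd = 0,
                          body_fraction = 0.1)
  ev <- simulate_event(prof, duration = 0.1, seed = 42)
  ps <- power_spectrum(ev)
  expect_equal(dominant_frequency(ps), 200, tolerance = 10 / 200)
  # spectral peak within 1/duration of the recorded fundamental
  expect_lt(abs(dominant_frequency(ps) - attr(ev, "f0")),
            frequency_resolution(ev))
})

test_that("jumper events have no peak in the wingbeat band", {
  lib <- default_species_library()
  for (seed in 1:5) {
    ev <- simulate_event(lib$flea_beetle_phyllotreta, duration = 0.08,
                         seed = seed)
    m <- colMeans(power_spectrum(ev)$magnitudes[, 31:1000])
    expect_lt(max(m) / median(m), 5)
  }
})

test_that("event generation is a pure function of its seed", {
  prof <- default_species_library()$sawfly
  e1 <- simulate_event(prof, duration = 0.09, seed = 7)
  e2 <- simulate_event(prof, duration = 0.09, seed = 7)
  expect_identical(e1$segment, e2$segment)
  e3 <- simulate_event(prof, duration = 0.09, seed = 8)
  expect_false(identical(e1$segment, e3$segment))
})

test_that("harmonic decay is encoded in the spectrum", {
  # ratio of magnitude at 2 f0 to magnitude at f0 ~ harmonic_decay
  for (decay in c(0.35, 0.5, 0.7)) {
    prof <- species_profile("probe", f0_mean = 180, f0_sd = 0,
                            harmonic_decay = decay, body_fraction = 0.1)
    ev <- simulate_event(prof, duration = 0.1, seed = 11)
    f0 <- attr(ev, "f0")
    mag <- colMeans(power_spectrum(ev)$magnitudes[, 1:1000])
    amp_at <- function(f) max(mag[seq(f - 10, f + 10) + 1L])
    expect_equal(amp_at(2 * f0) / amp_at(f0), decay, tolerance = 0.1)
  }
})

test_that("channel amplitude ratios recover the profile's parameters", {
  prof <- species_profile("probe", f0_mean = 220, f0_sd = 0,
                          depol_ratio = c(0.55, 0.3),
                          wavelength_ratio = 1.3)
  ev <- simulate_event(prof, duration = 0.1, seed = 5)
  mag <- power_spectrum(ev)$magnitudes[, 31:1000]
  band <- unname(rowSums(mag))
  expect_equal(band[2] / band[1], 0.55, tolerance = 0.1)
  expect_equal(band[4] / band[3], 0.3, tolerance = 0.1)
  expect_equal(band[1] / band[3], 1.3, tolerance = 0.1)
})

test_that("recordings honour the event rate and are reproducible", {
  rec0 <- simulate_recording(default_species_library(), event_rate = 0,
                             total_duration = 2, seed = 1)
  expect_identical(nrow(rec0$truth), 0L)
  expect_equal(ncol(rec0$samples), 40000L)

  rec1 <- simulate_recording(default_species_library(), event_rate = 0.6,
                             total_duration = 6, seed = 9)
  rec2 <- simulate_recording(default_species_library(), event_rate = 0.6,
                             total_duration = 6, seed = 9)
  expect_identical(rec1$samples, rec2$samples)
  expect_identical(rec1$truth, rec2$truth)
  # truth intervals within range, sorted, non-overlapping
  if (nrow(rec1$truth) > 1L) {
    expect_true(all(diff(rec1$truth$start) > 0))
    expect_true(all(rec1$truth$start[-1] >= head(rec1$truth$end, -1)))
  }
  expect_true(all(rec1$truth$start >= 0L &
                    rec1$truth$end <= ncol(rec1$samples)))
})

test_that("background noise has the stated sd", {
  rec <- noise_recording(5, noise_sd = 2.5, seed = 3)
  expect_equal(apply(rec$samples, 1, sd), rep(2.5, 4),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("inserted events are recovered by the detector", {
  lib <- default_species_library()
  rec <- simulate_recording(lib, event_rate = 0.5, total_duration = 10,
                            noise_sd = 1, seed = 21, peak_snr = 50)
  expect_gt(nrow(rec$truth), 0L)
  det <- detect_events(rec)
  expect_length(det, nrow(rec$truth))
  # one-to-one interval overlap with the truth
  for (i in seq_along(det)) {
    overlaps <- which(rec$truth$start < det[[i]]$end &
                        rec$truth$end > det[[i]]$start)
    expect_length(overlaps, 1L)
    expect_equal(overlaps, i, ignore_attr = TRUE)
  }
})

test_that("labeled datasets have exact per-species counts and durations", {
  lib <- default_species_library()
  ds <- fixture("small_dataset",
                simulate_labeled_dataset(lib, n_per_species = 40L,
                                         seed = 5L))
  expect_length(ds, 9L * 40L)
  expect_true(all(species_counts(ds) == 40L))
  # mean duration per species within 20% of the configured mean
  durations <- vapply(ds$events, `[[`, numeric(1), "duration")
  for (prof in lib) {
    mean_d <- mean(durations[ds$labels == prof$name]) * 1000
    expect_equal(mean_d, prof$duration_mean, tolerance = 0.2)
  }
  # determinism
  ds2 <- simulate_labeled_dataset(lib, n_per_species = 2L, seed = 5L)
  expect_identical(ds2$events[[1]]$segment, ds$events[[1]]$segment)
})

test_that("embedded re-extraction yields events consistent with windowing", {
  lib <- default_species_library()
  ds <- simulate_labeled_dataset(lib[c(1, 6)], n_per_species = 3L,
                                 seed = 12L, embed = TRUE)
  expect_length(ds, 6L)
  durations <- vapply(ds$events, `[[`, numeric(1), "duration")
  expect_true(all(durations > 0.02))
  expect_identical(ds$labels, rep(c("pollen_beetle", "sawfly"), each = 3L))
})

test_that("wider WBF separation improves WBF-method accuracy", {
  # separability dial at three settings, averaged over folds
  acc_at <- function(delta) {
    ds <- flyer_pair(200, 200 + delta, sd = 25, n = 60L, seed = 31L)
    dm <- design_matrices(ds)
    ev <- run_experiment(design = dm, methods = "wbf", n_folds = 20L,
                         seed = 17L,
                         split = split_spec("x", 30L, 30L, 15L))
    mean(ev$folds$accuracy)
  }
  accs <- c(acc_at(5), acc_at(40), acc_at(150))
  expect_true(accs[1] <= accs[2] + 0.05 && accs[2] <= accs[3] + 0.05)
  expect_gt(accs[3], accs[1])
})
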