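test_that("noise estimation recovers baseline and spread", {
  rec <- noise_recording(10, noise_sd = 1, seed = 2)   # 200,000 samples
  noise <- estimate_noise(rec)
  expect_equal(noise$sigma, rep(1, 4), tolerance = 0.05,
               ignore_attr = TRUE)
  expect_equal(noise$baseline, rep(0, 4), tolerance = 0.05,
               ignore_attr = TRUE)

  # constant channel has zero spread
  rec$samples[2, ] <- 3.5
  noise <- estimate_noise(rec)
  expect_identical(noise$sigma[2], 0)
  expect_identical(noise$baseline[2], 3.5)

  # equivariance under scaling
  rec2 <- noise_recording(2, noise_sd = 1, seed = 4)
  n1 <- estimate_noise(rec2)
  rec2$samples <- rec2$samples * 7
  n2 <- estimate_noise(rec2)
  expect_equal(n2$baseline, 7 * n1$baseline)
  expect_equal(n2$sigma, 7 * n1$sigma)

  # too-short recordings are rejected
  short <- noise_recording(2, seed = 1)
  short$samples <- short$samples[, 1:500]
  expect_error(estimate_noise(short), "too short")
})

test_that("the SNR trace is max-over-channels in sigma units", {
  rec <- noise_recording(2, noise_sd = 1, seed = 6)
  noise <- estimate_noise(rec)
  # plant a spike of exactly baseline + 20 sigma on one channel
  rec$samples[3, 10000] <- noise$baseline[3] + 20 * noise$sigma[3]
  snr <- snr_trace(rec, noise)
  expect_equal(snr[10000], 20)
  expect_true(all(snr >= 0))

  # offset invariance: shifting a channel shifts its baseline only
  rec2 <- noise_recording(2, noise_sd = 1, seed = 6)
  s1 <- snr_trace(rec2)
  rec2$samples[1, ] <- rec2$samples[1, ] + 100
  expect_equal(snr_trace(rec2), s1, tolerance = 1e-9)

  # pure noise essentially never crosses the detection threshold
  rec3 <- noise_recording(10, noise_sd = 1, seed = 8)
  expect_identical(sum(snr_trace(rec3) >= 10), 0L)

  # all-constant recording has undefined SNR
  rec3$samples[] <- 1
  expect_error(snr_trace(rec3), "zero noise sigma")
})

test_that("erosion and dilation match a brute-force oracle", {
  withr::with_seed(33, {
    for (case in 1:20) {
      mask <- runif(300) < 0.3
      w <- sample(c(3L, 5L, 9L), 1L)
      s <- sample(c(2L, 10L, 25L), 1L)
      expect_identical(wingbeatr:::binary_erode(mask, w),
                       brute_erode(mask, w))
      expect_identical(wingbeatr:::binary_dilate(mask, s),
                       brute_dilate(mask, s))
    }
  })
})

test_that("detection applies the documented morphology", {
  base <- noise_recording(1, noise_sd = 1, seed = 10)   # 20,000 samples

  # a 0.2 ms (4-sample) supra-threshold run is eroded away
  rec <- base
  rec$samples[1, 5000:5003] <- 50
  expect_length(detect_events(rec), 0L)

  # a 1 ms (20-sample) run -> 16 surviving + 2 x 400 dilation = 816
  rec <- base
  rec$samples[1, 5000:5019] <- 50
  det <- detect_events(rec)
  expect_length(det, 1L)
  expect_identical(det[[1]]$end - det[[1]]$start, 816L)
  expect_equal(1000 * det[[1]]$duration, 40.8)

  # two 1 ms runs separated by 30 ms (< 2 x 20 ms dilation) merge
  rec <- base
  rec$samples[1, 5000:5019] <- 50
  rec$samples[1, 5620:5639] <- 50
  det <- detect_events(rec)
  expect_length(det, 1L)

  # 40 ms-per-side reading doubles the widening
  rec <- base
  rec$samples[1, 10000:10019] <- 50
  det <- detect_events(rec, detection_params(dilate_per_side = TRUE))
  expect_identical(det[[1]]$end - det[[1]]$start, 16L + 1600L)

  # events touching an edge are discarded
  rec <- base
  rec$samples[1, 1:300] <- 50
  expect_length(detect_events(rec), 0L)
})

test_that("every event core stays above threshold for >= 0.25 ms", {
  rec <- simulate_recording(default_species_library(), event_rate = 0.5,
                            total_duration = 8, seed = 14, peak_snr = 50)
  params <- detection_params()
  noise <- estimate_noise(rec)
  snr <- snr_trace(rec, noise)
  side <- as.integer(round(params$dilation_width *
                             rec$sensor$sample_rate / 2))
  for (ev in detect_events(rec, params, noise)) {
    core <- snr[(ev$start + 1 + side):(ev$end - side)]
    runs <- rle(core >= params$snr_threshold)
    expect_gte(max(runs$lengths[runs$values]), 5L)
  }
})

test_that("masked duration grows monotonically as the threshold drops", {
  rec <- simulate_recording(default_species_library(), event_rate = 0.5,
                            total_duration = 6, seed = 15, peak_snr = 30)
  snr <- snr_trace(rec)
  masked <- vapply(c(20, 10, 5), function(thr) {
    m <- wingbeatr:::binary_erode(snr >= thr, 5L)
    sum(wingbeatr:::binary_dilate(m, 400L))
  }, numeric(1))
  expect_true(all(diff(masked) >= 0))
})

test_that("detection is idempotent on an unchanged recording", {
  rec <- simulate_recording(default_species_library(), event_rate = 0.4,
                            total_duration = 6, seed = 16, peak_snr = 50)
  expect_identical(detect_events(rec), detect_events(rec))
})

test_that("frequency resolution is the reciprocal duration", {
  expect_equal(round(frequency_resolution(0.0856), 1), 11.7)
  expect_equal(frequency_resolution(1), 1)
  expect_equal(frequency_resolution(0.040), 25)
  ev <- sine_event(duration = 0.1)
  expect_equal(frequency_resolution(ev), 10)
  expect_error(frequency_resolution(0), "positive")
})
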