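# Shared fixtures.  Expensive synthetic datasets and fold grids are
# built once per test run and memoized, so several test files (and the
# acceptance checks) can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# reduced-size network used for fold grids (the full 2000/1500/1000
# architecture is exercised separately in unit tests)
nn_small <- function() {
  nn_config(c(128L, 64L, 32L), learning_rate = 2e-3, epochs = 15L,
            batch_size = 64L)
}

nn_tiny <- function() {
  nn_config(c(48L, 24L, 12L), learning_rate = 2e-3, epochs = 10L,
            batch_size = 64L)
}

# default 9-species library at 500 events/species (strict splits need
# 383 target + 92 other pool sizes)
default_dataset <- function() {
  fixture("default_dataset",
          simulate_labeled_dataset(default_species_library(),
                                   n_per_species = 500L, seed = 101L))
}

default_design <- function() {
  fixture("default_design", design_matrices(default_dataset()))
}

# folds = 2 grid over all 9 targets and all 3 methods
grid_folds2 <- function() {
  fixture("grid_folds2",
          run_experiment(design = default_design(),
                         methods = c("wbf", "features", "nn"),
                         n_folds = 2L, seed = 202L, nn = nn_small()))
}

# a quick two-species flyer pair with controllable separation
flyer_pair <- function(f0_a, f0_b, sd = 5, n = 80L, seed = 1L) {
  profiles <- list(
    species_profile("species_a", f0_mean = f0_a, f0_sd = sd,
                    duration_mean = 80, duration_sd = 10),
    species_profile("species_b", f0_mean = f0_b, f0_sd = sd,
                    duration_mean = 80, duration_sd = 10))
  simulate_labeled_dataset(profiles, n_per_species = n, seed = seed)
}

# brute-force 1-D binary morphology oracles (independent of the
# cumulative-sum implementation under test)
brute_erode <- function(mask, width) {
  h <- (width - 1L) %/% 2L
  n <- length(mask)
  vapply(seq_len(n), function(i) {
    if (i - h < 1L || i + h > n) return(FALSE)
    all(mask[(i - h):(i + h)])
  }, logical(1))
}

brute_dilate <- function(mask, side) {
  n <- length(mask)
  vapply(seq_len(n), function(i) {
    any(mask[max(1L, i - side):min(n, i + side)])
  }, logical(1))
}

# noise-only recording of n samples (no events)
noise_recording <- function(n_seconds, noise_sd = 1, seed = 1L) {
  simulate_recording(default_species_library(), event_rate = 0,
                     total_duration = n_seconds, noise_sd = noise_sd,
                     seed = seed)
}

# a pure sinusoid event on all four channels
sine_event <- function(f0 = 200, duration = 0.1, fs = 20000,
                       amplitude = 1) {
  tt <- (seq_len(round(duration * fs)) - 1) / fs
  seg <- matrix(rep(amplitude * sin(2 * pi * f0 * tt), each = 4), nrow = 4)
  rownames(seg) <- c("co_l1", "de_l1", "co_l2", "de_l2")
  new_event(seg, fs)
}
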