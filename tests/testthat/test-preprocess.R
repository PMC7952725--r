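test_that("high-pass filter removes DC and passes/stops the right bands", {
  # constant input: DC fully removed away from edges
  y <- highpass_filter(rep(100, 5000), fs = 500)
  mid <- 1000:4000
  expect_lt(max(abs(y[mid])), 1e-6)

  # 100 Hz unit sinusoid at 1000 Hz: in the passband, amplitude within 5%
  t <- seq_len(10000) / 1000
  y <- highpass_filter(sin(2 * pi * 100 * t), fs = 1000)
  fitamp <- function(y, f, fs, idx) {
    tt <- idx / fs
    cf <- coef(lm(y[idx] ~ sin(2 * pi * f * tt) + cos(2 * pi * f * tt) - 1))
    sqrt(sum(cf^2))
  }
  expect_lt(abs(fitamp(y, 100, 1000, 2000:8000) - 1), 0.05)

  # 5 Hz at 500 Hz: in the stopband, attenuated by at least 20 dB
  t <- seq_len(10000) / 500
  y <- highpass_filter(sin(2 * pi * 5 * t), fs = 500)
  expect_lt(fitamp(y, 5, 500, 2000:8000), 10^(-20 / 20))

  expect_error(highpass_filter(rnorm(100), fs = 30, cutoff = 20), "Nyquist")
})

test_that("51-point moving-average subtraction annihilates constants and ramps", {
  expect_equal(subtract_moving_average(rep(3.7, 200)), rep(0, 200))

  ramp <- seq(0, 10, length.out = 200)
  out <- subtract_moving_average(ramp)
  interior <- 26:175   # >= 25 samples from each edge: full centered windows
  expect_equal(out[interior], rep(0, length(interior)), tolerance = 1e-12)

  expect_error(subtract_moving_average(rnorm(100), window = 50), "odd")
})

test_that("moving-average subtraction matches a per-sample brute-force loop", {
  set.seed(42)
  x <- rnorm(200)
  for (w in c(5, 51)) {
    h <- (w - 1) / 2
    brute <- vapply(seq_along(x), function(i) {
      x[i] - mean(x[max(1, i - h):min(length(x), i + h)])
    }, numeric(1))
    expect_equal(subtract_moving_average(x, w), brute, tolerance = 1e-12)
  }
})

test_that("rectification is the elementwise absolute value", {
  expect_equal(rectify(c(-1, 2, -3)), c(1, 2, 3))
  x <- rnorm(50)
  expect_equal(rectify(x), rectify(-x))
  expect_equal(rectify(numeric(10)), numeric(10))
})

test_that("epoching bins whole seconds and drops trailing partial bins", {
  ev <- tibble::tibble(trial_id = 1, condition = "a",
                       baseline_start_s = NA_real_,
                       stim_start_s = 0, stim_end_s = 1)
  out <- epoch_and_bin(rep(2, 1000), fs = 1000, events = ev)
  expect_equal(out$bins$value, 2.0)

  # 2.5 s at 500 Hz: two complete bins, the trailing 0.5 s is dropped
  ev$stim_end_s <- 2.5
  out <- epoch_and_bin(rep(2, 1250), fs = 500, events = ev)
  expect_equal(nrow(out$bins), 2L)

  ev$stim_end_s <- 10
  expect_error(epoch_and_bin(rep(2, 1250), fs = 500, events = ev), "trial 1")
})

test_that("artifact samples are excluded and mostly-excluded bins are missing", {
  fs <- 500
  set.seed(7)
  x <- abs(rnorm(3 * fs))
  ev <- tibble::tibble(trial_id = 1, condition = "a",
                       baseline_start_s = NA_real_,
                       stim_start_s = 0, stim_end_s = 3)
  # 0.4 s artifact inside bin 2 (40% excluded: bin kept, averaged over rest)
  art <- tibble::tibble(trial_id = 1, artifact_start_s = 1.2,
                        artifact_end_s = 1.6)
  out <- epoch_and_bin(x, fs, ev, artifacts = art)
  keep <- rep(TRUE, 3 * fs); keep[601:800] <- FALSE
  bin2 <- x[501:1000]; keep2 <- keep[501:1000]
  expect_equal(out$bins$value[2], mean(bin2[keep2]))
  expect_false(out$bins$missing[2])
  expect_equal(out$bins$value[c(1, 3)],
               c(mean(x[1:500]), mean(x[1001:1500])))

  # 0.6 s artifact: > 50% of bin 2 excluded, so it is marked missing
  art2 <- tibble::tibble(trial_id = 1, artifact_start_s = 1.2,
                         artifact_end_s = 1.8)
  out2 <- epoch_and_bin(x, fs, ev, artifacts = art2)
  expect_true(out2$bins$missing[2])
  expect_true(is.na(out2$bins$value[2]))
})

test_that("baseline correction subtracts the pre-stimulus mean (and can bypass)", {
  bins <- tibble::tibble(trial_id = c(1, 1), condition = "a",
                         t_bin_s = 0:1, value = c(5, 7), missing = FALSE)
  bl <- tibble::tibble(trial_id = 1, baseline_mean = 4)
  expect_equal(baseline_correct(bins, bl)$value, c(1, 3))
  expect_equal(baseline_correct(bins, bl, mode = "none")$value, c(5, 7))
  blna <- tibble::tibble(trial_id = 1, baseline_mean = NA_real_)
  expect_error(baseline_correct(bins, blna), "no baseline")

  # bins equal to the baseline mean become zero
  bins$value <- c(4, 4)
  expect_equal(baseline_correct(bins, bl)$value, c(0, 0))

  # the pre-stimulus mean is taken over the full annotated 10-s window
  fs <- 100
  x <- c(rep(3, 10 * fs), rep(8, 2 * fs))
  ev <- tibble::tibble(trial_id = 1, condition = "a", baseline_start_s = 0,
                       stim_start_s = 10, stim_end_s = 12)
  out <- epoch_and_bin(x, fs, ev)
  expect_equal(out$baselines$baseline_mean, 3)
})

test_that("within-individual standardization gives z-scores over the concatenation", {
  tr <- list(c(1, 2), c(3, 4))
  z <- standardize_within_individual(tr)
  # frozen hand-computed values (sample-SD convention)
  expect_equal(unlist(z), c(-1.161895, -0.387298, 0.387298, 1.161895),
               tolerance = 1e-6)
  allz <- unlist(z)
  expect_lt(abs(mean(allz)), 1e-9)
  expect_lt(abs(sd(allz) - 1), 1e-9)

  # scale invariance
  z2 <- standardize_within_individual(lapply(tr, function(v) v * 137.5))
  expect_equal(unlist(z2), unlist(z), tolerance = 1e-12)

  # missing bins excluded from the moments and left missing
  z3 <- standardize_within_individual(list(c(1, NA, 2), c(3, 4)))
  expect_true(is.na(z3[[1]][2]))
  expect_equal(unlist(z3)[!is.na(unlist(z3))], unlist(z), tolerance = 1e-12)

  expect_error(standardize_within_individual(list(c(2, 2, 2))), "variance")
  expect_error(standardize_within_individual(list(c(1, NA))), "2 non-missing")
})

test_that("the full pipeline is invariant to positive rescaling of the raw EMG", {
  sim <- simulate_experiment(tiny_exp1_cfg(seed = 3, n = 4))
  scaled <- sim
  for (nm in names(scaled$recordings)) {
    scaled$recordings[[nm]]$samples <- lapply(
      scaled$recordings[[nm]]$samples, function(v) v * 137.5)
  }
  a <- preprocess_dataset(sim)
  b <- preprocess_dataset(scaled)
  expect_equal(a$value_z, b$value_z, tolerance = 1e-9)
})

test_that("binned rectified envelope tracks the true amplitude envelope", {
  cfg <- sim_config(n_participants = 1, trials = tiny_trials(1, 120),
                    coupling = c(cs = -0.5, zm = 0.5), noise_sd = 0,
                    drift_amplitude_uv = 0, seed = 1)
  v <- simulate_valence_trace(120, 15, seed = 21, sd = 2)
  ch <- simulate_emg(v, "zm", cfg,
                     participant_effects = c(intercept = 0, slope = 0.5),
                     seed = 22, device = "wired")
  bins <- colMeans(matrix(rectify(ch$samples_uv), nrow = ch$fs))
  true_env <- cfg$amp_scale_uv * emgvalence:::softplus(0.5 * (v - 5) + 3)
  expect_gt(cor(bins, true_env), 0.98)
})

test_that("trial processing order does not leak across trials", {
  sim <- simulate_experiment(tiny_exp1_cfg(seed = 8, n = 4))
  rec <- sim$recordings[[1]]
  ev <- sim$events[sim$events$participant == rec$participant, ]
  a <- preprocess_recording(rec, ev)
  b <- preprocess_recording(rec, ev[rev(seq_len(nrow(ev))), ])
  key <- c("muscle", "trial_id", "t_bin_s")
  a <- a[do.call(order, a[key]), ]
  b <- b[do.call(order, b[key]), ]
  expect_equal(a$value, b$value, tolerance = 1e-12)
})
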