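test_that("an injected burst is detected with accurate onset/offset", {
  cfg <- sim_config(duration_s = 60, n_channels = 1, noise_slope = 1, seed = 41)
  bg <- gen_background(cfg)
  rms <- sd(bg$data[1, ])
  t <- seq(0, 1, by = 1 / 250)
  burst <- 10 * rms * sleeptmr:::hann_env(length(t)) * sin(2 * pi * 13 * t)
  x <- bg$data[1, ]
  x[7501:(7501 + length(burst) - 1)] <- x[7501:(7501 + length(burst) - 1)] + burst
  sp <- detect_spindles(x, 250, 13)
  expect_gte(nrow(sp), 1)
  hit <- which.min(abs(sp$onset_s - 30))
  expect_lt(abs(sp$onset_s[hit] - 30), 0.1 + 0.25)
  expect_lt(abs(sp$offset_s[hit] - 31), 0.1 + 0.25)
  expect_true(all(sp$duration_s >= 0.4))
})

test_that("supra-threshold runs shorter than 400 ms are rejected", {
  cfg <- sim_config(duration_s = 60, n_channels = 1, noise_slope = 1, seed = 42)
  bg <- gen_background(cfg)
  rms <- sd(bg$data[1, ])
  # weak short burst: its supra-threshold run (after wavelet smoothing)
  # stays under 400 ms
  t <- seq(0, 0.2, by = 1 / 250)
  burst <- 5 * rms * sleeptmr:::hann_env(length(t)) * sin(2 * pi * 13 * t)
  x <- bg$data[1, ]
  x[5001:(5000 + length(burst))] <- x[5001:(5000 + length(burst))] + burst
  sp <- detect_spindles(x, 250, 13)
  expect_false(any(abs(sp$onset_s - 20) < 0.5))

  # the duration rule itself: a 1 s burst passes at 0.4 s, fails at 2 s
  t1 <- seq(0, 1, by = 1 / 250)
  b1 <- 10 * rms * sleeptmr:::hann_env(length(t1)) * sin(2 * pi * 13 * t1)
  x2 <- bg$data[1, ]
  x2[2501:(2500 + length(b1))] <- x2[2501:(2500 + length(b1))] + b1
  expect_gte(nrow(detect_spindles(x2, 250, 13, min_dur_s = 0.4)), 1)
  expect_equal(nrow(detect_spindles(x2, 250, 13, min_dur_s = 2)), 0)

  expect_warning(out <- detect_spindles(rep(0, 5000), 250, 13), "degenerate")
  expect_equal(nrow(out), 0)
})

test_that("raising the detection threshold never increases event count", {
  cfg <- sim_config(duration_s = 300, n_channels = 1, seed = 43)
  inj <- inject_oscillatory_events(gen_background(cfg), "spindle",
                                   cfg$spindle, seed = 44)
  x <- get_channel(inj$recording, "Cz")
  counts <- vapply(c(3, 6, 9, 12, 15),
                   function(th) nrow(detect_spindles(x, 250, 14, threshold_factor = th)),
                   0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("slow-oscillation candidates follow the zero-crossing arithmetic", {
  fs <- 250
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- 80 * sin(2 * pi * 0.75 * t)
  so <- detect_slow_oscillations(x, fs)
  expect_true(all(abs(so$duration_s - 4 / 3) < 0.05))
  # 44 full cycles fit in 60 s; top quartile = ceiling(n/4)
  n_cand <- length(which(diff(sign(
    filter_signal(x, fs, "bandpass", c(0.5, 4)))) < 0))
  expect_equal(nrow(so), ceiling((n_cand - 1) / 4), tolerance = 1)

  # 0.4 Hz: spans of 2.5 s violate the 0.8-2 s rule; nothing except
  # possible filter edge transients can be marked
  x2 <- 80 * sin(2 * pi * 0.4 * t)
  so2 <- tryCatch(detect_slow_oscillations(x2, fs), error = function(e) NULL)
  if (!is.null(so2)) {
    expect_true(all(so2$start_s < 2 | so2$end_s > 58))
  } else {
    succeed()
  }
})

test_that("top-quartile retention keeps the largest candidate amplitudes", {
  cfg <- sim_config(duration_s = 600, n_channels = 1, seed = 45)
  inj <- inject_oscillatory_events(gen_background(cfg), "so", cfg$so, seed = 46)
  x <- get_channel(inj$recording, "Cz")
  so <- detect_slow_oscillations(x, 250)
  # injected high-gain SOs occupy the retained top quartile
  rec_rate <- event_recall(so$start_s, inj$truth$onset_s, tol = 0.25)
  expect_gte(rec_rate, 0.9)
})

test_that("coupling phase convention puts the trough at 180 degrees", {
  fs <- 250
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- 60 * cos(2 * pi * t)  # 1 Hz "SO train"
  so <- detect_slow_oscillations(x, fs)
  trough <- so$trough_time_s[1]
  spindles <- tibble::tibble(channel = "sig", onset_s = trough - 0.25,
                             offset_s = trough + 0.25, duration_s = 0.5,
                             peak_amplitude = 10, peak_time_s = trough,
                             center_frequency = 13)
  cp <- couple_events(spindles, so, x, fs)
  expect_equal(nrow(cp), 1)
  expect_lt(abs(abs(cp$coupling_phase_deg) - 180), 5)
})

test_that("coupling summary reports density, mean phase and vector length", {
  cp <- tibble::tibble(coupling_phase_deg = rep(45, 10))
  cs <- coupling_summary(cp, n_spindles = 20, nrem_minutes = 20)
  expect_equal(cs$coupled_density, 0.5)
  expect_equal(cs$mean_phase_deg, 45)
  expect_equal(cs$vector_length, 1)
  expect_error(coupling_summary(cp, 20, 0), "positive")
})

test_that("phase injection round-trips at high concentration", {
  for (mu in c(0, -90, 90, 180)) {
    cfg <- sim_config(duration_s = 600, n_channels = 1,
                      so = list(rate_per_min = 5),
                      coupling = list(fraction = 1, mu_deg = mu, kappa = 1e6),
                      seed = 47)
    cj <- inject_coupled_events(gen_background(cfg), cfg$so, cfg$spindle,
                                cfg$coupling, seed = 48)
    sig <- get_channel(cj$recording, "Cz")
    pk <- find_spectral_peak(welch_psd(sig, 250, derivative = TRUE), c(12.5, 16))
    sp <- detect_spindles(sig, 250, pk$peak_freq)
    so <- detect_slow_oscillations(sig, 250)
    cp <- couple_events(sp, so, sig, 250)
    expect_gt(nrow(cp), 20)
    truth_mean <- circ_mean_deg(cj$coupled_truth$phase_deg)
    err <- abs(sleeptmr:::wrap_deg(
      coupling_summary(cp, nrow(sp), 10)$mean_phase_deg - truth_mean))
    expect_lt(err, 10)
  }
})

test_that("every coupled event's spindle peak lies inside its SO span", {
  cfg <- sim_config(duration_s = 900, n_channels = 1, seed = 49)
  ses <- gen_tmr_session(cfg)
  sig <- get_channel(ses$recording, "Cz")
  pk <- find_spectral_peak(welch_psd(sig, 250, derivative = TRUE), c(12.5, 16))
  sp <- detect_spindles(sig, 250, pk$peak_freq)
  so <- detect_slow_oscillations(sig, 250)
  cp <- couple_events(sp, so, sig, 250)
  if (nrow(cp)) {
    expect_true(all(cp$peak_time_s >= cp$so_start_s & cp$peak_time_s < cp$so_end_s))
    expect_true(all(cp$coupling_phase_deg > -180 & cp$coupling_phase_deg <= 180))
  }
})

test_that("event density is count over minutes", {
  expect_equal(event_density(30, 60), 0.5)
  expect_equal(event_density(0, 60), 0)
  expect_equal(event_density(tibble::tibble(x = 1:30), 60), 0.5)
  expect_error(event_density(5, 0), "positive")
})
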