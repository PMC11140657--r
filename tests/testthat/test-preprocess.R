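test_that("resampling preserves in-band amplitude and rescales onsets", {
  rec <- sine_recording(10, fs = 500, dur_s = 20, amp = 40)
  out <- resample_recording(rec, 250)
  expect_equal(out$fs, 250)
  mid <- out$data[1, 1000:4000]  # avoid filter edges
  expect_lt(abs(sqrt(2) * sd(mid) - 40) / 40, 0.01)
  expect_identical(resample_recording(rec, 500), rec)
  expect_error(resample_recording(rec, 1000), "upsampling")
  expect_equal(rescale_onsets(1000L, 500, 250), 500L)
})

test_that("filters attenuate and pass as designed", {
  fs <- 250
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  x60 <- sin(2 * pi * 60 * t)
  y <- filter_signal(x60, fs, "notch", 60)
  expect_lt(sd(y[1000:4000]) / sd(x60), 0.05)

  drift <- sin(2 * pi * 0.1 * t)
  yd <- filter_signal(drift, fs, "highpass", 0.3)
  expect_lt(max(abs(yd[2000:3000])), 0.5)  # >50% amplitude reduction

  x1 <- sin(2 * pi * 1 * t)
  yb <- filter_signal(x1, fs, "bandpass", c(0.5, 4))
  expect_lt(abs(max(yb[2000:3000]) - 1), 0.05)

  expect_error(filter_signal(x1, fs, "highpass", 200), "Nyquist")
})

test_that("zero-phase filtering commutes with time reversal", {
  withr::with_seed(4, x <- rnorm(50000))
  fs <- 250
  y <- filter_signal(x, fs, "bandpass", c(0.5, 4))
  yr <- rev(filter_signal(rev(x), fs, "bandpass", c(0.5, 4)))
  expect_lt(max(abs(y[20000:30000] - yr[20000:30000])) / sd(y), 2e-3)
})

test_that("mastoid rereferencing is linear and idempotent", {
  rec <- fix_recording(n_ch = 4, n_samp = 200)
  rec$channels <- c("Cz", "Fz", "M1", "M2")
  rownames(rec$data) <- rec$channels
  rec$data[c("M1", "M2"), ] <- 0
  expect_equal(rereference(rec)$data, rec$data)

  rec2 <- fix_recording(n_ch = 4, n_samp = 200)
  rec2$channels <- c("Cz", "Fz", "M1", "M2")
  rownames(rec2$data) <- rec2$channels
  rec2$data["M1", ] <- 7; rec2$data["M2", ] <- 7
  out <- rereference(rec2)
  expect_equal(out$data["Cz", ], rec2$data["Cz", ] - 7)
  expect_equal(rereference(out)$data, out$data)  # second pass is a no-op
  expect_error(rereference(fix_recording(2, 100)), "mastoid")
})

test_that("epoching cuts the documented window and flags edge trials", {
  fs <- 250
  rec <- fix_recording(n_ch = 1, n_samp = 20 * fs)
  ev <- cue_events(c(125L, 2500L), c("negative", "control"), "N2")
  ep <- epoch_recording(rec, ev, window = c(-1, 3), baseline = FALSE)
  expect_equal(dim(ep$data), c(2, 1, 1000))
  expect_false(ep$metadata$kept[1])      # 0.5 s from start, -1 s impossible
  expect_equal(ep$metadata$reason[1], "edge")
  # trial 2: event at 10 s -> samples 2250..3249 (0-based)
  expect_equal(ep$data[2, 1, ], unname(rec$data[1, 2251:3250]))
  expect_equal(ep$times[1], -1)
  expect_equal(ep$times[251], 0)
})

test_that("baseline adjustment zeroes a constant trial", {
  fs <- 250
  rec <- eeg_recording(matrix(5, 1, 10 * fs), fs, "Cz")
  ev <- cue_events(5L * fs, "neutral", "N2")
  ep <- epoch_recording(rec, ev, baseline = TRUE)
  expect_true(all(abs(ep$data[1, 1, ]) < 1e-12))
})

test_that("amplitude and joint-probability rejection flag the right trials", {
  fs <- 100
  withr::with_seed(11, {
    rec <- eeg_recording(matrix(rnorm(2 * 300 * fs, sd = 20), 2, 300 * fs),
                         fs, c("Cz", "Fz"))
  })
  onsets <- seq(5, 295, by = 5.5) * fs
  ev <- cue_events(as.integer(onsets), "neutral", "N2")
  ep <- epoch_recording(rec, ev, baseline = FALSE)
  # spike one trial over 500 uV
  ep$data[10, 1, 50] <- 600
  out <- reject_epochs(ep)
  expect_true(10 %in% out$report$trial)
  expect_equal(out$report$reason[out$report$trial == 10], "amplitude")
  expect_false(out$epochs$metadata$kept[10])
  # homogeneous Gaussian trials: at most a few joint-probability rejections
  expect_lte(sum(out$report$reason != "amplitude"), 3)
  # sample values never modified
  expect_identical(out$epochs$data, ep$data)
})

test_that("a high-variance trial is caught by joint probability", {
  fs <- 100
  withr::with_seed(12, {
    rec <- eeg_recording(matrix(rnorm(1 * 300 * fs, sd = 10), 1, 300 * fs),
                         fs, "Cz")
  })
  onsets <- seq(5, 295, by = 5.5) * fs
  ev <- cue_events(as.integer(onsets), "neutral", "N2")
  ep <- epoch_recording(rec, ev, baseline = FALSE)
  withr::with_seed(13, ep$data[25, 1, ] <- rnorm(dim(ep$data)[3], sd = 100))
  out <- reject_epochs(ep)
  expect_true(25 %in% out$report$trial)
  expect_match(out$report$reason[out$report$trial == 25], "jointprob")
})

test_that("Hjorth parameters match the sinusoid closed form", {
  fs <- 250
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  h <- hjorth_params(sin(2 * pi * 10 * t), fs)
  expect_equal(unname(h["mobility"]), 2 * pi * 10, tolerance = 0.01)
  expect_equal(unname(h["complexity"]), 1, tolerance = 0.01)
})

test_that("Hjorth pass leaves homogeneous data untouched and repairs a bad channel", {
  fs <- 100
  n_ep <- 24
  hyp <- hypnogram(rep("N2", n_ep))
  withr::with_seed(21, {
    rec <- eeg_recording(matrix(rnorm(6 * n_ep * 30 * fs, sd = 15), 6),
                         fs, c("Cz", "Fz", "Pz", "C3", "C4", "F3"))
  })
  out <- hjorth_artifact_pass(rec, hyp)
  expect_true(all(out$epoch_mask))
  expect_equal(nrow(out$report[out$report$action == "interpolate_global", ]), 0)

  # one channel carrying mixed artifact types (high-amplitude bursts, slow
  # rail drift, pure-tone buzz) in 25% of epochs: each type deviates in a
  # different Hjorth parameter, so the channel crosses the 25%-of-epochs rule
  # and is interpolated globally
  rec2 <- rec
  spe <- 30 * fs
  tt <- seq_len(spe) / fs
  withr::with_seed(22, {
    put <- function(e, x) rec2$data[2, ((e - 1) * spe + 1):(e * spe)] <<- x
    put(2, rnorm(spe, sd = 15 * 20))            # activity outliers
    put(9, rnorm(spe, sd = 15 * 20))
    # two-tone mixtures chosen so each perturbs exactly one parameter
    put(5, 15 * sin(2 * pi * 2 * tt) + 15 * sin(2 * pi * 4.83 * tt))  # mobility
    put(13, 15 * sin(2 * pi * 2 * tt) + 15 * sin(2 * pi * 4.83 * tt))
    put(7, 15 * sin(2 * pi * 1 * tt) + 15 * sin(2 * pi * 49 * tt))    # complexity
    put(17, 15 * sin(2 * pi * 1 * tt) + 15 * sin(2 * pi * 49 * tt))
  })
  out2 <- hjorth_artifact_pass(rec2, hyp)
  expect_true("Fz" %in% out2$report$channel[out2$report$action == "interpolate_global"])
  # interpolation actually replaced the contaminated data
  expect_lt(sd(out2$recording$data[2, ]), sd(rec2$data[2, ]))
})

test_that("spherical splines reconstruct constant and smooth fields", {
  mon <- default_montage()
  labs <- mon$label[1:13]
  # constant field: reconstruction is exact up to solver tolerance
  rec <- eeg_recording(matrix(3.3, 13, 50), 100, labs)
  out <- interpolate_channels(rec, "Cz")
  expect_lt(max(abs(out$data["Cz", ] - 3.3)) / 3.3, 1e-6)

  # smooth dipolar field sampled on the montage, center channel removed
  pos <- as.matrix(mon[1:13, c("x", "y", "z")])
  dip <- c(0.2, 0.1, 0.9); dip <- dip / sqrt(sum(dip^2))
  field <- as.numeric(pos %*% dip)
  rec2 <- eeg_recording(outer(field, rep(1, 50)), 100, labs)
  out2 <- interpolate_channels(rec2, "Cz")
  expect_equal(unname(out2$data["Cz", 1]), field[1], tolerance = 0.12)

  rec3 <- eeg_recording(matrix(1, 5, 10), 100,
                        c("Cz", "Fz", "Pz", "C3", "Nowhere"))
  expect_error(interpolate_channels(rec3, "Nowhere"), "position")
})
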