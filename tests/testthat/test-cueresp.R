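make_epochs <- function(trials, gen, fs = 250, window = c(-1, 3),
                        category = "neutral") {
  n_t <- (window[2] - window[1]) * fs
  times <- window[1] + (seq_len(n_t) - 1) / fs
  data <- array(0, c(trials, 1, n_t))
  for (tr in seq_len(trials)) data[tr, 1, ] <- gen(times, tr)
  structure(list(data = data, times = times, fs = fs, channels = "Cz",
                 metadata = tibble::tibble(trial = seq_len(trials),
                                           category = rep(category, trials),
                                           kept = TRUE, reason = NA_character_)),
            class = "epoch_set")
}

test_that("Morlet TFR localizes frequency and scales quadratically", {
  ep <- make_epochs(2, function(t, tr) tr * 30 * sin(2 * pi * 10 * t))
  tfr <- tfr_morlet(ep)
  avg1 <- apply(tfr$power[1, , ], 1, mean)
  expect_lt(abs(tfr$freqs[which.max(avg1)] - 10) / 10, 0.12)
  mid <- tfr$times > 0 & tfr$times < 2
  ratio <- mean(tfr$power[2, which.max(avg1), mid]) /
    mean(tfr$power[1, which.max(avg1), mid])
  expect_equal(ratio, 4, tolerance = 0.01)
})

test_that("a transient burst is localized in time", {
  ep <- make_epochs(1, function(t, tr) {
    env <- exp(-(t - 1)^2 / (2 * 0.1^2))
    20 * env * sin(2 * pi * 13 * t) + rnorm(length(t), sd = 0.5)
  })
  tfr <- tfr_morlet(ep)
  fbin <- which.min(abs(tfr$freqs - 13))
  expect_lt(abs(tfr$times[which.max(tfr$power[1, fbin, ])] - 1), 0.15)
})

test_that("dB normalization satisfies its closed-form identities", {
  # stationary signal: every frequency keeps constant power over the epoch,
  # so the baseline window must average to 0 dB
  ep <- make_epochs(3, function(t, tr) 20 * sin(2 * pi * 10 * t))
  tfr <- tfr_morlet(ep)
  db <- db_normalize(tfr)
  bl <- db$times >= -0.5 & db$times <= -0.2
  # 0 dB in the baseline for bins carrying real signal power (bins with
  # ~zero power hold only wavelet edge leakage, meaningless on a log scale)
  avg <- apply(tfr$power, c(2, 3), mean)
  carrying <- rowMeans(avg) > 0.01 * max(avg)
  expect_lt(max(abs(rowMeans(db$power[carrying, bl]))), 0.01)
  # exact identity at every bin: mean power ratio over the baseline is 1
  expect_equal(rowMeans(10^(db$power[, bl] / 10)), rep(1, 30), tolerance = 1e-6)

  # direct ratio identities on a hand-built tfr
  tfr2 <- tfr
  tfr2$power <- array(1, c(1, 2, length(tfr$times)))
  tfr2$power[1, 1, tfr$times > 0] <- 10
  tfr2$power[1, 2, tfr$times > 0] <- 0.5
  db2 <- db_normalize(tfr2)
  post <- db2$times > 0.5
  expect_equal(mean(db2$power[1, post]), 10, tolerance = 1e-9)
  expect_equal(mean(db2$power[2, post]), 10 * log10(0.5), tolerance = 1e-9)

  # multiplicative gain invariance
  tfr3 <- tfr
  tfr3$power <- tfr$power * 7.3
  expect_equal(db_normalize(tfr3)$power, db$power, tolerance = 1e-9)

  expect_error(db_normalize(tfr, baseline = c(0.1, 0.5)), "before cue onset")
})

test_that("spindle probability is the trial-mean indicator", {
  times <- seq(-1, 3, by = 1 / 250)
  sp_all <- tidyr::expand_grid(trial = 1:10) |>
    dplyr::mutate(onset_s = 0.9, offset_s = 1.2)
  pr <- spindle_probability(sp_all, times, 1:10)
  expect_true(all(pr$probability[pr$time >= 0.9 & pr$time < 1.2] == 1))
  expect_true(all(pr$probability[pr$time < 0.9] == 0))

  sp_half <- sp_all[1:5, ]
  pr2 <- spindle_probability(sp_half, times, 1:10)
  expect_true(all(pr2$probability[pr2$time >= 0.9 & pr2$time < 1.2] == 0.5))

  pr3 <- spindle_probability(sp_all[0, ], times, 1:10)
  expect_true(all(pr3$probability == 0))
  expect_error(spindle_probability(sp_all, times, integer(0)), "zero trials")

  # invariant to trial order
  pr4 <- spindle_probability(sp_half[sample(5), ], times, 10:1)
  expect_equal(pr4$probability, pr2$probability)
})

test_that("trial matching subsamples the larger condition deterministically", {
  m <- match_trials(1:100, 201:260, seed = 5)
  expect_equal(length(m$selected_a), 60)
  expect_identical(m$selected_b, 201:260)
  expect_true(all(m$selected_a %in% 1:100))
  m2 <- match_trials(1:100, 201:260, seed = 5)
  expect_identical(m$selected_a, m2$selected_a)
  m3 <- match_trials(1:50, 51:100, seed = 5)
  expect_identical(m3$selected_a, 1:50)
})

test_that("identical condition maps produce no clusters", {
  withr::with_seed(51, A <- array(rnorm(10 * 5 * 20), c(10, 5, 20)))
  ct <- cluster_permutation(A, A, n_perm = 100, seed = 1)
  expect_equal(nrow(ct$clusters), 0)
})

test_that("cluster labelling matches a hand-checked map", {
  # deterministic t map via a crafted difference matrix: participants agree
  # strongly on points 1:4 of a 2x4 grid, disagree elsewhere
  n <- 12
  D <- matrix(0, n, 8)
  withr::with_seed(52, {
    D[, 1:4] <- 2 + rnorm(n * 4, sd = 0.5)
    D[, 5:8] <- rnorm(n * 4, sd = 3)
  })
  ct <- cluster_permutation(array(D, c(n, 2, 4)), array(0, c(n, 2, 4)),
                            n_perm = 500, seed = 2)
  expect_gte(nrow(ct$clusters), 1)
  big <- which.max(abs(ct$clusters$t_sum))
  mem <- cluster_members(ct, big)
  expect_true(all(which(mem) %in% 1:4))
  expect_equal(ct$clusters$sign[big], "positive")
  expect_lt(ct$clusters$p_value[big], 0.05)
  # members are contiguous under 4-connectivity by construction of labels
  expect_equal(ct$clusters$n_points[big], sum(mem))
})

test_that("permutation p-values are reproducible under a fixed seed", {
  withr::with_seed(53, {
    A <- array(rnorm(8 * 3 * 10), c(8, 3, 10))
    B <- array(rnorm(8 * 3 * 10), c(8, 3, 10))
  })
  ct1 <- cluster_permutation(A, B, n_perm = 300, seed = 9)
  ct2 <- cluster_permutation(A, B, n_perm = 300, seed = 9)
  expect_identical(tidy(ct1), tidy(ct2))
  expect_identical(ct1$null_max, ct2$null_max)
  g <- glance(ct1)
  expect_equal(g$n_perm, 300)
  expect_equal(g$n_participants, 8)
})

test_that("cluster averaging reduces member points to one scalar per participant", {
  contrast <- array(0, c(3, 2, 2))
  contrast[1, , ] <- matrix(c(1, 3, 2, 4), 2, 2)
  contrast[2, , ] <- 5
  members <- array(TRUE, c(2, 2))
  expect_equal(cluster_average(contrast, members), c(2.5, 5, 0))
  expect_error(cluster_average(contrast, array(FALSE, c(2, 2))), "empty")
})

test_that("memory > control spindle responses yield a significant cluster, null does not", {
  # per-participant dB maps built from the generator's cue-response model
  mk_maps <- function(gain, n_part = 12, seed0 = 600) {
    maps_m <- array(NA_real_, c(n_part, 12, 40))
    maps_c <- array(NA_real_, c(n_part, 12, 40))
    for (p in seq_len(n_part)) {
      withr::with_seed(seed0 + p, {
        base_m <- matrix(rnorm(12 * 40, sd = 0.5), 12, 40)
        base_c <- matrix(rnorm(12 * 40, sd = 0.5), 12, 40)
        base_m[7:9, 25:32] <- base_m[7:9, 25:32] + gain
      })
      maps_m[p, , ] <- base_m; maps_c[p, , ] <- base_c
    }
    list(m = maps_m, c = maps_c)
  }
  eff <- mk_maps(1)
  ct <- cluster_permutation(eff$m, eff$c, n_perm = 500, seed = 3)
  expect_true(any(ct$clusters$p_value < 0.05))
  best <- which.min(ct$clusters$p_value)
  truth <- array(FALSE, c(12, 40)); truth[7:9, 25:32] <- TRUE
  overlap <- sum(cluster_members(ct, best) & truth) / sum(truth)
  expect_gte(overlap, 0.7)

  nul <- mk_maps(0, seed0 = 700)
  ctn <- cluster_permutation(nul$m, nul$c, n_perm = 500, seed = 4)
  expect_false(any(ctn$clusters$p_value < 0.05))
})
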