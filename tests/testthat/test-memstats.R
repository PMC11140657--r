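test_that("corrected recognition is hit minus false alarm", {
  expect_equal(corrected_recognition(0.88, 0.12), 0.76)
  expect_equal(corrected_recognition(0.4, 0), 0.4)
  expect_equal(corrected_recognition(0.5, 0.5), 0)
  expect_error(corrected_recognition(1.2, 0), "\\[0, 1\\]")
})

test_that("cueing benefit is cued minus uncued", {
  expect_equal(cueing_benefit(0.68, 0.60), 0.08)
  expect_equal(cueing_benefit(0.3, 0.3), 0)
  expect_equal(cueing_benefit(0.76, 0.75), 0.01)
})

test_that("one-sample t handles regular and degenerate input", {
  out <- one_sample_t(c(5, 5, 5), mu = 5)
  expect_equal(out$t, 0)
  expect_equal(out$p_value, 1)
  withr::with_seed(61, v <- rnorm(20, mean = 1))
  out2 <- one_sample_t(v)
  ref <- t.test(v)
  expect_equal(out2$t, unname(ref$statistic))
  expect_equal(out2$p_value, ref$p.value)
  expect_error(one_sample_t(1), "at least 2")
})

# direct BH step-up, written independently of stats::p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

test_that("FDR adjustment is exactly Benjamini-Hochberg step-up", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(62, {
    for (i in 1:20) {
      p <- runif(sample(2:5, 1))
      expect_equal(fdr_adjust(p), bh_oracle(p))
    }
  })
})

# direct evaluation of the circular-linear correlation formula
circ_corr_oracle <- function(phi_deg, x) {
  phi <- phi_deg * pi / 180
  rxc <- cor(x, cos(phi)); rxs <- cor(x, sin(phi))
  rcs <- cor(cos(phi), sin(phi))
  sqrt((rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2))
}

test_that("circular-linear correlation matches its formula and bounds", {
  withr::with_seed(63, phi <- runif(50, -180, 180))
  expect_equal(circ_linear_corr(phi, cos(phi * pi / 180))$r, 1, tolerance = 1e-9)

  withr::with_seed(64, {
    phi2 <- runif(1000, -180, 180)
    x2 <- rnorm(1000)
  })
  expect_lt(circ_linear_corr(phi2, x2)$r, 0.1)

  phi6 <- c(-120, -40, 10, 60, 130, 170)
  x6 <- c(0.2, 0.9, 1.4, 0.7, -0.3, -0.8)
  expect_equal(circ_linear_corr(phi6, x6)$r, circ_corr_oracle(phi6, x6))

  # rotation invariance: rotating phases and regenerating values accordingly
  withr::with_seed(65, phi3 <- runif(40, -180, 180))
  x3 <- cos((phi3 - 35) * pi / 180) + 0.1
  r1 <- circ_linear_corr(phi3, x3)$r
  r2 <- circ_linear_corr(sleeptmr:::wrap_deg(phi3 + 90),
                         cos((phi3 - 35) * pi / 180) + 0.1)$r
  expect_equal(r1, r2, tolerance = 1e-9)

  expect_error(circ_linear_corr(phi6, rep(1, 6)), "constant")
  expect_error(circ_linear_corr(1:3, 1:3), "at least 4")
})

test_that("Watson-Williams separates distinct mean directions and not identical ones", {
  withr::with_seed(66, a <- rvonmises_deg(30, 0, 5))
  ww_same <- watson_williams(a, a)
  expect_lt(ww_same$F, 1e-6)
  expect_gt(ww_same$p_value, 0.99)

  hits <- vapply(1:40, function(i) {
    withr::with_seed(600 + i, {
      g1 <- rvonmises_deg(30, 0, 5); g2 <- rvonmises_deg(30, 90, 5)
    })
    watson_williams(g1, g2)$p_value < 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("Watson-Williams type-I error is near nominal", {
  rej <- vapply(1:200, function(i) {
    withr::with_seed(7000 + i, {
      g1 <- rvonmises_deg(25, 40, 4); g2 <- rvonmises_deg(25, 40, 4)
    })
    watson_williams(g1, g2)$p_value < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.1)
})

test_that("von Mises sampler matches its theoretical resultant", {
  withr::with_seed(67, s <- rvonmises_deg(3000, -30, 5))
  expect_lt(abs(circ_mean_deg(s) - (-30)), 3)
  expect_lt(abs(resultant_length(s) - von_mises_resultant(5)), 0.03)
  withr::with_seed(68, u <- rvonmises_deg(3000, 0, 0))
  expect_lt(resultant_length(u), 0.05)
})

test_that("robust regression resists outliers where OLS does not", {
  x <- seq(0, 5, length.out = 50)
  d_clean <- tibble::tibble(x = x, y = 2 + 1.5 * x)
  # exact linear data: IRLS endpoint equals OLS (scale collapses, so the
  # iteration-limit warning is expected noise)
  suppressWarnings(rob0 <- robust_regress(y ~ x, d_clean))
  expect_equal(unname(tidy(rob0)$estimate), unname(coef(lm(y ~ x, d_clean))),
               tolerance = 1e-6)

  withr::with_seed(69, y <- 2 + 1.5 * x + rnorm(50, sd = 0.1))
  d <- tibble::tibble(x = x, y = y)
  rob <- robust_regress(y ~ x, d)
  expect_equal(unname(tidy(rob)$estimate), unname(coef(lm(y ~ x, d))),
               tolerance = 1e-2)

  d_out <- d; d_out$y[50] <- 200
  rob2 <- robust_regress(y ~ x, d_out)
  slope_rob <- tidy(rob2)$estimate[2]
  slope_ols <- unname(coef(lm(y ~ x, d_out))[2])
  expect_lt(abs(slope_rob - 1.5) / 1.5, 0.05)
  expect_gt(abs(slope_ols - 1.5) / 1.5, 0.20)

  d_const <- tibble::tibble(x = x, y = 1)
  suppressWarnings(rc <- robust_regress(y ~ x, d_const))
  expect_lt(abs(tidy(rc)$estimate[2]), 1e-9)
  expect_error(robust_regress(y ~ x + I(2 * x), d), "rank-deficient")
})

test_that("sleep architecture metrics follow the epoch arithmetic", {
  hyp8 <- hypnogram(rep("N2", 960))  # 8 h
  sa <- sleep_architecture(hyp8)
  expect_equal(sa$tst_min, 480)
  expect_equal(sa$sol_min, 0)
  expect_equal(sa$waso_min, 0)
  expect_equal(sa$efficiency_pct, 100)
  expect_equal(sa$pct_n2, 100)

  hyp <- hypnogram(c(rep("W", 10), rep("N2", 50), rep("N3", 20), rep("REM", 20)))
  sa2 <- sleep_architecture(hyp)
  expect_equal(sa2$tst_min, 45)
  expect_equal(sa2$sol_min, 5)
  expect_equal(sa2$efficiency_pct, 90)
  expect_equal(sa2$pct_n1 + sa2$pct_n2 + sa2$pct_n3 + sa2$pct_rem, 100,
               tolerance = 0.01)
  expect_error(sleep_architecture(hypnogram(rep("W", 10))), "no sleep")
})

test_that("scoring a generated table recovers condition structure", {
  beh <- gen_behavior(4, seed = 71)
  sc <- score_recognition(beh)
  expect_equal(nrow(sc), 4 * 8)
  expect_true(all(sc$corrected_recognition ==
                    sc$hit_rate - sc$fa_rate))
  ben <- cueing_benefit_table(sc)
  expect_equal(nrow(ben), 4 * 4)
  expect_true(all(c("emotion", "component", "benefit") %in% names(ben)))
})
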