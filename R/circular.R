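#' Circular statistics for coupling phases
#'
#' Small, self-contained circular toolbox used by the coupling and group
#' comparison code: circular mean and resultant vector length, von Mises
#' sampling, the circular-linear correlation, and the Watson-Williams test.
#' Phases are handled in degrees at the interface (the field's convention for
#' reporting coupling phase) and radians internally.
#'
#' @name circular-stats
NULL

#' Circular mean direction (degrees)
#'
#' @param phases_deg numeric vector of angles in degrees.
#' @return mean direction in degrees, wrapped to (-180, 180].
#' @export
circ_mean_deg <- function(phases_deg) {
  r <- deg2rad(phases_deg)
  rad2deg(atan2(mean(sin(r)), mean(cos(r))))
}

#' Resultant vector length
#'
#' Consistency of a sample of angles: 1 means all identical, 0 means perfectly
#' dispersed.
#' @inheritParams circ_mean_deg
#' @return scalar in `[0, 1]`.
#' @export
resultant_length <- function(phases_deg) {
  r <- deg2rad(phases_deg)
  sqrt(mean(sin(r))^2 + mean(cos(r))^2)
}

#' Theoretical von Mises resultant length A(kappa) = I1(kappa)/I0(kappa)
#' @param kappa concentration parameter (>= 0).
#' @return expected resultant length of a von Mises sample.
#' @export
von_mises_resultant <- function(kappa) {
  if (kappa == 0) return(0)
  besselI(kappa, 1) / besselI(kappa, 0)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler. `kappa = 0` reduces to the uniform
#' distribution on the circle.
#'
#' @param n number of draws.
#' @param mu_deg mean direction, degrees.
#' @param kappa concentration (>= 0).
#' @return angles in degrees in (-180, 180].
#' @export
rvonmises_deg <- function(n, mu_deg, kappa) {
  stopifnot(kappa >= 0)
  if (kappa == 0) {
    return(wrap_deg(stats::runif(n, -180, 180)))
  }
  mu <- deg2rad(mu_deg)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_deg(rad2deg(out))
}

#' Circular-linear correlation
#'
#' Correlation between an angular variable (e.g., coupling phase) and a linear
#' variable (e.g., corrected recognition):
#' `r = sqrt((r_xc^2 + r_xs^2 - 2 r_xc r_xs r_cs) / (1 - r_cs^2))`
#' with `r_xc = cor(x, cos phi)`, `r_xs = cor(x, sin phi)`,
#' `r_cs = cor(cos phi, sin phi)`. The p value uses the asymptotic
#' `n * r^2 ~ chi^2(2)` approximation.
#'
#' @param phases_deg angles in degrees.
#' @param values linear variable, same length.
#' @return one-row tibble with `r`, `statistic`, `p_value`, `n`.
#' @export
circ_linear_corr <- function(phases_deg, values) {
  stopifnot(length(phases_deg) == length(values))
  n <- length(values)
  if (n < 4) abort("need at least 4 observations")
  if (sd(values) == 0) abort("`values` is constant; correlation undefined")
  phi <- deg2rad(phases_deg)
  rxc <- cor(values, cos(phi))
  rxs <- cor(values, sin(phi))
  rcs <- cor(cos(phi), sin(phi))
  r2 <- (rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2)
  r <- sqrt(max(0, min(1, r2)))
  stat <- n * r^2
  tibble::tibble(r = r, statistic = stat,
                 p_value = stats::pchisq(stat, df = 2, lower.tail = FALSE),
                 n = n)
}

#' Watson-Williams test for equal mean directions
#'
#' Circular one-way comparison of two groups' mean coupling phases, with the
#' standard correction factor `1 + 3/(8 kappa_hat)`. Validity requires
#' reasonably concentrated samples; a warning is raised when the pooled
#' resultant length is below 0.45.
#'
#' @param phases_a_deg,phases_b_deg angles in degrees, one vector per group.
#' @return one-row tibble with `F`, `df1`, `df2`, `p_value`, and the pooled
#'   resultant length `rbar`.
#' @export
watson_williams <- function(phases_a_deg, phases_b_deg) {
  na <- length(phases_a_deg); nb <- length(phases_b_deg)
  if (na < 5 || nb < 5) abort("each group needs at least 5 observations")
  n <- na + nb
  Ra <- na * resultant_length(phases_a_deg)
  Rb <- nb * resultant_length(phases_b_deg)
  R <- n * resultant_length(c(phases_a_deg, phases_b_deg))
  if (Ra == 0 || Rb == 0) abort("degenerate group (zero resultant length)")
  rbar <- (Ra + Rb) / n
  if (rbar < 0.45) {
    warn("pooled resultant length < 0.45; Watson-Williams assumptions doubtful")
  }
  kappa <- a1inv(rbar)
  correction <- 1 + 3 / (8 * kappa)
  Fstat <- correction * ((n - 2) * (Ra + Rb - R)) / (n - (Ra + Rb))
  Fstat <- max(0, Fstat)
  tibble::tibble(F = Fstat, df1 = 1, df2 = n - 2,
                 p_value = stats::pf(Fstat, 1, n - 2, lower.tail = FALSE),
                 rbar = rbar)
}

# Inverse of A(kappa) = I1/I0, Fisher's (1993) piecewise approximation.
a1inv <- function(rbar) {
  if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
}
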