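#' @importFrom Rcpp sourceCpp
#' @useDynLib sleeptmr, .registration = TRUE
#' @importFrom rlang abort warn .data
#' @importFrom stats approx coef cor fft lm median pt pf pchisq qt sd t.test var
#' @importFrom utils head tail
NULL

# Valid hypnogram stage labels (AASM).
STAGES <- c("W", "N1", "N2", "N3", "REM")

#' Run code with a temporary RNG seed
#'
#' All stochastic operations in the package funnel through this helper so that
#' a `seed` argument fully determines their output without disturbing the
#' caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

#' Derive a stream-specific child seed from a master seed
#'
#' Keeps independent stages (background noise, event placement, behavior)
#' decoupled: changing one stage's draws never shifts another's.
#' Result stays within 32-bit integer range.
#' @noRd
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0 | x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Wrap angles in degrees to (-180, 180]
#' @noRd
wrap_deg <- function(d) {
  w <- (d + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}
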