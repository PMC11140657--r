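#' Corrected recognition score
#'
#' Hit rate minus false-alarm rate, the accuracy measure of the
#' emotional-memory trade-off task.
#'
#' @param hit_rate,fa_rate rates in `[0, 1]` (vectorized).
#' @return hit - FA, in `[-1, 1]`.
#' @export
corrected_recognition <- function(hit_rate, fa_rate) {
  assert_prob(hit_rate, "hit_rate"); assert_prob(fa_rate, "fa_rate")
  hit_rate - fa_rate
}

#' Cueing benefit
#'
#' Cued minus uncued corrected recognition; positive values mean cueing
#' during sleep improved memory.
#'
#' @param cued_cr,uncued_cr corrected recognition scores (vectorized).
#' @return cued - uncued.
#' @export
cueing_benefit <- function(cued_cr, uncued_cr) cued_cr - uncued_cr

#' Score an item-level recognition table
#'
#' Computes per-participant hit and false-alarm rates and corrected
#' recognition per condition (emotion x component x cued/uncued). A hit is an
#' "old" response to an old item; a false alarm an "old" response to a new
#' item. False alarms are estimated per emotion for objects and pooled for
#' backgrounds (new backgrounds are all neutral).
#'
#' @param behavior item-level tibble as produced by [gen_behavior()]:
#'   participant, type (old/new), component, emotion, cue, response.
#' @return tibble: participant, emotion, component, cue, hit_rate, fa_rate,
#'   corrected_recognition.
#' @export
score_recognition <- function(behavior) {
  fa <- behavior |>
    dplyr::filter(.data$type == "new") |>
    dplyr::mutate(fa_key = ifelse(.data$component == "background", "background",
                                  paste(.data$emotion, "object", sep = "."))) |>
    dplyr::group_by(.data$participant, .data$fa_key) |>
    dplyr::summarise(fa_rate = mean(.data$response == "old"), .groups = "drop")
  behavior |>
    dplyr::filter(.data$type == "old") |>
    dplyr::group_by(.data$participant, .data$emotion, .data$component, .data$cue) |>
    dplyr::summarise(hit_rate = mean(.data$response == "old"), .groups = "drop") |>
    dplyr::mutate(fa_key = ifelse(.data$component == "background", "background",
                                  paste(.data$emotion, "object", sep = "."))) |>
    dplyr::left_join(fa, by = c("participant", "fa_key")) |>
    dplyr::mutate(corrected_recognition =
                    corrected_recognition(.data$hit_rate, .data$fa_rate)) |>
    dplyr::select(-"fa_key")
}

#' Per-participant cueing benefits from a scored table
#'
#' @param scores output of [score_recognition()].
#' @return tibble: participant, emotion, component, benefit (cued - uncued
#'   corrected recognition).
#' @export
cueing_benefit_table <- function(scores) {
  scores |>
    dplyr::select("participant", "emotion", "component", "cue",
                  "corrected_recognition") |>
    tidyr::pivot_wider(names_from = "cue", values_from = "corrected_recognition") |>
    dplyr::mutate(benefit = cueing_benefit(.data$cued, .data$uncued)) |>
    dplyr::select("participant", "emotion", "component", "benefit")
}

#' One-sample t test as a tidy row
#'
#' @param values numeric vector (n >= 2).
#' @param mu null value.
#' @return tibble: estimate, t, df, p_value, conf_low, conf_high.
#' @export
one_sample_t <- function(values, mu = 0) {
  if (length(values) < 2) abort("need at least 2 values")
  stderr_ <- sd(values) / sqrt(length(values))
  if (stderr_ < 10 * .Machine$double.eps * max(1, abs(mean(values)))) {
    # degenerate spread: t is 0 when the mean equals mu, infinite otherwise
    eq <- isTRUE(all.equal(mean(values), mu))
    return(tibble::tibble(estimate = mean(values),
                          t = if (eq) 0 else Inf * sign(mean(values) - mu),
                          df = length(values) - 1,
                          p_value = if (eq) 1 else 0,
                          conf_low = mean(values), conf_high = mean(values)))
  }
  ht <- stats::t.test(values, mu = mu)
  tibble::tibble(estimate = unname(ht$estimate), t = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 conf_low = ht$conf.int[1], conf_high = ht$conf.int[2])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate control; a thin wrapper over
#' `stats::p.adjust(method = "BH")` so the adjustment used across the
#' package is explicit and testable.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p values, same length.
#' @export
fdr_adjust <- function(p_values) {
  assert_prob(p_values, "p_values")
  stats::p.adjust(p_values, method = "BH")
}

#' Robust linear regression (IRLS, Tukey bisquare)
#'
#' Iteratively reweighted least squares with the bisquare psi function
#' (tuning constant 4.685) via `MASS::rlm`, used for models such as
#' `cueing benefit ~ cluster power * emotion` where single outlying
#' participants must not dominate. Approximate p values use the normal
#' reference for the robust t statistics.
#'
#' @param formula model formula.
#' @param data data frame.
#' @return object of class `robust_fit` (wrapping the `rlm` fit) with
#'   [tidy.robust_fit()] / [glance.robust_fit()] methods.
#' @export
robust_regress <- function(formula, data) {
  mm <- stats::model.matrix(formula, data)
  if (qr(mm)$rank < ncol(mm)) abort("rank-deficient design matrix")
  fit <- MASS::rlm(formula, data = data, psi = MASS::psi.bisquare, c = 4.685,
                   maxit = 200, acc = 1e-8)
  structure(list(fit = fit, formula = formula, n = nrow(data)),
            class = "robust_fit")
}

#' Tidy/glance for robust fits
#' @param x a `robust_fit`.
#' @param ... unused.
#' @return `tidy`: term, estimate, std_error, statistic, p_value;
#'   `glance`: n, scale estimate, converged flag.
#' @export
tidy.robust_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, "Value"],
                 std_error = s[, "Std. Error"], statistic = s[, "t value"],
                 p_value = 2 * stats::pnorm(-abs(s[, "t value"])))
}

#' @rdname tidy.robust_fit
#' @export
glance.robust_fit <- function(x, ...) {
  tibble::tibble(n = x$n, scale = x$fit$s, converged = x$fit$converged)
}

#' @export
print.robust_fit <- function(x, ...) {
  cat("<robust_fit> bisquare IRLS\n")
  print(tidy.robust_fit(x))
  invisible(x)
}

#' Sleep architecture summary from a hypnogram
#'
#' Total sleep time, sleep-onset latency, wake after sleep onset, sleep
#' efficiency and stage percentages of TST, computed over the
#' lights-off-to-lights-on interval (defaults to the whole hypnogram).
#'
#' @param hyp a [hypnogram()].
#' @param lights_off_epoch,lights_on_epoch 0-based epoch indices bounding
#'   time in bed (`lights_on_epoch` is exclusive).
#' @return one-row tibble: tst_min, sol_min, waso_min, tib_min,
#'   efficiency_pct, pct_n1, pct_n2, pct_n3, pct_rem.
#' @export
sleep_architecture <- function(hyp, lights_off_epoch = 0L,
                               lights_on_epoch = nrow(hyp)) {
  elen_min <- (attr(hyp, "epoch_length_s") %||% 30) / 60
  stages <- hyp$stage[(lights_off_epoch + 1L):lights_on_epoch]
  sleep <- stages != "W"
  if (!any(sleep)) abort("no sleep epochs in the time-in-bed window")
  onset <- which(sleep)[1]
  last_sleep <- max(which(sleep))
  tst <- sum(sleep) * elen_min
  tib <- length(stages) * elen_min
  waso <- sum(!sleep[onset:length(stages)]) * elen_min
  pct <- function(s) 100 * sum(stages == s) * elen_min / tst
  tibble::tibble(tst_min = tst, sol_min = (onset - 1) * elen_min,
                 waso_min = waso, tib_min = tib,
                 efficiency_pct = 100 * tst / tib,
                 pct_n1 = pct("N1"), pct_n2 = pct("N2"),
                 pct_n3 = pct("N3"), pct_rem = pct("REM"))
}
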