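#' Morlet time-frequency decomposition of cue-locked epochs
#'
#' Decomposes one channel of an epoch set at 30 logarithmically spaced
#' frequencies from 2 to 40 Hz, with wavelet cycles increasing from 5 to 10
#' in matching logarithmic steps; power is the squared wavelet magnitude per
#' trial.
#'
#' @param epochs an `epoch_set` (rejected trials are excluded).
#' @param channel channel to decompose (default "Cz", the cue-response
#'   analysis channel).
#' @param freqs frequency vector in Hz.
#' @param cycles wavelet cycles, same length as `freqs`.
#' @return a `tfr` object: list with `power` (trials x freqs x times array),
#'   `freqs`, `times`, `fs`, `channel`, `metadata`, `units` ("raw").
#' @export
tfr_morlet <- function(epochs, channel = "Cz",
                       freqs = exp(seq(log(2), log(40), length.out = 30)),
                       cycles = exp(seq(log(5), log(10), length.out = 30))) {
  stopifnot(length(freqs) == length(cycles))
  ch <- match(channel, epochs$channels)
  if (is.na(ch)) abort(sprintf("channel '%s' not in epochs", channel))
  ep <- kept_epochs(epochs)
  n_tr <- dim(ep$data)[1]; n_t <- dim(ep$data)[3]
  if (n_tr == 0) abort("no kept trials")
  longest <- max(cycles / freqs)
  if (n_t / ep$fs < longest) abort("epoch shorter than the longest wavelet")
  pow <- array(NA_real_, c(n_tr, length(freqs), n_t))
  for (f in seq_along(freqs)) {
    sigma_t <- cycles[f] / (2 * pi * freqs[f])
    fwhm_hz <- 2.355 / (2 * pi * sigma_t)
    for (tr in seq_len(n_tr)) {
      pow[tr, f, ] <- morlet_amplitude(ep$data[tr, ch, ], ep$fs, freqs[f],
                                       fwhm_hz)^2
    }
  }
  structure(list(power = pow, freqs = freqs, times = ep$times, fs = ep$fs,
                 channel = channel, metadata = ep$metadata, units = "raw"),
            class = "tfr")
}

#' @export
print.tfr <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<tfr> %s, %s x %d freqs (%.1f-%.1f Hz) x %d times, units: %s\n",
              x$channel,
              if (length(d) == 3) paste(d[1], "trials") else "averaged",
              length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), x$units))
  invisible(x)
}

#' Decibel baseline normalization of a TFR
#'
#' Averages power over trials, then expresses each time-frequency point as
#' `10*log10(power / baseline)` where the baseline is the mean trial-averaged
#' power per frequency in the given pre-cue window (default 500-200 ms before
#' onset, late enough to avoid post-stimulus leakage into the baseline).
#'
#' @param tfr a `tfr` from [tfr_morlet()].
#' @param baseline c(start, end) in seconds relative to cue onset.
#' @return a `tfr` with trial-averaged `power` (freqs x times) in dB.
#' @export
db_normalize <- function(tfr, baseline = c(-0.5, -0.2)) {
  if (baseline[1] < min(tfr$times) || baseline[2] > 0) {
    abort("baseline must lie inside the epoch and before cue onset")
  }
  avg <- if (length(dim(tfr$power)) == 3) {
    apply(tfr$power, c(2, 3), mean)
  } else tfr$power
  bl_idx <- tfr$times >= baseline[1] & tfr$times <= baseline[2]
  bl <- rowMeans(avg[, bl_idx, drop = FALSE])
  if (any(bl <= 0)) abort("nonpositive baseline power")
  tfr$power <- 10 * log10(sweep(avg, 1, bl, `/`))
  tfr$units <- "dB"
  tfr$baseline <- baseline
  tfr
}

#' Tidy a TFR into a long tibble
#' @param x a `tfr`.
#' @param ... unused.
#' @return tibble with time, freq, power (trial-averaged if needed).
#' @export
tidy.tfr <- function(x, ...) {
  avg <- if (length(dim(x$power)) == 3) apply(x$power, c(2, 3), mean) else x$power
  tidyr::expand_grid(freq = x$freqs, time = x$times) |>
    dplyr::arrange(.data$time, .data$freq) |>
    dplyr::mutate(power = as.numeric(avg))
}

#' @export
autoplot.tfr <- function(object, ...) {
  tidy.tfr(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time, y = .data$freq,
                                 fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$units) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time from cue (s)", y = "Frequency (Hz)",
                  title = sprintf("Cue-locked TFR (%s)", object$channel)) +
    ggplot2::theme_minimal()
}

#' Spindle probability time course
#'
#' For each epoch time point, the fraction of trials in which a detected
#' spindle is ongoing (1 where a spindle covers the time point, 0 elsewhere,
#' averaged across trials).
#'
#' @param spindles_by_trial tibble with columns `trial`, `onset_s`,
#'   `offset_s` in epoch time (seconds relative to cue onset).
#' @param times epoch time vector (seconds).
#' @param trials vector of trial ids defining the denominator.
#' @return tibble: time, probability.
#' @export
spindle_probability <- function(spindles_by_trial, times, trials) {
  if (!length(trials)) abort("zero trials")
  ind <- matrix(0, length(trials), length(times))
  for (i in seq_len(nrow(spindles_by_trial))) {
    r <- match(spindles_by_trial$trial[i], trials)
    if (is.na(r)) next
    cov <- times >= spindles_by_trial$onset_s[i] &
      times < spindles_by_trial$offset_s[i]
    ind[r, cov] <- 1
  }
  tibble::tibble(time = times, probability = colMeans(ind))
}

#' Match trial counts between two conditions
#'
#' Randomly subsamples (without replacement) the higher-count condition down
#' to the lower count so condition contrasts are not biased by trial numbers;
#' the selection is deterministic under `seed`.
#'
#' @param a,b `epoch_set`s, or integer vectors of trial indices.
#' @param seed RNG seed.
#' @return list with elements `a` and `b` of equal trial count, plus
#'   `selected_a`/`selected_b` index vectors.
#' @export
match_trials <- function(a, b, seed = NULL) {
  idx_a <- if (inherits(a, "epoch_set")) which(a$metadata$kept) else a
  idx_b <- if (inherits(b, "epoch_set")) which(b$metadata$kept) else b
  n <- min(length(idx_a), length(idx_b))
  with_seed(seed, {
    sel_a <- if (length(idx_a) > n) sort(sample(idx_a, n)) else idx_a
    sel_b <- if (length(idx_b) > n) sort(sample(idx_b, n)) else idx_b
    take <- function(x, sel, idx) {
      if (!inherits(x, "epoch_set")) return(sel)
      keep_rows <- match(sel, seq_len(dim(x$data)[1]))
      x$data <- x$data[keep_rows, , , drop = FALSE]
      x$metadata <- x$metadata[keep_rows, ]
      x
    }
    list(a = take(a, sel_a, idx_a), b = take(b, sel_b, idx_b),
         selected_a = sel_a, selected_b = sel_b)
  })
}

#' Cluster-based permutation test for paired condition maps
#'
#' Pointwise paired t tests between two per-participant maps, clustering of
#' supra-threshold points under 4-connectivity (runs for 1-D maps), cluster
#' statistic `t_sum`, and corrected p values against the permutation
#' distribution of the maximum |t_sum| built from 1,000 (default) random
#' within-participant condition swaps (sign flips of the difference) — the
#' exact permutation scheme for a paired design. Positive and negative
#' clusters are tested jointly against the two-sided max-|t_sum| null.
#'
#' @param maps_a,maps_b arrays: participants x freqs x times (or
#'   participants x times for 1-D maps such as spindle probability).
#' @param n_perm number of permutations.
#' @param point_alpha two-tailed cluster-forming alpha for the pointwise t.
#' @param seed RNG seed.
#' @param freqs,times optional axis values stored for reporting.
#' @return a `cluster_test` object; see [tidy.cluster_test()].
#' @export
cluster_permutation <- function(maps_a, maps_b, n_perm = 1000,
                                point_alpha = 0.05, seed = NULL,
                                freqs = NULL, times = NULL) {
  da <- dim(maps_a)
  if (!identical(da, dim(maps_b))) abort("condition maps must have identical dimensions")
  n <- da[1]
  if (n < 2) abort("need at least 2 participants")
  if (length(da) == 2) {
    nf <- 1L; nt <- da[2]
  } else {
    nf <- da[2]; nt <- da[3]
  }
  D <- matrix(maps_a - maps_b, nrow = n)  # flattens freq-fastest (column-major)
  tcrit <- stats::qt(1 - point_alpha / 2, df = n - 1)
  res <- with_seed(seed, cluster_perm_paired_cpp(D, nf, nt, n_perm, tcrit))
  k <- length(res$cluster_sums)
  clusters <- tibble::tibble(
    cluster = seq_len(k),
    t_sum = as.numeric(res$cluster_sums),
    sign = ifelse(res$cluster_sums > 0, "positive", "negative"),
    n_points = as.integer(tabulate(res$labels, k)),
    p_value = vapply(res$cluster_sums, function(s) {
      (1 + sum(res$null_max >= abs(s))) / (n_perm + 1)
    }, 0))
  structure(list(clusters = clusters,
                 t = array(res$t, if (nf == 1) nt else c(nf, nt)),
                 labels = array(res$labels, if (nf == 1) nt else c(nf, nt)),
                 null_max = as.numeric(res$null_max),
                 n_perm = n_perm, point_alpha = point_alpha, tcrit = tcrit,
                 n_participants = n, freqs = freqs, times = times),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  sig <- sum(x$clusters$p_value < 0.05)
  cat(sprintf("<cluster_test> %d participants, %d permutations, %d cluster(s), %d significant\n",
              x$n_participants, x$n_perm, nrow(x$clusters), sig))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Tidy/glance methods for cluster tests
#' @param x a `cluster_test`.
#' @param ... unused.
#' @return `tidy`: one row per cluster (t_sum, sign, size, corrected p);
#'   `glance`: one-row test summary.
#' @export
tidy.cluster_test <- function(x, ...) x$clusters

#' @rdname tidy.cluster_test
#' @export
glance.cluster_test <- function(x, ...) {
  tibble::tibble(n_participants = x$n_participants, n_perm = x$n_perm,
                 point_alpha = x$point_alpha, tcrit = x$tcrit,
                 n_clusters = nrow(x$clusters),
                 n_significant = sum(x$clusters$p_value < 0.05),
                 min_p = if (nrow(x$clusters)) min(x$clusters$p_value) else NA_real_)
}

#' Points belonging to one cluster
#' @param test a `cluster_test`.
#' @param cluster cluster id.
#' @return logical array matching the map dimensions.
#' @export
cluster_members <- function(test, cluster) {
  test$labels == cluster
}

#' Cluster-averaged contrast per participant
#'
#' Averages the per-participant contrast maps (memory minus control, dB) over
#' the member points of a significant cluster, yielding one scalar per
#' participant for regression against behavior.
#'
#' @param contrast array participants x (map dims) of condition differences.
#' @param members logical array over map points ([cluster_members()]).
#' @return numeric vector, one value per participant.
#' @export
cluster_average <- function(contrast, members) {
  if (!any(members)) abort("empty cluster")
  n <- dim(contrast)[1]
  flat <- matrix(contrast, nrow = n)
  rowMeans(flat[, as.logical(members), drop = FALSE])
}

#' Plot spindle probability curves per condition
#' @param curves tibble with columns time, probability and optionally
#'   condition.
#' @return a ggplot.
#' @export
plot_spindle_probability <- function(curves) {
  aes <- if ("condition" %in% names(curves)) {
    ggplot2::aes(x = .data$time, y = .data$probability, colour = .data$condition)
  } else {
    ggplot2::aes(x = .data$time, y = .data$probability)
  }
  ggplot2::ggplot(curves, aes) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time from cue (s)", y = "Spindle probability") +
    ggplot2::theme_minimal()
}
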