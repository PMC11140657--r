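#' Complex Morlet wavelet amplitude envelope
#'
#' Convolves the signal with a complex Morlet wavelet whose frequency-domain
#' Gaussian has the requested full-width-half-maximum (sigma_f = FWHM/2.355),
#' scaled so the returned magnitude equals the amplitude (uV) of a matched
#' sinusoid.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param freq wavelet center frequency in Hz.
#' @param fwhm_hz spectral full-width-half-maximum in Hz.
#' @return numeric vector of instantaneous amplitude at `freq`.
#' @export
morlet_amplitude <- function(x, fs, freq, fwhm_hz = 3) {
  Mod(morlet_transform(x, fs, freq, fwhm_hz))
}

morlet_transform <- function(x, fs, freq, fwhm_hz = 3) {
  sigma_f <- fwhm_hz / 2.355
  sigma_t <- 1 / (2 * pi * sigma_f)
  half <- ceiling(4 * sigma_t * fs)
  t <- (-half:half) / fs
  env <- exp(-t^2 / (2 * sigma_t^2))
  kern <- env * exp(2i * pi * freq * t) * (2 / sum(env))
  fft_convolve(x, kern)
}

# Centered FFT convolution returning a vector the length of x.
fft_convolve <- function(x, kern) {
  n <- length(x); m <- length(kern)
  L <- stats::nextn(n + m - 1, 2)
  y <- stats::fft(stats::fft(c(x, rep(0, L - n))) *
                    stats::fft(c(kern, rep(0, L - m))), inverse = TRUE) / L
  y[((m - 1) %/% 2 + 1):((m - 1) %/% 2 + n)]
}

#' Analytic signal via the Hilbert transform
#'
#' FFT-based analytic signal with 2 s reflection padding at both ends to
#' suppress edge effects (trimmed after the transform).
#'
#' @param x numeric vector.
#' @param fs sampling rate (used for the padding length).
#' @return complex vector; `Arg()` gives instantaneous phase with 0 at a
#'   positive peak of a cosine-like wave, `Mod()` the envelope.
#' @export
analytic_signal <- function(x, fs) {
  pad <- min(length(x) - 1, as.integer(2 * fs))
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(length(x) - pad):(length(x) - 1)]))
  n <- length(xp)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  ya <- stats::fft(stats::fft(xp) * h, inverse = TRUE) / n
  ya[(pad + 1):(pad + length(x))]
}

#' Detect sleep spindles with an individualized wavelet detector
#'
#' Computes the complex Morlet amplitude at the participant's spindle peak
#' frequency (3 Hz FWHM) and thresholds it at `threshold_factor` times the
#' median amplitude over artifact-free samples. Supra-threshold runs
#' separated by less than `merge_gap_s` are merged, runs of at least
#' `min_dur_s` become events, and events overlapping artifact-masked samples
#' are discarded. A zero median (degenerate threshold) yields no detections
#' with a warning.
#'
#' @param x numeric vector (one channel, uV).
#' @param fs sampling rate in Hz.
#' @param peak_freq individualized spindle peak frequency (Hz), from
#'   [find_spectral_peak()].
#' @param clean_mask logical vector marking artifact-free samples (default
#'   all clean).
#' @param threshold_factor multiple of the median amplitude.
#' @param min_dur_s minimum event duration in seconds.
#' @param fwhm_hz wavelet spectral FWHM.
#' @param merge_gap_s gap below which adjacent runs merge.
#' @param channel label recorded on each event.
#' @return tibble of events: channel, onset_s, offset_s, duration_s,
#'   peak_amplitude, peak_time_s, center_frequency.
#' @export
detect_spindles <- function(x, fs, peak_freq, clean_mask = NULL,
                            threshold_factor = 9, min_dur_s = 0.4,
                            fwhm_hz = 3, merge_gap_s = 0.1, channel = "sig") {
  clean_mask <- clean_mask %||% rep(TRUE, length(x))
  if (!any(clean_mask)) abort("empty clean mask")
  amp <- morlet_amplitude(x, fs, peak_freq, fwhm_hz)
  med <- median(amp[clean_mask])
  empty <- tibble::tibble(channel = character(), onset_s = numeric(),
                          offset_s = numeric(), duration_s = numeric(),
                          peak_amplitude = numeric(), peak_time_s = numeric(),
                          center_frequency = numeric())
  if (med <= 0) {
    warn("median amplitude is zero; degenerate threshold, no detections")
    return(empty)
  }
  supra <- amp > threshold_factor * med
  runs <- runs_from_logical(supra)
  if (!nrow(runs)) return(empty)
  runs <- merge_runs(runs, max_gap = as.integer(merge_gap_s * fs))
  runs <- runs[(runs$end - runs$start + 1) / fs >= min_dur_s, , drop = FALSE]
  if (!nrow(runs)) return(empty)
  ok <- vapply(seq_len(nrow(runs)), function(i) {
    all(clean_mask[runs$start[i]:runs$end[i]])
  }, TRUE)
  runs <- runs[ok, , drop = FALSE]
  if (!nrow(runs)) return(empty)
  purrr::map_dfr(seq_len(nrow(runs)), function(i) {
    seg <- runs$start[i]:runs$end[i]
    pk <- seg[which.max(amp[seg])]
    tibble::tibble(channel = channel,
                   onset_s = (runs$start[i] - 1) / fs,
                   offset_s = runs$end[i] / fs,
                   duration_s = (runs$end[i] - runs$start[i] + 1) / fs,
                   peak_amplitude = amp[pk],
                   peak_time_s = (pk - 1) / fs,
                   center_frequency = peak_freq)
  })
}

runs_from_logical <- function(m) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}

merge_runs <- function(runs, max_gap) {
  if (nrow(runs) <= 1) return(runs)
  out <- runs[1, ]
  for (i in 2:nrow(runs)) {
    if (runs$start[i] - out$end[nrow(out)] - 1L < max_gap) {
      out$end[nrow(out)] <- runs$end[i]
    } else {
      out <- rbind(out, runs[i, ])
    }
  }
  out
}

#' Detect slow oscillations (0.5-1.25 Hz, top-quartile amplitude)
#'
#' Bandpass filters 0.5-4 Hz, finds positive-to-negative zero crossings,
#' marks candidate oscillations where two consecutive crossings fall 0.8-2 s
#' apart, and retains the top quartile (`ceiling(n/4)` largest) of
#' peak-to-peak amplitudes. Candidates overlapping artifact-masked samples
#' are discarded before the quartile cut.
#'
#' @inheritParams detect_spindles
#' @param band delta filter band in Hz.
#' @param span_range allowed crossing-to-crossing duration in seconds.
#' @return tibble: channel, start_s, end_s, duration_s,
#'   peak_to_peak_amplitude, trough_time_s.
#' @export
detect_slow_oscillations <- function(x, fs, clean_mask = NULL,
                                     band = c(0.5, 4),
                                     span_range = c(0.8, 2),
                                     channel = "sig") {
  clean_mask <- clean_mask %||% rep(TRUE, length(x))
  xf <- filter_signal(x, fs, "bandpass", band)
  pn <- which(xf[-length(xf)] > 0 & xf[-1] <= 0)  # positive-to-negative
  if (length(pn) < 2) abort("no candidate slow oscillations (fewer than 2 zero crossings)")
  cand <- tibble::tibble(start = pn[-length(pn)], end = pn[-1])
  cand$dur <- (cand$end - cand$start) / fs
  cand <- cand[cand$dur >= span_range[1] & cand$dur <= span_range[2], ]
  if (!nrow(cand)) abort("no candidate slow oscillations in the 0.8-2 s range")
  ok <- vapply(seq_len(nrow(cand)), function(i) {
    all(clean_mask[cand$start[i]:cand$end[i]])
  }, TRUE)
  cand <- cand[ok, , drop = FALSE]
  if (!nrow(cand)) abort("no artifact-free candidate slow oscillations")
  feats <- purrr::map_dfr(seq_len(nrow(cand)), function(i) {
    seg <- cand$start[i]:cand$end[i]
    tibble::tibble(p2p = max(xf[seg]) - min(xf[seg]),
                   trough = seg[which.min(xf[seg])])
  })
  k <- ceiling(nrow(cand) / 4)
  keep <- order(feats$p2p, decreasing = TRUE)[seq_len(k)]
  keep <- sort(keep)
  tibble::tibble(channel = channel,
                 start_s = (cand$start[keep] - 1) / fs,
                 end_s = (cand$end[keep] - 1) / fs,
                 duration_s = cand$dur[keep],
                 peak_to_peak_amplitude = feats$p2p[keep],
                 trough_time_s = (feats$trough[keep] - 1) / fs)
}

#' SO-spindle coupling
#'
#' For each detected spindle whose amplitude peak falls inside the span of a
#' detected slow oscillation, extracts the SO phase at the spindle peak from
#' the analytic signal of the 0.5-4 Hz filtered trace. Phase convention:
#' 0 deg = SO positive peak, +/-180 deg = trough.
#'
#' @param spindles tibble from [detect_spindles()].
#' @param sos tibble from [detect_slow_oscillations()].
#' @param x the raw channel signal the events came from.
#' @param fs sampling rate in Hz.
#' @param band delta band for the phase-defining filter.
#' @return tibble of coupled events: spindle columns plus so_start_s,
#'   so_end_s, coupling_phase_deg.
#' @export
couple_events <- function(spindles, sos, x, fs, band = c(0.5, 4)) {
  if (nrow(spindles) && nrow(sos) &&
      !all(spindles$channel[1] == sos$channel[1])) {
    abort("spindles and slow oscillations come from different channels")
  }
  empty <- dplyr::mutate(spindles[0, ], so_start_s = numeric(),
                         so_end_s = numeric(), coupling_phase_deg = numeric())
  if (!nrow(spindles) || !nrow(sos)) return(empty)
  xf <- filter_signal(x, fs, "bandpass", band)
  phase <- Arg(analytic_signal(xf, fs))
  rows <- purrr::map_dfr(seq_len(nrow(spindles)), function(i) {
    pk <- spindles$peak_time_s[i]
    j <- which(sos$start_s <= pk & pk < sos$end_s)
    if (!length(j)) return(NULL)
    j <- j[1]
    samp <- as.integer(round(pk * fs)) + 1L
    dplyr::mutate(spindles[i, ], so_start_s = sos$start_s[j],
                  so_end_s = sos$end_s[j],
                  coupling_phase_deg = wrap_deg(rad2deg(phase[samp])))
  })
  if (is.null(rows) || !nrow(rows)) empty else rows
}

#' Summarize SO-spindle coupling
#'
#' @param coupled tibble from [couple_events()].
#' @param n_spindles total number of detected spindles.
#' @param nrem_minutes minutes of artifact-free NREM sleep.
#' @return one-row tibble: n_coupled, n_spindles, coupled_density (events per
#'   NREM minute), mean_phase_deg, vector_length.
#' @export
coupling_summary <- function(coupled, n_spindles, nrem_minutes) {
  if (nrem_minutes <= 0) abort("`nrem_minutes` must be positive")
  n <- nrow(coupled)
  tibble::tibble(
    n_coupled = n, n_spindles = n_spindles,
    coupled_density = n / nrem_minutes,
    mean_phase_deg = if (n) circ_mean_deg(coupled$coupling_phase_deg) else NA_real_,
    vector_length = if (n) resultant_length(coupled$coupling_phase_deg) else NA_real_)
}

#' Events per minute
#' @param n_events event count (or an event tibble).
#' @param minutes minutes of qualifying sleep (> 0).
#' @return rate per minute.
#' @export
event_density <- function(n_events, minutes) {
  if (minutes <= 0) abort("`minutes` must be positive")
  if (is.data.frame(n_events)) n_events <- nrow(n_events)
  n_events / minutes
}

#' Rose plot of coupling phases
#' @param coupled tibble with a `coupling_phase_deg` column.
#' @param binwidth histogram bin width in degrees.
#' @return a ggplot.
#' @export
plot_coupling_phases <- function(coupled, binwidth = 20) {
  ggplot2::ggplot(coupled, ggplot2::aes(x = .data$coupling_phase_deg)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = -180,
                            fill = "steelblue", colour = "white") +
    ggplot2::coord_polar(start = pi) +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = c(-90, 0, 90, 180)) +
    ggplot2::labs(x = "SO phase at spindle peak (deg; 0 = SO peak)",
                  y = "Count") +
    ggplot2::theme_minimal()
}
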