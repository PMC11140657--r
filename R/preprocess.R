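#' Zero-phase filtering of a signal or recording
#'
#' 4th-order Butterworth applied forward-backward (`signal::filtfilt`), the
#' conventional zero-phase choice for event-locked analyses; the notch is an
#' IIR biquad with Q = 30, also run forward-backward.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param kind "highpass", "lowpass", "bandpass" or "notch".
#' @param cutoff scalar cutoff (Hz) for highpass/lowpass/notch, length-2 for
#'   bandpass. Must lie below the Nyquist frequency.
#' @param q notch quality factor.
#' @return filtered numeric vector.
#' @export
filter_signal <- function(x, fs, kind = c("highpass", "lowpass", "bandpass", "notch"),
                          cutoff, q = 30) {
  kind <- match.arg(kind)
  nyq <- fs / 2
  if (any(cutoff >= nyq)) abort("cutoff must be below the Nyquist frequency")
  if (any(cutoff <= 0)) abort("cutoff must be positive")
  if (kind == "notch") {
    w0 <- 2 * pi * cutoff / fs
    alpha <- sin(w0) / (2 * q)
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
    return(as.numeric(signal::filtfilt(signal::Arma(b = b / a[1], a = a / a[1]), x)))
  }
  type <- switch(kind, highpass = "high", lowpass = "low", bandpass = "pass")
  flt <- signal::butter(4, cutoff / nyq, type = type)
  as.numeric(signal::filtfilt(flt, x))
}

#' @rdname filter_signal
#' @param rec an [eeg_recording()]; every channel is filtered.
#' @param ... passed on to [filter_signal()].
#' @export
filter_recording <- function(rec, ...) {
  data <- t(apply(rec$data, 1, filter_signal, fs = rec$fs, ...))
  eeg_recording(data, rec$fs, rec$channels, rec$reference, rec$annotations)
}

#' Resample a recording (downsampling only)
#'
#' Fourier-domain resampling: the spectrum is truncated at the new Nyquist
#' frequency (ideal anti-aliasing for band-limited signals) and inverted at
#' the new length. Upsampling is out of scope and raises an error.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs new sampling rate (<= current).
#' @return resampled [eeg_recording()].
#' @export
resample_recording <- function(rec, target_fs) {
  if (target_fs > rec$fs) abort("upsampling is not supported")
  if (target_fs == rec$fs) return(rec)
  n <- n_samples(rec)
  n_new <- as.integer(round(n * target_fs / rec$fs))
  data <- t(apply(rec$data, 1, fft_resample, n_new = n_new))
  eeg_recording(data, target_fs, rec$channels, rec$reference, rec$annotations)
}

fft_resample <- function(x, n_new) {
  n <- length(x)
  X <- stats::fft(x)
  keep <- n_new %/% 2
  Y <- complex(n_new)
  Y[1:(keep + 1)] <- X[1:(keep + 1)]
  Y[(n_new - keep + 1):n_new] <- X[(n - keep + 1):n]
  if (n_new %% 2 == 0) Y[keep + 1] <- Re(Y[keep + 1])  # split Nyquist bin
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Rescale event onsets after resampling
#' @param onset_sample 0-based onsets at `fs_from`.
#' @param fs_from,fs_to old and new sampling rates.
#' @return 0-based onsets at `fs_to`.
#' @export
rescale_onsets <- function(onset_sample, fs_from, fs_to) {
  as.integer(round(onset_sample * fs_to / fs_from))
}

#' Rereference to the average of the two mastoids
#'
#' @param rec an [eeg_recording()].
#' @param refs labels of the two mastoid channels.
#' @return rereferenced recording (`reference` set to "avg-mastoid"); the
#'   mastoid channels themselves are retained.
#' @export
rereference <- function(rec, refs = c("M1", "M2")) {
  missing <- setdiff(refs, rec$channels)
  if (length(missing)) abort(sprintf("missing mastoid channel(s): %s",
                                     paste(missing, collapse = ", ")))
  refsig <- colMeans(rec$data[refs, , drop = FALSE])
  data <- sweep(rec$data, 2, refsig)
  eeg_recording(data, rec$fs, rec$channels, "avg-mastoid", rec$annotations)
}

#' Epoch a recording around cue onsets
#'
#' Cuts `[window[1], window[2])` second windows around each event onset.
#' Events too close to a recording edge are flagged (`kept = FALSE`, reason
#' "edge"), never silently dropped. With `baseline = TRUE` each trial is
#' mean-adjusted to its mean voltage in the 1 s before cue onset.
#'
#' @param rec an [eeg_recording()].
#' @param events a [cue_events()] tibble.
#' @param window c(t_min, t_max) in seconds relative to onset.
#' @param baseline subtract the 1-s pre-onset mean per trial/channel.
#' @return an `epoch_set`: list with `data` (trials x channels x samples
#'   array), `times`, `fs`, `channels`, `metadata` tibble.
#' @export
epoch_recording <- function(rec, events, window = c(-1, 3), baseline = TRUE) {
  fs <- rec$fs
  n_t <- as.integer(round((window[2] - window[1]) * fs))
  times <- window[1] + (seq_len(n_t) - 1) / fs
  n_tr <- nrow(events)
  data <- array(NA_real_, c(n_tr, length(rec$channels), n_t))
  kept <- rep(TRUE, n_tr); reason <- rep(NA_character_, n_tr)
  for (i in seq_len(n_tr)) {
    a <- events$onset_sample[i] + as.integer(round(window[1] * fs)) + 1L
    b <- a + n_t - 1L
    if (a < 1L || b > n_samples(rec)) {
      kept[i] <- FALSE; reason[i] <- "edge"
      next
    }
    tr <- rec$data[, a:b, drop = FALSE]
    if (baseline) {
      bl <- times >= -1 & times < 0
      tr <- tr - rowMeans(tr[, bl, drop = FALSE])
    }
    data[i, , ] <- tr
  }
  structure(list(data = data, times = times, fs = fs, channels = rec$channels,
                 metadata = tibble::tibble(trial = seq_len(n_tr),
                                           category = events$category,
                                           kept = kept, reason = reason)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials (%d kept) x %d channels x %d samples, [%g, %g] s\n",
              dim(x$data)[1], sum(x$metadata$kept), dim(x$data)[2], dim(x$data)[3],
              min(x$times), max(x$times) + 1 / x$fs))
  invisible(x)
}

#' Keep only clean trials of an epoch_set
#' @param epochs an `epoch_set`.
#' @return `epoch_set` restricted to `kept` trials.
#' @export
kept_epochs <- function(epochs) {
  keep <- which(epochs$metadata$kept)
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$metadata <- epochs$metadata[keep, ]
  epochs
}

#' Artifact rejection: amplitude threshold + joint probability
#'
#' Trials with any sample beyond `abs_thresh_uv` are flagged "amplitude".
#' Joint-probability rejection flags epochs whose samples are collectively
#' improbable under the empirical distribution across epochs: per channel the
#' summed negative log of histogram-estimated sample probabilities, z-scored
#' across epochs, thresholded at `jp_single_sd` for single channels and
#' `jp_global_sd` for the all-channel pooled signal. Sample values are never
#' modified, only flags.
#'
#' @param epochs an `epoch_set` (>= 5 kept trials).
#' @param abs_thresh_uv absolute voltage threshold in microvolts.
#' @param jp_single_sd,jp_global_sd z thresholds for single-channel and
#'   global joint probability.
#' @param n_bins histogram bins for the empirical density.
#' @return list: `epochs` (flags updated) and `report` tibble (trial, reason).
#' @export
reject_epochs <- function(epochs, abs_thresh_uv = 500, jp_single_sd = 6,
                          jp_global_sd = 2, n_bins = 50) {
  keep0 <- which(epochs$metadata$kept)
  if (length(keep0) < 5) abort("need at least 5 trials for joint-probability statistics")
  dat <- epochs$data[keep0, , , drop = FALSE]
  n_tr <- dim(dat)[1]; n_ch <- dim(dat)[2]
  amp_bad <- apply(dat, 1, function(tr) any(abs(tr) > abs_thresh_uv))

  improb <- matrix(0, n_tr, n_ch)
  for (c_ in seq_len(n_ch)) {
    all_v <- as.numeric(dat[, c_, ])
    br <- seq(min(all_v), max(all_v), length.out = n_bins + 1)
    dens <- tabulate(findInterval(all_v, br, all.inside = TRUE), n_bins) / length(all_v)
    dens <- pmax(dens, 1e-12)
    for (t_ in seq_len(n_tr)) {
      idx <- findInterval(dat[t_, c_, ], br, all.inside = TRUE)
      improb[t_, c_] <- -sum(log(dens[idx]))
    }
  }
  # one-sided: only unusually improbable epochs are artifacts
  zs <- scale(improb)
  single_bad <- apply(zs, 1, max) > jp_single_sd
  glob <- rowSums(improb)
  zg <- as.numeric(scale(glob))
  global_bad <- zg > jp_global_sd

  md <- epochs$metadata
  reasons <- dplyr::case_when(amp_bad ~ "amplitude",
                              single_bad ~ "jointprob",
                              global_bad ~ "jointprob_global",
                              TRUE ~ NA_character_)
  bad <- !is.na(reasons)
  md$kept[keep0[bad]] <- FALSE
  md$reason[keep0[bad]] <- reasons[bad]
  epochs$metadata <- md
  list(epochs = epochs,
       report = tibble::tibble(trial = keep0[bad], reason = reasons[bad]))
}

#' Hjorth parameters of a signal segment
#'
#' Activity (variance), mobility (`sqrt(var(dx)/var(x)) * fs`, rad/s) and
#' complexity (mobility of the derivative over mobility of the signal). For a
#' pure sinusoid at f Hz mobility approximates `2*pi*f` and complexity 1.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @return named numeric vector: activity, mobility, complexity.
#' @export
hjorth_params <- function(x, fs) {
  dx <- diff(x); ddx <- diff(dx)
  v0 <- var(x); v1 <- var(dx); v2 <- var(ddx)
  mob <- sqrt(v1 / v0) * fs
  c(activity = v0, mobility = mob, complexity = sqrt(v2 / v1) / sqrt(v1 / v0))
}

#' Two-iteration Hjorth artifact pass over stage-masked data
#'
#' Epochs the stage-masked signal into hypnogram-aligned 30-s segments,
#' computes the three Hjorth parameters per epoch and channel, and applies
#' the screening rule: a channel deviating from its mean by more than
#' `3 * SD` in any parameter for at least 25% of epochs is interpolated
#' globally; epochs where more than 50% of channels deviate are removed;
#' remaining deviant channels are interpolated epoch-by-epoch. The whole
#' pass runs twice.
#'
#' @param rec an [eeg_recording()].
#' @param hyp a [hypnogram()].
#' @param stages stages to analyze (e.g. c("N2","N3")).
#' @param epoch_len_s segment length, aligned to hypnogram epochs.
#' @param iterations number of passes.
#' @param z_thresh deviation threshold in SD units.
#' @param montage channel positions for spherical-spline interpolation;
#'   channels without a position (or < 4 good channels) are flagged but left
#'   unmodified.
#' @return list: `recording` (interpolations applied), `epoch_mask` (logical
#'   over analyzed epochs; TRUE = clean), `epochs` (tibble mapping analyzed
#'   epochs to hypnogram epochs), `report` tibble of actions.
#' @export
hjorth_artifact_pass <- function(rec, hyp, stages = c("N2", "N3"),
                                 epoch_len_s = 30, iterations = 2,
                                 z_thresh = 3, montage = default_montage()) {
  fs <- rec$fs
  spe <- as.integer(epoch_len_s * fs)
  ep_idx <- which(hyp$stage %in% stages &
                    (hyp$epoch_index + 1L) * spe <= n_samples(rec))
  if (!length(ep_idx)) abort("no clean data: stage-masked data is empty")
  n_ep <- length(ep_idx); n_ch <- length(rec$channels)
  data <- rec$data
  mask <- rep(TRUE, n_ep)
  actions <- list()

  for (it in seq_len(iterations)) {
    H <- array(NA_real_, c(n_ep, n_ch, 3))
    for (e in seq_len(n_ep)) {
      a <- (ep_idx[e] - 1L) * spe + 1L
      seg <- data[, a:(a + spe - 1L), drop = FALSE]
      for (c_ in seq_len(n_ch)) H[e, c_, ] <- hjorth_params(seg[c_, ], fs)
    }
    bad <- matrix(FALSE, n_ep, n_ch)
    for (p in 1:3) {
      hp <- H[, , p, drop = FALSE][, , 1]
      if (n_ep == 1) hp <- matrix(hp, 1, n_ch)
      mu <- colMeans(hp[mask, , drop = FALSE])
      sdv <- apply(hp[mask, , drop = FALSE], 2, sd)
      bad <- bad | sweep(abs(sweep(hp, 2, mu)), 2, pmax(sdv, 1e-12) * z_thresh) > 0
    }
    bad[!mask, ] <- FALSE
    frac_bad_ch <- colMeans(bad[mask, , drop = FALSE])
    glob_bad_ch <- which(frac_bad_ch >= 0.25)
    good_ch <- setdiff(seq_len(n_ch), glob_bad_ch)
    for (c_ in glob_bad_ch) {
      data <- interp_into(data, rec$channels, c_, good_ch, montage)
      actions[[length(actions) + 1]] <- tibble::tibble(
        iteration = it, action = "interpolate_global",
        channel = rec$channels[c_], epoch = NA_integer_)
      bad[, c_] <- FALSE
    }
    frac_bad_ep <- rowMeans(bad)
    drop_ep <- which(mask & frac_bad_ep > 0.5)
    if (length(drop_ep)) {
      mask[drop_ep] <- FALSE
      actions[[length(actions) + 1]] <- tibble::tibble(
        iteration = it, action = "remove_epoch", channel = NA_character_,
        epoch = ep_idx[drop_ep])
    }
    for (e in which(mask)) {
      bc <- which(bad[e, ])
      if (!length(bc)) next
      a <- (ep_idx[e] - 1L) * spe + 1L
      seg <- data[, a:(a + spe - 1L), drop = FALSE]
      gc <- setdiff(seq_len(n_ch), bc)
      for (c_ in bc) {
        seg <- interp_into(seg, rec$channels, c_, gc, montage)
        actions[[length(actions) + 1]] <- tibble::tibble(
          iteration = it, action = "interpolate_epoch",
          channel = rec$channels[c_], epoch = ep_idx[e])
      }
      data[, a:(a + spe - 1L)] <- seg
    }
  }
  if (!any(mask)) abort("no clean data: all epochs removed")
  list(recording = eeg_recording(data, fs, rec$channels, rec$reference,
                                 rec$annotations),
       epoch_mask = mask,
       epochs = tibble::tibble(epoch_index = hyp$epoch_index[ep_idx],
                               stage = hyp$stage[ep_idx], clean = mask),
       report = if (length(actions)) dplyr::bind_rows(actions) else
         tibble::tibble(iteration = integer(), action = character(),
                        channel = character(), epoch = integer()))
}

# Replace channel `bad_i` of a channels x samples matrix by its
# spherical-spline estimate from `good_i`; silently returns the input when
# positions are missing or fewer than 4 good channels are available.
interp_into <- function(data, labels, bad_i, good_i, montage) {
  pos <- montage_positions(labels, montage)
  ok <- good_i[!is.na(pos$x[good_i])]
  if (length(ok) < 4 || is.na(pos$x[bad_i])) return(data)
  est <- spherical_spline_interp(
    as.matrix(pos[ok, c("x", "y", "z")]),
    as.matrix(pos[bad_i, c("x", "y", "z"), drop = FALSE]),
    data[ok, , drop = FALSE])
  data[bad_i, ] <- est
  data
}
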