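#' Welch power spectral density
#'
#' Averaged Hamming-windowed periodograms (default 5 s windows, 50% overlap),
#' one-sided density in uV^2/Hz. With `derivative = TRUE` the PSD is computed
#' on the first difference of the signal scaled by `fs` — a whitening step
#' that suppresses the 1/f trend and sharpens spectral peaks for peak
#' detection.
#'
#' @param x numeric vector, or an [eeg_recording()] (all channels).
#' @param fs sampling rate in Hz (taken from the recording if given one).
#' @param win_s window length in seconds.
#' @param overlap fractional overlap between windows.
#' @param derivative estimate on the derivative of the series.
#' @param channel label used in the output when `x` is a vector.
#' @return tibble (class `psd`) with columns channel, freq, power; attributes
#'   `fs`, `win_s`, `derivative`, `normalized`.
#' @export
welch_psd <- function(x, fs = NULL, win_s = 5, overlap = 0.5,
                      derivative = FALSE, channel = "sig") {
  if (inherits(x, "eeg_recording")) {
    out <- purrr::map_dfr(x$channels, function(ch) {
      welch_psd(get_channel(x, ch), x$fs, win_s, overlap, derivative, channel = ch)
    })
    return(as_psd(out, fs = x$fs, win_s = win_s, derivative = derivative))
  }
  if (is.null(fs)) abort("`fs` required for vector input")
  if (derivative) x <- diff(x) * fs
  L <- as.integer(round(win_s * fs))
  if (length(x) < L) abort("signal shorter than one Welch window")
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, L - 1) / (L - 1))  # Hamming
  U <- sum(w^2)
  n_f <- L %/% 2 + 1L
  acc <- numeric(n_f)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    X <- stats::fft(seg)[seq_len(n_f)]
    acc <- acc + Mod(X)^2
  }
  pxx <- acc / (length(starts) * U * fs)
  pxx[2:(n_f - 1L)] <- 2 * pxx[2:(n_f - 1L)]  # one-sided
  freq <- (seq_len(n_f) - 1) * fs / L
  as_psd(tibble::tibble(channel = channel, freq = freq, power = pxx),
         fs = fs, win_s = win_s, derivative = derivative)
}

as_psd <- function(tbl, fs, win_s, derivative, normalized = FALSE) {
  tbl <- tibble::as_tibble(tbl)
  class(tbl) <- unique(c("psd", class(tbl)))
  attr(tbl, "fs") <- fs; attr(tbl, "win_s") <- win_s
  attr(tbl, "derivative") <- derivative; attr(tbl, "normalized") <- normalized
  tbl
}

#' Locate the most prominent spectral peak inside a band
#'
#' Finds local maxima of the PSD inside the band and returns the one with the
#' greatest topographic prominence (peak height minus the higher of the two
#' flanking minima, searched in the band widened by 1 Hz so peaks near a band
#' edge keep their full prominence); ties break toward higher prominence then
#' lower frequency. With no in-band local maximum the band midpoint is returned
#' with `fallback_used = TRUE`. Canonical bands: fast spindle 12.5-16 Hz,
#' theta 3-8 Hz.
#'
#' @param psd a `psd` tibble from [welch_psd()].
#' @param band length-2 numeric band in Hz.
#' @return tibble with one row per channel: channel, peak_freq, prominence,
#'   band_lo, band_hi, fallback_used.
#' @export
find_spectral_peak <- function(psd, band = c(12.5, 16)) {
  if (band[1] < min(psd$freq) || band[2] > max(psd$freq)) {
    abort("band outside the PSD's frequency support")
  }
  pad <- 1
  purrr::map_dfr(split(psd, psd$channel), function(d) {
    d <- d[order(d$freq), ]
    wide <- d$freq >= band[1] - pad & d$freq <= band[2] + pad
    f <- d$freq[wide]; p <- d$power[wide]
    inb <- f >= band[1] & f <= band[2]
    n <- length(p)
    is_max <- if (n >= 3) {
      c(FALSE, p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] >= p[3:n], FALSE)
    } else rep(FALSE, n)
    is_max <- is_max & inb
    if (!any(is_max)) {
      return(tibble::tibble(channel = d$channel[1],
                            peak_freq = mean(band), prominence = NA_real_,
                            band_lo = band[1], band_hi = band[2],
                            fallback_used = TRUE))
    }
    idx <- which(is_max)
    prom <- vapply(idx, function(i) {
      left <- if (i > 1) min(p[1:(i - 1)]) else p[i]
      right <- if (i < n) min(p[(i + 1):n]) else p[i]
      p[i] - max(left, right)
    }, 0)
    best <- idx[order(-prom, f[idx])][1]
    tibble::tibble(channel = d$channel[1], peak_freq = f[best],
                   prominence = prom[order(-prom, f[idx])][1],
                   band_lo = band[1], band_hi = band[2], fallback_used = FALSE)
  })
}

#' Normalize a PSD by each channel's average power
#'
#' Divides power at each frequency by the channel's mean power so the
#' normalized spectrum averages exactly 1 — removing between-participant
#' amplitude differences (skull thickness, gyral folding) before band-power
#' comparison.
#'
#' @param psd a `psd` tibble.
#' @return normalized `psd` tibble (attribute `normalized = TRUE`).
#' @export
normalize_psd <- function(psd) {
  out <- dplyr::group_by(psd, .data$channel)
  mp <- dplyr::summarise(out, m = mean(.data$power))$m
  if (any(mp <= 0)) abort("zero-power channel cannot be normalized")
  out <- dplyr::mutate(out, power = .data$power / mean(.data$power))
  out <- dplyr::ungroup(out)
  as_psd(out, attr(psd, "fs"), attr(psd, "win_s"), attr(psd, "derivative"),
         normalized = TRUE)
}

#' Mean band power around an individualized peak
#'
#' Averages (normalized) power over `[peak - half_width, peak + half_width]`
#' Hz, clipped to the PSD's frequency support; clipping is recorded.
#'
#' @param psd a `psd` tibble.
#' @param peak_freq peak frequency in Hz (scalar, or one per channel in the
#'   order of `unique(psd$channel)`).
#' @param half_width half-width of the band in Hz.
#' @return tibble: channel, band_power, band_lo, band_hi, clipped.
#' @export
band_power_around_peak <- function(psd, peak_freq, half_width = 1.5) {
  chans <- unique(psd$channel)
  peaks <- if (length(peak_freq) == 1) rep(peak_freq, length(chans)) else peak_freq
  stopifnot(length(peaks) == length(chans))
  purrr::map2_dfr(chans, peaks, function(ch, pk) {
    d <- psd[psd$channel == ch, ]
    lo <- pk - half_width; hi <- pk + half_width
    clipped <- lo < min(d$freq) || hi > max(d$freq)
    lo <- max(lo, min(d$freq)); hi <- min(hi, max(d$freq))
    sel <- d$freq >= lo & d$freq <= hi
    if (!any(sel)) abort("empty band after clipping to the PSD support")
    tibble::tibble(channel = ch, band_power = mean(d$power[sel]),
                   band_lo = lo, band_hi = hi, clipped = clipped)
  })
}

#' @export
autoplot.psd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq, y = .data$power,
                                       colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = if (isTRUE(attr(object, "normalized"))) "Relative power"
                      else expression(paste("Power (", mu, V^2, "/Hz)")),
                  colour = "Channel") +
    ggplot2::theme_minimal()
}
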