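# Shared fixture builders: everything is generated in code at test time.

fix_recording <- function(n_ch = 3, n_samp = 1000, fs = 250, seed = 1) {
  withr::with_seed(seed, {
    eeg_recording(matrix(rnorm(n_ch * n_samp, sd = 10), n_ch, n_samp),
                  fs = fs, channels = paste0("ch", seq_len(n_ch)))
  })
}

# Sinusoid recording on named channels
sine_recording <- function(freq, fs = 250, dur_s = 10, amp = 50,
                           channels = "Cz") {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  data <- matrix(rep(amp * sin(2 * pi * freq * t), length(channels)),
                 nrow = length(channels), byrow = TRUE)
  eeg_recording(data, fs, channels)
}

# log-log PSD slope over a frequency band, via Welch fit
psd_slope <- function(x, fs, band = c(1, 40), derivative = FALSE) {
  psd <- welch_psd(x, fs, derivative = derivative)
  d <- psd[psd$freq >= band[1] & psd$freq <= band[2], ]
  unname(coef(lm(log10(power) ~ log10(freq), data = d))[2])
}

# onset-tolerance recall/precision between detected and true event tables
event_recall <- function(det_onsets, true_onsets, tol = 0.25) {
  if (!length(true_onsets)) return(NA_real_)
  mean(vapply(true_onsets,
              function(o) any(abs(det_onsets - o) <= tol), TRUE))
}
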