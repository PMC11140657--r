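#' Simulation configuration for a synthetic TMR session
#'
#' Bundles every generator parameter with defaults matching the study design
#' this package analyses: 250 Hz sampling, 1/f background, fast spindles
#' (12.5-16 Hz, >= 0.4 s), slow oscillations (0.5-1.25 Hz), von Mises
#' SO-spindle coupling, cueing blocks of 46 memory (23 negative, 23 neutral)
#' plus 6 control sounds at a 5 s inter-stimulus interval, and a recognition
#' task of 368 trials per participant.
#'
#' @param duration_s session length in seconds.
#' @param fs sampling rate in Hz.
#' @param n_channels number of EEG channels (labelled from the built-in
#'   montage, Cz first).
#' @param noise_slope 1/f exponent of the background (power ~ 1/f^slope).
#' @param background_rms_uv background RMS amplitude in microvolts.
#' @param spindle list: `rate_per_min`, `freq_range` (Hz), `duration_range`
#'   (s), `gain` (amplitude in units of background RMS), `mode`
#'   ("fixed" count or "poisson").
#' @param so list: `rate_per_min`, `freq_range` (Hz, 0.5-1.25), `gain`, `mode`.
#' @param coupling list: `fraction` of SOs carrying a coupled spindle,
#'   `mu_deg` preferred coupling phase (0 deg = SO positive peak), `kappa`
#'   von Mises concentration.
#' @param cue list: `n_memory` (split evenly negative/neutral), `n_control`,
#'   `isi_s`, `theta_gain`, `theta_latency_s`, `spindle_gain`,
#'   `spindle_latency_s`, `latency_jitter_s`, `p_response_memory`,
#'   `p_response_control`.
#' @param behavior list: `hit` named per-condition hit-rate means
#'   (emotion x component x cue), `fa` false-alarm means, `sd_logit`
#'   between-participant SD on the logit scale.
#' @param seed master seed; `NULL` leaves the RNG untouched.
#' @return a `sim_config` list.
#' @export
sim_config <- function(duration_s = 1200, fs = 250, n_channels = 3,
                       noise_slope = 1, background_rms_uv = 15,
                       spindle = list(), so = list(), coupling = list(),
                       cue = list(), behavior = list(), seed = NULL) {
  spindle <- utils::modifyList(list(
    rate_per_min = 4, freq_range = c(12.5, 16), center_freq = NULL,
    freq_jitter_hz = 0.5, duration_range = c(0.5, 2),
    gain = 10, mode = "fixed"), spindle)
  so <- utils::modifyList(list(
    rate_per_min = 3, freq_range = c(0.5, 1.25), gain = 10, mode = "fixed"), so)
  coupling <- utils::modifyList(list(
    fraction = 0.5, mu_deg = -30, kappa = 5), coupling)
  cue <- utils::modifyList(list(
    n_memory = 46, n_control = 6, isi_s = 5,
    theta_gain = 2, theta_latency_s = 0.69, theta_freq = 5.5,
    theta_duration_s = 0.5,
    spindle_gain = 2, spindle_latency_s = 1.05, spindle_freq = 13.5,
    spindle_duration_s = 0.6, latency_jitter_s = 0.05,
    p_response_memory = 0.8, p_response_control = 0.2), cue)
  behavior <- utils::modifyList(default_behavior_spec(), behavior)
  stopifnot(duration_s > 0, fs > 0, n_channels >= 1,
            spindle$rate_per_min >= 0, so$rate_per_min >= 0)
  assert_prob(coupling$fraction, "coupling$fraction")
  stopifnot(coupling$kappa >= 0)
  assert_prob(c(cue$p_response_memory, cue$p_response_control), "cue response probs")
  structure(list(duration_s = duration_s, fs = fs, n_channels = n_channels,
                 noise_slope = noise_slope, background_rms_uv = background_rms_uv,
                 spindle = spindle, so = so, coupling = coupling, cue = cue,
                 behavior = behavior, seed = seed),
            class = "sim_config")
}

#' Behavioral condition means used by the generator
#'
#' Hit and false-alarm rate means per condition (emotion x component x cued /
#' uncued) with a logit-normal between-participant SD; the defaults are the
#' group means of the study design the generator emulates.
#'
#' @return list with `hit` (named vector), `fa` (named vector), `sd_logit`.
#' @export
default_behavior_spec <- function() {
  list(
    hit = c(negative.object.cued = 0.88, negative.object.uncued = 0.87,
            negative.background.cued = 0.59, negative.background.uncued = 0.58,
            neutral.object.cued = 0.77, neutral.object.uncued = 0.69,
            neutral.background.cued = 0.67, neutral.background.uncued = 0.71),
    fa = c(negative.object = 0.12, neutral.object = 0.09, background = 0.09),
    sd_logit = 0.5)
}

#' Generate 1/f background EEG
#'
#' Gaussian noise spectrally shaped so power falls as `1/f^slope`, RMS
#' calibrated per channel. Deterministic under `seed`.
#'
#' @param cfg a [sim_config()]; `duration_s`, `fs`, `n_channels`,
#'   `noise_slope`, `background_rms_uv` and `seed` are used.
#' @return an [eeg_recording()].
#' @export
gen_background <- function(cfg) {
  n <- round(cfg$duration_s * cfg$fs)
  labels <- montage_labels(cfg$n_channels)
  with_seed(child_seed(cfg$seed, 1L), {
    data <- matrix(0, cfg$n_channels, n)
    freqs <- c(0, seq_len(n - 1))
    freqs <- pmin(freqs, n - freqs) * cfg$fs / n  # two-sided frequency axis
    shape <- c(0, (freqs[-1])^(-cfg$noise_slope / 2))
    for (i in seq_len(cfg$n_channels)) {
      x <- stats::rnorm(n)
      y <- Re(stats::fft(stats::fft(x) * shape, inverse = TRUE)) / n
      data[i, ] <- y / sd(y) * cfg$background_rms_uv
    }
    eeg_recording(data, fs = cfg$fs, channels = labels)
  })
}

montage_labels <- function(n) {
  base <- c("Cz", "Fz", "Pz", "C3", "C4", "F3", "F4", "P3", "P4",
            "Fp1", "Fp2", "O1", "O2", "F7", "F8", "T7", "T8", "P7", "P8",
            "M1", "M2")
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("X", seq_len(n - length(base))))
}

# Place n_events non-overlapping intervals of the given durations in
# [0, duration_s); errors when the rate is infeasible.
place_events <- function(n_events, durations, duration_s, min_gap_s = 0.5) {
  if (n_events == 0) return(numeric(0))
  # uniform placement with guaranteed separation: distribute the free time
  # left after all intervals and gaps among the n_events + 1 spacings
  free <- duration_s - sum(durations) - (n_events + 1) * min_gap_s
  if (free <= 0) {
    abort("infeasible event rate: requested events cannot fit without overlap")
  }
  u <- sort(stats::runif(n_events, 0, free))
  u + min_gap_s + c(0, cumsum(durations[-n_events] + min_gap_s))
}

event_count <- function(rate_per_min, duration_s, mode) {
  lambda <- rate_per_min * duration_s / 60
  if (identical(mode, "poisson")) stats::rpois(1, lambda) else round(lambda)
}

# Per-recording spindle peak (participant trait) with small per-event
# jitter, kept inside the configured band — mirrors the individualized-peak
# premise of the detector.
resolve_spindle_center <- function(spec) {
  if (is.null(spec$center_freq)) {
    j <- spec$freq_jitter_hz %||% 0.5
    spec$center_freq <- stats::runif(1, spec$freq_range[1] + j,
                                     spec$freq_range[2] - j)
  }
  spec
}

spindle_freqs <- function(n, spec) {
  ctr <- spec$center_freq %||% mean(spec$freq_range)
  j <- spec$freq_jitter_hz %||% 0.5
  pmin(pmax(ctr + stats::runif(n, -j, j), spec$freq_range[1]),
       spec$freq_range[2])
}

spindle_wave <- function(fs, duration_s, freq, amplitude, phase = 0) {
  t <- seq(0, duration_s, by = 1 / fs)
  amplitude * hann_env(length(t)) * sin(2 * pi * freq * t + phase)
}

hann_env <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

# SO template: one period of -sin(2*pi*t/T); starts and ends at
# positive-to-negative zero crossings, trough at T/4, peak at 3T/4. The
# negative half-wave is emphasized (deeper trough than peak), as in scalp SOs.
so_wave <- function(fs, period_s, amplitude, pos_scale = 0.6) {
  t <- seq(0, period_s, by = 1 / fs)
  w <- -sin(2 * pi * t / period_s)
  w[w > 0] <- w[w > 0] * pos_scale
  amplitude * w
}

# Invert the SO template's own analytic phase: find the within-span time
# whose Hilbert phase is closest to the requested angle (0 deg = positive
# peak). The phase is read from the 0.5-4 Hz filtered template — the same
# convention the coupling measurement uses — so the emphasized-trough
# asymmetry and the delta filter's waveform reshaping cannot bias recovery;
# the boundary guard keeps the spindle peak strictly inside the span.
# Returns the offset time and the phase actually realized there.
so_phase_time <- function(period_s, fs, phi_deg, pos_scale = 0.6) {
  w <- so_wave(fs, period_s, 1, pos_scale)
  n <- length(w) - 1L  # drop duplicated endpoint
  tiled <- filter_signal(rep(w[seq_len(n)], 5), fs, "bandpass", c(0.5, 4))
  ph <- rad2deg(Arg(analytic_signal(tiled, fs)))
  mid <- ph[(2L * n + 1L):(3L * n)]
  lo <- max(2L, ceiling(0.1 * n)); hi <- min(n - 1L, floor(0.9 * n))
  idx <- lo:hi
  d <- abs(wrap_deg(mid[idx] - phi_deg))
  best <- idx[which.min(d)]
  list(t_offset = (best - 1L) / fs, phase_deg = wrap_deg(mid[best]))
}

add_packet <- function(data, fs, onset_s, wave) {
  a <- round(onset_s * fs) + 1L
  b <- a + length(wave) - 1L
  if (a < 1L || b > ncol(data)) return(data)
  for (i in seq_len(nrow(data))) data[i, a:b] <- data[i, a:b] + wave
  data
}

#' Inject spindle or slow-oscillation events into a recording
#'
#' Spindles are Hann-windowed sinusoidal bursts with per-event frequency drawn
#' inside the configured band; slow oscillations are single emphasized-trough
#' cycles bounded by positive-to-negative zero crossings. Events are injected
#' coherently on all channels; exact intervals are returned as ground truth.
#'
#' @param rec an [eeg_recording()].
#' @param kind "spindle" or "so".
#' @param spec the matching `spindle`/`so` sub-list of [sim_config()].
#' @param seed RNG seed.
#' @return list with `recording` and `truth` (tibble: kind, onset_s,
#'   offset_s, freq, amplitude).
#' @export
inject_oscillatory_events <- function(rec, kind = c("spindle", "so"), spec,
                                      seed = NULL) {
  kind <- match.arg(kind)
  dur_s <- n_samples(rec) / rec$fs
  rms <- sd(rec$data[1, ])
  with_seed(seed, {
    if (kind == "spindle") spec <- resolve_spindle_center(spec)
    n_ev <- event_count(spec$rate_per_min, dur_s, spec$mode %||% "fixed")
    if (kind == "spindle") {
      durs <- stats::runif(n_ev, spec$duration_range[1], spec$duration_range[2])
      freqs <- spindle_freqs(n_ev, spec)
    } else {
      freqs <- stats::runif(n_ev, spec$freq_range[1], spec$freq_range[2])
      durs <- 1 / freqs
    }
    onsets <- place_events(n_ev, durs, dur_s)
    amp <- spec$gain * rms
    data <- rec$data
    for (k in seq_len(n_ev)) {
      wave <- if (kind == "spindle") {
        spindle_wave(rec$fs, durs[k], freqs[k], amp)
      } else {
        so_wave(rec$fs, durs[k], amp)
      }
      data <- add_packet(data, rec$fs, onsets[k], wave)
    }
    truth <- tibble::tibble(kind = rep(kind, n_ev), onset_s = onsets,
                            offset_s = onsets + durs, freq = freqs,
                            amplitude = rep(amp, n_ev))
    list(recording = eeg_recording(data, rec$fs, rec$channels, rec$reference,
                                   rec$annotations),
         truth = truth[order(truth$onset_s), ])
  })
}

#' Inject SO-spindle coupled events
#'
#' Places slow oscillations and, for a configurable fraction, a spindle whose
#' envelope maximum sits at an SO phase drawn from von Mises(`mu_deg`,
#' `kappa`) under the convention 0 deg = SO positive peak, +/-180 deg =
#' trough. True phases are stored per coupled event.
#'
#' @param rec an [eeg_recording()].
#' @param so_spec,spindle_spec,coupling_spec sub-lists of [sim_config()].
#' @param seed RNG seed.
#' @return list with `recording`, `so_truth`, `spindle_truth`,
#'   `coupled_truth` (tibble with `phase_deg`, `spindle_peak_s`, SO interval).
#' @export
inject_coupled_events <- function(rec, so_spec, spindle_spec, coupling_spec,
                                  seed = NULL) {
  dur_s <- n_samples(rec) / rec$fs
  rms <- sd(rec$data[1, ])
  with_seed(seed, {
    spindle_spec <- resolve_spindle_center(spindle_spec)
    n_so <- event_count(so_spec$rate_per_min, dur_s, so_spec$mode %||% "fixed")
    periods <- 1 / stats::runif(n_so, so_spec$freq_range[1], so_spec$freq_range[2])
    onsets <- place_events(n_so, periods, dur_s, min_gap_s = 1.5)
    n_cpl <- round(coupling_spec$fraction * n_so)
    coupled_idx <- if (n_cpl > 0) sort(sample(n_so, n_cpl)) else integer(0)
    phases <- if (n_cpl > 0) {
      rvonmises_deg(n_cpl, coupling_spec$mu_deg, coupling_spec$kappa)
    } else numeric(0)
    data <- rec$data
    so_amp <- so_spec$gain * rms
    sp_amp <- spindle_spec$gain * rms
    sp_rows <- list()
    for (k in seq_len(n_so)) {
      data <- add_packet(data, rec$fs, onsets[k], so_wave(rec$fs, periods[k], so_amp))
    }
    cp_rows <- tibble::tibble(so_onset_s = numeric(), so_offset_s = numeric(),
                              spindle_peak_s = numeric(), phase_deg = numeric())
    for (j in seq_along(coupled_idx)) {
      k <- coupled_idx[j]
      T_ <- periods[k]
      pt <- so_phase_time(T_, rec$fs, phases[j])
      phases[j] <- pt$phase_deg
      t_peak <- onsets[k] + pt$t_offset
      sp_dur <- stats::runif(1, max(0.5, spindle_spec$duration_range[1]),
                             min(1, spindle_spec$duration_range[2]))
      sp_freq <- spindle_freqs(1, spindle_spec)
      sp_on <- t_peak - sp_dur / 2
      data <- add_packet(data, rec$fs, sp_on, spindle_wave(rec$fs, sp_dur, sp_freq, sp_amp))
      sp_rows[[j]] <- tibble::tibble(kind = "spindle", onset_s = sp_on,
                                     offset_s = sp_on + sp_dur, freq = sp_freq,
                                     amplitude = sp_amp)
      cp_rows <- dplyr::bind_rows(cp_rows, tibble::tibble(
        so_onset_s = onsets[k], so_offset_s = onsets[k] + T_,
        spindle_peak_s = t_peak, phase_deg = phases[j]))
    }
    list(recording = eeg_recording(data, rec$fs, rec$channels, rec$reference,
                                   rec$annotations),
         so_truth = tibble::tibble(kind = "so", onset_s = onsets,
                                   offset_s = onsets + periods,
                                   freq = 1 / periods, amplitude = so_amp),
         spindle_truth = dplyr::bind_rows(sp_rows),
         coupled_truth = cp_rows)
  })
}

# Deterministic hypnogram template scaled to the session length: brief wake,
# alternating N2/N3 with one mid-session arousal epoch, REM tail.
build_hypnogram <- function(duration_s) {
  n_ep <- floor(duration_s / 30)
  stages <- rep("N2", n_ep)
  if (n_ep >= 2) stages[1:2] <- "W"
  n3 <- which(seq_len(n_ep) > 0.35 * n_ep & seq_len(n_ep) <= 0.6 * n_ep)
  stages[n3] <- "N3"
  rem <- which(seq_len(n_ep) > 0.85 * n_ep)
  stages[rem] <- "REM"
  mid <- floor(0.5 * n_ep)
  if (mid > 2) stages[mid] <- "W"  # simulated arousal
  hypnogram(stages)
}

#' Generate a complete synthetic TMR session
#'
#' Produces a recording with 1/f background, endogenous SO-spindle activity,
#' a hypnogram with N2/N3/REM bouts and a mid-session arousal, and a cue log:
#' blocks of 46 memory (23 negative, 23 neutral) + 6 control sounds in random
#' order with a 5 s inter-stimulus interval, rerandomized each block,
#' restricted to N2/N3 (cueing halts across the arousal and stops at the
#' first REM epoch). Memory cues receive an additive theta transient and a
#' spindle packet with higher probability than control cues; every injected
#' response is recorded as ground truth.
#'
#' @param cfg a [sim_config()].
#' @return list with `recording`, `hypnogram`, `events` ([cue_events()]),
#'   and `truth` (list: so/spindle/coupled tibbles, `cue_responses` tibble).
#' @export
gen_tmr_session <- function(cfg) {
  rec <- gen_background(cfg)
  bg_rms <- sd(rec$data[1, ])
  # one spindle peak per session, shared by coupled and uncoupled events
  cfg$spindle <- with_seed(child_seed(cfg$seed, 5L),
                           resolve_spindle_center(cfg$spindle))
  # endogenous uncoupled spindles first (while RMS reflects the background),
  # then SOs with their coupled spindles
  sp_inj <- inject_oscillatory_events(rec, "spindle", cfg$spindle,
                                      seed = child_seed(cfg$seed, 4L))
  inj <- inject_coupled_events(sp_inj$recording, cfg$so, cfg$spindle,
                               cfg$coupling, seed = child_seed(cfg$seed, 2L))
  inj$spindle_truth <- dplyr::bind_rows(sp_inj$truth, inj$spindle_truth)
  inj$spindle_truth <- inj$spindle_truth[order(inj$spindle_truth$onset_s), ]
  rec <- inj$recording
  hyp <- build_hypnogram(cfg$duration_s)
  fs <- cfg$fs

  with_seed(child_seed(cfg$seed, 3L), {
    cue_pool <- function() {
      n_half <- cfg$cue$n_memory %/% 2
      cats <- c(rep("negative", n_half), rep("neutral", cfg$cue$n_memory - n_half),
                rep("control", cfg$cue$n_control))
      sample(cats)
    }
    first_rem <- which(hyp$stage == "REM")[1]
    stop_sample <- if (is.na(first_rem)) n_samples(rec) else (first_rem - 1L) * 30L * fs
    in_n23 <- stage_mask(hyp, c("N2", "N3"), fs, n_samples(rec))
    onsets <- integer(0); cats <- character(0); blocks <- integer(0)
    block <- 0L; pool <- cue_pool(); pool_i <- 1L
    max_t <- stop_sample - 3 * fs  # post-cue window must fit
    t <- which(in_n23)[1] %||% NA_integer_
    while (!is.na(t) && t < max_t) {
      if (in_n23[t]) {
        onsets <- c(onsets, t - 1L)  # 0-based
        cats <- c(cats, pool[pool_i]); blocks <- c(blocks, block)
        pool_i <- pool_i + 1L
        if (pool_i > length(pool)) { block <- block + 1L; pool <- cue_pool(); pool_i <- 1L }
        t <- t + as.integer(cfg$cue$isi_s * fs)
      } else {
        nxt <- which(in_n23 & seq_along(in_n23) > t)[1]
        if (is.na(nxt)) break
        t <- nxt
      }
    }
    events <- cue_events(onsets, cats, hyp$stage[onsets %/% (30L * fs) + 1L], blocks)

    # cue-evoked responses: additive theta + spindle packets, memory > control
    data <- rec$data
    resp <- vector("list", nrow(events))
    for (i in seq_len(nrow(events))) {
      p <- if (events$category[i] == "control") cfg$cue$p_response_control else cfg$cue$p_response_memory
      responded <- stats::runif(1) < p
      th_lat <- sp_lat <- NA_real_
      if (responded) {
        on_s <- events$onset_sample[i] / fs
        th_lat <- cfg$cue$theta_latency_s +
          stats::rnorm(1, 0, cfg$cue$latency_jitter_s)
        sp_lat <- cfg$cue$spindle_latency_s +
          stats::rnorm(1, 0, cfg$cue$latency_jitter_s)
        th <- spindle_wave(fs, cfg$cue$theta_duration_s, cfg$cue$theta_freq,
                           cfg$cue$theta_gain * bg_rms)
        sp <- spindle_wave(fs, cfg$cue$spindle_duration_s, cfg$cue$spindle_freq,
                           cfg$cue$spindle_gain * bg_rms)
        data <- add_packet(data, fs, on_s + th_lat - cfg$cue$theta_duration_s / 2, th)
        data <- add_packet(data, fs, on_s + sp_lat - cfg$cue$spindle_duration_s / 2, sp)
      }
      resp[[i]] <- tibble::tibble(trial = i, category = events$category[i],
                                  responded = responded,
                                  theta_latency_s = th_lat,
                                  spindle_latency_s = sp_lat)
    }
    rec <- eeg_recording(data, fs, rec$channels, rec$reference, rec$annotations)
    list(recording = rec, hypnogram = hyp, events = events,
         truth = list(so = inj$so_truth, spindle = inj$spindle_truth,
                      coupled = inj$coupled_truth,
                      cue_responses = dplyr::bind_rows(resp)))
  })
}

#' Generate a synthetic recognition-memory table
#'
#' Item-level old/new responses forming 368 recognition trials per
#' participant: 92 old objects (46 negative / 46 neutral, each split 23 cued /
#' 23 uncued), 92 old backgrounds (paired emotion, same cued split), 92 new
#' objects and 92 new backgrounds. Participant-level hit/false-alarm rates
#' are logit-normal around the configured condition means; with `sd_logit =
#' 0`, responses follow a deterministic quota so observed rates equal the
#' means up to the 1/23 trial-count quantization.
#'
#' @param n_participants number of simulated participants.
#' @param spec behavior spec (see [default_behavior_spec()]).
#' @param seed RNG seed.
#' @return tibble with columns participant, item, type (old/new), component,
#'   emotion, cue (cued/uncued/new), response ("old"/"new").
#' @export
gen_behavior <- function(n_participants, spec = default_behavior_spec(),
                         seed = NULL) {
  assert_prob(spec$hit, "behavior hit means")
  assert_prob(spec$fa, "behavior fa means")
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_participants), function(p) {
      gen_behavior_one(p, spec)
    })
  })
}

gen_behavior_one <- function(p, spec) {
  items <- dplyr::bind_rows(
    tidyr::expand_grid(type = "old", component = c("object", "background"),
                       emotion = c("negative", "neutral"),
                       cue = c("cued", "uncued"), idx = 1:23),
    tidyr::expand_grid(type = "new", component = "object",
                       emotion = c("negative", "neutral"), cue = "new", idx = 1:46),
    tidyr::expand_grid(type = "new", component = "background",
                       emotion = "neutral", cue = "new", idx = 1:92))
  shift <- if (spec$sd_logit > 0) stats::rnorm(1, 0, spec$sd_logit) else 0
  rate_for <- function(type, component, emotion, cue) {
    m <- if (type == "old") {
      spec$hit[paste(emotion, component, cue, sep = ".")]
    } else if (component == "background") {
      spec$fa["background"]
    } else {
      spec$fa[paste(emotion, component, sep = ".")]
    }
    stats::plogis(stats::qlogis(m) + shift)
  }
  items <- dplyr::group_by(items, .data$type, .data$component, .data$emotion, .data$cue)
  items <- dplyr::mutate(items, .rate = rate_for(.data$type[1], .data$component[1],
                                                 .data$emotion[1], .data$cue[1]))
  if (spec$sd_logit > 0) {
    items <- dplyr::mutate(items,
                           response = ifelse(stats::runif(dplyr::n()) < .data$.rate,
                                             "old", "new"))
  } else {
    items <- dplyr::mutate(items, response = ifelse(
      seq_len(dplyr::n()) <= round(.data$.rate[1] * dplyr::n()), "old", "new"))
  }
  items <- dplyr::ungroup(items)
  tibble::tibble(participant = p,
                 item = seq_len(nrow(items)),
                 type = items$type, component = items$component,
                 emotion = items$emotion, cue = items$cue,
                 response = items$response)
}
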