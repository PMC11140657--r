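#' EEG recording container
#'
#' A multichannel time series in microvolts: a channels x samples matrix plus
#' sampling rate, channel labels (10-20 montage names, mastoids M1/M2, EOG,
#' EMG), the current reference scheme, and free-form annotations. Sample
#' indexing is 0-based and intervals are half-open `[onset, offset)`
#' throughout the package.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channels character vector of unique channel labels, one per row.
#' @param reference label describing the current reference (default "raw").
#' @param annotations tibble with columns `onset_s`, `duration_s`, `label`
#'   (may be empty).
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels = rownames(data),
                          reference = "raw", annotations = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) abort("`fs` must be a positive scalar")
  if (is.null(channels)) abort("channel labels are required")
  channels <- as.character(channels)
  if (length(channels) != nrow(data)) abort("one label per data row required")
  if (anyDuplicated(channels)) abort("duplicate channel label")
  if (anyNA(data)) abort("recording data contains NaN/NA")
  if (is.null(annotations)) {
    annotations <- tibble::tibble(onset_s = numeric(), duration_s = numeric(),
                                  label = character())
  }
  rownames(data) <- channels
  structure(
    list(data = data, fs = fs, channels = channels,
         reference = reference, annotations = tibble::as_tibble(annotations)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), ref: %s\n",
              nrow(x$data), ncol(x$data), x$fs, n_samples(x) / x$fs, x$reference))
  cat("channels:", paste(utils::head(x$channels, 12), collapse = " "),
      if (length(x$channels) > 12) "..." else "", "\n")
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

#' Extract one channel as a numeric vector
#' @param rec an [eeg_recording()].
#' @param channel channel label.
#' @return numeric vector of samples (microvolts).
#' @export
get_channel <- function(rec, channel) {
  if (!channel %in% rec$channels) abort(sprintf("channel '%s' not present", channel))
  rec$data[channel, ]
}

#' Hypnogram constructor
#'
#' Per-30-s-epoch sleep stage labels aligned to the start of a recording.
#'
#' @param stages character vector with values in W, N1, N2, N3, REM.
#' @param epoch_length_s epoch length, fixed at 30 s by scoring convention.
#' @return tibble with columns `epoch_index` (0-based) and `stage`, class
#'   `hypnogram`, attribute `epoch_length_s`.
#' @export
hypnogram <- function(stages, epoch_length_s = 30) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), STAGES)
  if (length(bad)) abort(sprintf("unknown stage label(s): %s", paste(bad, collapse = ", ")))
  out <- tibble::tibble(epoch_index = seq_along(stages) - 1L, stage = stages)
  class(out) <- c("hypnogram", class(out))
  attr(out, "epoch_length_s") <- epoch_length_s
  out
}

#' Cue event log constructor
#'
#' @param onset_sample 0-based integer cue onsets, strictly increasing.
#' @param category one of "negative", "neutral", "control" per event.
#' @param stage sleep stage at delivery.
#' @param block 0-based cueing block index.
#' @return tibble with the four columns, class `cue_events`.
#' @export
cue_events <- function(onset_sample, category, stage, block = 0L) {
  category <- as.character(category)
  bad <- setdiff(unique(category), c("negative", "neutral", "control"))
  if (length(bad)) abort(sprintf("unknown cue category: %s", paste(bad, collapse = ", ")))
  if (is.unsorted(onset_sample, strictly = TRUE)) abort("cue onsets must be strictly increasing")
  out <- tibble::tibble(onset_sample = as.integer(onset_sample),
                        category = category,
                        stage = as.character(stage),
                        block = as.integer(block))
  class(out) <- c("cue_events", class(out))
  out
}

#' Boolean sample mask for a set of sleep stages
#'
#' Marks every sample falling inside a 30-s epoch scored as one of the
#' requested stages. Samples beyond the hypnogram's coverage are unscored and
#' always FALSE, so masks over disjoint stage sets partition the scored
#' samples.
#'
#' @param hyp a [hypnogram()].
#' @param stages character vector of stages (subset of W/N1/N2/N3/REM).
#' @param fs sampling rate in Hz.
#' @param n_samples total mask length; defaults to the samples covered by the
#'   hypnogram.
#' @return logical vector of length `n_samples`.
#' @export
stage_mask <- function(hyp, stages, fs, n_samples = NULL) {
  bad <- setdiff(stages, STAGES)
  if (length(bad)) abort(sprintf("unknown stage label(s): %s", paste(bad, collapse = ", ")))
  elen <- attr(hyp, "epoch_length_s") %||% 30
  spe <- as.integer(round(elen * fs))
  covered <- nrow(hyp) * spe
  n_samples <- n_samples %||% covered
  mask <- rep(FALSE, n_samples)
  hit <- which(hyp$stage %in% stages)
  for (i in hit) {
    a <- (i - 1L) * spe + 1L
    b <- min(i * spe, n_samples)
    if (a <= n_samples) mask[a:b] <- TRUE
  }
  mask
}
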