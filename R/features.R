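#' Labelled feature tensor for classification
#'
#' One classifier input: a real feature tensor of kind `erp`
#' (channels x time), `tf_power`, `phase_sync` or `tf_phase`
#' (channels x freqs x time), with its condition label and provenance.
#'
#' @param kind one of `"erp"`, `"tf_power"`, `"phase_sync"`, `"tf_phase"`.
#' @param tensor real feature array.
#' @param label `"rare"`, `"frequent"`, or NA for descriptive use.
#' @param participant_id provenance.
#' @param trial_ids trial indices the feature was computed from.
#' @param times,freqs axis metadata (ms, Hz).
#' @return object of class `feature_sample`.
#' @export
feature_sample <- function(kind, tensor, label = NA_character_,
                           participant_id = NA_character_,
                           trial_ids = integer(), times = NULL, freqs = NULL) {
  kind <- match.arg(kind, c("erp", "tf_power", "phase_sync", "tf_phase"))
  if (!all(is.finite(tensor))) stop("feature tensor contains non-finite values")
  structure(list(kind = kind, tensor = tensor, label = label,
                 participant_id = participant_id, trial_ids = trial_ids,
                 times = times, freqs = freqs),
            class = "feature_sample")
}

#' @export
print.feature_sample <- function(x, ...) {
  cat(sprintf("<feature_sample %s [%s] %s: %s>\n", x$kind,
              paste(dim(x$tensor) %||% length(x$tensor), collapse = " x "),
              x$participant_id, x$label))
  invisible(x)
}

#' Average ERP over a subset of trials
#'
#' Arithmetic mean of the selected epochs, then per-channel baseline
#' correction.
#'
#' @param rec an [epoched_recording].
#' @param trial_subset trial indices (default: all trials).
#' @param baseline a [baseline_spec()].
#' @param label condition label attached to the sample.
#' @return a [feature_sample()] of kind `erp` (channels x time, microvolts).
#' @export
compute_erp <- function(rec, trial_subset = NULL, baseline = baseline_spec(),
                        label = NA_character_) {
  trial_subset <- trial_subset %||% seq_len(dim(rec$data)[1])
  if (length(trial_subset) == 0) stop("trial subset is empty")
  avg <- colMeans(rec$data[trial_subset, , , drop = FALSE], dims = 1)
  tens <- baseline_correct(avg, rec_times(rec), baseline)
  feature_sample("erp", tens, label, rec$participant_id,
                 trial_ids = as.integer(trial_subset), times = rec_times(rec))
}

#' Time-frequency amplitude ("TF power")
#'
#' The modulus (amplitude, not its square) of the complex wavelet
#' coefficients. With `average = TRUE`, the per-trial amplitude is averaged
#' over the subset and then baseline-corrected per channel and frequency;
#' with `average = FALSE` each trial's amplitude is baselined individually
#' and the per-trial array is returned.
#'
#' @param dec a [cwt()] decomposition.
#' @param trial_subset trial indices (default: all).
#' @param baseline a [baseline_spec()], or NULL to skip baselining.
#' @param average average over the subset (default TRUE).
#' @param label condition label.
#' @return `average = TRUE`: a [feature_sample()] of kind `tf_power`
#'   (channels x freqs x time); otherwise a numeric array
#'   (trials x channels x freqs x time) of per-trial baselined amplitude.
#' @export
tf_power <- function(dec, trial_subset = NULL, baseline = baseline_spec(),
                     average = TRUE, label = NA_character_) {
  trial_subset <- trial_subset %||% seq_len(dim(dec$coeffs)[1])
  if (length(trial_subset) == 0) stop("trial subset is empty")
  amp <- Mod(dec$coeffs[trial_subset, , , , drop = FALSE])
  if (average) {
    tens <- colMeans(amp, dims = 1)
    if (!is.null(baseline))
      tens <- baseline_correct(tens, dec$times, baseline)
    feature_sample("tf_power", tens, label, dec$participant_id,
                   trial_ids = as.integer(trial_subset),
                   times = dec$times, freqs = dec$freqs)
  } else {
    if (is.null(baseline)) amp
    else baseline_correct(amp, dec$times, baseline)
  }
}

#' Single-trial wavelet phase
#'
#' The angle of the complex coefficients in `(-pi, pi]` (a real negative
#' coefficient maps to `pi`). Not baseline-subtracted: angles are not
#' additive offsets.
#'
#' @param dec a [cwt()] decomposition.
#' @param trial trial index.
#' @param label condition label.
#' @return a [feature_sample()] of kind `tf_phase` (channels x freqs x time).
#' @export
tf_phase <- function(dec, trial, label = NA_character_) {
  stopifnot(length(trial) == 1, trial >= 1, trial <= dim(dec$coeffs)[1])
  tens <- Arg(dec$coeffs[trial, , , ])
  dim(tens) <- dim(dec$coeffs)[2:4]
  feature_sample("tf_phase", tens, label, dec$participant_id,
                 trial_ids = as.integer(trial),
                 times = dec$times, freqs = dec$freqs)
}

N_PHASE_BINS <- 10L

#' The 10-bin cross-trial phase-synchronization statistic for one phase set
#'
#' Partitions `(-pi, pi]` into 10 equal half-open bins (a phase of exactly
#' `-pi` falls in bin 1), forms the bin probabilities `p_i = count_i / n`,
#' and returns `sqrt(sum((p_i - mu)^2) / 10)` with `mu = 0.1`. 0 for a
#' perfectly uniform histogram, 0.3 when all phases share one bin.
#'
#' @param phases numeric vector of phases (radians).
#' @return the statistic, in `[0, 0.3]`.
#' @export
phase_sync_stat <- function(phases) {
  n <- length(phases)
  if (n < 2) stop("need at least 2 trials for cross-trial phase synchronization")
  w <- 2 * pi / N_PHASE_BINS
  b <- pmin(pmax(ceiling((phases + pi) / w), 1L), N_PHASE_BINS)
  p <- tabulate(b, N_PHASE_BINS) / n
  sqrt(sum((p - 1 / N_PHASE_BINS)^2) / N_PHASE_BINS)
}

#' Cross-trial phase synchronization over time and frequency
#'
#' At every (channel, frequency, time) point the phases of the selected
#' trials are collected, binned into 10 equal bins over `(-pi, pi]`, and the
#' spread of the bin probabilities `sqrt(sum((p_i - mu)^2)/10)` is taken as
#' the synchronization index; the result is then baseline-corrected per
#' channel and frequency.
#'
#' @param dec a [cwt()] decomposition.
#' @param trial_subset trial indices, at least 2 (default: all).
#' @param baseline a [baseline_spec()], or NULL to skip baselining.
#' @param label condition label.
#' @return a [feature_sample()] of kind `phase_sync`
#'   (channels x freqs x time).
#' @export
phase_synchronization <- function(dec, trial_subset = NULL,
                                  baseline = baseline_spec(),
                                  label = NA_character_) {
  trial_subset <- trial_subset %||% seq_len(dim(dec$coeffs)[1])
  n <- length(trial_subset)
  if (n < 2) stop("need at least 2 trials for cross-trial phase synchronization")
  ph <- Arg(dec$coeffs[trial_subset, , , , drop = FALSE])
  w <- 2 * pi / N_PHASE_BINS
  bins <- pmin(pmax(ceiling((ph + pi) / w), 1L), N_PHASE_BINS)
  mu <- 1 / N_PHASE_BINS
  ss <- 0
  for (i in seq_len(N_PHASE_BINS)) {
    p_i <- colSums(bins == i, dims = 1) / n
    ss <- ss + (p_i - mu)^2
  }
  tens <- sqrt(ss / N_PHASE_BINS)
  if (!is.null(baseline))
    tens <- baseline_correct(tens, dec$times, baseline)
  feature_sample("phase_sync", tens, label, dec$participant_id,
                 trial_ids = as.integer(trial_subset),
                 times = dec$times, freqs = dec$freqs)
}

#' Crop the trailing time axis of a feature tensor
#'
#' Used to restrict classifier inputs to an interior analysis window (the
#' default experiment crop is \[-500, 1500\] ms) away from epoch edges.
#'
#' @param x array whose last axis is time.
#' @param times ms per sample of the trailing axis.
#' @param window `c(t0, t1)` ms, inclusive.
#' @return list with the cropped array `x` and the cropped `times`.
#' @export
crop_time <- function(x, times, window) {
  sel <- times >= window[1] & times <= window[2]
  if (!any(sel)) stop("crop window contains no samples")
  dm <- dim(x)
  m <- matrix(x, ncol = length(times))[, sel, drop = FALSE]
  dim(m) <- c(dm[-length(dm)], sum(sel))
  list(x = m, times = times[sel])
}
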