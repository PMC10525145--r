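#' Epoched EEG recording
#'
#' Container for stimulus-locked EEG epochs from one participant: a
#' trials x channels x time voltage tensor (microvolts) with its sampling
#' rate, epoch window and per-trial condition labels.
#'
#' @param data numeric array, `(n_trials, n_channels, n_samples)`, microvolts.
#' @param srate sampling rate, Hz.
#' @param window epoch window `c(t_start, t_end)` in ms relative to event
#'   onset; must straddle the onset (`t_start < 0 < t_end`).
#' @param labels character vector of per-trial condition tags, each
#'   `"rare"` or `"frequent"`.
#' @param channel_names electrode labels; defaults to `ch01, ch02, ...`.
#' @param participant_id identifier string.
#' @return an object of class `epoched_recording`.
#' @export
epoched_recording <- function(data, srate, window, labels,
                              channel_names = NULL, participant_id = "P000") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (trials, channels, samples)")
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("`data` contains non-finite voltages")
  window <- as.numeric(window)
  if (!(window[1] < 0 && window[2] > 0))
    stop("epoch window must straddle the event onset (t_start < 0 < t_end)")
  n_exp <- n_epoch_samples(window, srate)
  if (dim(data)[3] != n_exp)
    stop(sprintf("data has %d time samples but window/srate imply %d",
                 dim(data)[3], n_exp))
  labels <- as.character(labels)
  if (length(labels) != dim(data)[1])
    stop("length(labels) must equal the number of trials")
  if (!all(labels %in% c("rare", "frequent")))
    stop("labels must be 'rare' or 'frequent'")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(dim(data)[2]))
  if (length(channel_names) != dim(data)[2])
    stop("channel_names length must equal the number of channels")
  structure(
    list(data = data, srate = as.numeric(srate), window = window,
         labels = labels, channel_names = as.character(channel_names),
         participant_id = as.character(participant_id)),
    class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoched_recording %s: %d trials (%d rare / %d frequent), %d channels, %d samples @ %g Hz, [%g, %g] ms>\n",
    x$participant_id, d[1], sum(x$labels == "rare"),
    sum(x$labels == "frequent"), d[2], d[3], x$srate,
    x$window[1], x$window[2]))
  invisible(x)
}

#' Time axis of an epoched recording (ms)
#' @param rec an [epoched_recording].
#' @export
rec_times <- function(rec) epoch_times(rec$window, rec$srate)

#' Cut stimulus-locked epochs out of a continuous recording
#'
#' Trial i contains the inclusive sample range
#' `onset_i + round(t_start/1000 * srate)` ...
#' `onset_i + round(t_start/1000 * srate) + n_samples - 1`.
#' Events whose window would fall outside the record are dropped with a
#' warning; if no event survives, an error is raised.
#'
#' @param signal numeric matrix, channels x samples, microvolts.
#' @param srate sampling rate, Hz.
#' @param events data frame with columns `onset_sample` (1-based sample index
#'   of the event, strictly increasing) and `label`.
#' @param window epoch window `c(t_start, t_end)` in ms.
#' @param channel_names,participant_id passed to [epoched_recording()].
#' @return an [epoched_recording].
#' @export
epoch_continuous <- function(signal, srate, events, window,
                             channel_names = NULL, participant_id = "P000") {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1)
  stopifnot(is.data.frame(events),
            all(c("onset_sample", "label") %in% names(events)))
  onset <- as.integer(events$onset_sample)
  if (any(diff(onset) <= 0)) stop("event onsets must be strictly increasing")
  n_s <- n_epoch_samples(window, srate)
  k0 <- as.integer(round(window[1] / 1000 * srate))
  first <- onset + k0
  last <- first + n_s - 1L
  ok <- first >= 1L & last <= ncol(signal)
  if (any(!ok))
    warning(sprintf("dropping %d event(s) too close to the record edge",
                    sum(!ok)))
  if (!any(ok)) stop("no event fits inside the continuous record")
  keep <- which(ok)
  data <- array(0, c(length(keep), nrow(signal), n_s))
  for (i in seq_along(keep)) {
    idx <- first[keep[i]]:last[keep[i]]
    data[i, , ] <- signal[, idx, drop = FALSE]
  }
  epoched_recording(data, srate, window,
                    labels = as.character(events$label)[keep],
                    channel_names = channel_names,
                    participant_id = participant_id)
}

#' Baseline specification
#'
#' Pre-stimulus window whose mean is subtracted from each trace or
#' time-frequency series. Default `c(-200, 0)` ms, endpoint at 0 included.
#'
#' @param window `c(b_start, b_end)` in ms; requires `b_start < b_end <= 0`.
#' @return numeric length-2 vector of class `baseline_spec`.
#' @export
baseline_spec <- function(window = c(-200, 0)) {
  window <- as.numeric(window)
  if (!(window[1] < window[2] && window[2] <= 0))
    stop("baseline window must satisfy b_start < b_end <= 0")
  structure(window, class = "baseline_spec")
}

#' Subtract the pre-stimulus baseline mean
#'
#' For every leading index of `x` (trial, channel, frequency, ...), subtracts
#' the mean over the baseline samples of the trailing time axis, so that the
#' baseline mean of the output is 0. Idempotent.
#'
#' @param x numeric array whose *last* axis is time.
#' @param times time in ms for each sample of the trailing axis.
#' @param baseline a [baseline_spec()] or length-2 ms window.
#' @return array of the same shape as `x`.
#' @export
baseline_correct <- function(x, times, baseline = baseline_spec()) {
  baseline <- as.numeric(baseline)
  dm <- dim(x) %||% length(x)
  n_t <- dm[length(dm)]
  if (length(times) != n_t)
    stop("`times` must match the trailing (time) axis of `x`")
  sel <- times >= baseline[1] & times <= baseline[2]
  if (!any(sel)) stop("baseline window contains no samples")
  m <- matrix(x, ncol = n_t)                 # time is the slowest axis
  mu <- rowMeans(m[, sel, drop = FALSE])
  out <- m - mu
  dim(out) <- dm
  out
}
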