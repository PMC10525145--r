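#' Derive a reproducible sub-stream seed
#'
#' Combines a master seed with one or more integer tags (participant index,
#' source index, stage number, ...) into a new seed, so that independent
#' stages of a pipeline can be re-run in isolation while remaining a pure
#' function of the master seed.
#'
#' @param seed master seed (integer).
#' @param ... integer tags identifying the sub-stream.
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
substream_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  s <- as.double(seed %% m)
  for (x in c(...)) {
    # LCG-style mixing; multipliers kept small enough that the product of
    # doubles stays exactly representable
    s <- (s * 48271 + (as.double(x) + 1) * 16807) %% m
    s <- (s * 69621) %% m
  }
  as.integer(s %% (m - 2L)) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ef_log <- function(verbose, ...) {
  if (isTRUE(verbose)) message(sprintf(...))
}

#' Time axis of an epoch
#'
#' @param window epoch window `c(t_start, t_end)` in ms relative to onset.
#' @param srate sampling rate in Hz.
#' @return vector of sample times in ms, both endpoints included.
#' @export
epoch_times <- function(window, srate) {
  n <- n_epoch_samples(window, srate)
  window[1] + (seq_len(n) - 1) * 1000 / srate
}

#' Number of samples in an epoch window
#'
#' Inclusive-endpoint convention: sample k corresponds to
#' `t_start + k * 1000/srate` ms, and both window endpoints are sampled
#' (451 samples for a \[-1000, 2000\] ms window at 150 Hz).
#'
#' @inheritParams epoch_times
#' @return integer sample count.
#' @export
n_epoch_samples <- function(window, srate) {
  as.integer(round((window[2] - window[1]) / 1000 * srate)) + 1L
}
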