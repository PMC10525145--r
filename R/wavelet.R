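#' Complex Morlet analysis specification
#'
#' Mother wavelet `psi(t) = (pi*fb)^(-1/2) * exp(-t^2/fb) * exp(i*2*pi*t)`
#' (bandwidth parameter `fb` = the time-decay parameter, centre frequency
#' 1 Hz), dilated to analysis frequency `f` by the scale `a = 1/f`, so that
#' `1/a` is proportional to frequency. The default decay of 0.5 balances time
#' against frequency resolution for slow cortical rhythms (envelope SD
#' `0.5/f` s, i.e. half a cycle).
#'
#' @param freqs analysis frequencies, Hz; each must lie in `(0, srate/2)`.
#' @param srate sampling rate, Hz.
#' @param decay time-decay (bandwidth) parameter `fb`, s^2; default 0.5.
#' @return object of class `wavelet_spec`.
#' @export
wavelet_spec <- function(freqs, srate, decay = 0.5) {
  freqs <- as.numeric(freqs)
  if (decay <= 0) stop("decay must be positive")
  if (any(freqs <= 0) || any(freqs >= srate / 2))
    stop("all analysis frequencies must lie in (0, srate/2)")
  structure(list(freqs = freqs, srate = as.numeric(srate),
                 decay = as.numeric(decay)),
            class = "wavelet_spec")
}

KERNEL_TRUNC <- 1e-5  # envelope cutoff relative to its peak

#' Sampled complex Morlet kernel at one frequency
#'
#' Returns the dilated wavelet `psi_f(t) = psi(t/a)`, `a = 1/f`, sampled at
#' the spec's rate and truncated where the Gaussian envelope falls below
#' 1e-5 of its peak. The kernel value at t = 0 is real and positive.
#'
#' @param f analysis frequency, Hz.
#' @param spec a [wavelet_spec()].
#' @return list with complex `values`, sample times `t` (s), `scale` `a`,
#'   and `half` (one-sided length in samples).
#' @export
morlet_kernel <- function(f, spec) {
  if (f >= spec$srate / 2) stop("frequency at or above Nyquist")
  a <- 1 / f
  half <- ceiling(a * sqrt(spec$decay * log(1 / KERNEL_TRUNC)) * spec$srate)
  t <- (-half:half) / spec$srate
  u <- t / a
  values <- (pi * spec$decay)^(-0.5) * exp(-u^2 / spec$decay) *
    exp(2i * pi * u)
  list(values = values, t = t, scale = a, half = as.integer(half))
}

#' Continuous wavelet transform of epoched EEG
#'
#' Computes `W(a, b) = a^(-1/2) * integral S(t) psi*((t - b)/a) dt` for each
#' trial and channel by FFT convolution, on the analysis frequencies of
#' `spec`. With `calibrate = TRUE` (default) coefficients are rescaled by
#' `2/sqrt(a)` so that a unit-amplitude sinusoid at an analysis frequency
#' yields modulus ~1 there; only baselined differences matter downstream, so
#' the calibration fixes units without loss of generality. Epoch edges are
#' handled by zero-padding; `edge_margin` flags the per-frequency number of
#' samples at each end that touch the padding.
#'
#' @param rec an [epoched_recording].
#' @param spec a [wavelet_spec()]; its srate must match the recording.
#' @param calibrate rescale to unit-sinusoid modulus 1 (default TRUE).
#' @return object of class `spectral_decomposition`: complex `coeffs`
#'   (trials x channels x freqs x time), `freqs`, `srate`, `window`, `times`
#'   (ms), and `edge_margin` (samples, per frequency).
#' @export
cwt <- function(rec, spec, calibrate = TRUE) {
  stopifnot(inherits(rec, "epoched_recording"), inherits(spec, "wavelet_spec"))
  if (spec$srate != rec$srate)
    stop("wavelet_spec srate does not match the recording")
  d <- dim(rec$data)
  n_tr <- d[1]; n_ch <- d[2]; n_t <- d[3]
  kernels <- lapply(spec$freqs, morlet_kernel, spec = spec)
  lens <- vapply(kernels, function(k) 2L * k$half + 1L, 1L)
  if (any(lens > n_t))
    stop(sprintf("epoch (%d samples) shorter than the kernel at %g Hz (%d samples)",
                 n_t, spec$freqs[which.max(lens)], max(lens)))
  nfft <- stats::nextn(n_t + max(lens) - 1L, 2)
  # signals as columns: time x (trials*channels)
  sig <- matrix(aperm(rec$data, c(3, 1, 2)), nrow = n_t)
  S <- stats::mvfft(rbind(sig, matrix(0, nfft - n_t, ncol(sig))))
  dt <- 1 / rec$srate
  coeffs <- array(0i, c(n_tr, n_ch, length(spec$freqs), n_t))
  for (j in seq_along(spec$freqs)) {
    k <- kernels[[j]]
    # W(b) = sum_m S(b + m*dt) a^{-1/2} psi*(m*dt/a) dt; with an even
    # envelope and odd phase this cross-correlation is the convolution of S
    # with the *non*-conjugated kernel.
    hk <- k$scale^(-0.5) * k$values * dt
    if (calibrate) hk <- hk * 2 / sqrt(k$scale)
    H <- stats::fft(c(hk, rep(0i, nfft - length(hk))))
    full <- stats::mvfft(S * H, inverse = TRUE) / nfft
    w <- full[(k$half + 1L):(k$half + n_t), , drop = FALSE]
    coeffs[, , j, ] <- array(t(w), c(n_tr, n_ch, n_t))
  }
  structure(list(coeffs = coeffs, freqs = spec$freqs, srate = rec$srate,
                 window = rec$window, times = rec_times(rec),
                 edge_margin = vapply(kernels, `[[`, 1L, "half"),
                 labels = rec$labels, participant_id = rec$participant_id),
            class = "spectral_decomposition")
}

#' @export
print.spectral_decomposition <- function(x, ...) {
  d <- dim(x$coeffs)
  cat(sprintf("<spectral_decomposition %s: %d trials x %d channels x %d freqs x %d samples, %g-%g Hz>\n",
              x$participant_id, d[1], d[2], d[3], d[4],
              min(x$freqs), max(x$freqs)))
  invisible(x)
}
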