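# Instantaneous-phase extraction (zero-phase low-pass + complex Morlet
# continuous wavelet transform) and global synchrony metrics: the Kuramoto
# order parameter R and the metastability chi.

#' Complex Morlet continuous wavelet transform at one scale
#'
#' FFT-based CWT of a real signal with the analytic Morlet mother wavelet
#' (centre frequency `omega0`), returning the complex coefficients at the
#' requested scale. Normalization follows the standard frequency-domain
#' construction; only relative power across scales and the complex angle
#' are used downstream.
#'
#' @param x real signal (mean is removed).
#' @param fs sampling rate (Hz).
#' @param scale wavelet scale (s).
#' @param omega0 Morlet centre frequency (dimensionless, default 6).
#' @return complex vector the length of `x`.
#' @export
morlet_cwt <- function(x, fs, scale, omega0 = 6) {
  n <- length(x)
  x <- x - mean(x)
  xh <- stats::fft(x)
  w <- 2 * pi * fs * c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1) / n
  daughter <- rep(0, n)
  pos <- w > 0
  daughter[pos] <- sqrt(2 * pi * scale * fs) * pi^(-0.25) *
    exp(-0.5 * (scale * w[pos] - omega0)^2)
  stats::fft(xh * daughter, inverse = TRUE) / n
}

# Fourier period factor of the Morlet wavelet: freq = ff / scale.
morlet_fourier_factor <- function(omega0 = 6) {
  (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
}

# Mean wavelet power per scale without inverse transforms (Parseval).
morlet_scale_power <- function(x, fs, scales, omega0 = 6) {
  n <- length(x)
  x <- x - mean(x)
  xh2 <- Mod(stats::fft(x))^2
  w <- 2 * pi * fs * c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1) / n
  pos <- w > 0
  vapply(scales, function(s) {
    d2 <- (2 * pi * s * fs) / sqrt(pi) *
      exp(-(s * w[pos] - omega0)^2)
    sum(xh2[pos] * d2) / n^2
  }, numeric(1))
}

#' Instantaneous phase of multichannel voltage traces
#'
#' Each trace is zero-phase low-pass filtered (forward-backward 4th-order
#' Butterworth at `lowpass_hz`), then a complex Morlet wavelet transform
#' determines, in one step, the predominant frequency (the scale with the
#' largest time-averaged wavelet power) and the instantaneous phase at
#' that frequency (the complex angle at that scale). Half a wavelet
#' support (the e-folding time of the widest selected wavelet) is
#' discarded at each end of the series before metrics are computed.
#'
#' @param V matrix (samples x nodes) or vector of voltage traces (mV).
#' @param fs sampling rate (Hz); must exceed `2 * lowpass_hz`.
#' @param lowpass_hz low-pass cutoff (Hz).
#' @param freq_range scanned frequency band (Hz).
#' @param n_scales number of logarithmically spaced scales (>= 32
#'   recommended).
#' @param omega0 Morlet centre frequency.
#' @return list of class `phase_ensemble`: `phases` (samples x nodes,
#'   radians, edge-trimmed), `freqs` (per-node predominant frequency,
#'   Hz), `fs`, `t_offset_ms` (time of the first retained sample).
#' @export
extract_phase <- function(V, fs, lowpass_hz = 50, freq_range = c(0.5, 50),
                          n_scales = 32, omega0 = 6) {
  if (is.null(dim(V))) V <- matrix(V, ncol = 1)
  stopifnot(fs > 2 * lowpass_hz)
  N <- ncol(V)
  n <- nrow(V)
  bf <- signal::butter(4, lowpass_hz / (fs / 2), type = "low")
  ff <- morlet_fourier_factor(omega0)
  freqs_grid <- exp(seq(log(freq_range[1]), log(freq_range[2]),
                        length.out = n_scales))
  scales <- ff / freqs_grid

  phases <- matrix(NA_real_, n, N)
  freqs <- numeric(N)
  for (k in seq_len(N)) {
    x <- V[, k]
    if (stats::sd(x) < 1e-10)
      stop("undefined phase: node ", k, " has a constant trace")
    xf <- signal::filtfilt(bf, x)
    pw <- morlet_scale_power(xf, fs, scales, omega0)
    best <- which.max(pw)
    freqs[k] <- freqs_grid[best]
    W <- morlet_cwt(xf, fs, scales[best], omega0)
    phases[, k] <- Arg(W)
  }
  # discard half a wavelet support (e-folding time sqrt(2)*scale) per end
  s_max <- ff / min(freqs)
  n_edge <- min(floor((n - 2) / 2), ceiling(sqrt(2) * s_max * fs))
  keep <- (n_edge + 1):(n - n_edge)
  structure(list(phases = phases[keep, , drop = FALSE], freqs = freqs,
                 fs = fs, t_offset_ms = (n_edge) * 1000 / fs),
            class = "phase_ensemble")
}

#' Kuramoto order parameter
#'
#' Modulus of the population-mean unit phasor. For a matrix of phases
#' (samples x nodes) the instantaneous series `R_t` is returned; for a
#' vector (one time point) a scalar.
#'
#' @param phases numeric vector or matrix of phases (radians).
#' @return `R_t` in `[0, 1]`.
#' @examples
#' order_parameter(c(0, pi / 2, pi, 3 * pi / 2)) # 0
#' @export
order_parameter <- function(phases) {
  if (is.matrix(phases)) {
    Mod(rowMeans(exp(1i * phases)))
  } else {
    Mod(mean(exp(1i * phases)))
  }
}

#' Metastability (temporal variance of the order parameter)
#'
#' `chi = mean((R_t - mean(R_t))^2)`: zero for a system that stays
#' completely synchronized or completely desynchronized, positive only
#' when global coherence waxes and wanes. Bounded by 1/4 for a
#' `[0, 1]`-valued series.
#'
#' @param R_t instantaneous order-parameter series.
#' @return non-negative scalar.
#' @export
metastability <- function(R_t) {
  stopifnot(length(R_t) >= 2)
  mean((R_t - mean(R_t))^2)
}

#' Global synchrony metrics of a phase ensemble
#'
#' @param phases a `phase_ensemble` or a samples x nodes phase matrix.
#' @return list of class `synchrony_metrics`: `R` (time-mean order
#'   parameter), `chi` (metastability), `R_t` (series).
#' @export
synchrony_metrics <- function(phases) {
  if (inherits(phases, "phase_ensemble")) phases <- phases$phases
  R_t <- order_parameter(phases)
  structure(list(R = mean(R_t), chi = metastability(R_t), R_t = R_t),
            class = "synchrony_metrics")
}

#' @export
print.synchrony_metrics <- function(x, ...) {
  cat(sprintf("R = %.4f, chi = %.5f (%d samples)\n", x$R, x$chi,
              length(x$R_t)))
  invisible(x)
}

#' Hilbert-transform phase (reference path)
#'
#' Analytic-signal phase via the frequency-domain Hilbert transform;
#' retained as an independent cross-check of the wavelet phase on clean
#' narrowband signals.
#'
#' @param x real signal.
#' @return phase in radians, the length of `x`.
#' @export
hilbert_phase <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Arg(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}
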