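# Surrogate fixtures: phase ensembles and voltage-like traces with known
# ground-truth synchrony/FC/FCD/spike statistics, so every analysis stage
# is testable without ODE simulation.

#' Generate a surrogate fixture
#'
#' Deterministic (seeded) generators for the analysis stages:
#' \describe{
#'   \item{locked}{all nodes share one phase trajectory: R = 1, chi = 0,
#'     all FC entries 1, FCD all 1 (degenerate).}
#'   \item{independent}{i.i.d. uniform phases per node and sample — every
#'     time point is a fresh draw from the incoherent ensemble:
#'     `E[R_t] = sqrt(pi)/(2 sqrt(N))`, off-diagonal FCD near 0.}
#'   \item{constant_lag}{node k runs at the common frequency with a fixed
#'     offset `lag * (k-1)`: `FC_kl = |cos(lag (k-l) / 2)|` exactly.}
#'   \item{block_switching}{two phase-offset configurations alternate in
#'     blocks of `block_ms`; FC inside a block is one of two fixed
#'     patterns, so the FCD (windows aligned to blocks) takes values 1 and
#'     `c` (the between-pattern correlation) with closed-form variance.}
#'   \item{spike_train}{voltage-like trace: subthreshold sinusoid plus
#'     stereotyped spike waveforms at prescribed event times, amplitudes
#'     matched to the neuron model (rest near -60 mV, spikes overshooting
#'     +30 mV); ground truth carries spike times, rate and burst
#'     fraction.}
#'   \item{subthreshold}{pure subthreshold sinusoid, no spikes.}
#' }
#'
#' @param kind one of the generator kinds above.
#' @param N nodes.
#' @param fs sampling rate (Hz).
#' @param duration_ms duration (ms).
#' @param seed RNG seed.
#' @param freq_hz common oscillation frequency (Hz).
#' @param lag phase lag step (rad) for `constant_lag`.
#' @param block_ms block duration for `block_switching`.
#' @param offsets_a,offsets_b node phase offsets (rad) of the two
#'   block-switching configurations; default random (seeded).
#' @param events list of spike-time vectors (ms), one per event, for
#'   `spike_train`; default three triple-spike bursts and two singles.
#' @param amp_mv subthreshold amplitude (mV) for voltage fixtures.
#' @return list: `kind`, `data` (phase matrix or voltage matrix), `fs`,
#'   `ground_truth` (named list of exact/expected values).
#' @export
generate_surrogate <- function(kind = c("locked", "independent",
                                        "constant_lag", "block_switching",
                                        "spike_train", "subthreshold"),
                               N = 10, fs = 1000, duration_ms = 10000,
                               seed = 1L, freq_hz = 4, lag = pi / 4,
                               block_ms = 2000, offsets_a = NULL,
                               offsets_b = NULL, events = NULL,
                               amp_mv = 10) {
  kind <- match.arg(kind)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  n <- round(duration_ms * fs / 1000)
  tt <- (seq_len(n) - 1) / fs          # seconds
  base <- 2 * pi * freq_hz * tt
  switch(kind,
    locked = {
      ph <- matrix(rep(base, N), n, N)
      list(kind = kind, data = ph, fs = fs,
           ground_truth = list(R = 1, chi = 0, fc_all = 1, fcd_all = 1))
    },
    independent = {
      ph <- matrix(stats::runif(n * N, 0, 2 * pi), n, N)
      list(kind = kind, data = ph, fs = fs,
           ground_truth = list(E_Rt = sqrt(pi) / (2 * sqrt(N)),
                               fcd_offdiag = 0))
    },
    constant_lag = {
      lags <- lag * (seq_len(N) - 1)
      ph <- outer(base, rep(1, N)) + outer(rep(1, n), lags)
      fc <- abs(cos(outer(lags, lags, "-") / 2))
      diag(fc) <- 1
      list(kind = kind, data = ph, fs = fs,
           ground_truth = list(
             fc = fc, lags = lags,
             R = Mod(mean(exp(1i * lags))), chi = 0))
    },
    block_switching = {
      if (is.null(offsets_a)) offsets_a <- stats::runif(N, 0, 2 * pi)
      if (is.null(offsets_b)) offsets_b <- stats::runif(N, 0, 2 * pi)
      nb <- round(block_ms * fs / 1000)
      state <- (((seq_len(n) - 1) %/% nb) %% 2) + 1    # 1,2,1,2,...
      off <- rbind(offsets_a, offsets_b)[state, ]
      ph <- outer(base, rep(1, N)) + off
      fca <- abs(cos(outer(offsets_a, offsets_a, "-") / 2)); diag(fca) <- 1
      fcb <- abs(cos(outer(offsets_b, offsets_b, "-") / 2)); diag(fcb) <- 1
      list(kind = kind, data = ph, fs = fs,
           ground_truth = list(fc_a = fca, fc_b = fcb, block_ms = block_ms,
                               state = state))
    },
    spike_train = {
      if (is.null(events))
        events <- list(c(1000, 1010, 1020), c(2500), c(4000, 4012, 4025),
                       c(6000, 6010, 6021), c(8200))
      spikes <- sort(unlist(events))
      V <- rep(-60, n) + amp_mv * sin(2 * pi * freq_hz * tt)
      # stereotyped spike: 2 ms triangular depolarization to +30 mV
      half <- round(0.001 * fs)
      wave <- c(seq(0, 1, length.out = half + 1),
                seq(1, 0, length.out = half + 1)[-1])
      for (s in spikes) {
        i0 <- round(s * fs / 1000) + 1
        idx <- i0:(i0 + length(wave) - 1)
        ok <- idx >= 1 & idx <= n
        V[idx[ok]] <- -60 + 90 * wave[ok]
      }
      b <- mean(vapply(events, length, integer(1)) >= 2)
      list(kind = kind, data = matrix(V, n, 1), fs = fs,
           ground_truth = list(
             spike_times_ms = spikes,
             firing_rate = length(spikes) / (duration_ms / 1000),
             n_events = length(events),
             n_bursts = sum(vapply(events, length, integer(1)) >= 2),
             b_k = b, pattern_code = 4L))
    },
    subthreshold = {
      V <- -60 + amp_mv * sin(2 * pi * freq_hz * tt)
      list(kind = kind, data = matrix(V, n, 1), fs = fs,
           ground_truth = list(firing_rate = 0, pattern_code = 1L,
                               freq_hz = freq_hz))
    })
}
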