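# Firing-rate / firing-pattern characterization, burst statistics,
# parameter-plane scanning, and matched-firing-rate population sampling.

#' Mean firing rate
#'
#' @param spikes spike times (ms).
#' @param t_record recording duration (ms), `> 0`.
#' @return rate in spikes/s.
#' @export
firing_rate <- function(spikes, t_record) {
  stopifnot(t_record > 0)
  length(spikes) / (t_record / 1000)
}

#' Dominant slow-oscillation period of a voltage trace
#'
#' Spectral peak below `f_max` of the (detrended) trace, used to group
#' spikes into events riding on the slow subthreshold rhythm. Returns `NA`
#' when no meaningful peak exists (flat or aperiodic trace).
#'
#' @param V voltage trace (mV).
#' @param fs sampling rate (Hz).
#' @param f_max upper frequency bound (Hz) for the slow rhythm.
#' @param min_sd minimum trace SD (mV) for an oscillation to be declared.
#' @return list `period_ms`, `freq_hz`, `oscillating` (logical).
#' @export
slow_oscillation <- function(V, fs, f_max = 20, min_sd = 0.5) {
  n <- length(V)
  x <- V - mean(V)
  if (stats::sd(x) < min_sd)
    return(list(period_ms = NA_real_, freq_hz = NA_real_, oscillating = FALSE))
  spec <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1) * fs / n
  band <- which(freq >= 0.2 & freq <= f_max)
  if (!length(band))
    return(list(period_ms = NA_real_, freq_hz = NA_real_, oscillating = FALSE))
  pk <- band[which.max(spec[band])]
  f0 <- freq[pk]
  # peak must concentrate power to count as rhythmic
  oscillating <- spec[pk] > 5 * stats::median(spec[band])
  list(period_ms = 1000 / f0, freq_hz = f0, oscillating = oscillating)
}

#' Group spikes into events
#'
#' Consecutive spikes are merged into one event while the inter-spike
#' interval stays below `gap_frac` of the slow-oscillation period (the
#' model is a parabolic burster: events ride the slow cycles). The period
#' is estimated from `V` when provided, or passed explicitly; without
#' either, a fallback gap of 2.5 times the median ISI is used.
#'
#' @param spikes sorted spike times (ms).
#' @param V optional voltage trace for period estimation.
#' @param fs sampling rate of `V` (Hz).
#' @param period_ms slow-oscillation period (ms), overrides estimation.
#' @param gap_frac fraction of the period below which ISIs are intra-event.
#' @return list of numeric vectors, one per event.
#' @export
group_events <- function(spikes, V = NULL, fs = NULL, period_ms = NULL,
                         gap_frac = 0.5) {
  if (!length(spikes)) return(list())
  stopifnot(!is.unsorted(spikes))
  if (is.null(period_ms) && !is.null(V)) {
    so <- slow_oscillation(V, fs)
    period_ms <- so$period_ms
  }
  gap <- if (!is.null(period_ms) && is.finite(period_ms)) {
    gap_frac * period_ms
  } else if (length(spikes) > 2) {
    2.5 * stats::median(diff(spikes))
  } else {
    Inf
  }
  if (length(spikes) == 1) return(list(spikes))
  breaks <- which(diff(spikes) >= gap)
  idx <- cbind(c(1, breaks + 1), c(breaks, length(spikes)))
  lapply(seq_len(nrow(idx)), function(i) spikes[idx[i, 1]:idx[i, 2]])
}

#' Burst fraction of one neuron
#'
#' `b_k = Nb / Te`: the number of bursts (events with two or more spikes)
#' over the total number of events.
#'
#' @param events list of events from [group_events()].
#' @return fraction in `[0, 1]`; `NA` when there are no events.
#' @export
burst_fraction <- function(events) {
  if (!length(events)) return(NA_real_)
  mean(vapply(events, length, integer(1)) >= 2)
}

#' Mean burst fraction of a population
#'
#' Arithmetic mean of per-neuron burst fractions `b_k` across the network
#' (neurons with no events are excluded).
#'
#' @param b numeric vector of per-neuron burst fractions.
#' @return mean in `[0, 1]`.
#' @export
mean_burst_fraction <- function(b) {
  stopifnot(length(b) >= 1)
  mean(b, na.rm = TRUE)
}

#' Firing-pattern classification
#'
#' Maps a single-neuron recording to a firing-pattern code:
#' \describe{
#'   \item{0}{no oscillation (flat trace, no spikes)}
#'   \item{1}{subthreshold oscillations, no spikes}
#'   \item{2}{oscillations with spike skipping (slow cycles outnumber
#'     spike events by at least 20 percent)}
#'   \item{3}{regular tonic spiking (rate below 20 spikes/s, one spike per
#'     event; irregular non-skipping, non-bursting firing falls here too)}
#'   \item{4}{burst firing (a majority of events carry >= 2 spikes)}
#'   \item{5}{tonic with rate between 20 and 50 spikes/s}
#'   \item{6}{rate above 50 spikes/s}
#' }
#' Deterministic and total: every finite record maps to exactly one code.
#'
#' @param rec a `sim_record`, or a list with `V`, `spikes`, `fs`,
#'   `t_record`.
#' @param burst_majority fraction of bursting events required for code 4.
#' @param skip_excess slow-cycle/event ratio in excess of 1 required for
#'   code 2.
#' @param cv_regular ISI coefficient-of-variation bound for "regular".
#' @return list: `code` (integer), `firing_rate`, `b_k`,
#'   `spikes_per_burst` (mean; `NA` unless code 4).
#' @export
classify_pattern <- function(rec, burst_majority = 0.5, skip_excess = 0.2,
                             cv_regular = 0.1) {
  V <- rec$V
  spikes <- rec$spikes
  fs <- rec$fs
  t_record <- rec$t_record
  fr <- firing_rate(spikes, t_record)
  so <- slow_oscillation(V, fs)
  out <- function(code, spb = NA_real_, b = NA_real_)
    list(code = as.integer(code), firing_rate = fr, b_k = b,
         spikes_per_burst = spb)
  if (!length(spikes)) {
    return(if (so$oscillating) out(1) else out(0))
  }
  if (fr > 50) return(out(6))
  if (fr >= 20) return(out(5))
  events <- group_events(spikes, V = V, fs = fs)
  sizes <- vapply(events, length, integer(1))
  b <- mean(sizes >= 2)
  if (b >= burst_majority)
    return(out(4, spb = mean(sizes[sizes >= 2]), b = b))
  n_cycles <- if (so$oscillating) t_record / so$period_ms else NA_real_
  if (is.finite(n_cycles) && n_cycles >= (1 + skip_excess) * length(events))
    return(out(2, b = b))
  out(3, b = b)
}

#' Scan a conductance plane
#'
#' Simulates one isolated neuron per grid point of the `(g_sd, g_sr)`
#' plane at fixed `g_h`, records firing rate, firing pattern and the
#' maximal Lyapunov exponent. Points whose integration diverges are
#' flagged, not fatal.
#'
#' @param g_sd,g_sr numeric vectors of grid values (>= 2 each).
#' @param g_h fixed Ih conductance (0 gives the NoIh plane).
#' @param base_params template parameters; the scanned entries override.
#' @param t_record recording duration per point (ms).
#' @param t_transient discarded transient (ms).
#' @param mle_average MLE averaging duration (ms).
#' @param mle_band estimator noise half-band (1/ms): points with
#'   `|mle| <= mle_band` are flagged `uncertain`.
#' @param seed RNG seed for MLE perturbation directions.
#' @param progress print progress every so many points (0 = quiet).
#' @return data.frame: `g_sd, g_sr, g_h, mle, converged, firing_rate,
#'   firing_pattern, spikes_per_burst, class, uncertain, diverged`.
#' @export
scan_parameter_plane <- function(g_sd, g_sr, g_h = 0.4,
                                 base_params = hbih_params(),
                                 t_record = 10000, t_transient = 3000,
                                 mle_average = 20000, mle_band = 5e-4,
                                 seed = 1L, progress = 0) {
  stopifnot(length(g_sd) >= 2, length(g_sr) >= 2)
  grid <- expand.grid(g_sd = g_sd, g_sr = g_sr, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  res <- data.frame(grid, g_h = g_h, mle = NA_real_, converged = NA,
                    firing_rate = NA_real_, firing_pattern = NA_integer_,
                    spikes_per_burst = NA_real_, class = NA_character_,
                    uncertain = NA, diverged = FALSE)
  for (i in seq_len(n)) {
    p <- base_params
    p[["g_sd"]] <- grid$g_sd[i]
    p[["g_sr"]] <- grid$g_sr[i]
    p[["g_h"]] <- g_h
    rec <- try(simulate_neuron(p, t_transient = t_transient,
                               t_record = t_record), silent = TRUE)
    if (inherits(rec, "try-error")) {
      res$diverged[i] <- TRUE
      next
    }
    cls <- classify_pattern(rec)
    res$firing_rate[i] <- cls$firing_rate
    res$firing_pattern[i] <- cls$code
    res$spikes_per_burst[i] <- cls$spikes_per_burst
    est <- try(mle_neuron(p, t_transient = 0, t_average = mle_average,
                          state0 = rec$final_state, seed = seed),
               silent = TRUE)
    if (inherits(est, "try-error")) {
      res$diverged[i] <- TRUE
      next
    }
    res$mle[i] <- est$mle
    res$converged[i] <- est$converged
    res$class[i] <- classify_chaotic(est$mle)
    res$uncertain[i] <- abs(est$mle) <= mle_band
    if (progress > 0 && i %% progress == 0)
      message(sprintf("scan: %d/%d", i, n))
  }
  res
}

#' Sample chaotic / non-chaotic / NoIh populations with matched rates
#'
#' Implements the firing-rate-matched sampling used to compare node
#' dynamics at constant functional heterogeneity: the rate band is divided
#' into fixed-width bins and, per bin, the same number of `(g_sd, g_sr)`
#' combinations is drawn from each source region. Chaotic points must
#' exceed the estimator noise band, non-chaotic points must have
#' `mle <= 0`, and the NoIh region comes from a `g_h = 0` scan.
#'
#' @param scan data.frame from [scan_parameter_plane()] at `g_h > 0`.
#' @param scan_noih data.frame from a `g_h = 0` scan.
#' @param band rate band `c(lo, hi)` in spikes/s.
#' @param bin_width histogram bin width (spikes/s).
#' @param n_per_bin desired draws per bin per population; shrunk
#'   uniformly (with a warning) if some bin has fewer candidates.
#' @param seed RNG seed for the draws.
#' @param mle_band estimator noise half-band (1/ms).
#' @param drop_empty_bins with the default `FALSE`, a bin empty in any
#'   region is an error; with `TRUE`, bins that cannot be filled in every
#'   region contribute zero draws to all three populations (per-bin counts
#'   stay exactly equal) and the per-bin count is capped bin-wise rather
#'   than uniformly. Useful when the firing-rate staircase of the
#'   non-chaotic regime leaves structural holes in the scanned region.
#' @return list of class `matched_populations`: `chaotic`, `non_chaotic`,
#'   `noih` (data.frames), `rate_bins`, `n_per_bin`, `bin_counts`,
#'   `ks_pvalues`.
#' @export
sample_matched_populations <- function(scan, scan_noih, band = c(3, 4.5),
                                       bin_width = 0.1, n_per_bin = 3,
                                       seed = 1L, mle_band = 5e-4,
                                       drop_empty_bins = FALSE) {
  edges <- seq(band[1], band[2], by = bin_width)
  in_band <- function(d) d[!d$diverged & !is.na(d$firing_rate) &
                            d$firing_rate >= band[1] &
                            d$firing_rate < band[2], , drop = FALSE]
  regions <- list(
    chaotic = in_band(scan[!is.na(scan$mle) & scan$mle > mle_band, ]),
    non_chaotic = in_band(scan[!is.na(scan$mle) & scan$mle <= 0, ]),
    noih = in_band(scan_noih[!is.na(scan_noih$mle) &
                               scan_noih$mle <= mle_band, ]))
  bin_of <- function(fr) findInterval(fr, edges, rightmost.closed = FALSE)
  n_bins <- length(edges) - 1
  counts <- vapply(regions, function(d)
    tabulate(bin_of(d$firing_rate), nbins = n_bins), integer(n_bins))
  empty <- which(apply(counts, 1, min) == 0)
  if (length(empty) && !drop_empty_bins)
    stop("infeasible matching: empty bins [",
         paste(sprintf("%.1f-%.1f", edges[empty], edges[empty + 1]),
               collapse = ", "),
         ") Hz in at least one region")
  if (drop_empty_bins) {
    n_bin_use <- pmin(n_per_bin, apply(counts, 1, min))
  } else {
    n_use <- min(n_per_bin, min(counts))
    if (n_use < n_per_bin)
      warning("per-bin count shrunk from ", n_per_bin, " to ", n_use,
              " to fit the sparsest bin")
    n_bin_use <- rep(n_use, n_bins)
  }
  if (all(n_bin_use == 0)) stop("infeasible matching: no usable bins")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  draw <- function(d) {
    picked <- lapply(seq_len(n_bins), function(b) {
      if (n_bin_use[b] == 0) return(NULL)
      rows <- which(bin_of(d$firing_rate) == b)
      d[rows[sample.int(length(rows), n_bin_use[b])], , drop = FALSE]
    })
    out <- do.call(rbind, picked)
    rownames(out) <- NULL
    out
  }
  pops <- lapply(regions, draw)
  ks <- function(a, b) suppressWarnings(
    stats::ks.test(a$firing_rate, b$firing_rate)$p.value)
  structure(list(chaotic = pops$chaotic, non_chaotic = pops$non_chaotic,
                 noih = pops$noih, rate_bins = edges,
                 n_per_bin = n_bin_use, bin_counts = counts,
                 ks_pvalues = c(
                   chaotic_vs_non = ks(pops$chaotic, pops$non_chaotic),
                   chaotic_vs_noih = ks(pops$chaotic, pops$noih),
                   non_vs_noih = ks(pops$non_chaotic, pops$noih))),
            class = "matched_populations")
}

#' Draw per-node parameters from a population
#'
#' Samples `N` rows (with replacement when needed) from a population
#' data.frame of `(g_sd, g_sr, g_h)` triples and expands them into the
#' parameter matrix consumed by [network_spec()].
#'
#' @param population data.frame with columns `g_sd`, `g_sr`, `g_h`.
#' @param N number of neurons.
#' @param base_params template parameter vector.
#' @param seed RNG seed.
#' @return N x 28 parameter matrix.
#' @export
population_params <- function(population, N, base_params = hbih_params(),
                              seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  idx <- sample.int(nrow(population), N, replace = nrow(population) < N)
  m <- params_matrix(base_params, N = N)
  m[, "g_sd"] <- population$g_sd[idx]
  m[, "g_sr"] <- population$g_sr[idx]
  m[, "g_h"] <- population$g_h[idx]
  m
}
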