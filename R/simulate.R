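# Fixed-step Euler integration of single neurons and networks, spike
# detection on the recorded voltage traces.

#' Simulate an isolated HB + Ih neuron
#'
#' Integrates the five-variable neuron with the forward Euler method at a
#' fixed step (`dt = 0.025` ms by default), discards a transient, then
#' records the voltage at `record_dt` intervals. Spikes are detected on the
#' recorded trace by interpolated upward threshold crossings.
#'
#' @param params parameter vector from [hbih_params()].
#' @param t_transient discarded duration (ms).
#' @param t_record recorded duration (ms).
#' @param dt Euler step (ms).
#' @param record_dt sampling interval of the stored trace (ms); must be a
#'   multiple of `dt`.
#' @param state0 initial state; default from [hbih_initial_state()].
#' @param threshold,refractory spike detection settings (mV, ms).
#' @return list of class `sim_record`: `t` (ms, from 0), `V` (mV),
#'   `spikes` (ms), `fs` (Hz), plus the settings used.
#' @examples
#' \donttest{
#' rec <- simulate_neuron(hbih_params(), t_transient = 1000, t_record = 2000)
#' length(rec$spikes)
#' }
#' @export
simulate_neuron <- function(params, t_transient = 5000, t_record = 10000,
                            dt = 0.025, record_dt = 1, state0 = NULL,
                            threshold = -20, refractory = 2) {
  stopifnot(dt > 0, t_transient >= 0, t_record > 0)
  stride <- stride_of(record_dt, dt)
  if (is.null(state0)) state0 <- hbih_initial_state(params)
  out <- hbih_integrate_cpp(as.numeric(params), as_state(state0), dt,
                            t_transient, t_record, stride)
  V <- out$V
  t <- seq_along(V) * record_dt - record_dt
  spikes <- detect_spikes(V, fs = 1000 / record_dt, threshold = threshold,
                          refractory = refractory)
  structure(list(t = t, V = V, spikes = spikes, fs = 1000 / record_dt,
                 dt = dt, t_transient = t_transient, t_record = t_record,
                 final_state = out$final_state, integrator = "euler"),
            class = "sim_record")
}

stride_of <- function(record_dt, dt) {
  stride <- record_dt / dt
  if (abs(stride - round(stride)) > 1e-9)
    stop("record_dt must be a multiple of dt")
  as.integer(round(stride))
}

#' Simulate a coupled network
#'
#' Forward Euler integration of `N` gap-junction-coupled neurons described
#' by a [network_spec()]. All neurons share the time grid; per-node voltage
#' traces are recorded after the transient at `record_dt` resolution.
#'
#' @param spec a [network_spec()].
#' @param t_transient,t_record,dt,record_dt as in [simulate_neuron()].
#' @param states0 N x 5 matrix of initial states; default jitters the
#'   initial voltage uniformly in a seeded way so nodes desynchronize.
#' @param seed_init seed for the default initial-state jitter.
#' @param threshold,refractory spike detection settings.
#' @return list of class `network_record`: `t`, `V` (samples x N matrix),
#'   `spikes` (list of per-node spike-time vectors), `fs`, `spec`.
#' @export
simulate_network <- function(spec, t_transient = 5000, t_record = 30000,
                             dt = 0.025, record_dt = 1, states0 = NULL,
                             seed_init = 1L, threshold = -20,
                             refractory = 2) {
  stopifnot(inherits(spec, "network_spec"), dt > 0, t_record > 0)
  stride <- stride_of(record_dt, dt)
  if (is.null(states0)) states0 <- network_initial_states(spec, seed_init)
  out <- hbih_network_integrate_cpp(spec$params, spec$edges, spec$g,
                                    states0, dt, t_transient, t_record,
                                    stride)
  V <- out$V
  t <- seq_len(nrow(V)) * record_dt - record_dt
  fs <- 1000 / record_dt
  spikes <- lapply(seq_len(ncol(V)), function(k)
    detect_spikes(V[, k], fs = fs, threshold = threshold,
                  refractory = refractory))
  structure(list(t = t, V = V, spikes = spikes, fs = fs, dt = dt,
                 t_transient = t_transient, t_record = t_record,
                 final_state = out$final_state, spec = spec,
                 integrator = "euler"),
            class = "network_record")
}

#' Seeded initial states for a network
#'
#' Per-node initial voltages drawn uniformly in (-70, -50) mV with gates at
#' their steady state, so that identical parameters still start
#' desynchronized. Deterministic given `seed`.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed.
#' @return N x 5 matrix.
#' @export
network_initial_states <- function(spec, seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  V0 <- stats::runif(spec$N, -70, -50)
  t(vapply(seq_len(spec$N), function(k) {
    p <- spec$params[k, ]
    c(V0[k],
      steady_state_activation(V0[k], p[["s_r"]], p[["V0_r"]]),
      steady_state_activation(V0[k], p[["s_sd"]], p[["V0_sd"]]),
      0.1,
      steady_state_activation(V0[k], p[["s_h"]], p[["V0_h"]]))
  }, numeric(5)))
}

#' Spike detection by threshold crossing
#'
#' Upward crossings of `threshold`, with the crossing time linearly
#' interpolated between the bracketing samples; crossings closer than
#' `refractory` to the previous accepted spike are discarded.
#'
#' @param V voltage trace (mV), uniformly sampled.
#' @param fs sampling rate (Hz).
#' @param threshold crossing level (mV); action potentials in this model
#'   overshoot 0 mV while subthreshold oscillations stay below -40 mV.
#' @param refractory minimum spike separation (ms).
#' @return numeric vector of spike times (ms), strictly increasing.
#' @export
detect_spikes <- function(V, fs, threshold = -20, refractory = 2) {
  n <- length(V)
  if (n < 2) return(numeric(0))
  up <- which(V[-n] < threshold & V[-1] >= threshold)
  if (!length(up)) return(numeric(0))
  dt_ms <- 1000 / fs
  frac <- (threshold - V[up]) / (V[up + 1] - V[up])
  times <- (up - 1 + frac) * dt_ms
  keep <- numeric(0)
  last <- -Inf
  for (tt in times) {
    if (tt - last >= refractory) {
      keep <- c(keep, tt)
      last <- tt
    }
  }
  keep
}

#' Export voltage traces and spikes as plain text
#'
#' Traces go to a (gz-compressible) CSV of `t_ms` plus one column per node;
#' spikes to a two-column CSV `node,spike_time_ms`. A run manifest with all
#' scalar settings is written as `key: value` lines.
#'
#' @param rec a `sim_record` or `network_record`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
export_record <- function(rec, dir, prefix = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  V <- rec$V
  if (is.null(dim(V))) V <- matrix(V, ncol = 1)
  tr <- file.path(dir, paste0(prefix, "_traces.csv"))
  utils::write.csv(data.frame(t_ms = rec$t, V), tr, row.names = FALSE)
  spikes <- rec$spikes
  if (!is.list(spikes)) spikes <- list(spikes)
  sp <- file.path(dir, paste0(prefix, "_spikes.csv"))
  df <- do.call(rbind, lapply(seq_along(spikes), function(k)
    if (length(spikes[[k]]))
      data.frame(node = k - 1L, spike_time_ms = spikes[[k]])))
  if (is.null(df)) df <- data.frame(node = integer(0),
                                    spike_time_ms = numeric(0))
  utils::write.csv(df, sp, row.names = FALSE)
  mf <- file.path(dir, paste0(prefix, "_manifest.txt"))
  keys <- c(dt = rec$dt, t_transient = rec$t_transient,
            t_record = rec$t_record, fs = rec$fs)
  writeLines(paste0(names(keys), ": ", keys), mf)
  invisible(c(traces = tr, spikes = sp, manifest = mf))
}
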