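# Shared helpers: small reference integrators and test systems used as
# independent oracles.

# Plain R forward-Euler integrator recording the full state; used to
# cross-check the compiled integrator and to track gating bounds.
euler_trace <- function(rhs, x0, dt, n_steps, record_every = 1L) {
  x <- as.numeric(x0)
  out <- matrix(NA_real_, floor(n_steps / record_every) + 1, length(x))
  out[1, ] <- x
  r <- 1L
  for (s in seq_len(n_steps)) {
    x <- x + dt * rhs(x)
    if (s %% record_every == 0) {
      r <- r + 1L
      out[r, ] <- x
    }
  }
  out[seq_len(r), , drop = FALSE]
}

lorenz_rhs <- function(sigma = 10, rho = 28, beta = 8 / 3) {
  function(x) c(sigma * (x[2] - x[1]),
                x[1] * (rho - x[3]) - x[2],
                x[1] * x[2] - beta * x[3])
}

# Slow-oscillation period of the default neuron is ~250-350 ms; a compact
# set of parameter points with known character (from package scans):
point_chaotic <- function() hbih_params(g_sd = 0.212, g_sr = 0.268)
point_regular <- function() hbih_params(g_sd = 0.28, g_sr = 0.32)

# deSolve-compatible wrapper of the neuron vector field.
desolve_rhs <- function(params) {
  function(t, y, parms) list(hbih_derivatives(y, params))
}
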