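# Single-neuron HB + Ih model: parameters, temperature factors, gating,
# currents and the vector field. The compiled integrator (src/hbih.cpp)
# consumes parameter vectors in the fixed order `hbih_param_names`.

#' @useDynLib hbihsync, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical parameter order; must match the enum in src/hbih.cpp.
hbih_param_names <- c(
  "C_m", "T", "g_d", "g_r", "g_sd", "g_sr", "g_l", "g_h",
  "V0_d", "V0_r", "V0_sd", "V0_h",
  "s_d", "s_r", "s_sd", "s_h",
  "tau_r", "tau_sd", "tau_sr", "tau_h",
  "eta", "kappa",
  "E_d", "E_r", "E_sd", "E_sr", "E_l", "E_h"
)

# Reference defaults for the cold-thermoreceptor (Huber-Braun) neuron
# extended with the hyperpolarization-activated current Ih, at 36 degrees C.
# Units: C_m uF/cm^2, conductances mS/cm^2, voltages mV, slopes 1/mV,
# time constants ms, eta cm^2/uA, kappa dimensionless.
hbih_default_values <- c(
  C_m = 1.0, T = 36,
  g_d = 2.5, g_r = 2.8, g_sd = 0.21, g_sr = 0.28, g_l = 0.06, g_h = 0.4,
  V0_d = -25, V0_r = -25, V0_sd = -40, V0_h = -85,
  s_d = 0.25, s_r = 0.25, s_sd = 0.11, s_h = -0.14,
  tau_r = 2, tau_sd = 10, tau_sr = 35, tau_h = 125,
  eta = 0.014, kappa = 0.18,
  E_d = 50, E_r = -90, E_sd = 50, E_sr = -90, E_l = -80, E_h = -30
)

#' HB + Ih neuron parameters
#'
#' Returns the full named parameter vector of the conductance-based
#' HB + Ih neuron (Huber-Braun cold-thermoreceptor model plus a
#' hyperpolarization-activated cation current), with reference defaults.
#' The model couples a fast spiking subsystem (depolarizing `g_d`,
#' repolarizing `g_r`) to a slow subsystem (persistent sodium `g_sd`,
#' calcium-activated potassium `g_sr`, and `g_h`) that drives parabolic
#' bursting and subthreshold oscillations.
#'
#' @param ... named overrides of individual parameters, e.g.
#'   `hbih_params(g_sd = 0.25, g_h = 0)`.
#' @return named numeric vector of length 28 with class `hbih_params`.
#' @examples
#' p <- hbih_params()
#' p[["g_sd"]]
#' @export
hbih_params <- function(...) {
  p <- hbih_default_values[hbih_param_names]
  over <- list(...)
  if (length(over)) {
    nm <- names(over)
    if (is.null(nm) || any(nm == ""))
      stop("all parameter overrides must be named")
    bad <- setdiff(nm, hbih_param_names)
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[nm] <- vapply(over, as.numeric, numeric(1))
  }
  validate_hbih_params(p)
  structure(p, class = "hbih_params")
}

validate_hbih_params <- function(p) {
  g <- p[c("g_d", "g_r", "g_sd", "g_sr", "g_l", "g_h")]
  tau <- p[c("tau_r", "tau_sd", "tau_sr", "tau_h")]
  if (any(!is.finite(p))) stop("parameters must be finite")
  if (any(g < 0)) stop("conductance densities must be >= 0")
  if (any(tau <= 0)) stop("time constants must be > 0")
  if (p[["C_m"]] <= 0) stop("C_m must be > 0")
  invisible(p)
}

#' Temperature scaling factors
#'
#' Scale factors applied to maximal conductances (`rho`) and to gating
#' kinetics (`phi`), with Q10 values of 1.3 and 3 referenced to 25 degrees C:
#' `rho = 1.3^((T-25)/10)`, `phi = 3^((T-25)/10)`.
#'
#' @param T temperature in degrees Celsius.
#' @return named numeric vector `c(rho=, phi=)`, both positive.
#' @examples
#' temperature_factors(25) # c(rho = 1, phi = 1)
#' @export
temperature_factors <- function(T) {
  stopifnot(is.finite(T))
  c(rho = 1.3^((T - 25) / 10), phi = 3^((T - 25) / 10))
}

#' Steady-state activation sigmoid
#'
#' Boltzmann open-probability curve `1 / (1 + exp(-s * (V - V0)))`.
#' Increasing in `V` for positive slope `s`; the Ih gate uses a negative
#' slope (`s_h = -0.14`), making it hyperpolarization-activated.
#'
#' @param V membrane voltage (mV); vectorized.
#' @param s activation slope (1/mV).
#' @param V0 half-activation voltage (mV).
#' @return open probability in (0, 1).
#' @export
steady_state_activation <- function(V, s, V0) {
  1 / (1 + exp(-s * (V - V0)))
}

#' Ionic membrane currents
#'
#' Evaluates the six membrane currents at a given state. Each current is
#' `rho(T) * g_i * a_i * (V - E_i)` with the leak gate fixed at 1 and the
#' fast depolarizing gate `a_d` instantaneous at its steady state. The slow
#' repolarizing current gates on intracellular calcium through the Hill-type
#' factor `a_sr^2 / (a_sr^2 + 0.4^2)`.
#'
#' @param state numeric state vector `c(V, a_r, a_sd, a_sr, a_h)`.
#' @param params parameter vector from [hbih_params()].
#' @return named numeric vector `I_d, I_r, I_sd, I_sr, I_h, I_l` (uA/cm^2).
#' @export
ionic_currents <- function(state, params) {
  hbih_currents_cpp(as_state(state), as.numeric(params))
}

#' Time derivative of the neuron state
#'
#' The full vector field: `C_m dV/dt = -(I_sd + I_sr + I_h + I_d + I_r +
#' I_l) + I_syn`; relaxation gating `da_i/dt = phi(T) (a_i_inf(V) - a_i) /
#' tau_i` for the repolarizing, slow-depolarizing and Ih gates; and
#' calcium-like dynamics `da_sr/dt = phi(T) (-eta I_sd - kappa a_sr) /
#' tau_sr`, so inward (negative) slow depolarizing current raises a_sr.
#'
#' @param state numeric state vector `c(V, a_r, a_sd, a_sr, a_h)`.
#' @param params parameter vector from [hbih_params()].
#' @param I_syn synaptic/gap-junction input current (uA/cm^2).
#' @return numeric length-5 derivative, in units per ms.
#' @export
hbih_derivatives <- function(state, params, I_syn = 0) {
  d <- hbih_deriv_cpp(as_state(state), as.numeric(params), I_syn)
  names(d) <- c("V", "a_r", "a_sd", "a_sr", "a_h")
  d
}

as_state <- function(state) {
  state <- as.numeric(state)
  if (length(state) != 5)
    stop("state must have 5 entries (V, a_r, a_sd, a_sr, a_h)")
  if (any(!is.finite(state)))
    stop("non-finite state: numerical blow-up")
  state
}

#' Default initial condition
#'
#' Voltage at `V0` with relaxation gates at their steady state for `V0` and
#' the calcium variable at a small positive level. Optional seeded jitter
#' decorrelates neurons in a network; the post-transient attractor does not
#' depend on the exact choice.
#'
#' @param params parameter vector from [hbih_params()].
#' @param V0 initial voltage (mV).
#' @param a_sr0 initial calcium-like variable.
#' @param jitter SD of Gaussian voltage jitter (mV); gates follow V.
#' @param seed optional RNG seed used when `jitter > 0`.
#' @return named numeric state vector of length 5.
#' @export
hbih_initial_state <- function(params, V0 = -60, a_sr0 = 0.1, jitter = 0,
                               seed = NULL) {
  if (jitter > 0) {
    if (!is.null(seed)) set.seed(seed)
    V0 <- V0 + stats::rnorm(1, 0, jitter)
  }
  c(V = V0,
    a_r = steady_state_activation(V0, params[["s_r"]], params[["V0_r"]]),
    a_sd = steady_state_activation(V0, params[["s_sd"]], params[["V0_sd"]]),
    a_sr = a_sr0,
    a_h = steady_state_activation(V0, params[["s_h"]], params[["V0_h"]]))
}

#' Plain-function form of the vector field
#'
#' Returns `function(state) derivative` closing over fixed parameters, for
#' use with generic integrators and the generic Lyapunov estimator. With
#' `noih = TRUE` the Ih gate is dropped and the model reduces to four
#' variables per neuron (the NoIh model); this is exactly the `g_h = 0`
#' limit of the full model as far as the voltage trajectory is concerned.
#'
#' @param params parameter vector from [hbih_params()].
#' @param noih drop the a_h variable (forces `g_h = 0`).
#' @return function mapping a state vector to its time derivative.
#' @export
hbih_rhs_fun <- function(params, noih = FALSE) {
  p <- as.numeric(params)
  names(p) <- hbih_param_names
  if (!noih) {
    return(function(state) hbih_deriv_cpp(state, p, 0))
  }
  p[["g_h"]] <- 0
  function(state) {
    # 4-variable reduction: state = (V, a_r, a_sd, a_sr), a_h absent.
    full <- hbih_deriv_cpp(c(state, 0), p, 0)
    full[1:4]
  }
}

#' Read/write flat parameter tables
#'
#' One row per neuron, one column per parameter, tab-separated text.
#' `read_params_table` validates names and returns a matrix in canonical
#' column order as consumed by the network integrator.
#'
#' @param params matrix (neurons x 28) or a single parameter vector.
#' @param path file path.
#' @return `read_params_table`: numeric matrix with columns
#'   `hbih_param_names`.
#' @export
write_params_table <- function(params, path) {
  if (is.null(dim(params))) params <- matrix(params, nrow = 1,
                                             dimnames = list(NULL, names(params)))
  stopifnot(identical(colnames(params), hbih_param_names))
  utils::write.table(params, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_params_table
#' @export
read_params_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  missing <- setdiff(hbih_param_names, colnames(d))
  if (length(missing))
    stop("parameter table is missing: ", paste(missing, collapse = ", "))
  m <- as.matrix(d[, hbih_param_names])
  apply(m, 1, validate_hbih_params)
  m
}

#' Per-neuron parameter matrix
#'
#' Expands a list of parameter vectors (or a single vector) into the
#' N x 28 matrix used by the network integrator.
#'
#' @param params a `hbih_params` vector, a list of them, or a matrix.
#' @param N number of neurons (used to replicate a single vector).
#' @return numeric matrix N x 28 with columns `hbih_param_names`.
#' @export
params_matrix <- function(params, N = NULL) {
  if (is.matrix(params)) {
    stopifnot(identical(colnames(params), hbih_param_names))
    return(params)
  }
  if (is.list(params)) {
    m <- do.call(rbind, lapply(params, function(p) as.numeric(p)[seq_len(28)]))
    colnames(m) <- hbih_param_names
    return(m)
  }
  stopifnot(!is.null(N))
  m <- matrix(as.numeric(params), nrow = N, ncol = 28, byrow = TRUE)
  colnames(m) <- hbih_param_names
  m
}
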