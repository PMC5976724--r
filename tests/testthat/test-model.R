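# Single-neuron model: parameters, temperature scaling, gating, currents,
# vector field.

test_that("temperature factors follow the Q10 laws", {
  expect_equal(temperature_factors(25), c(rho = 1, phi = 1))
  expect_equal(temperature_factors(35), c(rho = 1.3, phi = 3))
  tf <- temperature_factors(36)
  expect_equal(tf[["rho"]], 1.3^1.1, tolerance = 1e-12)
  expect_equal(tf[["phi"]], 3^1.1, tolerance = 1e-12)
  expect_true(all(temperature_factors(0) > 0))
})

test_that("reference defaults carry the published constant set", {
  p <- hbih_params()
  expect_equal(
    as.numeric(p[c("C_m", "T", "g_d", "g_r", "g_sd", "g_sr", "g_l", "g_h")]),
    c(1.0, 36, 2.5, 2.8, 0.21, 0.28, 0.06, 0.4))
  expect_equal(as.numeric(p[c("V0_d", "V0_r", "V0_sd", "V0_h")]),
               c(-25, -25, -40, -85))
  expect_equal(as.numeric(p[c("s_d", "s_r", "s_sd", "s_h")]),
               c(0.25, 0.25, 0.11, -0.14))
  expect_equal(as.numeric(p[c("tau_r", "tau_sd", "tau_sr", "tau_h")]),
               c(2, 10, 35, 125))
  expect_equal(as.numeric(p[c("eta", "kappa")]), c(0.014, 0.18))
  expect_equal(as.numeric(p[c("E_d", "E_r", "E_sd", "E_sr", "E_l", "E_h")]),
               c(50, -90, 50, -90, -80, -30))
})

test_that("parameter validation rejects unphysical values", {
  expect_error(hbih_params(g_sd = -0.1), "conductance")
  expect_error(hbih_params(tau_r = 0), "time constants")
  expect_error(hbih_params(C_m = -1), "C_m")
  expect_error(hbih_params(q_zz = 1), "unknown parameter")
})

test_that("steady-state activation is a proper sigmoid", {
  p <- hbih_params()
  expect_equal(steady_state_activation(-40, p[["s_sd"]], -40), 0.5)
  expect_equal(steady_state_activation(1e4, 0.25, -25), 1, tolerance = 1e-10)
  V <- seq(-100, 20, 1)
  up <- steady_state_activation(V, p[["s_sd"]], p[["V0_sd"]])
  dn <- steady_state_activation(V, p[["s_h"]], p[["V0_h"]])
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(dn) < 0))   # Ih gate opens on hyperpolarization
  expect_true(all(up > 0 & up < 1 & dn > 0 & dn < 1))
})

test_that("currents vanish at their reversal potentials", {
  p <- hbih_params()
  for (i in c("d", "r", "sd", "sr", "h", "l")) {
    st <- c(V = p[[paste0("E_", i)]], a_r = 0.3, a_sd = 0.3, a_sr = 0.3,
            a_h = 0.3)
    expect_equal(ionic_currents(st, p)[[paste0("I_", i)]], 0)
  }
})

test_that("calcium gating of I_sr follows the Hill factor", {
  p <- hbih_params()
  rho <- temperature_factors(p[["T"]])[["rho"]]
  st <- c(V = -50, a_r = 0, a_sd = 0, a_sr = 0.4, a_h = 0)
  # at a_sr = 0.4 the gating factor is exactly 1/2
  expect_equal(ionic_currents(st, p)[["I_sr"]],
               rho * p[["g_sr"]] * 0.5 * (-50 - p[["E_sr"]]))
  st[["a_sr"]] <- 0
  expect_equal(ionic_currents(st, p)[["I_sr"]], 0)
})

test_that("gating derivatives vanish at steady state and a_sr at its fixed point", {
  p <- hbih_params()
  V <- -55
  st <- c(V = V,
          a_r = steady_state_activation(V, p[["s_r"]], p[["V0_r"]]),
          a_sd = steady_state_activation(V, p[["s_sd"]], p[["V0_sd"]]),
          a_sr = 0.2,
          a_h = steady_state_activation(V, p[["s_h"]], p[["V0_h"]]))
  d <- hbih_derivatives(st, p)
  expect_equal(unname(d[c("a_r", "a_sd", "a_h")]), c(0, 0, 0),
               tolerance = 1e-12)
  # da_sr/dt = 0 iff a_sr = -eta I_sd / kappa (positive for inward I_sd)
  Isd <- ionic_currents(st, p)[["I_sd"]]
  st[["a_sr"]] <- -p[["eta"]] * Isd / p[["kappa"]]
  expect_gt(st[["a_sr"]], 0)
  expect_equal(hbih_derivatives(st, p)[["a_sr"]], 0, tolerance = 1e-12)
})

test_that("the full vector field vanishes at a numerically located equilibrium", {
  p <- hbih_params()
  # reduce to a scalar problem: gates at steady state, a_sr at its
  # V-dependent fixed point, then root-find dV/dt over V
  Fv <- function(V) {
    st <- c(V = V,
            a_r = steady_state_activation(V, p[["s_r"]], p[["V0_r"]]),
            a_sd = steady_state_activation(V, p[["s_sd"]], p[["V0_sd"]]),
            a_sr = 0,
            a_h = steady_state_activation(V, p[["s_h"]], p[["V0_h"]]))
    Isd <- ionic_currents(st, p)[["I_sd"]]
    st[["a_sr"]] <- -p[["eta"]] * Isd / p[["kappa"]]
    hbih_derivatives(st, p)[["V"]]
  }
  root <- stats::uniroot(Fv, c(-90, -40), tol = 1e-12)$root
  st <- c(V = root,
          a_r = steady_state_activation(root, p[["s_r"]], p[["V0_r"]]),
          a_sd = steady_state_activation(root, p[["s_sd"]], p[["V0_sd"]]),
          a_sr = 0,
          a_h = steady_state_activation(root, p[["s_h"]], p[["V0_h"]]))
  st[["a_sr"]] <- -p[["eta"]] * ionic_currents(st, p)[["I_sd"]] / p[["kappa"]]
  expect_equal(max(abs(hbih_derivatives(st, p))), 0, tolerance = 1e-8)
})

test_that("activation variables stay in [0,1] along trajectories", {
  rhs <- hbih_rhs_fun(hbih_params())
  x0 <- as.numeric(hbih_initial_state(hbih_params()))
  tr <- euler_trace(rhs, x0, dt = 0.025, n_steps = 60000, record_every = 10)
  gates <- tr[, c(2, 3, 5)]
  expect_true(all(gates >= 0 & gates <= 1))
  expect_true(all(is.finite(tr)))
  expect_true(all(tr[, 4] > 0))    # calcium-like variable stays positive
})

test_that("dropping the Ih gate (NoIh) reproduces the g_h = 0 voltage exactly", {
  p <- hbih_params(g_h = 0)
  full <- hbih_rhs_fun(p)
  red <- hbih_rhs_fun(p, noih = TRUE)
  x0 <- as.numeric(hbih_initial_state(p))
  tr5 <- euler_trace(full, x0, dt = 0.025, n_steps = 40000, record_every = 40)
  tr4 <- euler_trace(red, x0[1:4], dt = 0.025, n_steps = 40000,
                     record_every = 40)
  expect_equal(tr4[, 1], tr5[, 1], tolerance = 1e-12)
})

test_that("non-finite states are rejected as blow-up", {
  p <- hbih_params()
  expect_error(hbih_derivatives(c(NaN, 0.1, 0.1, 0.1, 0.1), p), "blow-up")
  expect_error(hbih_derivatives(c(Inf, 0.1, 0.1, 0.1, 0.1), p), "blow-up")
})

test_that("the packaged reference parameter file matches the code defaults", {
  path <- system.file("extdata", "hbih_reference_params.tsv",
                      package = "hbihsync")
  expect_true(nzchar(path))
  m <- read_params_table(path)
  expect_equal(unname(m[1, ]), unname(as.numeric(hbih_params())))
})

test_that("parameter tables round-trip through text files", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  m <- rbind(as.numeric(hbih_params()),
             as.numeric(hbih_params(g_sd = 0.3, g_h = 0)))
  colnames(m) <- names(hbih_params())
  write_params_table(m, tf)
  back <- read_params_table(tf)
  expect_equal(back, m, ignore_attr = TRUE)
})
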