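# Windowed functional connectivity, FCD and the multi-stability variance.

test_that("FC equals the pairwise phase-agreement closed forms", {
  sg <- generate_surrogate("constant_lag", N = 6, fs = 250,
                           duration_ms = 8000, lag = pi / 3)
  fcs <- fc_windows(sg$data, fs = 250, width_ms = 2000, overlap_frac = 0.5)
  for (m in seq_len(dim(fcs$fc)[3]))
    expect_equal(fcs$fc[, , m], sg$ground_truth$fc, tolerance = 1e-12)

  # antiphase pair cancels exactly
  sg2 <- generate_surrogate("constant_lag", N = 2, fs = 250,
                            duration_ms = 4000, lag = pi)
  fcs2 <- fc_windows(sg2$data, fs = 250)
  expect_equal(fcs2$fc[1, 2, 1], 0, tolerance = 1e-12)

  # locked ensemble: all entries 1
  sg3 <- generate_surrogate("locked", N = 5, fs = 250, duration_ms = 4000)
  fcs3 <- fc_windows(sg3$data, fs = 250)
  expect_true(all(abs(fcs3$fc - 1) < 1e-12))
})

test_that("window bookkeeping: 2 s windows at 90% overlap on 30 s give 141 windows", {
  ph <- matrix(stats::runif(30000 * 3), 30000, 3)
  fcs <- fc_windows(ph, fs = 1000, width_ms = 2000, overlap_frac = 0.9)
  expect_equal(dim(fcs$fc)[3], 141)
  expect_equal(fcs$stride_ms, 200)
  expect_equal(fcs$width_ms, 2000)
  expect_error(fc_windows(ph[1:1500, ], fs = 1000, width_ms = 2000),
               "shorter than one window")
  expect_error(fc_windows(ph[1:2100, ], fs = 1000, width_ms = 2000,
                          overlap_frac = 0), "fewer than 2")
})

test_that("FCD is all ones for stationary patterns and block-structured for switching", {
  # identical FCs with internal variance: all correlations exactly 1
  sg <- generate_surrogate("constant_lag", N = 8, fs = 250,
                           duration_ms = 12000, lag = 0.7)
  fcs <- fc_windows(sg$data, fs = 250, width_ms = 2000, overlap_frac = 0.5)
  fcd <- fcd_matrix(fcs)
  expect_true(all(abs(fcd$fcd - 1) < 1e-8))
  expect_false(any(fcd$degenerate))

  # two-state switching: exact blocks of 1 and the cross-correlation c
  set.seed(6)
  sg2 <- generate_surrogate("block_switching", N = 12, fs = 250,
                            duration_ms = 16000, block_ms = 2000, seed = 6)
  fcs2 <- fc_windows(sg2$data, fs = 250, width_ms = 2000, overlap_frac = 0)
  fcd2 <- fcd_matrix(fcs2)
  mask <- (row(sg2$ground_truth$fc_a) - col(sg2$ground_truth$fc_a)) > 1
  c_ab <- stats::cor(sg2$ground_truth$fc_a[mask], sg2$ground_truth$fc_b[mask])
  M <- dim(fcs2$fc)[3]
  same <- outer(seq_len(M) %% 2, seq_len(M) %% 2, "==")
  expected <- ifelse(same, 1, c_ab)
  expect_equal(fcd2$fcd, unname(expected), tolerance = 1e-8)
})

test_that("fully locked synchrony gives a degenerate all-1 FCD", {
  sg <- generate_surrogate("locked", N = 6, fs = 250, duration_ms = 10000)
  fcd <- fcd_matrix(fc_windows(sg$data, fs = 250, overlap_frac = 0.5))
  expect_true(all(fcd$degenerate))
  expect_true(all(fcd$fcd == 1))
})

test_that("independent phases decorrelate FC patterns across windows", {
  means <- vapply(1:5, function(s) {
    sg <- generate_surrogate("independent", N = 30, fs = 250,
                             duration_ms = 12000, seed = s)
    fcd <- fcd_matrix(fc_windows(sg$data, fs = 250, overlap_frac = 0))
    off <- fcd$fcd[row(fcd$fcd) != col(fcd$fcd)]
    mean(off)
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.05)
})

test_that("FC and FCD are invariant under a global phase shift", {
  set.seed(9)
  ph <- matrix(stats::runif(4000, 0, 2 * pi), 1000, 4) +
    outer(seq_len(1000) / 100, rep(1, 4))
  a <- fc_windows(ph, fs = 100, width_ms = 2000, overlap_frac = 0.5)
  b <- fc_windows(ph + 2.5, fs = 100, width_ms = 2000, overlap_frac = 0.5)
  expect_equal(a$fc, b$fc, tolerance = 1e-12)
  expect_equal(fcd_matrix(a)$fcd, fcd_matrix(b)$fcd, tolerance = 1e-10)
})

test_that("the multi-stability variance is the second central moment off the band", {
  M <- 30
  f <- matrix(0.5, M, M)
  expect_equal(multistability_variance(f, exclude_band = 2), 0)

  # half zeros / half ones off the band
  idx <- which(abs(row(f) - col(f)) > 2)
  f2 <- matrix(0, M, M)
  ord <- idx[order(seq_along(idx))]
  f2[ord[seq_len(floor(length(ord) / 2))]] <- 1
  v <- multistability_variance(f2, exclude_band = 2)
  x <- f2[abs(row(f2) - col(f2)) > 2]
  expect_equal(v, mean((x - mean(x))^2))
  expect_equal(v, 0.25, tolerance = 1e-3)

  # histogram-moment agreement on a realistic FCD
  sg <- generate_surrogate("block_switching", N = 10, fs = 250,
                           duration_ms = 16000, block_ms = 2000, seed = 2)
  fcd <- fcd_matrix(fc_windows(sg$data, fs = 250, overlap_frac = 0))
  vals <- fcd_values(fcd, exclude_band = 0)
  expect_equal(multistability_variance(fcd, exclude_band = 0),
               mean((vals - mean(vals))^2))
})

test_that("block switching attains the closed-form variance p(1-p)(1-c)^2", {
  sg <- generate_surrogate("block_switching", N = 12, fs = 250,
                           duration_ms = 16000, block_ms = 2000, seed = 6)
  fcs <- fc_windows(sg$data, fs = 250, width_ms = 2000, overlap_frac = 0)
  fcd <- fcd_matrix(fcs)
  M <- nrow(fcd$fcd)
  mask <- (row(sg$ground_truth$fc_a) - col(sg$ground_truth$fc_a)) > 1
  c_ab <- stats::cor(sg$ground_truth$fc_a[mask], sg$ground_truth$fc_b[mask])
  # enumeration oracle over the alternating window schedule
  states <- seq_len(M) %% 2
  off <- which(abs(row(diag(M)) - col(diag(M))) > 0)
  vals <- ifelse(outer(states, states, "==")[off], 1, c_ab)
  q <- mean(outer(states, states, "==")[off])
  expect_equal(mean((vals - mean(vals))^2), q * (1 - q) * (1 - c_ab)^2,
               tolerance = 1e-12)
  expect_equal(multistability_variance(fcd, exclude_band = 0),
               q * (1 - q) * (1 - c_ab)^2, tolerance = 1e-8)
})

test_that("the overlap-based exclusion band defaults to 9 for 2 s / 90%", {
  expect_equal(fcd_exclude_band(2000, 200), 9L)
  expect_equal(fcd_exclude_band(2000, 2000), 0L)
})
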