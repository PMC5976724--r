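# Firing rates, events and bursts, pattern codes, parameter scans and
# matched-population sampling.

test_that("firing rate is spike count per second", {
  expect_equal(firing_rate(numeric(0), 10000), 0)
  expect_equal(firing_rate(seq_len(35), 10000), 3.5)
  expect_equal(firing_rate(seq_len(80), 10000), 8.0)
  expect_error(firing_rate(1, 0))
})

test_that("spikes are grouped into events and the burst fraction follows", {
  # far-apart singles: one event each, no bursts
  ev <- group_events(c(100, 600, 1100), period_ms = 500)
  expect_length(ev, 3)
  expect_equal(burst_fraction(ev), 0)

  # 3 bursts of 3 spikes + 2 singles: 5 events, b_k = 3/5
  sp <- sort(c(1000, 1010, 1020, 2500, 4000, 4012, 4025,
               6000, 6010, 6021, 8200))
  ev <- group_events(sp, period_ms = 400)
  expect_length(ev, 5)
  expect_equal(sum(vapply(ev, length, integer(1)) >= 2), 3)
  expect_equal(burst_fraction(ev), 0.6)

  expect_identical(group_events(numeric(0)), list())
})

test_that("event grouping recovers the fixture from its voltage trace", {
  sg <- generate_surrogate("spike_train", fs = 1000, duration_ms = 10000)
  sp <- detect_spikes(sg$data[, 1], fs = sg$fs)
  expect_equal(length(sp), length(sg$ground_truth$spike_times_ms))
  ev <- group_events(sp, V = sg$data[, 1], fs = sg$fs)
  expect_equal(length(ev), sg$ground_truth$n_events)
  expect_equal(burst_fraction(ev), sg$ground_truth$b_k)
})

test_that("mean burst fraction is the population mean of b_k", {
  expect_equal(mean_burst_fraction(rep(0, 5)), 0)
  expect_equal(mean_burst_fraction(c(0, 0, 1, 1)), 0.5)
  set.seed(1)
  b <- stats::runif(40)
  expect_equal(mean_burst_fraction(b), sum(b) / 40)
  expect_equal(mean_burst_fraction(c(0.5, NA)), 0.5)
})

test_that("pattern codes cover flat, subthreshold, bursting and fast tonic", {
  fs <- 1000
  flat <- list(V = rep(-60, 5000), spikes = numeric(0), fs = fs,
               t_record = 5000)
  expect_equal(classify_pattern(flat)$code, 0L)

  sub <- generate_surrogate("subthreshold", fs = fs, duration_ms = 5000)
  expect_equal(classify_pattern(list(V = sub$data[, 1], spikes = numeric(0),
                                     fs = fs, t_record = 5000))$code, 1L)

  burst <- generate_surrogate("spike_train", fs = fs, duration_ms = 10000)
  recb <- list(V = burst$data[, 1],
               spikes = detect_spikes(burst$data[, 1], fs),
               fs = fs, t_record = 10000)
  cb <- classify_pattern(recb)
  expect_equal(cb$code, burst$ground_truth$pattern_code)
  expect_equal(cb$b_k, burst$ground_truth$b_k)
  expect_equal(cb$spikes_per_burst, 3)

  # rates above the tonic bands dominate the code
  fast <- list(V = rep(-60, 10000), spikes = seq(10, 9990, length.out = 600),
               fs = fs, t_record = 10000)
  expect_equal(classify_pattern(fast)$code, 6L)
  mid <- list(V = rep(-60, 10000), spikes = seq(10, 9990, length.out = 250),
              fs = fs, t_record = 10000)
  expect_equal(classify_pattern(mid)$code, 5L)
})

test_that("skipping is detected when slow cycles outnumber events", {
  fs <- 1000
  tt <- seq(0, 10, by = 1 / fs)[-1]
  V <- -60 + 10 * sin(2 * pi * 4 * tt)       # 4 Hz slow rhythm, 40 cycles
  spikes <- seq(250, 9750, by = 500)         # one spike every 2nd cycle
  rec <- list(V = V, spikes = spikes, fs = fs, t_record = 10000)
  expect_equal(classify_pattern(rec)$code, 2L)
})

test_that("a small parameter scan is complete, deterministic and anchored", {
  sc <- scan_parameter_plane(c(0.21, 0.28), c(0.28, 0.32), g_h = 0.4,
                             t_record = 4000, t_transient = 2000,
                             mle_average = 4000, seed = 2)
  expect_equal(nrow(sc), 4)
  expect_true(all(!is.na(sc$mle)))
  expect_true(all(!is.na(sc$firing_rate)))
  expect_true(all(sc$class %in% c("chaotic", "non_chaotic")))
  sc2 <- scan_parameter_plane(c(0.21, 0.28), c(0.28, 0.32), g_h = 0.4,
                              t_record = 4000, t_transient = 2000,
                              mle_average = 4000, seed = 2)
  expect_identical(sc, sc2)
  # the reference default point appears with a positive firing rate
  single <- simulate_neuron(hbih_params(), t_transient = 2000,
                            t_record = 4000)
  i <- which(sc$g_sd == 0.21 & sc$g_sr == 0.28)
  expect_equal(sc$firing_rate[i], firing_rate(single$spikes, 4000))
  expect_gt(sc$firing_rate[i], 0)
})

# Synthetic scan tables with fully controlled rates/MLEs let the sampling
# contract be tested without simulation.
fake_scan <- function(fr, mle, g_h = 0.4) {
  n <- length(fr)
  data.frame(g_sd = seq(0.2, 0.3, length.out = n),
             g_sr = seq(0.25, 0.35, length.out = n), g_h = g_h,
             mle = mle, converged = TRUE, firing_rate = fr,
             firing_pattern = 3L, spikes_per_burst = NA_real_,
             class = ifelse(mle > 0, "chaotic", "non_chaotic"),
             uncertain = FALSE, diverged = FALSE)
}

test_that("matched sampling enforces equal per-bin counts and matches distributions", {
  centers <- rep(seq(3.05, 4.45, by = 0.1), each = 6)
  sc1 <- fake_scan(c(centers, centers),
                   c(rep(0.003, length(centers)), rep(-0.002, length(centers))))
  sc0 <- fake_scan(centers, rep(-0.001, length(centers)), g_h = 0)
  m <- sample_matched_populations(sc1, sc0, band = c(3, 4.5),
                                  bin_width = 0.1, n_per_bin = 4, seed = 3)
  expect_length(m$rate_bins, 16)      # 15 bins spanning 3.0-4.5 Hz
  h <- function(d) tabulate(findInterval(d$firing_rate, m$rate_bins), 15)
  expect_equal(h(m$chaotic), rep(4, 15))
  expect_equal(h(m$chaotic), h(m$non_chaotic))
  expect_equal(h(m$chaotic), h(m$noih))
  # identical candidate rates per bin: the drawn samples are identical
  expect_true(all(m$ks_pvalues == 1))
})

test_that("matched sampling shrinks uniformly, errors on empty bins, and can drop them", {
  centers <- seq(3.05, 4.45, by = 0.1)
  rich <- rep(centers, each = 5)
  poor <- c(rep(centers[-3], each = 5), centers[3])  # bin 3 has one point
  sc1 <- fake_scan(c(rich, poor), c(rep(0.003, length(rich)),
                                    rep(-0.002, length(poor))))
  sc0 <- fake_scan(rich, rep(-0.001, length(rich)), g_h = 0)
  expect_warning(
    m <- sample_matched_populations(sc1, sc0, n_per_bin = 4, seed = 1),
    "shrunk")
  expect_true(all(m$n_per_bin == 1))

  gone <- rep(centers[-3], each = 5)   # bin 3 empty in the non-chaotic set
  sc1b <- fake_scan(c(rich, gone), c(rep(0.003, length(rich)),
                                     rep(-0.002, length(gone))))
  expect_error(sample_matched_populations(sc1b, sc0, n_per_bin = 2),
               "infeasible matching.*3\\.2")
  m2 <- sample_matched_populations(sc1b, sc0, n_per_bin = 2,
                                   drop_empty_bins = TRUE)
  h <- function(d) tabulate(findInterval(d$firing_rate, m2$rate_bins), 15)
  expect_equal(h(m2$chaotic), h(m2$non_chaotic))
  expect_equal(h(m2$chaotic)[3], 0)
  expect_equal(sum(h(m2$chaotic)), 2 * 14)
})

test_that("population draws expand into valid parameter matrices", {
  pop <- data.frame(g_sd = c(0.2, 0.25), g_sr = c(0.3, 0.28), g_h = 0.4)
  pm <- population_params(pop, N = 10, seed = 5)
  expect_equal(dim(pm), c(10, 28))
  expect_true(all(pm[, "g_sd"] %in% pop$g_sd))
  expect_true(all(pm[, "g_h"] == 0.4))
  expect_identical(pm, population_params(pop, N = 10, seed = 5))
})
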