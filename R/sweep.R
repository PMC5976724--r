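# End-to-end conductance sweep: for each (population, g, network seed)
# build a Newman-Watts network, simulate, and measure synchrony (R, chi),
# optional network MLE, FCD variance and burst statistics; aggregate
# across seeds into transition curves.

#' Run one (population, g, seed) network simulation and measure it
#'
#' Topology, parameter draw and initial conditions are all controlled by
#' `seed`, so that different populations and g values can share identical
#' connectivity matrices.
#'
#' @param population data.frame of `(g_sd, g_sr, g_h)` triples, or `NULL`
#'   to use `base_params` homogeneously.
#' @param g gap-junction conductance (mS/cm^2).
#' @param seed network realization seed (topology + parameter draw +
#'   initial states).
#' @param N,K,p Newman-Watts parameters.
#' @param t_transient,t_record durations (ms).
#' @param base_params template neuron parameters.
#' @param with_mle estimate the network MLE (adds a second integration).
#' @param with_fcd compute the FCD variance.
#' @param with_bursts compute the mean burst fraction.
#' @param mle_average network MLE averaging time (ms).
#' @param fc_width_ms,fc_overlap FC window geometry.
#' @param dt,record_dt integration step and trace sampling interval (ms).
#' @return one-row data.frame of metrics.
#' @export
run_network_condition <- function(population, g, seed, N = 50, K = 5,
                                  p = 0.1, t_transient = 3000,
                                  t_record = 20000,
                                  base_params = hbih_params(),
                                  with_mle = FALSE, with_fcd = TRUE,
                                  with_bursts = FALSE,
                                  mle_average = 10000,
                                  fc_width_ms = 2000, fc_overlap = 0.9,
                                  dt = 0.025, record_dt = 1) {
  A <- newman_watts(N, K, p, seed = seed)
  pm <- if (is.null(population)) params_matrix(base_params, N = N)
        else population_params(population, N, base_params, seed = seed)
  spec <- network_spec(A, g, pm)
  rec <- simulate_network(spec, t_transient = t_transient,
                          t_record = t_record, seed_init = seed,
                          dt = dt, record_dt = record_dt)
  ph <- extract_phase(rec$V, rec$fs)
  sm <- synchrony_metrics(ph)
  fcd_var <- NA_real_
  if (with_fcd) {
    fcd_var <- tryCatch({
      fcs <- fc_windows(ph, width_ms = fc_width_ms,
                        overlap_frac = fc_overlap)
      multistability_variance(fcd_matrix(fcs))
    }, error = function(e) NA_real_)
  }
  mle <- NA_real_
  if (with_mle) {
    est <- mle_network(spec, t_transient = 0, t_average = mle_average,
                       states0 = rec$final_state, seed = seed, dt = dt)
    mle <- est$mle
  }
  mb <- NA_real_
  if (with_bursts) {
    b <- vapply(seq_len(N), function(k)
      burst_fraction(group_events(rec$spikes[[k]], V = rec$V[, k],
                                  fs = rec$fs)), numeric(1))
    mb <- mean_burst_fraction(b)
  }
  data.frame(g = g, seed = seed, R = sm$R, chi = sm$chi,
             fcd_var = fcd_var, mle_network = mle, mean_burst = mb,
             mean_rate = mean(vapply(rec$spikes, length, integer(1))) /
               (t_record / 1000))
}

#' Conductance sweep over populations and network seeds
#'
#' For every population label, coupling value and seed, runs
#' [run_network_condition()] and aggregates across seeds (mean, SD, SEM).
#' With `out_dir` set, per-run rows are written as small CSVs and
#' completed runs are skipped on re-execution, making long sweeps
#' resumable; failed runs are counted and excluded from averages, never
#' silently absorbed.
#'
#' @param populations named list of population data.frames (or `NULL`
#'   entries for homogeneous networks of `base_params`).
#' @param g_values non-negative, sorted coupling values; default 0 plus
#'   log-spaced values in `[1e-4, 1]`.
#' @param n_seeds network realizations per condition.
#' @param out_dir optional directory for resumable per-run CSVs.
#' @param seeds explicit per-realization seeds (default `1:n_seeds`);
#'   shared across populations and g values so every condition sees the
#'   same set of connectivity matrices.
#' @param N,K,p Newman-Watts geometry, forwarded to
#'   [run_network_condition()].
#' @param ... further arguments to [run_network_condition()].
#' @return list of class `sweep_result`: `runs` (per-run rows), `curves`
#'   (per population x g aggregates), `n_failed`.
#' @export
run_sweep <- function(populations, g_values = default_g_grid(),
                      n_seeds = 3, out_dir = NULL,
                      seeds = seq_len(n_seeds), N = 50, K = 5, p = 0.1,
                      ...) {
  stopifnot(all(g_values >= 0), !is.unsorted(g_values), length(seeds) >= 1)
  if (is.null(names(populations)) && length(populations) > 0)
    names(populations) <- paste0("pop", seq_along(populations))
  runs <- list()
  n_failed <- 0L
  for (lab in names(populations)) {
    for (g in g_values) {
      for (s in seeds) {
        path <- NULL
        if (!is.null(out_dir)) {
          dir.create(file.path(out_dir, "runs"), recursive = TRUE,
                     showWarnings = FALSE)
          path <- file.path(out_dir, "runs",
                            sprintf("%s_g%.6g_s%d.csv", lab, g, s))
          if (file.exists(path)) {
            runs[[length(runs) + 1L]] <-
              cbind(population = lab,
                    utils::read.csv(path, stringsAsFactors = FALSE))
            next
          }
        }
        row <- tryCatch(run_network_condition(populations[[lab]], g, s,
                                              N = N, K = K, p = p, ...),
                        error = function(e) {
                          warning(sprintf("run failed (%s, g=%g, seed=%d): %s",
                                          lab, g, s, conditionMessage(e)))
                          NULL
                        })
        if (is.null(row)) {
          n_failed <- n_failed + 1L
          next
        }
        if (!is.null(path)) utils::write.csv(row, path, row.names = FALSE)
        runs[[length(runs) + 1L]] <- cbind(population = lab, row)
      }
    }
  }
  runs <- do.call(rbind, runs)
  structure(list(runs = runs, curves = aggregate_sweep(runs),
                 n_failed = n_failed),
            class = "sweep_result")
}

#' Default coupling grid
#'
#' Zero plus 25 logarithmically spaced values in `[1e-4, 1]`, matching the
#' logarithmic presentation of synchronization transition curves.
#'
#' @param n number of log-spaced points.
#' @return sorted numeric vector of length `n + 1`.
#' @export
default_g_grid <- function(n = 25) {
  c(0, exp(seq(log(1e-4), log(1), length.out = n)))
}

aggregate_sweep <- function(runs) {
  if (is.null(runs) || nrow(runs) == 0) return(NULL)
  metrics <- c("R", "chi", "fcd_var", "mle_network", "mean_burst",
               "mean_rate")
  out <- list()
  for (lab in unique(runs$population)) {
    for (g in unique(runs$g[runs$population == lab])) {
      sub <- runs[runs$population == lab & runs$g == g, , drop = FALSE]
      row <- data.frame(population = lab, g = g, n_seeds = nrow(sub))
      for (m in metrics) {
        x <- sub[[m]]
        x <- x[is.finite(x)]
        row[[paste0(m, "_mean")]] <- if (length(x)) mean(x) else NA_real_
        row[[paste0(m, "_sd")]] <- if (length(x) > 1) stats::sd(x) else NA_real_
        row[[paste0(m, "_sem")]] <- if (length(x) > 1)
          stats::sd(x) / sqrt(length(x)) else NA_real_
      }
      out[[length(out) + 1L]] <- row
    }
  }
  out <- do.call(rbind, out)
  out[order(out$population, out$g), ]
}

#' Compare transition curves between two populations
#'
#' Per-g difference of seed means for a metric, with the standard error of
#' the difference from seed-level dispersion. The two curves must share
#' the same g grid.
#'
#' @param sweep a `sweep_result` (or its `curves` data.frame).
#' @param pop_a,pop_b population labels.
#' @param metric metric name (`"R"`, `"chi"`, `"fcd_var"`, ...).
#' @return data.frame `g`, `mean_a`, `mean_b`, `diff`, `se_diff`.
#' @export
compare_conditions <- function(sweep, pop_a, pop_b, metric = "R") {
  curves <- if (inherits(sweep, "sweep_result")) sweep$curves else sweep
  a <- curves[curves$population == pop_a, ]
  b <- curves[curves$population == pop_b, ]
  a <- a[order(a$g), ]
  b <- b[order(b$g), ]
  if (!isTRUE(all.equal(a$g, b$g)))
    stop("mismatched g grids between populations")
  ma <- a[[paste0(metric, "_mean")]]
  mb <- b[[paste0(metric, "_mean")]]
  sa <- a[[paste0(metric, "_sem")]]
  sb <- b[[paste0(metric, "_sem")]]
  data.frame(g = a$g, mean_a = ma, mean_b = mb, diff = ma - mb,
             se_diff = sqrt(sa^2 + sb^2))
}
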