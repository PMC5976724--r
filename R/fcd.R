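# Windowed functional connectivity (pairwise phase agreement), the FCD
# matrix (correlation between FC patterns at all window pairs) and the
# variance-based multi-stability measure.

#' Windowed functional connectivity series
#'
#' Splits a phase ensemble into overlapping windows and computes, per
#' window, the pairwise phase-agreement matrix
#' `FC_kl = < | (e^{i phi_k} + e^{i phi_l}) / 2 | >_t` (the two-oscillator
#' order parameter), which equals the time average of `|cos((phi_k -
#' phi_l)/2)|`. Diagonal entries are 1.
#'
#' @param phases a `phase_ensemble` or samples x nodes phase matrix.
#' @param fs sampling rate (Hz); taken from the ensemble when omitted.
#' @param width_ms window width (ms).
#' @param overlap_frac fractional overlap between consecutive windows in
#'   `[0, 1)`; 0.9 gives a 10 percent stride.
#' @return list of class `fc_series`: `fc` (N x N x M array), `windows`
#'   (data.frame `start_ms`, `end_ms`), `width_ms`, `stride_ms`.
#' @export
fc_windows <- function(phases, fs = NULL, width_ms = 2000,
                       overlap_frac = 0.9) {
  if (inherits(phases, "phase_ensemble")) {
    fs <- phases$fs
    phases <- phases$phases
  }
  stopifnot(!is.null(fs), overlap_frac >= 0, overlap_frac < 1)
  n <- nrow(phases)
  width <- round(width_ms * fs / 1000)
  stride <- max(1L, round(width * (1 - overlap_frac)))
  if (width > n) stop("recording shorter than one window")
  starts <- seq(0L, n - width, by = stride)
  if (length(starts) < 2)
    stop("insufficient data: fewer than 2 windows")
  fc <- fc_windows_cpp(phases, as.integer(starts), as.integer(width))
  stride_ms <- stride * 1000 / fs
  structure(list(
    fc = fc,
    windows = data.frame(start_ms = starts * 1000 / fs,
                         end_ms = (starts + width) * 1000 / fs),
    width_ms = width * 1000 / fs, stride_ms = stride_ms),
    class = "fc_series")
}

# Lower-triangle vectorization of each FC, excluding the main diagonal
# and `exclude_diag` adjacent sub-diagonals.
fc_vectors <- function(fc, exclude_diag = 1) {
  N <- dim(fc)[1]
  M <- dim(fc)[3]
  mask <- (row(matrix(0, N, N)) - col(matrix(0, N, N))) > exclude_diag
  if (!any(mask)) stop("exclusion removes the whole lower triangle")
  matrix(vapply(seq_len(M), function(m) fc[, , m][mask],
                numeric(sum(mask))),
         nrow = sum(mask), ncol = M)
}

#' Functional connectivity dynamics matrix
#'
#' Pairwise Pearson correlation between the vectorized FC patterns of all
#' window pairs. Each FC is vectorized from its lower triangle, discarding
#' the diagonal and the `exclude_diag` values adjacent to it. Fully
#' synchronized (zero-variance) FC vectors have no defined correlation:
#' two constant, equal vectors are assigned 1, a constant against a
#' varying vector 0, and such windows are flagged degenerate.
#'
#' @param fcs an `fc_series`, or an N x N x M array of FC matrices.
#' @param exclude_diag sub-diagonals of FC excluded from vectorization.
#' @return list of class `fcd_matrix`: `fcd` (M x M, symmetric, unit
#'   diagonal), `degenerate` (logical, per window), `stride_ms`,
#'   `width_ms` (NA when unknown).
#' @export
fcd_matrix <- function(fcs, exclude_diag = 1) {
  width_ms <- stride_ms <- NA_real_
  if (inherits(fcs, "fc_series")) {
    width_ms <- fcs$width_ms
    stride_ms <- fcs$stride_ms
    fcs <- fcs$fc
  }
  M <- dim(fcs)[3]
  if (M < 3) stop("need at least 3 windows for an FCD matrix")
  v <- fc_vectors(fcs, exclude_diag)
  sds <- apply(v, 2, stats::sd)
  degen <- is.na(sds) | sds < 1e-12
  fcd <- matrix(1, M, M)
  ok <- which(!degen)
  if (length(ok) >= 2)
    fcd[ok, ok] <- stats::cor(v[, ok, drop = FALSE])
  for (i in which(degen)) {
    for (j in seq_len(M)) {
      if (i == j) next
      fcd[i, j] <- fcd[j, i] <-
        if (degen[j] && max(abs(v[, i] - v[, j])) < 1e-8) 1 else 0
    }
  }
  diag(fcd) <- 1
  structure(list(fcd = fcd, degenerate = degen, stride_ms = stride_ms,
                 width_ms = width_ms),
            class = "fcd_matrix")
}

#' Default FCD exclusion band
#'
#' Number of FCD off-diagonals whose windows overlap in time (those pairs
#' are trivially correlated): `ceiling(width/stride) - 1`, e.g. 9 for 2 s
#' windows at 90 percent overlap.
#'
#' @param width_ms,stride_ms window geometry (ms).
#' @return integer band half-width.
#' @export
fcd_exclude_band <- function(width_ms, stride_ms) {
  as.integer(ceiling(width_ms / stride_ms) - 1)
}

#' Multi-stability measure: variance of off-band FCD values
#'
#' Variance (second central moment) of the FCD entries with
#' `|i - j| > exclude_band`. Near zero both for fully evolving dynamics
#' (all entries near 0) and for frozen synchrony (all entries near 1);
#' large when transiently recurring synchronization patterns produce a
#' mixture of high and low FC correlations.
#'
#' @param fcd an `fcd_matrix` or a plain M x M matrix.
#' @param exclude_band off-diagonal half-band to drop; defaults to the
#'   overlap-based band when the window geometry is known, else 9.
#' @return non-negative scalar.
#' @export
multistability_variance <- function(fcd, exclude_band = NULL) {
  if (inherits(fcd, "fcd_matrix")) {
    if (is.null(exclude_band))
      exclude_band <- if (is.finite(fcd$stride_ms))
        fcd_exclude_band(fcd$width_ms, fcd$stride_ms) else 9L
    fcd <- fcd$fcd
  }
  if (is.null(exclude_band)) exclude_band <- 9L
  M <- nrow(fcd)
  if (M <= exclude_band + 1)
    stop("need more windows than the exclusion band")
  sel <- abs(row(fcd) - col(fcd)) > exclude_band
  x <- fcd[sel]
  mean((x - mean(x))^2)
}

#' Off-band FCD values
#'
#' The FCD entries entering the multi-stability variance (upper triangle,
#' `j - i > exclude_band`), e.g. for histograms.
#'
#' @inheritParams multistability_variance
#' @return numeric vector.
#' @export
fcd_values <- function(fcd, exclude_band = NULL) {
  if (inherits(fcd, "fcd_matrix")) {
    if (is.null(exclude_band))
      exclude_band <- if (is.finite(fcd$stride_ms))
        fcd_exclude_band(fcd$width_ms, fcd$stride_ms) else 9L
    fcd <- fcd$fcd
  }
  if (is.null(exclude_band)) exclude_band <- 9L
  fcd[col(fcd) - row(fcd) > exclude_band]
}
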