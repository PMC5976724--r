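# Structural connectivity: Newman-Watts small-world graphs and the
# gap-junction coupling terms of the network vector field.

#' Newman-Watts small-world adjacency matrix
#'
#' Builds a ring lattice of `N` nodes where each node is connected to its
#' `K` nearest neighbours on either side (degree `2K`), then, for each
#' node, adds one shortcut edge with probability `p` to a uniformly chosen
#' node that is neither itself nor an existing neighbour. No lattice edge
#' is removed and the result is symmetrized, as appropriate for electrical
#' synapses. Identical seeds give identical matrices.
#'
#' @param N number of nodes; must satisfy `N > 2K`.
#' @param K nearest neighbours per side on the ring.
#' @param p per-node shortcut probability in `[0, 1]`.
#' @param seed RNG seed controlling shortcut placement.
#' @return symmetric 0/1 matrix with zero diagonal.
#' @examples
#' A <- newman_watts(20, 2, 0.1, seed = 1)
#' all(rowSums(A) >= 4)
#' @export
newman_watts <- function(N, K, p, seed = 1L) {
  if (!(N > 2 * K && K >= 1)) stop("invalid topology: need N > 2K >= 2")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  A <- matrix(0L, N, N)
  for (d in seq_len(K)) {
    for (k in seq_len(N)) {
      l <- ((k - 1 + d) %% N) + 1
      A[k, l] <- 1L
      A[l, k] <- 1L
    }
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  for (k in seq_len(N)) {
    if (stats::runif(1) < p) {
      candidates <- which(A[k, ] == 0L)
      candidates <- setdiff(candidates, k)
      if (length(candidates)) {
        l <- candidates[sample.int(length(candidates), 1)]
        A[k, l] <- 1L
        A[l, k] <- 1L
      }
    }
  }
  A
}

# Seed scoping: draw from a private RNG stream without disturbing the
# caller's .Random.seed.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Edge list of a symmetric adjacency matrix
#'
#' Each undirected edge appears once, as 0-based indices `(k, l)` with
#' `k < l` — the representation consumed by the compiled integrator.
#'
#' @param A symmetric 0/1 adjacency matrix.
#' @return integer matrix with two columns.
#' @export
adjacency_to_edges <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (!isTRUE(all.equal(A, t(A)))) stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency must have zero diagonal")
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  e <- cbind(idx[, 1], idx[, 2]) - 1L
  storage.mode(e) <- "integer"
  colnames(e) <- c("k", "l")
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

#' @rdname adjacency_to_edges
#' @param edges integer edge matrix (0-based).
#' @param N number of nodes.
#' @export
edges_to_adjacency <- function(edges, N) {
  A <- matrix(0L, N, N)
  for (e in seq_len(nrow(edges))) {
    k <- edges[e, 1] + 1L
    l <- edges[e, 2] + 1L
    A[k, l] <- 1L
    A[l, k] <- 1L
  }
  A
}

#' Edge-list text serialization
#'
#' Writes one `"k l"` pair per line (0-based indices); the round trip
#' preserves the adjacency exactly.
#'
#' @param A adjacency matrix.
#' @param path file path.
#' @export
write_edge_list <- function(A, path) {
  e <- adjacency_to_edges(A)
  utils::write.table(e, path, sep = " ", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @param N number of nodes.
#' @export
read_edge_list <- function(path, N) {
  e <- as.matrix(utils::read.table(path, header = FALSE))
  storage.mode(e) <- "integer"
  edges_to_adjacency(e, N)
}

#' Gap-junction current between two membrane potentials
#'
#' Diffusive electrical coupling: the current entering neuron `k` from
#' neuron `l` is `g * (V_l - V_k)`, pulling `V_k` toward `V_l`. Summed over
#' a symmetric adjacency the total injected current is zero.
#'
#' @param V_k,V_l membrane voltages (mV); vectorized.
#' @param g gap conductance (mS/cm^2), `>= 0`.
#' @return current into neuron k (uA/cm^2).
#' @export
gap_junction_current <- function(V_k, V_l, g) {
  stopifnot(all(g >= 0))
  g * (V_l - V_k)
}

#' Network specification
#'
#' Bundles adjacency, uniform gap conductance and per-node parameters.
#'
#' @param A symmetric adjacency matrix.
#' @param g uniform gap conductance (mS/cm^2).
#' @param params per-node parameters (matrix, list, or single vector).
#' @return list with class `network_spec`: `N`, `A`, `edges`, `g`, `params`.
#' @export
network_spec <- function(A, g, params) {
  N <- nrow(A)
  edges <- adjacency_to_edges(A)
  pm <- params_matrix(params, N = N)
  if (nrow(pm) != N) stop("params must have one row per node")
  stopifnot(g >= 0)
  structure(list(N = N, A = A, edges = edges, g = g, params = pm),
            class = "network_spec")
}

#' Coupled-network vector field
#'
#' Evaluates the time derivative of all neuron states, with gap-junction
#' input `I_syn,k = g * sum_l C_kl (V_l - V_k)`. For a symmetric adjacency
#' the gap currents conserve: `sum_k I_syn,k = 0` exactly.
#'
#' @param states N x 5 matrix of neuron states (rows: neurons).
#' @param spec a [network_spec()].
#' @return N x 5 matrix of derivatives.
#' @export
network_rhs <- function(states, spec) {
  stopifnot(inherits(spec, "network_spec"))
  if (!is.matrix(states) || nrow(states) != spec$N || ncol(states) != 5)
    stop("states must be an N x 5 matrix")
  Isyn <- network_isyn_cpp(states[, 1], spec$edges, spec$g)
  out <- matrix(0, spec$N, 5)
  for (k in seq_len(spec$N)) {
    out[k, ] <- hbih_deriv_cpp(states[k, ], spec$params[k, ], Isyn[k])
  }
  colnames(out) <- c("V", "a_r", "a_sd", "a_sr", "a_h")
  out
}

#' Gap input currents for a voltage configuration
#'
#' @param V voltage vector (mV).
#' @param spec a [network_spec()].
#' @return numeric vector of per-node input currents (uA/cm^2).
#' @export
network_isyn <- function(V, spec) {
  network_isyn_cpp(V, spec$edges, spec$g)
}
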