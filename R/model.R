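## Markov model representation: undirected connected graph of conformational
## states, per-state relative conductance, and the (alpha, beta) parameter
## vectors that generate detailed-balance-respecting rates (see
## rates_at_voltage()).

#' Construct a Markov model of channel gating
#'
#' A gating model is a connected undirected graph on `n_states` conformational
#' states, a per-state relative conductance in `[0, 1]`, and rate parameters.
#' Each state `i` carries a vector `alpha[i, ]` (length F, the basis
#' dimension) parameterizing its unnormalized equilibrium occupancy
#' `s_i(v) = exp(f(v) . alpha_i)`; each edge `{i, j}` carries `beta[e, ]`
#' parameterizing the product of its forward and backward rates
#' `k_ij(v) = exp(f(v) . beta_e)`. Rates derived from `(alpha, beta)` satisfy
#' detailed balance at every voltage by construction.
#'
#' State 1's alpha row is pinned to zero: equilibrium occupancies enter the
#' rates only through differences `alpha_j - alpha_i`, so one row per basis
#' dimension is not identifiable and is fixed as a gauge choice.
#'
#' @param n_states Number of states (>= 1).
#' @param edges Two-column integer matrix of undirected edges (1-based state
#'   ids); stored canonically with each row sorted and rows ordered
#'   lexicographically.
#' @param conductance Numeric vector of per-state relative conductances in
#'   `[0, 1]` (usually 0/1).
#' @param alpha `n_states x F` matrix of per-state occupancy parameters; row 1
#'   must be zero.
#' @param beta `E x F` matrix of per-edge rate-product parameters, rows
#'   aligned with the canonical edge order.
#' @param basis A [voltage_basis()].
#' @return An object of class `"markov_model"`.
#' @seealso [random_model()], [build_Q()], [validate_model()]
#' @export
markov_model <- function(n_states, edges, conductance, alpha, beta, basis) {
  gf_check(is.numeric(n_states) && length(n_states) == 1L && n_states >= 1,
           "gatefit_invalid_argument", "n_states must be a positive integer")
  n_states <- as.integer(n_states)
  edges <- canonical_edges(edges, n_states)
  alpha <- as.matrix(alpha)
  beta <- matrix(as.numeric(as.matrix(beta)), nrow = nrow(edges))
  model <- structure(
    list(n_states = n_states,
         edges = edges,
         conductance = as.numeric(conductance),
         alpha = alpha,
         beta = beta,
         basis = basis),
    class = "markov_model")
  rep <- validate_model(model)
  gf_check(rep$ok, "gatefit_invalid_argument",
           paste0("invalid model: ", paste(rep$violations, collapse = "; ")))
  model
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("<markov_model: %d states, %d edges, %s basis>\n",
              x$n_states, nrow(x$edges), x$basis$kind))
  cat("  conducting state(s):", which(x$conductance > 0), "\n")
  cat("  edges:", paste(apply(x$edges, 1L, paste, collapse = "-"),
                        collapse = ", "), "\n")
  invisible(x)
}

## Canonical edge storage: each row (i, j) with i < j, rows sorted
## lexicographically, no duplicates. Forward rate direction is i -> j.
canonical_edges <- function(edges, n_states) {
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2L)
  gf_check(nrow(edges) >= 1L, "gatefit_invalid_argument",
           "edge set must be non-empty")
  gf_check(all(edges >= 1L & edges <= n_states),
           "gatefit_invalid_argument", "edge references an invalid state id")
  gf_check(all(edges[, 1L] != edges[, 2L]),
           "gatefit_invalid_argument", "self-loops are not allowed")
  swap <- edges[, 1L] > edges[, 2L]
  edges[swap, ] <- edges[swap, 2:1]
  ord <- order(edges[, 1L], edges[, 2L])
  edges <- edges[ord, , drop = FALSE]
  gf_check(!anyDuplicated(edges), "gatefit_invalid_argument",
           "duplicate edges are not allowed")
  dimnames(edges) <- NULL
  edges
}

## Connected components by breadth-first search over an adjacency list.
## Kept dependency-free because it sits inside the annealer's perturbation
## loop; igraph serves as the independent oracle in the tests.
graph_components <- function(n_states, edges) {
  comp <- integer(n_states)
  if (n_states == 0L) return(comp)
  adj <- vector("list", n_states)
  if (nrow(edges) > 0L) {
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1L]; j <- edges[e, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  cid <- 0L
  for (root in seq_len(n_states)) {
    if (comp[root] != 0L) next
    cid <- cid + 1L
    queue <- root
    comp[root] <- cid
    while (length(queue) > 0L) {
      node <- queue[[1L]]
      queue <- queue[-1L]
      for (nb in adj[[node]]) {
        if (comp[nb] == 0L) {
          comp[nb] <- cid
          queue <- c(queue, nb)
        }
      }
    }
  }
  comp
}

is_connected <- function(n_states, edges) {
  all(graph_components(n_states, edges) == 1L)
}

#' Random connected graph on n states
#'
#' Draws from the space of connected undirected graphs in two stages. A
#' spanning tree is grown by a random walk over the complete graph: each time
#' the walk first reaches an unvisited state, the entering edge is added.
#' Afterwards every absent state pair is added independently with probability
#' `p_extra`.
#'
#' Uses R's global random number generator; call `set.seed()` for
#' reproducibility.
#'
#' @param n_states Number of states, >= 2.
#' @param p_extra Probability of adding each non-tree edge.
#' @return A two-column integer matrix of edges in canonical order.
#' @examples
#' set.seed(1)
#' random_connected_graph(5, p_extra = 0.2)
#' @export
random_connected_graph <- function(n_states, p_extra = 0) {
  gf_check(is.numeric(n_states) && length(n_states) == 1L && n_states >= 2,
           "gatefit_invalid_argument", "n_states must be >= 2")
  gf_check(is.numeric(p_extra) && p_extra >= 0 && p_extra <= 1,
           "gatefit_invalid_argument", "p_extra must be a probability")
  n_states <- as.integer(n_states)
  visited <- logical(n_states)
  current <- sample.int(n_states, 1L)
  visited[current] <- TRUE
  n_seen <- 1L
  tree <- matrix(0L, nrow = n_states - 1L, ncol = 2L)
  while (n_seen < n_states) {
    nxt <- sample.int(n_states - 1L, 1L)
    if (nxt >= current) nxt <- nxt + 1L  # uniform neighbor != current
    if (!visited[nxt]) {
      visited[nxt] <- TRUE
      tree[n_seen, ] <- c(current, nxt)
      n_seen <- n_seen + 1L
    }
    current <- nxt
  }
  edges <- tree
  if (p_extra > 0 && n_states > 2L) {
    pairs <- which(upper.tri(matrix(0, n_states, n_states)), arr.ind = TRUE)
    key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    absent <- !(paste(pairs[, 1L], pairs[, 2L]) %in% key)
    add <- absent & (runif(nrow(pairs)) < p_extra)
    if (any(add)) {
      edges <- rbind(edges, pairs[add, , drop = FALSE])
    }
  }
  canonical_edges(edges, n_states)
}

#' Random initial gating model
#'
#' Builds a random connected graph with [random_connected_graph()], draws
#' rate parameters from independent normal distributions, marks exactly one
#' randomly chosen state as conducting, and pins `alpha[1, ]` to zero (gauge
#' fix).
#'
#' Offset (constant) parameter entries are drawn `N(0, 1)`; voltage-dependent
#' entries are drawn with standard deviation `sd_vdep` (default 0.2), which
#' keeps initial rates numerically reasonable across the physiological
#' `[-120, 60]` mV range under the linear basis.
#'
#' @inheritParams random_connected_graph
#' @param basis A [voltage_basis()].
#' @param sd_offset,sd_vdep Standard deviations for the offset and
#'   voltage-dependent parameter entries.
#' @return A valid `markov_model`.
#' @export
random_model <- function(n_states, p_extra = 0.15,
                         basis = voltage_basis("linear"),
                         sd_offset = 1, sd_vdep = 0.2) {
  edges <- random_connected_graph(n_states, p_extra)
  n_states <- as.integer(n_states)
  f_dim <- basis_dim(basis)
  alpha <- cbind(rnorm(n_states, sd = sd_offset),
                 matrix(rnorm(n_states * (f_dim - 1L), sd = sd_vdep),
                        nrow = n_states))
  alpha[1L, ] <- 0
  beta <- cbind(rnorm(nrow(edges), sd = sd_offset),
                matrix(rnorm(nrow(edges) * (f_dim - 1L), sd = sd_vdep),
                       nrow = nrow(edges)))
  conductance <- numeric(n_states)
  conductance[sample.int(n_states, 1L)] <- 1
  markov_model(n_states, edges, conductance, alpha, beta, basis)
}

#' Validate a gating model
#'
#' Checks structural invariants: graph connectivity, at least one conducting
#' state, conductances in `[0, 1]`, the gauge fix `alpha[1, ] == 0`, and
#' parameter array shapes consistent with the basis dimension. Reports rather
#' than throws, so the annealer can use it as a cheap post-condition.
#'
#' @param model A `markov_model` (or a bare list with the same fields).
#' @return A list with elements `ok` (logical) and `violations` (character
#'   vector, empty when valid).
#' @export
validate_model <- function(model) {
  v <- character(0)
  n <- model$n_states
  f_dim <- basis_dim(model$basis)
  if (!(is.numeric(n) && length(n) == 1L && n >= 1)) {
    v <- c(v, "n_states must be a positive integer")
    return(list(ok = FALSE, violations = v))
  }
  e <- model$edges
  if (!is.matrix(e) || ncol(e) != 2L || nrow(e) < n - 1L) {
    v <- c(v, sprintf("edge set must be a 2-column matrix with >= %d rows", n - 1L))
  } else if (any(e < 1L | e > n)) {
    v <- c(v, "edge references an invalid state id")
  } else if (!is_connected(n, e)) {
    v <- c(v, "graph is not connected")
  }
  if (length(model$conductance) != n) {
    v <- c(v, "conductance length mismatch")
  } else {
    if (!any(model$conductance > 0)) v <- c(v, "no conducting state")
    if (any(model$conductance < 0 | model$conductance > 1))
      v <- c(v, "conductance entries must lie in [0, 1]")
  }
  if (!is.matrix(model$alpha) || nrow(model$alpha) != n ||
      ncol(model$alpha) != f_dim) {
    v <- c(v, "parameter length mismatch: alpha must be n_states x F")
  } else if (any(model$alpha[1L, ] != 0)) {
    v <- c(v, "gauge violation: alpha of state 1 must be the zero vector")
  }
  if (!is.matrix(model$beta) || ncol(model$beta) != f_dim ||
      (is.matrix(e) && nrow(model$beta) != nrow(e))) {
    v <- c(v, "parameter length mismatch: beta must be E x F")
  }
  list(ok = length(v) == 0L, violations = v)
}

#' Transition-rate matrix at a voltage
#'
#' Assembles the infinitesimal generator `Q` of the gating master equation
#' `dx/dt = Q x` at membrane voltage `v`. `Q[i, j]` holds the rate from state
#' `j` to state `i` for connected pairs, and each diagonal entry is minus the
#' sum of rates leaving that state, so every column of `Q` sums to zero and
#' total occupancy is conserved.
#'
#' @param model A valid `markov_model`.
#' @param v Membrane voltage, mV.
#' @return An `n x n` rate matrix (1/ms) with attribute `"voltage"`.
#' @export
build_Q <- function(model, v) {
  r <- rates_at_voltage(model, v)
  n <- model$n_states
  Q <- matrix(0, n, n)
  e <- model$edges
  # column convention: Q[to, from] = rate(from -> to)
  Q[cbind(e[, 2L], e[, 1L])] <- r$fwd
  Q[cbind(e[, 1L], e[, 2L])] <- r$bwd
  diag(Q) <- -colSums(Q)
  attr(Q, "voltage") <- v
  Q
}

#' Equilibrium occupancy of a rate matrix
#'
#' Returns the stationary occupancy `x` with `Q x = 0`, `sum(x) = 1` (unique
#' for connected models).
#'
#' Generators built by this package are reversible, so the stationary
#' distribution is first reconstructed from detailed balance: log occupancy
#' ratios along a spanning tree are read off the pairwise rate ratios
#' (`ln(x_j / x_i) = ln(Q[j,i] / Q[i,j])`) and accepted if every non-tree
#' edge is consistent. Working in the log domain keeps the answer accurate
#' even when rates span many orders of magnitude, where a dense solve loses
#' the small components. For generators without detailed balance the linear
#' system with the last row of `Q` replaced by ones is solved directly, with
#' an eigen-decomposition fallback if it is ill-conditioned (reciprocal
#' condition < 1e-12).
#'
#' @param Q Rate matrix from [build_Q()] (columns summing to zero).
#' @return Occupancy vector: non-negative, summing to 1.
#' @export
steady_state <- function(Q) {
  n <- nrow(Q)
  if (n == 1L) return(1)
  x <- reversible_steady_state(Q)
  if (is.null(x)) x <- generic_steady_state(Q)
  gf_check(all(is.finite(x)) && min(x) > -1e-8, "gatefit_degenerate_model",
           "steady-state solve produced a non-occupancy vector")
  x[x < 0] <- 0
  x / sum(x)
}

## Detailed-balance route: log potentials phi with phi_j - phi_i =
## ln(Q[j,i]/Q[i,j]) on spanning-tree edges; NULL if the graph is
## disconnected, some edge is one-directional, or a non-tree edge breaks
## consistency (the generator is then not reversible and the generic solver
## applies). See rev_log_potentials() in simulate.R.
reversible_steady_state <- function(Q, tol = 1e-6) {
  phi <- rev_log_potentials(Q, tol)
  if (is.null(phi)) return(NULL)
  x <- exp(phi - max(phi))
  x / sum(x)
}

generic_steady_state <- function(Q) {
  n <- nrow(Q)
  A <- Q
  A[n, ] <- 1
  b <- c(numeric(n - 1L), 1)
  x <- NULL
  rc <- rcond(A)
  if (is.finite(rc) && rc > 1e-12) {
    x <- tryCatch(solve(A, b), error = function(e) NULL)
  }
  if (is.null(x) || !all(is.finite(x))) {
    ev <- eigen(Q)
    tol <- 1e-9 * max(1, max(abs(Q)))
    null_idx <- which(Mod(ev$values) < tol)
    gf_check(length(null_idx) >= 1L, "gatefit_degenerate_model",
             "rate matrix has no numerical null vector (degenerate generator)")
    gf_check(length(null_idx) == 1L, "gatefit_degenerate_model",
             "rate matrix null space has dimension > 1 (disconnected generator)")
    x <- Re(ev$vectors[, null_idx])
    x <- x / sum(x)
  }
  x
}
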