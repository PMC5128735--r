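## Microscopic reversibility by construction.
##
## Detailed balance requires r_ij * s_i = r_ji * s_j on every edge, where s
## is the equilibrium occupancy. Instead of constraining rates after the
## fact, rates are *generated* from independent parameters: per-state
## ln s_i(v) = f(v) . alpha_i and per-edge ln k_ij(v) = f(v) . beta_ij with
## k_ij = r_ij * r_ji. The pair (balance equation, product equation) is a
## square linear system in (ln r_ij, ln r_ji) whose solution
##   r_ij = sqrt(k_ij * s_j / s_i),  r_ji = sqrt(k_ij * s_i / s_j)
## satisfies detailed balance identically in v. The closed form is used in
## production; the equivalent stacked-matrix solve is kept as an oracle.

## Per-edge theta vectors: ln r(v) = f(v) . theta. Forward = low id -> high id.
model_thetas <- function(model) {
  e <- model$edges
  a_from <- model$alpha[e[, 1L], , drop = FALSE]
  a_to <- model$alpha[e[, 2L], , drop = FALSE]
  list(fwd = (model$beta + a_to - a_from) / 2,
       bwd = (model$beta + a_from - a_to) / 2)
}

#' Voltage-dependent transition rates of a model
#'
#' Computes the forward and backward rate of every edge at voltage `v` from
#' the model's `(alpha, beta)` parameters. Forward means low-id to high-id
#' state in the canonical edge order. The rates satisfy detailed balance with
#' respect to `s_i(v) = exp(f(v) . alpha_i)` at every voltage.
#'
#' @param model A valid `markov_model`.
#' @param v Membrane voltage, mV.
#' @return A list with numeric vectors `fwd` and `bwd` (1/ms), one entry per
#'   edge in canonical order.
#' @export
rates_at_voltage <- function(model, v) {
  th <- model_thetas(model)
  f <- basis_eval(model$basis, v)
  ln_fwd <- as.numeric(th$fwd %*% f)
  ln_bwd <- as.numeric(th$bwd %*% f)
  bad <- which(abs(c(ln_fwd, ln_bwd)) > 700)
  if (length(bad) > 0L) {
    e_idx <- ((bad[1L] - 1L) %% nrow(model$edges)) + 1L
    gf_stop("gatefit_stiffness_error",
            sprintf("rate overflow on edge %d-%d at %g mV (|ln r| > 700)",
                    model$edges[e_idx, 1L], model$edges[e_idx, 2L], v),
            edge = model$edges[e_idx, ], voltage = v)
  }
  list(fwd = exp(ln_fwd), bwd = exp(ln_bwd))
}

#' Stacked linear system enforcing detailed balance
#'
#' Builds the matrices of the reversibility system for an edge set: the
#' `E x 2E` difference matrix `D` mapping the stacked log-rate vector
#' `(ln r_1fwd, ln r_1bwd, ln r_2fwd, ...)` to per-edge log-rate differences,
#' its elementwise absolute value `abs(D)` mapping to per-edge sums, and the
#' signed incidence rows `IeT` (`E x n_states`, -1 at the low-id endpoint and
#' +1 at the high-id endpoint) acting on the per-state log occupancies.
#' Stacking `D` over `abs(D)` gives a block-diagonal `2E x 2E` matrix of
#' `[[1, -1], [1, 1]]` blocks (determinant `2^E`), so log rates are uniquely
#' determined by the log occupancy differences and log rate products.
#'
#' Used as the test oracle for [rates_at_voltage()]; production code uses the
#' equivalent per-edge closed form.
#'
#' @param edges Canonical two-column edge matrix.
#' @param n_states Number of states (defaults to the largest id in `edges`).
#' @return List with matrices `D`, `absD`, `IeT`.
#' @export
build_reversibility_system <- function(edges, n_states = max(edges)) {
  gf_check(is.matrix(edges) && nrow(edges) >= 1L, "gatefit_invalid_argument",
           "edge set must be a non-empty 2-column matrix")
  n_e <- nrow(edges)
  D <- matrix(0, n_e, 2L * n_e)
  IeT <- matrix(0, n_e, n_states)
  for (k in seq_len(n_e)) {
    D[k, 2L * k - 1L] <- 1
    D[k, 2L * k] <- -1
    IeT[k, edges[k, 1L]] <- -1
    IeT[k, edges[k, 2L]] <- 1
  }
  list(D = D, absD = abs(D), IeT = IeT)
}

## Matrix-route solution of the reversibility system; oracle counterpart of
## rates_at_voltage(). Returns the same (fwd, bwd) list.
rates_via_system <- function(model, v) {
  sys <- build_reversibility_system(model$edges, model$n_states)
  f <- basis_eval(model$basis, v)
  ln_s <- as.numeric(model$alpha %*% f)
  ln_k <- as.numeric(model$beta %*% f)
  rhs <- c(as.numeric(sys$IeT %*% ln_s), ln_k)
  ln_r <- solve(rbind(sys$D, sys$absD), rhs)
  idx <- seq_len(nrow(model$edges))
  list(fwd = exp(ln_r[2L * idx - 1L]), bwd = exp(ln_r[2L * idx]))
}

#' Detailed-balance residual over the cycle basis
#'
#' For each fundamental cycle of the model graph (one per non-tree edge of a
#' breadth-first spanning tree), sums the signed log rate ratios
#' `ln(r_fwd) - ln(r_bwd)` around the cycle. Under detailed balance every
#' cycle sum is zero; the maximum absolute cycle sum is returned. Trees have
#' an empty cycle basis and residual 0.
#'
#' The residual is computed from the realized rates (via
#' [rates_at_voltage()]), not from the parameterization identity, so it
#' detects any construction defect.
#'
#' @param model A valid `markov_model`.
#' @param v Membrane voltage, mV.
#' @param rates Optional precomputed rates (list with `fwd`, `bwd`) to test a
#'   perturbed rate assignment on the model's graph.
#' @return Maximum absolute cycle log-flux imbalance (dimensionless).
#' @export
detailed_balance_residual <- function(model, v, rates = NULL) {
  if (is.null(rates)) rates <- rates_at_voltage(model, v)
  e <- model$edges
  n <- model$n_states
  ln_ratio <- log(rates$fwd) - log(rates$bwd)  # low->high minus high->low
  ## BFS spanning tree from state 1; potential phi with phi[j] - phi[i] =
  ## ln_ratio on tree edges; each non-tree edge's residual is the cycle sum.
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    i <- e[k, 1L]; j <- e[k, 2L]
    adj[[i]] <- rbind(adj[[i]], c(j, k, 1))
    adj[[j]] <- rbind(adj[[j]], c(i, k, -1))
  }
  phi <- rep(NA_real_, n)
  in_tree <- logical(nrow(e))
  phi[1L] <- 0
  queue <- 1L
  while (length(queue) > 0L) {
    node <- queue[[1L]]
    queue <- queue[-1L]
    nbrs <- adj[[node]]
    if (is.null(nbrs)) next
    for (r in seq_len(nrow(nbrs))) {
      nb <- nbrs[r, 1L]
      if (is.na(phi[nb])) {
        phi[nb] <- phi[node] + nbrs[r, 3L] * ln_ratio[nbrs[r, 2L]]
        in_tree[nbrs[r, 2L]] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  loops <- which(!in_tree)
  if (length(loops) == 0L) return(0)
  max(abs(ln_ratio[loops] - (phi[e[loops, 2L]] - phi[e[loops, 1L]])))
}

#' Parameterized equilibrium occupancy
#'
#' Evaluates `s_i(v) = exp(f(v) . alpha_i)` for every state and normalizes to
#' sum 1. Because the rates satisfy detailed balance with respect to `s(v)`,
#' this equals `steady_state(build_Q(model, v))` for connected models.
#'
#' @inheritParams rates_at_voltage
#' @return Normalized occupancy vector of length `n_states`.
#' @export
equilibrium_occupancy <- function(model, v) {
  f <- basis_eval(model$basis, v)
  ln_s <- as.numeric(model$alpha %*% f)
  s <- exp(ln_s - max(ln_s))
  s / sum(s)
}
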