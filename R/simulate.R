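## Protocol simulation. Voltage within a step is constant, so the master
## equation dx/dt = Q x is linear time-invariant over the step and the exact
## solution x(t) = expm(t Q) x0 replaces ODE integration. Recorded steps are
## sampled on a fixed grid by precomputing H = expm(dt Q) once and repeatedly
## applying it ("powering up"). An adaptive-step ODE backend (deSolve) is
## kept as an independent reference.

expm_mat <- function(M) {
  tryCatch(.cpp_expm(M),
           error = function(e) gf_stop("gatefit_stiffness_error",
                                       paste0("matrix exponential failed: ",
                                              conditionMessage(e))))
}

## Matrix exponential specialized to generators, expm(t * Q).
##
## Reversible generators (every Q built by this package) are similar to a
## symmetric matrix: with D = diag(sqrt(pi)), A = D^-1 Q D has off-diagonals
## sqrt(Q[i,j] * Q[j,i]). The exponential is then reconstructed from the
## (stable, orthogonal) symmetric eigendecomposition,
## expm(tQ) = D U exp(t Lambda) U' D^-1, which stays accurate where
## Pade scaling-and-squaring loses all precision (||tQ|| beyond ~1e9, where
## repeated squaring amplifies roundoff catastrophically). The known null
## mode (Lambda = 0, eigenvector sqrt(pi)) is deflated and injected exactly,
## so the stationary direction carries no eigenvalue error. Columns are then
## renormalized to sum exactly to 1 (the exact exponential of a generator is
## column-stochastic), which keeps mass conserved under repeated powering.
## Non-reversible or numerically unusable inputs fall back to Pade.
expm_generator <- function(Q, t) {
  H <- .cpp_expm_reversible(Q, t)
  if (length(H) == 0L) H <- expm_mat(t * Q)
  ## strict accuracy gate: the exact exponential of a generator is
  ## column-stochastic, so any visible drift means the model is too stiff to
  ## simulate reliably in double precision -- raise the typed stiffness
  ## error (the annealer's cost turns it into a rejection) rather than
  ## return silently wrong dynamics
  neg <- min(H)
  cs <- colSums(H)
  if (neg < -1e-8 || any(!is.finite(cs)) || any(abs(cs - 1) > 1e-8)) {
    gf_stop("gatefit_stiffness_error",
            "matrix exponential lost probability conservation (model too stiff)")
  }
  ## project the roundoff back onto the column-stochastic manifold so that
  ## repeated powering conserves mass to machine precision
  if (neg < 0) H[H < 0] <- 0
  H / rep(colSums(H), each = nrow(H))
}

## Log stationary potentials (phi = log pi up to a constant) from pairwise
## rate ratios; NULL when the generator is not reversible/connected.
rev_log_potentials <- function(Q, tol = 1e-6) {
  n <- nrow(Q)
  phi <- rep(NA_real_, n)
  phi[1L] <- 0
  queue <- 1L
  while (length(queue) > 0L) {
    i <- queue[[1L]]
    queue <- queue[-1L]
    for (j in seq_len(n)) {
      if (j == i || Q[j, i] <= 0) next
      if (Q[i, j] <= 0) return(NULL)
      lr <- log(Q[j, i]) - log(Q[i, j])
      if (is.na(phi[j])) {
        phi[j] <- phi[i] + lr
        queue <- c(queue, j)
      } else if (abs(phi[j] - phi[i] - lr) > tol * max(1, abs(phi[j]))) {
        return(NULL)
      }
    }
  }
  if (anyNA(phi)) return(NULL)
  phi
}

#' Propagate occupancy through a constant-voltage interval
#'
#' Computes `x(duration) = expm(duration * Q) %*% x0`, the exact solution of
#' the master equation at fixed voltage. Occupancy conservation and
#' non-negativity are preserved up to rounding.
#'
#' @param Q Rate matrix from [build_Q()].
#' @param x0 Initial occupancy vector.
#' @param duration Interval length, ms (>= 0).
#' @return Occupancy vector after `duration`.
#' @export
propagate <- function(Q, x0, duration) {
  gf_check(is.numeric(duration) && length(duration) == 1L && duration >= 0,
           "gatefit_invalid_argument", "duration must be a non-negative number")
  if (duration == 0) return(as.numeric(x0))
  as.numeric(expm_generator(Q, duration) %*% x0)
}

#' Sample occupancy on a fixed time grid
#'
#' Precomputes `H = expm(dt * Q)` once and generates
#' `x(i * dt) = H %*% x((i-1) * dt)` for `i = 1, ..., n_steps`.
#'
#' @inheritParams propagate
#' @param dt Sampling interval, ms.
#' @param n_steps Number of samples after the initial point.
#' @return `(n_steps + 1) x n` matrix of occupancies; row 1 is `x0`.
#' @export
sample_trace <- function(Q, x0, dt, n_steps) {
  gf_check(is.numeric(dt) && dt > 0, "gatefit_invalid_argument",
           "dt must be positive")
  gf_check(is.numeric(n_steps) && n_steps >= 1,
           "gatefit_invalid_argument", "n_steps must be >= 1")
  H <- expm_generator(Q, dt)
  tryCatch(.cpp_power_trace(H, as.numeric(x0), as.integer(n_steps)),
           error = function(e) gf_stop("gatefit_stiffness_error",
                                       conditionMessage(e)))
}

#' Reference ODE propagation of the master equation
#'
#' Integrates `dx/dt = Q x` with an adaptive-step stiff-capable solver
#' (`deSolve::lsoda`). This is the reference backend against which the
#' matrix-exponential path is verified; it is also the route a model destined
#' for continuous-voltage (action potential) simulation would take.
#'
#' @inheritParams propagate
#' @param times Output times, ms (must start at 0); defaults to
#'   `c(0, duration)`.
#' @param duration Used when `times` is not given.
#' @param rtol,atol Relative and absolute integration tolerances.
#' @return Matrix of occupancies, one row per output time.
#' @export
propagate_ode <- function(Q, x0, duration = NULL, times = NULL,
                          rtol = 1e-10, atol = 1e-12) {
  if (is.null(times)) {
    gf_check(!is.null(duration), "gatefit_invalid_argument",
             "either duration or times must be supplied")
    times <- c(0, duration)
  }
  n <- nrow(Q)
  if (n <= 12L) {
    ## compiled RHS/Jacobian (src/ode_rhs.c); Q is passed zero-padded
    parms <- numeric(12L * 12L + 1L)
    parms[1L] <- n
    parms[1L + seq_len(n * n)] <- as.numeric(Q)
    args <- list(y = as.numeric(x0), times = times, func = "gf_derivs",
                 initfunc = "gf_initmod", jacfunc = "gf_jac",
                 jactype = "fullusr", dllname = "gatefit", parms = parms,
                 rtol = rtol, atol = atol, maxsteps = 100000L)
  } else {
    deriv <- function(t, y, parms) list(as.numeric(Q %*% y))
    args <- list(y = as.numeric(x0), times = times, func = deriv,
                 jacfunc = function(t, y, parms) Q, jactype = "fullusr",
                 rtol = rtol, atol = atol, maxsteps = 100000L)
  }
  ## capture.output: the Fortran core prints step-size complaints directly
  ## to the console on near-failure; they are handled below
  utils::capture.output(
    sol <- suppressWarnings(do.call(deSolve::lsoda, args)))
  if (attr(sol, "istate")[1L] < 0) {
    ## lsoda can fail outright on extremely stiff generators; retry with the
    ## L-stable implicit Runge-Kutta solver before giving up
    utils::capture.output(
      sol <- suppressWarnings(do.call(deSolve::radau, args)))
  }
  if (attr(sol, "istate")[1L] < 0) {
    gf_stop("gatefit_stiffness_error",
            sprintf("ODE integration failed (istate %d); step-size diagnostics: %s",
                    attr(sol, "istate")[1L],
                    paste(utils::capture.output(deSolve::diagnostics(sol)),
                          collapse = " ")))
  }
  unname(as.matrix(sol[, -1L, drop = FALSE]))
}

## 10%-90% rise and 90%-20% fall times of a conductance trace -------------

crossing_time <- function(g, times, threshold, from = 1L, to = length(g),
                          direction = c("up", "down")) {
  direction <- match.arg(direction)
  idx <- from:to
  hit <- if (direction == "up") which(g[idx] >= threshold)
         else which(g[idx] <= threshold)
  if (length(hit) == 0L || hit[1L] == 1L) return(NA_real_)
  i2 <- idx[hit[1L]]
  i1 <- i2 - 1L
  frac <- (threshold - g[i1]) / (g[i2] - g[i1])
  times[i1] + frac * (times[i2] - times[i1])
}

#' Rise and fall times of a conductance trace
#'
#' `rise_time()` returns the time for the trace to rise from 10% to 90% of
#' its peak value (pre-peak crossings); `fall_time()` the time to fall from
#' 90% to 20% of peak (post-peak crossings). Crossing times are linearly
#' interpolated between samples.
#'
#' @param g Sampled conductance trace (non-negative).
#' @param dt Sampling interval, ms.
#' @return Time in ms.
#' @export
rise_time <- function(g, dt) {
  v <- rise_time_or_na(g, dt)
  gf_check(!is.na(v), "gatefit_feature_undefined",
           "trace never crosses the 10%/90% thresholds before its peak")
  v
}

#' @rdname rise_time
#' @export
fall_time <- function(g, dt) {
  v <- fall_time_or_na(g, dt)
  gf_check(!is.na(v), "gatefit_feature_undefined",
           "trace never falls through the 90%/20% thresholds after its peak")
  v
}

rise_time_or_na <- function(g, dt) {
  ip <- which.max(g)
  peak <- g[ip]
  if (!is.finite(peak) || peak <= 0 || ip < 2L) return(NA_real_)
  times <- (seq_along(g) - 1L) * dt
  t10 <- crossing_time(g, times, 0.1 * peak, 1L, ip, "up")
  t90 <- crossing_time(g, times, 0.9 * peak, 1L, ip, "up")
  if (is.na(t10) || is.na(t90)) return(NA_real_)
  t90 - t10
}

fall_time_or_na <- function(g, dt) {
  ip <- which.max(g)
  peak <- g[ip]
  if (!is.finite(peak) || peak <= 0 || ip >= length(g)) return(NA_real_)
  times <- (seq_along(g) - 1L) * dt
  t90 <- crossing_time(g, times, 0.9 * peak, ip, length(g), "down")
  t20 <- crossing_time(g, times, 0.2 * peak, ip, length(g), "down")
  if (is.na(t90) || is.na(t20)) return(NA_real_)
  t20 - t90
}

## Protocol runner ---------------------------------------------------------

## Shared guts of run_protocol()/model_cost(): returns list(x, y, traces).
## Q and expm results are cached per (voltage) and (voltage, interval) within
## one call, which collapses the cost of sweeps sharing fixed steps.
simulate_protocol <- function(model, prot, backend = "expm",
                              keep_traces = FALSE, cache = NULL) {
  G <- model$conductance
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  getQ <- function(v) {
    key <- paste0("Q", v)
    q <- cache[[key]]
    if (is.null(q)) {
      q <- build_Q(model, v)
      cache[[key]] <- q
    }
    q
  }
  getH <- function(v, interval) {
    key <- paste0("H", v, "_", interval)
    h <- cache[[key]]
    if (is.null(h)) {
      h <- expm_generator(getQ(v), interval)
      cache[[key]] <- h
    }
    h
  }
  hold_key <- paste0("ss", prot$holding)
  x_hold <- cache[[hold_key]]
  if (is.null(x_hold)) {
    x_hold <- steady_state(getQ(prot$holding))
    cache[[hold_key]] <- x_hold
  }
  n_sweep <- length(prot$sweep)
  raw <- rep(NA_real_, n_sweep)
  traces <- if (keep_traces) vector("list", n_sweep) else NULL
  trace_out <- NULL  # (time, y) for normalized_trace protocols
  for (si in seq_len(n_sweep)) {
    sv <- prot$sweep[si]
    x <- x_hold
    windows <- list()
    for (step in prot$steps) {
      st <- resolve_step(step, sv)
      Q <- getQ(st$voltage)
      if (st$record) {
        n_steps <- max(1L, as.integer(round(st$duration / st$dt)))
        occ <- if (backend == "expm") {
          tryCatch(.cpp_power_trace(getH(st$voltage, st$dt), x, n_steps),
                   error = function(e) gf_stop("gatefit_stiffness_error",
                                               conditionMessage(e)))
        } else {
          propagate_ode(Q, x, times = (0:n_steps) * st$dt)
        }
        g <- as.numeric(occ %*% G)
        windows[[length(windows) + 1L]] <-
          list(g = g, dt = st$dt, v = st$voltage, occ = occ)
        x <- occ[n_steps + 1L, ]
      } else {
        x <- if (backend == "expm") {
          as.numeric(getH(st$voltage, st$duration) %*% x)
        } else {
          propagate_ode(Q, x, duration = st$duration)[2L, ]
        }
      }
    }
    if (keep_traces) traces[[si]] <- windows
    if (prot$feature == "normalized_trace") {
      g <- windows[[1L]]$g
      peak <- max(g)
      trace_out <- list(x = (seq_along(g) - 1L) * windows[[1L]]$dt,
                        y = if (peak > 0) g / peak else g)
    } else {
      raw[si] <- extract_feature(prot$feature, windows)
    }
  }
  if (prot$feature == "normalized_trace") {
    return(list(x = trace_out$x, y = trace_out$y, traces = traces))
  }
  y <- switch(prot$normalization,
              none = raw,
              max_over_sweep = {
                m <- suppressWarnings(max(abs(raw), na.rm = TRUE))
                if (is.finite(m) && m > 0) raw / m else raw
              },
              first_sweep = raw / raw[1L])
  list(x = prot$sweep, y = y, traces = traces)
}

extract_feature <- function(kind, windows) {
  w1 <- windows[[1L]]
  switch(kind,
         peak_conductance_over_driving_force = max(w1$g),
         normalized_peak = max(w1$g),
         peak_ratio = {
           p1 <- max(w1$g)
           p2 <- max(windows[[2L]]$g)
           if (p1 > 0) p2 / p1 else NA_real_
         },
         rise_time_10_90 = rise_time_or_na(w1$g, w1$dt),
         fall_time_90_20 = fall_time_or_na(w1$g, w1$dt),
         min_abs_current_over_driving_force = min(w1$g))
}

#' Simulate a voltage-clamp protocol
#'
#' Runs every sweep of `prot` on `model`: the occupancy starts at the steady
#' state of the holding potential, each step is propagated with the chosen
#' backend, conductance `g(t) = sum_i G_i x_i(t)` is recorded where the
#' protocol asks for it, and the protocol's feature is extracted and
#' normalized across the sweep.
#'
#' @param model A valid `markov_model`.
#' @param prot A [protocol()].
#' @param backend `"expm"` (matrix exponential, default) or `"ode"`
#'   (adaptive-step reference integrator).
#' @param keep_traces If `TRUE` the full recorded occupancy windows are
#'   attached as attribute `"traces"`.
#' @return A data frame with columns `protocol`, `x` (sweep value, or time in
#'   ms for trace features) and `y` (feature value; `NA` when undefined,
#'   e.g. a rise time whose thresholds are never crossed).
#' @export
run_protocol <- function(model, prot, backend = c("expm", "ode"),
                         keep_traces = FALSE) {
  backend <- match.arg(backend)
  sim <- simulate_protocol(model, prot, backend, keep_traces)
  out <- data.frame(protocol = prot$name, x = sim$x, y = sim$y,
                    stringsAsFactors = FALSE)
  if (keep_traces) attr(out, "traces") <- sim$traces
  out
}

#' Stiffness penalty of a model
#'
#' The largest-magnitude eigenvalue of `Q(v)` over a voltage grid. Stiff
#' models (very fast eigenmodes) force tiny steps on ODE integrators and are
#' physically implausible; the annealer adds this value times
#' `penalty_weight` to the cost.
#'
#' @param model A valid `markov_model`.
#' @param v_grid Voltage grid, mV.
#' @return Scalar, 1/ms.
#' @export
stiffness_penalty <- function(model, v_grid = seq(-120, 20, by = 10)) {
  if (model$n_states == 1L) return(0)
  th <- model_thetas(model)
  fmat <- vapply(v_grid, function(v) basis_eval(model$basis, v),
                 numeric(basis_dim(model$basis)))
  ln_fwd <- th$fwd %*% fmat   # E x V
  ln_bwd <- th$bwd %*% fmat
  if (max(abs(ln_fwd), abs(ln_bwd)) > 700) {
    gf_stop("gatefit_stiffness_error",
            "rate overflow while evaluating the stiffness penalty grid")
  }
  rf <- exp(ln_fwd)
  rb <- exp(ln_bwd)
  n <- model$n_states
  e <- model$edges
  i_f <- cbind(e[, 2L], e[, 1L])
  i_b <- cbind(e[, 1L], e[, 2L])
  mx <- 0
  for (k in seq_along(v_grid)) {
    Q <- matrix(0, n, n)
    Q[i_f] <- rf[, k]
    Q[i_b] <- rb[, k]
    diag(Q) <- -colSums(Q)
    mx <- max(mx, .cpp_spectral_radius(Q))
  }
  mx
}

#' Penalized squared-error cost of a model against a dataset
#'
#' Simulates every protocol referenced by the dataset and accumulates
#' `sum(weight * (simulated - observed)^2)`, plus
#' `penalty_weight * stiffness_penalty(model)`. Simulated features that are
#' undefined (e.g. thresholds never crossed) contribute a fixed residual of
#' `missing_residual` (squared-error contribution `missing_residual^2` = 100
#' per row by default) instead of aborting, so the optimizer can move away
#' from pathological models. Any simulation failure (rate overflow, matrix
#' exponential breakdown, degenerate steady state) yields `Inf`, which the
#' annealer always rejects.
#'
#' @param model A valid `markov_model`.
#' @param protocols Named list of [protocol()] objects (names must cover
#'   `dataset$protocol`).
#' @param dataset Data frame with columns `protocol`, `x`, `y`, `weight`.
#' @param penalty_weight Weight of the stiffness penalty (per 1/ms); 0
#'   disables it.
#' @param backend Simulation backend passed to [run_protocol()].
#' @param missing_residual Residual charged per undefined simulated feature.
#' @param v_grid Stiffness-penalty voltage grid.
#' @return Non-negative scalar cost (`Inf` on simulation failure).
#' @export
model_cost <- function(model, protocols, dataset, penalty_weight = 1e-4,
                       backend = "expm", missing_residual = 10,
                       v_grid = seq(-120, 20, by = 10)) {
  if (!is.null(names(protocols)) && all(nzchar(names(protocols)))) {
    prot_names <- names(protocols)
  } else {
    prot_names <- vapply(protocols, function(p) p$name, character(1))
    names(protocols) <- prot_names
  }
  used <- unique(dataset$protocol)
  missing <- setdiff(used, prot_names)
  gf_check(length(missing) == 0L, "gatefit_invalid_argument",
           paste0("dataset references unknown protocol(s): ",
                  paste(missing, collapse = ", ")))
  tryCatch({
    total <- 0
    cache <- new.env(parent = emptyenv())  # Q/H/steady-state shared across protocols
    for (pn in used) {
      sim <- simulate_protocol(model, protocols[[pn]], backend, cache = cache)
      rows <- which(dataset$protocol == pn)
      idx <- match(signif(dataset$x[rows], 10), signif(sim$x, 10))
      gf_check(!anyNA(idx), "gatefit_invalid_argument",
               sprintf("dataset rows for protocol \"%s\" do not resolve to simulated sweep values", pn))
      res <- sim$y[idx] - dataset$y[rows]
      res[is.na(res)] <- missing_residual
      total <- total + sum(dataset$weight[rows] * res^2)
    }
    if (penalty_weight > 0) {
      total <- total + penalty_weight * stiffness_penalty(model, v_grid)
    }
    total
  }, gatefit_stiffness_error = function(e) Inf,
     gatefit_degenerate_model = function(e) Inf)
}
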