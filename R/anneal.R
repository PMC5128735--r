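## Synchronous multi-chain simulated annealing over model structure and rate
## parameters. Chains share one exponential temperature schedule but are
## perturbed and accepted independently; they never exchange state, so each
## chain's path depends only on its own RNG stream and the schedule.

MOVE_NAMES <- c("state_add", "state_remove", "edge_add", "edge_remove",
                "conductance_flip")

#' Configuration for simulated annealing
#'
#' @param n_chains Number of independent chains sharing the temperature
#'   schedule.
#' @param n_iterations Number of annealing iterations.
#' @param T0 Initial temperature in cost units; `NULL` (default) sets it to
#'   the median finite cost of the initial random models, giving a
#'   scale-free start.
#' @param gamma Cooling factor per iteration, in (0, 1): `T(t) = T0 *
#'   gamma^t`.
#' @param p Per-parameter probability that a rate-update perturbation touches
#'   an entry. May be a vector (with `sigma` of the same length) defining a
#'   mixture kernel: one `(p, sigma)` component is drawn uniformly per
#'   proposal.
#' @param sigma Standard deviation of the additive normal rate-parameter
#'   perturbation, applied per basis column scaled by the typical feature
#'   magnitude over the physiological voltage range (see [perturb()]).
#' @param move_probs Named probabilities for the structural moves
#'   `state_add`, `state_remove`, `edge_add`, `edge_remove` and the optional
#'   `conductance_flip` (default 0; moves the conducting state to a random
#'   other state). Each move fires independently per proposal; a rate update
#'   is always applied.
#' @param min_states,max_states Bounds on model size during the search.
#' @param init_states,init_p_extra Size and extra-edge probability of the
#'   initial random models.
#' @param basis [voltage_basis()] used for initial models and new states.
#' @param sd_offset,sd_vdep Initial-draw standard deviations (see
#'   [random_model()]); also used for parameters of states/edges created by
#'   structural moves.
#' @param penalty_weight Stiffness-penalty weight passed to [model_cost()].
#' @param backend Simulation backend.
#' @param seed Integer RNG seed; mandatory, every source of randomness in a
#'   fit derives from it.
#' @return An `anneal_config` list.
#' @export
anneal_config <- function(n_chains = 12L, n_iterations = 1000L, T0 = NULL,
                          gamma = 0.999, p = 0.2, sigma = 0.1,
                          move_probs = c(state_add = 0.05, state_remove = 0.05,
                                         edge_add = 0.05, edge_remove = 0.05,
                                         conductance_flip = 0),
                          min_states = 2L, max_states = 10L,
                          init_states = 4L, init_p_extra = 0.15,
                          basis = voltage_basis("linear"),
                          sd_offset = 1, sd_vdep = 0.2,
                          penalty_weight = 1e-4, backend = "expm",
                          seed = NULL) {
  mp <- c(state_add = 0.05, state_remove = 0.05, edge_add = 0.05,
          edge_remove = 0.05, conductance_flip = 0)
  if (!is.null(move_probs)) {
    gf_check(!is.null(names(move_probs)) &&
               all(names(move_probs) %in% MOVE_NAMES),
             "gatefit_invalid_argument",
             paste0("move_probs names must be among: ",
                    paste(MOVE_NAMES, collapse = ", ")))
    mp[names(move_probs)] <- move_probs
  }
  gf_check(all(mp >= 0 & mp <= 1), "gatefit_invalid_argument",
           "move probabilities must lie in [0, 1]")
  gf_check(is.numeric(gamma) && gamma > 0 && gamma < 1,
           "gatefit_invalid_argument", "gamma must lie in (0, 1)")
  gf_check(is.numeric(p) && all(p >= 0 & p <= 1),
           "gatefit_invalid_argument", "p must be probabilities")
  gf_check(is.numeric(sigma) && all(sigma >= 0) && length(sigma) == length(p),
           "gatefit_invalid_argument",
           "sigma must be non-negative and match p in length")
  gf_check(min_states >= 2 && max_states >= min_states,
           "gatefit_invalid_argument", "need 2 <= min_states <= max_states")
  gf_check(is.null(T0) || (is.numeric(T0) && T0 > 0),
           "gatefit_invalid_argument", "T0 must be positive (or NULL)")
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 T0 = T0, gamma = gamma, p = p, sigma = sigma,
                 move_probs = mp,
                 min_states = as.integer(min_states),
                 max_states = as.integer(max_states),
                 init_states = as.integer(init_states),
                 init_p_extra = init_p_extra,
                 basis = basis, sd_offset = sd_offset, sd_vdep = sd_vdep,
                 penalty_weight = penalty_weight, backend = backend,
                 seed = seed),
            class = "anneal_config")
}

#' Exponential annealing temperature
#'
#' @param t Iteration index (0-based; `t = 0` gives `T0`).
#' @param config An [anneal_config()] with `T0` resolved to a number.
#' @return `T0 * gamma^t`.
#' @export
anneal_temperature <- function(t, config) {
  gf_check(all(t >= 0), "gatefit_invalid_argument", "t must be >= 0")
  config$T0 * config$gamma^t
}

#' Metropolis acceptance rule
#'
#' Accepts with probability `min(1, exp(-(e_new - e_old) / temp))`: downhill
#' moves always, uphill moves with Boltzmann probability. An infinite
#' proposal cost (failed simulation) is always rejected.
#'
#' @param e_old,e_new Previous and proposed cost.
#' @param temp Current temperature (> 0).
#' @return Logical.
#' @export
accept_move <- function(e_old, e_new, temp) {
  gf_check(is.numeric(temp) && temp > 0, "gatefit_invalid_argument",
           "temperature must be positive")
  if (!is.finite(e_new)) return(FALSE)
  if (e_new <= e_old) return(TRUE)
  runif(1) < exp(-(e_new - e_old) / temp)
}

## -- structural edit helpers ----------------------------------------------

draw_param_row <- function(f_dim, config) {
  c(rnorm(1, sd = config$sd_offset), rnorm(f_dim - 1L, sd = config$sd_vdep))
}

## Insert edge {i, j} (assumed absent) with parameter row, re-canonicalizing.
insert_edge <- function(model, i, j, beta_row) {
  e <- rbind(model$edges, sort(c(i, j)))
  b <- rbind(model$beta, beta_row)
  ord <- order(e[, 1L], e[, 2L])
  model$edges <- matrix(as.integer(e[ord, ]), ncol = 2L)
  model$beta <- b[ord, , drop = FALSE]
  model
}

drop_edges <- function(model, idx) {
  model$edges <- model$edges[-idx, , drop = FALSE]
  model$beta <- model$beta[-idx, , drop = FALSE]
  model
}

## Join disconnected components with uniformly drawn cross-component edges
## (a random spanning tree over components); fresh parameters per new edge.
reconnect <- function(model, config) {
  repeat {
    comp <- graph_components(model$n_states, model$edges)
    if (all(comp == 1L) || max(comp) == 1L) break
    cids <- sample(unique(comp), 2L)
    i <- resample(which(comp == cids[1L]), 1L)
    j <- resample(which(comp == cids[2L]), 1L)
    model <- insert_edge(model, i, j,
                         draw_param_row(basis_dim(model$basis), config))
  }
  model
}

## sample() misbehaves on length-1 vectors; the usual guard.
resample <- function(x, size) x[sample.int(length(x), size)]

move_state_add <- function(model, config) {
  if (model$n_states >= config$max_states) return(model)
  f_dim <- basis_dim(model$basis)
  new_id <- model$n_states + 1L
  anchor <- sample.int(model$n_states, 1L)
  model$n_states <- new_id
  model$alpha <- rbind(model$alpha, draw_param_row(f_dim, config))
  model$conductance <- c(model$conductance, 0)
  insert_edge(model, anchor, new_id, draw_param_row(f_dim, config))
}

move_state_remove <- function(model, config) {
  if (model$n_states <= config$min_states) return(model)
  ## never remove the last conducting state (conductance is otherwise fixed)
  conducting <- which(model$conductance > 0)
  candidates <- seq_len(model$n_states)
  if (length(conducting) == 1L) candidates <- setdiff(candidates, conducting)
  if (length(candidates) == 0L) return(model)
  victim <- resample(candidates, 1L)
  incident <- which(model$edges[, 1L] == victim | model$edges[, 2L] == victim)
  model <- drop_edges(model, incident)
  keep <- setdiff(seq_len(model$n_states), victim)
  relabel <- integer(model$n_states)
  relabel[keep] <- seq_along(keep)
  model$edges <- matrix(relabel[model$edges], ncol = 2L)
  model$alpha <- model$alpha[keep, , drop = FALSE]
  model$conductance <- model$conductance[keep]
  model$n_states <- model$n_states - 1L
  ## re-gauge: rates depend only on alpha differences, so subtracting the new
  ## state 1's row changes nothing observable
  model$alpha <- sweep(model$alpha, 2L, model$alpha[1L, ])
  model$alpha[1L, ] <- 0
  if (nrow(model$edges) > 0L) {
    ord <- order(model$edges[, 1L], model$edges[, 2L])
    model$edges <- model$edges[ord, , drop = FALSE]
    model$beta <- model$beta[ord, , drop = FALSE]
  }
  reconnect(model, config)
}

move_edge_add <- function(model, config) {
  n <- model$n_states
  if (nrow(model$edges) >= n * (n - 1L) / 2L) return(model)
  key <- model$edges[, 1L] * (n + 1L) + model$edges[, 2L]
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pkey <- pairs[, 1L] * (n + 1L) + pairs[, 2L]
  absent <- which(!(pkey %in% key))
  pick <- pairs[resample(absent, 1L), ]
  insert_edge(model, pick[1L], pick[2L],
              draw_param_row(basis_dim(model$basis), config))
}

move_edge_remove <- function(model, config) {
  if (nrow(model$edges) <= 1L) return(model)
  victim <- sample.int(nrow(model$edges), 1L)
  reconnect(drop_edges(model, victim), config)
}

move_conductance_flip <- function(model, config) {
  conducting <- which(model$conductance > 0)
  if (length(conducting) != 1L || model$n_states < 2L) return(model)
  target <- resample(setdiff(seq_len(model$n_states), conducting), 1L)
  model$conductance[conducting] <- 0
  model$conductance[target] <- 1
  model
}

#' Propose a perturbed model
#'
#' Applies each structural move (state addition/removal, edge
#' addition/removal, optional conductance flip) independently with its
#' configured probability, then always applies the rate update: every
#' parameter entry is touched with probability `p` by adding `N(0, sigma)`
#' noise. Inapplicable moves (removal at `min_states`, addition at
#' `max_states`, edge addition on a complete graph) are skipped silently.
#' The input model is never modified; the result always passes
#' [validate_model()] and keeps detailed balance by construction.
#'
#' @param model A valid `markov_model`.
#' @param config An [anneal_config()].
#' @return A list with `model` (the proposal) and `moves` (character vector
#'   of structural moves that fired).
#' @export
perturb <- function(model, config) {
  fired <- character(0)
  for (mv in MOVE_NAMES) {
    pr <- config$move_probs[[mv]]
    if (pr > 0 && runif(1) < pr) {
      model <- switch(mv,
                      state_add = move_state_add(model, config),
                      state_remove = move_state_remove(model, config),
                      edge_add = move_edge_add(model, config),
                      edge_remove = move_edge_remove(model, config),
                      conductance_flip = move_conductance_flip(model, config))
      fired <- c(fired, mv)
    }
  }
  ## rate update (always): alpha rows 2..n (row 1 is the gauge) and all beta.
  ## The kernel is scaled per basis column by the typical magnitude of the
  ## corresponding voltage feature over the physiological range, so each
  ## entry's proposal shifts log rates by a comparable amount: a linear-basis
  ## voltage slope acts multiplied by ~100 mV, a sigmoid feature by at most 1.
  ## When p/sigma are vectors they define a mixture kernel: one component is
  ## drawn uniformly per proposal (coarse components hop between basins,
  ## fine components refine within one).
  k <- if (length(config$p) > 1L) sample.int(length(config$p), 1L) else 1L
  p_k <- config$p[k]
  col_sd <- config$sigma[k] / basis_feature_scales(model$basis)
  f_dim <- basis_dim(model$basis)
  n <- model$n_states
  if (n > 1L) {
    a <- model$alpha[-1L, , drop = FALSE]
    mask <- matrix(runif(length(a)) < p_k, nrow = nrow(a))
    sds <- matrix(col_sd, nrow = nrow(a), ncol = f_dim, byrow = TRUE)
    a[mask] <- a[mask] + rnorm(sum(mask), sd = sds[mask])
    model$alpha[-1L, ] <- a
  }
  b <- model$beta
  mask <- matrix(runif(length(b)) < p_k, nrow = nrow(b))
  sds <- matrix(col_sd, nrow = nrow(b), ncol = f_dim, byrow = TRUE)
  b[mask] <- b[mask] + rnorm(sum(mask), sd = sds[mask])
  model$beta <- b
  list(model = model, moves = fired)
}

## -- per-chain RNG streams -------------------------------------------------
## Each chain owns an independent RNG state, so results do not depend on the
## order in which chains are advanced within an iteration (chains could be
## evaluated concurrently without changing the answer).

rng_state_new <- function(seed) {
  old <- get0(".Random.seed", envir = .GlobalEnv)
  set.seed(seed)
  st <- get(".Random.seed", envir = .GlobalEnv)
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  st
}

with_rng_state <- function(state, expr) {
  assign(".Random.seed", state, envir = .GlobalEnv)
  value <- force(expr)
  list(value = value, state = get(".Random.seed", envir = .GlobalEnv))
}

#' Fit a gating model by synchronous multi-chain simulated annealing
#'
#' Initializes `n_chains` independent random models, then for each iteration
#' perturbs every chain's model ([perturb()]), evaluates the penalized cost
#' ([model_cost()]) and accepts or rejects with the Metropolis rule
#' ([accept_move()]) at the shared temperature `T0 * gamma^t`. Chains never
#' exchange information. The whole run is reproducible from `config$seed`;
#' each chain draws from its own RNG stream so the result is independent of
#' chain evaluation order.
#'
#' @param protocols Named list of [protocol()] objects.
#' @param dataset Data frame with columns `protocol`, `x`, `y`, `weight`.
#' @param config An [anneal_config()]; `config$seed` must be set.
#' @param cost_fn Optional replacement cost function `function(model)`; used
#'   for algorithm testing with an injected objective. Defaults to
#'   [model_cost()] on `protocols`/`dataset`.
#' @param init_models Optional list of `n_chains` starting models; defaults
#'   to random draws per chain.
#' @param log_file Optional path; when set, one line per (iteration, chain)
#'   proposal is appended: `iteration,chain,temperature,moves,cost,accepted`.
#' @param progress_every Print the global best cost every this many
#'   iterations (0 = silent).
#' @return A `gatefit_fit` list: `best_model`, `best_cost`, per-chain
#'   `chain_best_models`/`chain_best_costs`, the `(n_iterations + 1) x
#'   n_chains` best-so-far `cost_trajectory`, per-move `proposed`/`accepted`
#'   counts, resolved `T0`, `chain_seeds` and the `config`.
#' @export
anneal <- function(protocols, dataset, config, cost_fn = NULL,
                   init_models = NULL, log_file = NULL, progress_every = 0) {
  gf_check(inherits(config, "anneal_config"), "gatefit_invalid_argument",
           "config must come from anneal_config()")
  gf_check(!is.null(config$seed), "gatefit_invalid_argument",
           "config$seed is mandatory: fits must be reproducible")
  if (is.null(cost_fn)) {
    cost_fn <- function(model) model_cost(model, protocols, dataset,
                                          penalty_weight = config$penalty_weight,
                                          backend = config$backend)
  }
  n_chains <- config$n_chains
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max, n_chains)
  rng <- lapply(chain_seeds, rng_state_new)

  ## initialization (with retries on failed simulation)
  current <- vector("list", n_chains)
  cur_cost <- rep(Inf, n_chains)
  for (c_i in seq_len(n_chains)) {
    st <- rng[[c_i]]
    for (try_i in seq_len(50L)) {
      out <- with_rng_state(st, {
        m <- if (!is.null(init_models)) init_models[[c_i]] else
          random_model(config$init_states, config$init_p_extra, config$basis,
                       config$sd_offset, config$sd_vdep)
        list(m = m, cost = cost_fn(m))
      })
      st <- out$state
      if (is.finite(out$value$cost) || !is.null(init_models)) break
    }
    rng[[c_i]] <- st
    current[[c_i]] <- out$value$m
    cur_cost[c_i] <- out$value$cost
  }
  gf_check(any(is.finite(cur_cost)), "gatefit_initialization_failure",
           "no chain produced a finite cost after 50 initialization attempts")

  T0 <- config$T0
  if (is.null(T0)) T0 <- max(median(cur_cost[is.finite(cur_cost)]), 1e-12)
  config$T0 <- T0

  best <- current
  best_cost <- cur_cost
  traj <- matrix(NA_real_, nrow = config$n_iterations + 1L, ncol = n_chains)
  traj[1L, ] <- best_cost
  proposed <- setNames(numeric(length(MOVE_NAMES) + 1L), c(MOVE_NAMES, "rate_update"))
  accepted <- proposed
  log_con <- NULL
  if (!is.null(log_file)) {
    log_con <- file(log_file, open = "wt")
    on.exit(close(log_con), add = TRUE)
    writeLines("iteration,chain,temperature,moves,cost,accepted", log_con)
  }

  for (t_i in seq_len(config$n_iterations)) {
    temp <- anneal_temperature(t_i - 1L, config)
    for (c_i in seq_len(n_chains)) {
      out <- with_rng_state(rng[[c_i]], {
        prop <- perturb(current[[c_i]], config)
        e_new <- cost_fn(prop$model)
        ok <- accept_move(cur_cost[c_i], e_new, temp)
        list(prop = prop, e_new = e_new, ok = ok)
      })
      rng[[c_i]] <- out$state
      res <- out$value
      mvs <- c(res$prop$moves, "rate_update")
      proposed[mvs] <- proposed[mvs] + 1
      if (res$ok) {
        accepted[mvs] <- accepted[mvs] + 1
        current[[c_i]] <- res$prop$model
        cur_cost[c_i] <- res$e_new
        if (res$e_new < best_cost[c_i]) {
          best_cost[c_i] <- res$e_new
          best[[c_i]] <- res$prop$model
        }
      }
      if (!is.null(log_con)) {
        writeLines(sprintf("%d,%d,%.8g,%s,%.10g,%d", t_i, c_i, temp,
                           paste(res$prop$moves, collapse = "+"),
                           res$e_new, as.integer(res$ok)), log_con)
      }
    }
    traj[t_i + 1L, ] <- best_cost
    if (progress_every > 0 && t_i %% progress_every == 0L) {
      message(sprintf("iteration %d: T = %.4g, best cost = %.6g",
                      t_i, temp, min(best_cost)))
    }
  }

  g_best <- which.min(best_cost)
  structure(list(best_model = best[[g_best]],
                 best_cost = best_cost[g_best],
                 chain_best_models = best,
                 chain_best_costs = best_cost,
                 cost_trajectory = traj,
                 proposed = proposed,
                 accepted = accepted,
                 T0 = T0,
                 chain_seeds = chain_seeds,
                 config = config),
            class = "gatefit_fit")
}

#' @export
print.gatefit_fit <- function(x, ...) {
  cat(sprintf("<gatefit_fit: %d chains x %d iterations>\n",
              x$config$n_chains, x$config$n_iterations))
  cat(sprintf("  best cost: %.6g (%d states, %d edges)\n", x$best_cost,
              x$best_model$n_states, nrow(x$best_model$edges)))
  cat("  per-chain best costs:",
      paste(sprintf("%.3g", x$chain_best_costs), collapse = ", "), "\n")
  invisible(x)
}
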