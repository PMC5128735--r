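test_that("temperature schedule is exactly exponential", {
  cfg <- anneal_config(T0 = 8, gamma = 0.5, seed = 1)
  expect_identical(anneal_temperature(0, cfg), 8)
  expect_identical(anneal_temperature(3, cfg), 1)
  temps <- anneal_temperature(0:50, anneal_config(T0 = 2, gamma = 0.97, seed = 1))
  expect_equal(temps, 2 * 0.97^(0:50))
  expect_true(all(diff(temps) < 0))
})

test_that("Metropolis rule: downhill always, uphill at the Boltzmann rate", {
  set.seed(123)
  expect_true(all(replicate(50, accept_move(2, 1.99, 0.01))))
  expect_true(accept_move(2, 2, 1e-9))  # equal cost counts as downhill
  expect_false(accept_move(1, Inf, 100))

  # empirical acceptance at (e' - e)/T = 1 over many draws: e^-1
  n <- 1e5
  acc <- sum(replicate(n, accept_move(0, 1, 1)))
  p_hat <- acc / n
  se <- sqrt(exp(-1) * (1 - exp(-1)) / n)
  expect_lt(abs(p_hat - exp(-1)), 3 * se)

  # T -> 0+: uphill acceptance vanishes
  expect_false(any(replicate(50, accept_move(1, 1.001, 1e-8))))

  # binned acceptance frequencies match exp(-de/T) (chi-square)
  de <- c(0.25, 0.5, 1, 2)
  counts <- vapply(de, function(d) sum(replicate(2e4, accept_move(0, d, 1))),
                   numeric(1))
  p_exp <- exp(-de)
  chi <- sum((counts - 2e4 * p_exp)^2 / (2e4 * p_exp * (1 - p_exp)))
  expect_gt(stats::pchisq(chi, df = 4, lower.tail = FALSE), 0.01)
})

test_that("zero-variance rate update is the identity and guards hold", {
  cfg <- anneal_config(p = 1, sigma = 0,
                       move_probs = c(state_add = 0, state_remove = 0,
                                      edge_add = 0, edge_remove = 0),
                       seed = 1)
  set.seed(5)
  m <- random_model(4, 0.3)
  out <- perturb(m, cfg)
  expect_identical(out$model, m)
  expect_identical(out$moves, character(0))

  # state removal blocked at min_states
  cfg2 <- anneal_config(p = 0, sigma = 0, min_states = 2,
                        move_probs = c(state_add = 0, state_remove = 1,
                                       edge_add = 0, edge_remove = 0),
                        seed = 1)
  m2 <- two_state_model(2, 3)
  out2 <- perturb(m2, cfg2)
  expect_identical(out2$model$n_states, 2L)
  expect_identical(out2$model$edges, m2$edges)

  # edge addition blocked on the complete graph
  cfg3 <- anneal_config(p = 0, sigma = 0,
                        move_probs = c(state_add = 0, state_remove = 0,
                                       edge_add = 1, edge_remove = 0),
                        seed = 1)
  ring <- markov_model(3, rbind(c(1L,2L), c(1L,3L), c(2L,3L)), c(1, 0, 0),
                       alpha = matrix(0, 3, 2), beta = matrix(0, 3, 2),
                       basis = voltage_basis("linear"))
  expect_identical(nrow(perturb(ring, cfg3)$model$edges), 3L)
})

test_that("perturbation preserves validity, connectivity and detailed balance", {
  cfg <- anneal_config(p = 0.4, sigma = 0.5,
                       move_probs = c(state_add = 0.2, state_remove = 0.2,
                                      edge_add = 0.2, edge_remove = 0.2,
                                      conductance_flip = 0.1),
                       min_states = 2, max_states = 8, seed = 1)
  set.seed(77)
  m <- random_model(4, 0.3)
  for (i in 1:2000) {
    m_in <- m
    out <- perturb(m, cfg)
    expect_identical(m, m_in)  # input untouched (copy semantics)
    m <- out$model
    rep <- validate_model(m)
    if (!rep$ok) fail(paste(rep$violations, collapse = "; "))
    expect_lt(detailed_balance_residual(m, -40), 1e-10)
  }
  expect_true(validate_model(m)$ok)
})

test_that("annealing on an injected quadratic objective finds its minimum", {
  # cost depends on one beta offset only; minimum at beta[1,1] = 1.7
  cost_fn <- function(model) (model$beta[1, 1] - 1.7)^2
  cfg <- anneal_config(n_chains = 3, n_iterations = 800, T0 = 1,
                       gamma = (1e-6)^(1 / 800), p = 1, sigma = 0.25,
                       move_probs = c(state_add = 0, state_remove = 0,
                                      edge_add = 0, edge_remove = 0),
                       init_states = 2, seed = 99)
  fit <- anneal(NULL, NULL, cfg, cost_fn = cost_fn)
  expect_lt(abs(fit$best_model$beta[1, 1] - 1.7), 0.05)
  expect_lt(fit$best_cost, 0.05^2)
})

test_that("fits are deterministic and bookkeeping is sound", {
  cost_fn <- function(model) sum(model$beta^2)
  cfg <- anneal_config(n_chains = 3, n_iterations = 150, T0 = 1, gamma = 0.99,
                       sigma = 0.3, init_states = 3, seed = 7)
  f1 <- anneal(NULL, NULL, cfg, cost_fn = cost_fn)
  f2 <- anneal(NULL, NULL, cfg, cost_fn = cost_fn)
  expect_identical(f1$cost_trajectory, f2$cost_trajectory)
  expect_identical(f1$best_model, f2$best_model)

  # n_iterations = 0: global best is the best initial model
  cfg0 <- anneal_config(n_chains = 4, n_iterations = 0, T0 = 1,
                        init_states = 3, seed = 13)
  f0 <- anneal(NULL, NULL, cfg0, cost_fn = cost_fn)
  expect_identical(f0$best_cost, min(f0$cost_trajectory[1, ]))

  # best-so-far trajectories are non-increasing, global best is the min
  expect_true(all(apply(f1$cost_trajectory, 2, function(tr) all(diff(tr) <= 0))))
  expect_identical(f1$best_cost, min(f1$chain_best_costs))
  expect_true(validate_model(f1$best_model)$ok)
})

test_that("every model visited in a real fit is valid and balanced", {
  na3 <- ground_truth_model("na3")
  prots <- nav_protocols(reduced = TRUE)
  set.seed(1)
  ds <- synth_dataset(na3, prots, noise_sd = 0.01)
  visited <- new.env(parent = emptyenv()); visited$n <- 0L
  base_cost <- function(model) {
    rep <- validate_model(model)
    if (!rep$ok) fail(paste(rep$violations, collapse = "; "))
    expect_lt(detailed_balance_residual(model, -40), 1e-10)
    visited$n <- visited$n + 1L
    model_cost(model, prots, ds)
  }
  cfg <- anneal_config(n_chains = 2, n_iterations = 40, sigma = 0.4, p = 0.3,
                       init_states = 3, seed = 3,
                       move_probs = c(state_add = 0.1, state_remove = 0.1,
                                      edge_add = 0.1, edge_remove = 0.1))
  fit <- anneal(prots, ds, cfg, cost_fn = base_cost)
  expect_gte(visited$n, 80L)
  expect_true(is.finite(fit$best_cost))
})
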