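test_that("matrix-exponential propagation matches closed forms", {
  # pure decay: rate 2 out of state 1, no return
  Q <- matrix(c(-2, 2, 0, 0), 2, 2)
  x <- propagate(Q, c(1, 0), 0.5)
  expect_equal(x[1], exp(-1), tolerance = 1e-12)
  expect_equal(propagate(Q, c(1, 0), 0), c(1, 0))

  # stationarity: steady state is a fixed point for any duration
  m <- two_state_model(2, 3)
  Qm <- build_Q(m, 0)
  ss <- steady_state(Qm)
  expect_equal(propagate(Qm, ss, 13.7), ss, tolerance = 1e-10)

  # cross-check against the independent dense exponential
  skip_if_not_installed("Matrix")
  set.seed(2)
  for (i in 1:10) {
    m <- random_simulable_model(sample(3:5, 1), 0.4)
    Q <- build_Q(m, runif(1, -80, 20))
    x0 <- steady_state(build_Q(m, -100))
    H_ref <- as.matrix(Matrix::expm(0.7 * Q))
    # the dense Pade reference is only a valid oracle while it conserves
    # probability itself (it degrades on stiff generators)
    if (max(abs(colSums(H_ref) - 1)) < 1e-10) {
      expect_lt(max(abs(propagate(Q, x0, 0.7) -
                          as.numeric(H_ref %*% x0))), 1e-7)
    }
  }
})

test_that("powered-up sampling equals one-shot propagation and conserves mass", {
  Q <- matrix(c(-2, 2, 0, 0), 2, 2)
  tr <- sample_trace(Q, c(1, 0), dt = 0.1, n_steps = 10)
  expect_identical(dim(tr), c(11L, 2L))
  expect_equal(tr[, 1], exp(-0.2 * (0:10)), tolerance = 1e-12)

  set.seed(3)
  m <- random_model(4, 0.3)
  Q <- build_Q(m, -20)
  x0 <- steady_state(build_Q(m, -100))
  tr <- sample_trace(Q, x0, dt = 0.05, n_steps = 40)
  expect_equal(tr[41, ], propagate(Q, x0, 2), tolerance = 1e-12)
  expect_true(all(abs(rowSums(tr) - 1) < 1e-9))
  expect_gte(min(tr), -1e-12)
})

test_that("ODE reference backend agrees with the exponential", {
  Q <- matrix(c(-2, 2, 0, 0), 2, 2)
  expect_equal(propagate_ode(Q, c(1, 0), 0.5)[2, 1], exp(-1),
               tolerance = 1e-6)
  set.seed(17)
  for (i in 1:20) {
    m <- random_simulable_model(sample(3:6, 1))
    v <- runif(1, -100, 40)
    Q <- build_Q(m, v)
    x0 <- steady_state(build_Q(m, -100))
    expect_equal(propagate_ode(Q, x0, 1.5)[2, ], propagate(Q, x0, 1.5),
                 tolerance = 1e-6)
  }
})

test_that("rise and fall times recover analytic crossing times", {
  tau <- 1
  dt <- tau / 100
  tt <- seq(0, 8 * tau, by = dt)
  g_rise <- 1 - exp(-tt / tau)
  expect_equal(rise_time(g_rise, dt), tau * log(9), tolerance = 0.01)
  # peak then mono-exponential fall
  g_fall <- c(g_rise[tt <= 3 * tau], exp(-(tt[tt > 0] / tau))[1:500])
  expect_equal(fall_time(g_fall, dt), tau * log(0.9 / 0.2), tolerance = 0.01)
  # monotone rising trace never falls back: undefined fall time
  expect_error(fall_time(g_rise, dt), class = "gatefit_feature_undefined")
  expect_true(is.na(gatefit:::fall_time_or_na(g_rise, dt)))
})

test_that("stiffness penalty is the spectral radius over the voltage grid", {
  expect_equal(stiffness_penalty(two_state_model(2, 3)), 5, tolerance = 1e-10)
  # scaling all rates by c scales the penalty by c (shift both theta offsets)
  m <- two_state_model(2, 3)
  m2 <- m
  m2$beta[1, 1] <- m2$beta[1, 1] + 2 * log(7)  # scales k by 7^2 -> rates by 7
  expect_equal(stiffness_penalty(m2), 7 * stiffness_penalty(m),
               tolerance = 1e-9)
})

test_that("protocol runs extract the expected features", {
  prots <- nav_protocols(reduced = TRUE)
  # voltage-independent model: normalized G-V flat at 1
  flat <- two_state_model(1, 1)
  gv <- run_protocol(flat, prots$na_act)
  expect_equal(gv$y, rep(1, length(gv$x)), tolerance = 1e-9)

  # fast-recovering model: peak ratio approaches 1 at long intervals
  na3 <- ground_truth_model("na3")
  rec <- run_protocol(na3, prots$na_rec)
  expect_gt(rec$y[which.max(rec$x)], 0.9)
  expect_true(all(diff(rec$y[order(rec$x)]) > 0))  # recovery is monotone

  # na3 depolarizing trace: rises then falls (single interior maximum)
  tr <- run_protocol(na3, prots$na_trace)
  pk <- which.max(tr$y)
  expect_gt(pk, 1)
  expect_lt(pk, nrow(tr))
  expect_equal(max(tr$y), 1)

  # expm and ode backends agree on features
  for (pn in c("na_act", "na_ssi", "na_rec")) {
    a <- run_protocol(na3, prots[[pn]], backend = "expm")
    b <- run_protocol(na3, prots[[pn]], backend = "ode")
    expect_equal(a$y, b$y, tolerance = 1e-5)
  }
})

test_that("occupancies stay conserved and non-negative along whole protocols", {
  set.seed(12)
  prots <- nav_protocols(reduced = TRUE)
  for (i in 1:5) {
    m <- random_simulable_model(sample(3:5, 1))
    for (pn in c("na_act", "na_ssi", "na_rec")) {
      res <- run_protocol(m, prots[[pn]], keep_traces = TRUE)
      for (wins in attr(res, "traces")) {
        for (w in wins) {
          expect_true(all(abs(rowSums(w$occ) - 1) < 1e-9))
          expect_gte(min(w$occ), -1e-12)
        }
      }
    }
  }
})

test_that("cost is the weighted squared error plus stiffness penalty", {
  na3 <- ground_truth_model("na3")
  prots <- nav_protocols(reduced = TRUE)
  set.seed(44)
  ds <- synth_dataset(na3, prots, noise_sd = 0)
  # simulated == observed, penalty off -> exactly zero
  expect_equal(model_cost(na3, prots, ds, penalty_weight = 0), 0,
               tolerance = 1e-20)
  # single-row difference d with weight w -> w * d^2
  ds1 <- ds[ds$protocol == "na_act", ][1, ]
  ds1$y <- ds1$y + 0.3
  ds1$weight <- 2
  expect_equal(model_cost(na3, prots, ds1, penalty_weight = 0), 2 * 0.09,
               tolerance = 1e-10)
  # penalty weight adds the stiffness term
  expect_equal(model_cost(na3, prots, ds, penalty_weight = 1e-4),
               1e-4 * stiffness_penalty(na3), tolerance = 1e-10)
  # brute-force per-row recomputation agrees
  set.seed(45)
  ds_n <- synth_dataset(na3, prots, noise_sd = 0.05)
  sims <- lapply(prots, function(p) run_protocol(na3, p))
  total <- 0
  for (r in seq_len(nrow(ds_n))) {
    sim <- sims[[ds_n$protocol[r]]]
    total <- total + ds_n$weight[r] *
      (sim$y[which.min(abs(sim$x - ds_n$x[r]))] - ds_n$y[r])^2
  }
  expect_equal(model_cost(na3, prots, ds_n, penalty_weight = 0), total,
               tolerance = 1e-10)
  # unmatched rows are an error, not silently dropped
  ds_bad <- ds[1, ]; ds_bad$x <- 999
  expect_error(model_cost(na3, prots, ds_bad),
               class = "gatefit_invalid_argument")
})

test_that("driving-force singularities are rejected at protocol validation", {
  expect_error(
    protocol("bad", -100,
             steps = list(protocol_step("sweep", 5, record = TRUE, dt = 0.01)),
             sweep = c(-20, 49.5),
             feature = "peak_conductance_over_driving_force",
             normalization = "max_over_sweep", reversal = 50),
    class = "gatefit_invalid_argument")
})
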