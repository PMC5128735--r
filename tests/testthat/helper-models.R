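# Shared fixtures, built in code.

# Two-state model with voltage-independent rates r12 (1 -> 2) and r21
# (2 -> 1): alpha2 = ln(r12/r21), k = r12 * r21.
two_state_model <- function(r12 = 2, r21 = 3, basis = voltage_basis("linear")) {
  f_dim <- basis_dim(basis)
  pad <- function(x) c(x, numeric(f_dim - 1L))
  markov_model(2, rbind(c(1L, 2L)), c(0, 1),
               alpha = rbind(numeric(f_dim), pad(log(r12 / r21))),
               beta = rbind(pad(log(r12 * r21))),
               basis = basis)
}

# Chain 1-2-3 with all four rates equal to 1 (voltage independent).
unit_chain3 <- function() {
  markov_model(3, rbind(c(1L, 2L), c(2L, 3L)), c(0, 1, 0),
               alpha = matrix(0, 3, 2), beta = matrix(0, 2, 2),
               basis = voltage_basis("linear"))
}

random_cyclic_model <- function(n_states = 4, basis = voltage_basis("linear")) {
  repeat {
    m <- random_model(n_states, p_extra = 0.5, basis = basis)
    if (nrow(m$edges) > m$n_states - 1L) return(m)  # at least one cycle
  }
}

# Random model that simulates cleanly: occasional draws are so stiff that
# the exponential cannot be evaluated in double precision; those raise the
# typed stiffness error (the same mechanism by which the annealer rejects
# them) and are redrawn here.
random_simulable_model <- function(n_states, p_extra = 0.3,
                                   basis = voltage_basis("linear"),
                                   v_probe = c(-120, -60, 0, 60)) {
  repeat {
    m <- random_model(n_states, p_extra, basis = basis)
    ok <- tryCatch({
      for (v in v_probe) propagate(build_Q(m, v), steady_state(build_Q(m, -100)), 1)
      TRUE
    }, gatefit_stiffness_error = function(e) FALSE,
       gatefit_degenerate_model = function(e) FALSE)
    if (ok) return(m)
  }
}

expect_occupancy <- function(x, tol = 1e-9) {
  expect_equal(sum(x), 1, tolerance = tol)
  expect_true(min(x) >= -tol)
}
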