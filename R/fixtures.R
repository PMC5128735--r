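## Packaged protocol suites and ground-truth models. Real Nav1.5/KCNQ1
## recordings are published only as figures, so quantitative end-to-end
## testing runs against synthetic targets generated from fixed ground-truth
## models under the same protocol definitions.

#' Sodium-channel (Nav1.5-style) protocol suite
#'
#' The five-protocol suite used for cardiac Na+ channel fitting, with
#' reversal potential +50 mV:
#' \describe{
#'   \item{`na_act`}{Voltage-dependent activation: depolarizing pulses from
#'     -120 to +20 mV in 10 mV increments from a -100 mV resting potential;
#'     peak conductance over driving force, normalized to its maximum (G-V).}
#'   \item{`na_ssi`}{Steady-state inactivation: hold -120 mV, 200 ms
#'     conditioning pulses from -120 to +20 mV in 10 mV increments, then a
#'     -20 mV test pulse; normalized peak current.}
#'   \item{`na_rec`}{Recovery from inactivation: hold -120 mV, 200 ms
#'     conditioning pulse at -20 mV, recovery at -120 mV for 1-1000 ms, then
#'     a -20 mV test pulse; test peak normalized to conditioning peak.}
#'   \item{`na_rise`, `na_fall`}{Activation-protocol pulses scored by 10-90%
#'     rise time and 90-20% fall time of the conductance trace (the fall
#'     time tracks fast inactivation). Kept as two protocols sharing one
#'     step definition so that every protocol extracts a single feature.}
#'   \item{`na_trace`}{Normalized conductance trace over 5 ms at a -10 mV
#'     depolarizing pulse.}
#' }
#'
#' @param reduced If `TRUE`, returns coarser variants for fast optimization
#'   runs: every other sweep voltage, shorter conditioning/test pulses and a
#'   10x coarser sampling grid. The full variants encode the experimental
#'   protocol values.
#' @return Named list of [protocol()] objects.
#' @export
nav_protocols <- function(reduced = FALSE) {
  e_na <- 50
  if (!reduced) {
    act_sweep <- seq(-120, 20, by = 10)
    ssi_sweep <- seq(-120, 20, by = 10)
    rec_sweep <- c(1, 2, 5, 10, 20, 50, 100, 200, 500, 1000)
    rf_sweep <- seq(-60, 20, by = 10)
    cond_ms <- 200; pulse_ms <- 20; dt <- 0.005
  } else {
    act_sweep <- seq(-120, 20, by = 20)
    ssi_sweep <- seq(-120, 20, by = 20)
    rec_sweep <- c(1, 3, 10, 30, 100)
    rf_sweep <- seq(-60, 20, by = 20)
    cond_ms <- 50; pulse_ms <- 10; dt <- 0.05
  }
  pulse <- list(protocol_step("sweep", pulse_ms, record = TRUE, dt = dt))
  list(
    na_act = protocol("na_act", holding = -100, steps = pulse,
                      sweep = act_sweep,
                      feature = "peak_conductance_over_driving_force",
                      normalization = "max_over_sweep", reversal = e_na),
    na_ssi = protocol("na_ssi", holding = -120,
                      steps = list(protocol_step("sweep", cond_ms),
                                   protocol_step(-20, pulse_ms, record = TRUE,
                                                 dt = dt)),
                      sweep = ssi_sweep, feature = "normalized_peak",
                      normalization = "max_over_sweep", reversal = e_na),
    na_rec = protocol("na_rec", holding = -120,
                      steps = list(protocol_step(-20, cond_ms, record = TRUE,
                                                 dt = dt),
                                   protocol_step(-120, "sweep"),
                                   protocol_step(-20, pulse_ms, record = TRUE,
                                                 dt = dt)),
                      sweep = rec_sweep, feature = "peak_ratio",
                      normalization = "none", reversal = e_na),
    na_rise = protocol("na_rise", holding = -100, steps = pulse,
                       sweep = rf_sweep, feature = "rise_time_10_90",
                       normalization = "none", reversal = e_na),
    na_fall = protocol("na_fall", holding = -100, steps = pulse,
                       sweep = rf_sweep, feature = "fall_time_90_20",
                       normalization = "none", reversal = e_na),
    na_trace = protocol("na_trace", holding = -100,
                        steps = list(protocol_step("sweep", 5, record = TRUE,
                                                   dt = dt)),
                        sweep = -10, feature = "normalized_trace",
                        reversal = e_na))
}

#' Potassium-channel (KCNQ1-style) protocol suite
#'
#' Protocols for K+ channel fitting, reversal potential -90 mV:
#' \describe{
#'   \item{`k_act`}{Activation: pulses from -100 to +60 mV in 20 mV
#'     increments from -100 mV rest; peak conductance over driving force,
#'     normalized (G-V).}
#'   \item{`k_deact`}{Deactivation: hold -80 mV, 2 ms depolarizing pulse at
#'     +60 mV, then 4 ms conditioning pulses from -120 to 0 mV; minimum
#'     absolute current over driving force, normalized.}
#'   \item{`k_rise`}{Activation pulses scored by 10-90% rise time.}
#'   \item{`k_trace_m20`, `k_trace_0`, `k_trace_p40`}{Normalized conductance
#'     traces over 4 ms at -20, 0 and +40 mV from a -80 mV resting
#'     potential (one protocol per pulse voltage).}
#' }
#'
#' @inheritParams nav_protocols
#' @return Named list of [protocol()] objects.
#' @export
kcnq1_protocols <- function(reduced = FALSE) {
  e_k <- -90
  if (!reduced) {
    act_sweep <- seq(-100, 60, by = 20)
    deact_sweep <- seq(-120, 0, by = 20)
    dt <- 0.01
  } else {
    act_sweep <- seq(-100, 60, by = 40)
    deact_sweep <- seq(-120, 0, by = 40)
    dt <- 0.05
  }
  act_steps <- list(protocol_step("sweep", 4, record = TRUE, dt = dt))
  ktrace <- function(name, v) {
    protocol(name, holding = -80,
             steps = list(protocol_step("sweep", 4, record = TRUE, dt = dt)),
             sweep = v, feature = "normalized_trace", reversal = e_k)
  }
  list(
    k_act = protocol("k_act", holding = -100, steps = act_steps,
                     sweep = act_sweep,
                     feature = "peak_conductance_over_driving_force",
                     normalization = "max_over_sweep", reversal = e_k),
    k_deact = protocol("k_deact", holding = -80,
                       steps = list(protocol_step(60, 2),
                                    protocol_step("sweep", 4, record = TRUE,
                                                  dt = dt)),
                       sweep = deact_sweep,
                       feature = "min_abs_current_over_driving_force",
                       normalization = "max_over_sweep", reversal = e_k),
    k_rise = protocol("k_rise", holding = -100, steps = act_steps,
                      sweep = act_sweep, feature = "rise_time_10_90",
                      normalization = "none", reversal = e_k),
    k_trace_m20 = ktrace("k_trace_m20", -20),
    k_trace_0 = ktrace("k_trace_0", 0),
    k_trace_p40 = ktrace("k_trace_p40", 40))
}

#' Fixed ground-truth gating models
#'
#' Deterministic models with hand-set parameters used to generate synthetic
#' target data:
#' \describe{
#'   \item{`"na3"`}{Three-state closed-open-inactivated chain (C1 - O2 - I3,
#'     state 2 conducting) with a linear voltage basis. Depolarization
#'     favors the open state over the closed state with half-activation near
#'     -40 mV, and the inactivated state dominates at depolarized steady
#'     state, so a depolarizing step produces the transient Na+-like
#'     conductance: a fast rise followed by decay. Recovery from
#'     inactivation at -120 mV runs on a ~10 ms timescale.}
#'   \item{`"k4"`}{Four-state chain C1 - C2 - C3 - O4 (state 4 conducting),
#'     linear basis, no inactivated state: conductance rises monotonically
#'     under depolarization and deactivates on hyperpolarization, a
#'     delayed-rectifier-like K+ phenotype on a millisecond scale.}
#' }
#'
#' @param name `"na3"` or `"k4"`.
#' @return A valid `markov_model`.
#' @export
ground_truth_model <- function(name) {
  gf_check(is.character(name) && length(name) == 1L,
           "gatefit_invalid_argument", "name must be a string")
  basis <- voltage_basis("linear")
  switch(name,
    na3 = markov_model(
      n_states = 3L,
      edges = rbind(c(1L, 2L), c(2L, 3L)),
      conductance = c(0, 1, 0),
      ## ln s2 = 6 + 0.15 v (activation, V1/2 ~ -40 mV);
      ## ln s3 = 8.4 + 0.12 v (inactivation dominates when depolarized)
      alpha = rbind(c(0, 0), c(6, 0.15), c(8.4, 0.12)),
      ## k12 fast (activation ~ sub-ms at -20 mV), k23 slower with recovery
      ## from inactivation ~ 10 ms at -120 mV
      beta = rbind(c(0.6, 0.02), c(-2.64, -0.022)),
      basis = basis),
    k4 = markov_model(
      n_states = 4L,
      edges = rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L)),
      conductance = c(0, 0, 0, 1),
      ## successive openings favored by depolarization; overall V1/2 ~ -20 mV
      alpha = rbind(c(0, 0), c(0.6, 0.03), c(1.2, 0.06), c(2.4, 0.12)),
      beta = rbind(c(1.2, 0.01), c(0.8, 0.01), c(0.4, 0.01)),
      basis = basis),
    gf_stop("gatefit_invalid_argument",
            sprintf("unknown ground-truth model \"%s\"", name)))
}

#' Generate a synthetic target dataset from a ground-truth model
#'
#' Simulates every protocol with the matrix-exponential backend, adds i.i.d.
#' Gaussian noise with standard deviation `noise_sd` times the protocol's
#' feature scale (the maximum absolute feature value), and returns the rows
#' as a unit-weight dataset. Rows whose feature is undefined for the
#' ground-truth model (e.g. a fall time at a voltage where the channel barely
#' opens) are dropped: they correspond to quantities an experimenter could
#' not have measured either.
#'
#' Uses R's global RNG; seed it for reproducibility.
#'
#' @param model Ground-truth `markov_model`.
#' @param protocols Named list of [protocol()] objects.
#' @param noise_sd Noise standard deviation relative to the per-protocol
#'   feature scale (0.01 = 1% noise).
#' @param backend Simulation backend.
#' @return Data frame with columns `protocol`, `x`, `y`, `weight` and
#'   attributes `"truth"` (noiseless feature values) and `"noise_floor"`
#'   (`sum(weight * noise^2)`, the cost the ground-truth model incurs on
#'   this dataset without penalty).
#' @export
synth_dataset <- function(model, protocols, noise_sd = 0.01,
                          backend = "expm") {
  rows <- lapply(protocols, function(p) {
    sim <- run_protocol(model, p, backend)
    sim[!is.na(sim$y), , drop = FALSE]
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  truth <- out$y
  scale_by <- ave(abs(out$y), out$protocol, FUN = max)
  scale_by[scale_by == 0] <- 1
  noise <- rnorm(nrow(out), sd = noise_sd * scale_by)
  out$y <- out$y + noise
  out$weight <- 1
  attr(out, "truth") <- truth
  attr(out, "noise_floor") <- sum(noise^2)
  out
}

#' Half-activation voltage of a G-V curve
#'
#' Linear interpolation of the first upward crossing of 0.5 on a normalized
#' conductance-voltage curve.
#'
#' @param v Sweep voltages, mV (ascending).
#' @param g Normalized conductances.
#' @return Voltage in mV (`NA` if the curve never crosses 0.5).
#' @export
gv_half_activation <- function(v, g) {
  ord <- order(v)
  v <- v[ord]; g <- g[ord]
  above <- which(g >= 0.5)
  if (length(above) == 0L) return(NA_real_)
  i2 <- above[1L]
  if (i2 == 1L) return(v[1L])
  i1 <- i2 - 1L
  v[i1] + (0.5 - g[i1]) / (g[i2] - g[i1]) * (v[i2] - v[i1])
}
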