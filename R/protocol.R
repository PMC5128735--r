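## Voltage-clamp protocols as ordered piecewise-constant voltage steps plus a
## feature-extraction rule. A protocol sweeps one variable (a step voltage or
## a step duration) over a list of values; each sweep is simulated from the
## steady state at the holding potential.

FEATURE_KINDS <- c("peak_conductance_over_driving_force", "normalized_peak",
                   "peak_ratio", "rise_time_10_90", "fall_time_90_20",
                   "normalized_trace", "min_abs_current_over_driving_force")
NORMALIZATIONS <- c("max_over_sweep", "first_sweep", "none")

#' Define one voltage step of a clamp protocol
#'
#' @param voltage Step voltage in mV, or the string `"sweep"` to substitute
#'   the protocol's sweep variable.
#' @param duration Step duration in ms, or `"sweep"`.
#' @param record Whether occupancy is sampled during this step (features are
#'   extracted from recorded steps only).
#' @param dt Sampling interval in ms; required when `record = TRUE`.
#' @return A `protocol_step` list.
#' @export
protocol_step <- function(voltage, duration, record = FALSE, dt = NULL) {
  chk_field <- function(x, nm) {
    ok <- (is.numeric(x) && length(x) == 1L && is.finite(x)) ||
      (is.character(x) && identical(x, "sweep"))
    gf_check(ok, "gatefit_invalid_argument",
             sprintf("step %s must be a finite number or \"sweep\"", nm))
  }
  chk_field(voltage, "voltage")
  chk_field(duration, "duration")
  if (is.numeric(duration)) {
    gf_check(duration > 0, "gatefit_invalid_argument",
             "step duration must be positive")
  }
  if (record) {
    gf_check(is.numeric(dt) && length(dt) == 1L && dt > 0,
             "gatefit_invalid_argument", "recorded steps need a positive dt")
  }
  structure(list(voltage = voltage, duration = duration,
                 record = isTRUE(record),
                 dt = if (record) as.numeric(dt) else NULL),
            class = "protocol_step")
}

#' Define a voltage-clamp protocol
#'
#' A protocol is an ordered list of [protocol_step()]s applied from the
#' steady state at `holding` mV, repeated once per value of the sweep
#' variable, plus a feature specification describing the scalar (or trace)
#' extracted per sweep.
#'
#' Feature kinds:
#' \describe{
#'   \item{`peak_conductance_over_driving_force`}{Peak current in the first
#'     recorded step divided by the driving force `v - reversal` (a G-V
#'     point).}
#'   \item{`normalized_peak`}{Peak current of the first recorded (test)
#'     step; pair with `normalization = "max_over_sweep"` for steady-state
#'     inactivation curves.}
#'   \item{`peak_ratio`}{Peak of the second recorded step over the peak of
#'     the first (recovery from inactivation).}
#'   \item{`rise_time_10_90`, `fall_time_90_20`}{Activation and inactivation
#'     kinetics of the first recorded step, see [rise_time()].}
#'   \item{`min_abs_current_over_driving_force`}{Minimum absolute current in
#'     the first recorded step divided by the driving force (deactivation).}
#'   \item{`normalized_trace`}{The full normalized conductance trace of the
#'     first recorded step; the sweep must then contain exactly one value
#'     and the returned x column is time in ms.}
#' }
#'
#' @param name Protocol name (matched against dataset rows).
#' @param holding Holding (resting) potential, mV.
#' @param steps List of [protocol_step()]s.
#' @param sweep Numeric vector of sweep-variable values (mV or ms, depending
#'   on which step field carries the `"sweep"` placeholder).
#' @param feature Feature kind, one of the values listed above.
#' @param normalization How feature values are normalized across the sweep:
#'   `"max_over_sweep"`, `"first_sweep"` or `"none"`.
#' @param reversal Reversal potential of the conducted ion, mV.
#' @return A `protocol` object.
#' @export
protocol <- function(name, holding, steps, sweep, feature,
                     normalization = "none", reversal = 0) {
  feature <- match.arg(feature, FEATURE_KINDS)
  normalization <- match.arg(normalization, NORMALIZATIONS)
  gf_check(is.character(name) && length(name) == 1L && nzchar(name),
           "gatefit_invalid_argument", "protocol name must be a non-empty string")
  gf_check(is.numeric(holding) && length(holding) == 1L && is.finite(holding),
           "gatefit_invalid_argument", "holding potential must be a finite number")
  gf_check(is.list(steps) && length(steps) >= 1L &&
             all(vapply(steps, inherits, logical(1), "protocol_step")),
           "gatefit_invalid_argument", "steps must be a list of protocol_step objects")
  gf_check(is.numeric(sweep) && length(sweep) >= 1L && all(is.finite(sweep)),
           "gatefit_invalid_argument", "sweep must be a non-empty numeric vector")
  p <- structure(list(name = name, holding = as.numeric(holding),
                      steps = steps, sweep = as.numeric(sweep),
                      feature = feature, normalization = normalization,
                      reversal = as.numeric(reversal)),
                 class = "protocol")
  validate_protocol(p)
  p
}

validate_protocol <- function(p) {
  n_rec <- sum(vapply(p$steps, function(s) s$record, logical(1)))
  need <- if (p$feature == "peak_ratio") 2L else 1L
  gf_check(n_rec >= need, "gatefit_invalid_argument",
           sprintf("feature %s needs at least %d recorded step(s), got %d",
                   p$feature, need, n_rec))
  if (p$feature == "normalized_trace") {
    gf_check(length(p$sweep) == 1L, "gatefit_invalid_argument",
             "normalized_trace protocols must have exactly one sweep value")
  }
  ## reject sweep voltages near the reversal potential: the driving force
  ## v - E_rev would blow up conductance estimates
  sweeps_voltage <- any(vapply(p$steps, function(s)
    identical(s$voltage, "sweep"), logical(1)))
  if (sweeps_voltage && p$feature %in%
      c("peak_conductance_over_driving_force",
        "min_abs_current_over_driving_force")) {
    bad <- abs(p$sweep - p$reversal) < 1
    gf_check(!any(bad), "gatefit_invalid_argument",
             sprintf("sweep voltage %g mV is within 1 mV of the reversal potential (%g mV)",
                     p$sweep[which(bad)[1L]], p$reversal))
  }
  invisible(TRUE)
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("<protocol \"%s\": hold %g mV, %d steps, %d sweep values, feature %s>\n",
              x$name, x$holding, length(x$steps), length(x$sweep), x$feature))
  invisible(x)
}

## Substitute the sweep value into a step's placeholders.
resolve_step <- function(step, sweep_value) {
  if (identical(step$voltage, "sweep")) step$voltage <- sweep_value
  if (identical(step$duration, "sweep")) step$duration <- sweep_value
  step
}
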