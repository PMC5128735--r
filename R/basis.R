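#' Voltage basis for rate parameterization
#'
#' Transition rates are modeled as `r(v) = exp(f(v) . theta)`, where `f(v)`
#' is a small feature vector of the membrane voltage and `theta` a parameter
#' vector. Because every rate is log-linear in the same features, detailed
#' balance imposed at one voltage holds at all voltages (see
#' [rates_at_voltage()]).
#'
#' Three bases are supported:
#' \describe{
#'   \item{`linear`}{`f(v) = (1, v)` -- the Eyring-type form
#'     `r(v) = exp(theta1 + theta2 v)`.}
#'   \item{`polynomial`}{`f(v) = (1, v, ..., v^order)`; more expressive but
#'     prone to overfitting and stiffness.}
#'   \item{`sigmoid`}{`f(v) = (1, sig((v - a)/b))` with `sig` the logistic
#'     function; rates are bounded in voltage, which limits stiffness. `a`
#'     (midpoint, mV) and `b` (slope factor, mV) are fixed and shared across
#'     all rates.}
#' }
#'
#' @param kind One of `"linear"`, `"polynomial"`, `"sigmoid"`.
#' @param order Polynomial order (polynomial basis only), an integer >= 1.
#' @param a,b Sigmoid midpoint and slope factor in mV (sigmoid basis only);
#'   `b` must be nonzero.
#' @return An object of class `"voltage_basis"`.
#' @examples
#' basis_eval(voltage_basis("linear"), -40)
#' basis_eval(voltage_basis("sigmoid", a = 0, b = 10), 0)
#' @export
voltage_basis <- function(kind = c("linear", "polynomial", "sigmoid"),
                          order = 2L, a = -40, b = 15) {
  kind <- match.arg(kind)
  if (kind == "polynomial") {
    gf_check(is.numeric(order) && length(order) == 1L && order >= 1 &&
               order == round(order),
             "gatefit_invalid_argument", "polynomial `order` must be an integer >= 1")
  }
  if (kind == "sigmoid") {
    gf_check(is.numeric(b) && length(b) == 1L && b != 0,
             "gatefit_invalid_argument", "sigmoid slope factor `b` must be nonzero")
    gf_check(is.numeric(a) && length(a) == 1L && is.finite(a),
             "gatefit_invalid_argument", "sigmoid midpoint `a` must be a finite number")
  }
  out <- list(kind = kind)
  if (kind == "polynomial") out$order <- as.integer(order)
  if (kind == "sigmoid") { out$a <- as.numeric(a); out$b <- as.numeric(b) }
  class(out) <- "voltage_basis"
  out
}

#' @rdname voltage_basis
#' @param basis A `voltage_basis` object.
#' @return `basis_dim()` returns the basis dimension F (2 for linear and
#'   sigmoid, `order + 1` for polynomial).
#' @export
basis_dim <- function(basis) {
  switch(basis$kind,
         linear = 2L,
         sigmoid = 2L,
         polynomial = basis$order + 1L)
}

#' @rdname voltage_basis
#' @param v Membrane voltage in mV (scalar).
#' @return `basis_eval()` returns the feature vector `f(v)` of length
#'   `basis_dim(basis)`.
#' @export
basis_eval <- function(basis, v) {
  switch(basis$kind,
         linear = c(1, v),
         polynomial = v^(0:basis$order),
         sigmoid = c(1, 1 / (1 + exp(-(v - basis$a) / basis$b))))
}

#' @export
print.voltage_basis <- function(x, ...) {
  extra <- switch(x$kind,
                  linear = "",
                  polynomial = sprintf(" (order %d)", x$order),
                  sigmoid = sprintf(" (a = %g mV, b = %g mV)", x$a, x$b))
  cat(sprintf("<voltage_basis: %s%s, F = %d>\n", x$kind, extra, basis_dim(x)))
  invisible(x)
}

## Typical magnitude of each basis feature over the physiological voltage
## range; used to scale per-column perturbation kernels.
basis_feature_scales <- function(basis, v_range = c(-120, 60)) {
  grid <- seq(v_range[1L], v_range[2L], length.out = 19L)
  f <- vapply(grid, function(v) basis_eval(basis, v), numeric(basis_dim(basis)))
  pmax(1, apply(abs(f), 1L, max))
}

basis_to_list <- function(basis) {
  unclass(basis)
}

basis_from_list <- function(lst) {
  gf_check(is.list(lst) && !is.null(lst$kind), "gatefit_parse_error",
           "basis spec must be a list with a `kind` field")
  voltage_basis(kind = lst$kind,
                order = if (!is.null(lst$order)) lst$order else 2L,
                a = if (!is.null(lst$a)) lst$a else -40,
                b = if (!is.null(lst$b)) lst$b else 15)
}
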