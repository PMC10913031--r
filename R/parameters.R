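#' Control parameters of the sense-making landscape
#'
#' Bundle the six control parameters of the quartic sense-making free energy
#' \deqn{F(\phi) = -h_{ext}\,\phi + \frac{a}{2}\phi^2 + \frac{h_{int}}{3}\phi^3
#'   + \frac{b}{4}\phi^4, \qquad a = a_0\,(T - T_0).}
#' The order parameter \eqn{\phi} is the automatic perception of the symptom:
#' negative values are survival-oriented (alert-protection), positive values
#' liveliness-oriented (trust-explore), zero is neutral. All quantities are
#' dimensionless.
#'
#' @param h_ext Information bias from the expert culture. Negative values act
#'   as nocebo messages, positive values as trustworthy neurobiological
#'   education.
#' @param h_int Historical information bias; positive values encode alarming
#'   learned rules about the symptom.
#' @param a0 Innate sensitivity scale; must be strictly positive.
#' @param b Innate quartic stiffness; must be strictly positive.
#' @param T Information from the senses about the context; must be
#'   non-negative (zero means complete absence of sensory information).
#' @param T0 Innate critical context.
#'
#' @return An object of class `"model_parameters"`: a named list with the six
#'   fields above. The effective quadratic coefficient `a` is never stored;
#'   it is always recomputed via [effective_context_coefficient()] so that
#'   sweeps over `T` cannot desynchronize.
#'
#' @examples
#' p <- model_parameters(h_int = 3, T = 7, T0 = 5)
#' effective_context_coefficient(p)
#' @seealso [sense_making_energy()], [stationary_points()],
#'   [analyze_landscape()]
#' @export
model_parameters <- function(h_ext = 0, h_int = 0, a0 = 1, b = 1,
                             T = 1, T0 = 1) {
  p <- structure(
    list(h_ext = as.numeric(h_ext), h_int = as.numeric(h_int),
         a0 = as.numeric(a0), b = as.numeric(b),
         T = as.numeric(T), T0 = as.numeric(T0)),
    class = "model_parameters")
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks the structural invariants of [model_parameters()]: all fields
#' finite scalars, `a0 > 0`, `b > 0`, `T >= 0`.
#'
#' @param params A `"model_parameters"` object (or a bare named list with the
#'   same fields).
#' @return `params`, invisibly, if valid; otherwise an error of class
#'   `"sensescape_invalid_parameters"`.
#' @export
validate_parameters <- function(params) {
  fields <- c("h_ext", "h_int", "a0", "b", "T", "T0")
  bad <- function(msg) {
    stop(structure(class = c("sensescape_invalid_parameters", "error",
                             "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  if (!is.list(params) || !all(fields %in% names(params)))
    bad(paste("parameters must contain fields:",
              paste(fields, collapse = ", ")))
  vals <- unlist(params[fields])
  if (!is.numeric(vals) || any(!is.finite(vals)))
    bad("all parameters must be finite numbers")
  if (params$a0 <= 0) bad("a0 must be strictly positive")
  if (params$b <= 0) bad("b must be strictly positive")
  if (params$T < 0) bad("T must be non-negative")
  invisible(params)
}

#' Effective context coefficient
#'
#' The quadratic coefficient of the landscape, `a = a0 * (T - T0)`. It is
#' negative when the sensory context falls below the innate critical context
#' `T0`, which is what opens the double-well (bistable) structure.
#'
#' @inheritParams validate_parameters
#' @return The scalar `a`.
#' @export
effective_context_coefficient <- function(params) {
  validate_parameters(params)
  params$a0 * (params$T - params$T0)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Sense-making model parameters (dimensionless):\n")
  cat(sprintf("  h_ext = %g  (expert-culture bias)\n", x$h_ext))
  cat(sprintf("  h_int = %g  (historical bias)\n", x$h_int))
  cat(sprintf("  a0 = %g, b = %g  (innate constants)\n", x$a0, x$b))
  cat(sprintf("  T = %g, T0 = %g  =>  a = %g\n", x$T, x$T0,
              x$a0 * (x$T - x$T0)))
  invisible(x)
}

# Update selected fields of a parameter set, revalidating.
modify_parameters <- function(params, ...) {
  changes <- list(...)
  changes <- changes[!vapply(changes, is.null, logical(1))]
  for (nm in names(changes)) params[[nm]] <- as.numeric(changes[[nm]])
  validate_parameters(params)
  params
}
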