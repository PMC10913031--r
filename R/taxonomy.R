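#' Critical context (closed form)
#'
#' For an untilted landscape (`h_ext = 0`) the context at which the neutral
#' perception and the nonzero perception become exactly degenerate (both at
#' sense-making energy 0) is
#' \deqn{T^* = T_0 + \frac{2 h_{int}^2}{9 a_0 b}.}
#' With no historical bias (`h_int = 0`) this collapses to `T0` and the
#' transition is second order; any learned historical information shifts the
#' onset of uncertainty upward, i.e. the perceived critical context depends
#' on personal history.
#'
#' @inheritParams validate_parameters
#' @return The scalar `T*`.
#' @seealso [degeneracy_context_numeric()] for the tilted (`h_ext != 0`)
#'   generalization.
#' @export
critical_context <- function(params) {
  validate_parameters(params)
  if (params$h_ext != 0)
    stop("critical_context() has a closed form only for h_ext = 0; ",
         "use degeneracy_context_numeric() for tilted landscapes.")
  params$T0 + 2 * params$h_int^2 / (9 * params$a0 * params$b)
}

#' Degeneracy context (numerical)
#'
#' Locates by grid scan plus bisection the context `T` at which the two
#' wells of the landscape are degenerate (equal sense-making energy within
#' `tol`). Generalizes [critical_context()] to `h_ext != 0`; for `h_ext = 0`
#' the two agree within tolerance. In the fully symmetric case (`h_int = 0`,
#' `h_ext = 0`) every bistable landscape is degenerate, and the returned
#' value is the largest `T` with a two-well structure, i.e. `T0`.
#'
#' @inheritParams validate_parameters
#' @param tol Tolerance on the energy difference (and on `T`). Default
#'   `1e-8`.
#' @param T_range Search interval for `T`; defaults to
#'   `[max(0, T0 - |h_int| - |h_ext| - 1), T0 + h_int^2/(a0 b) + |h_ext| + 1]`,
#'   which brackets every admissible degeneracy.
#' @param n_grid Number of scan points before bisection. Default 2001.
#' @return The degeneracy context `T`.
#' @export
degeneracy_context_numeric <- function(params, tol = 1e-8, T_range = NULL,
                                       n_grid = 2001) {
  validate_parameters(params)
  stopifnot(tol > 0)
  if (is.null(T_range)) {
    lo <- max(0, params$T0 - abs(params$h_int) - abs(params$h_ext) - 1)
    hi <- params$T0 + params$h_int^2 / (params$a0 * params$b) +
      abs(params$h_ext) + 1
    T_range <- c(lo, hi)
  }
  not_found <- function(msg) {
    stop(structure(class = c("sensescape_not_found", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  sgn <- function(g) {
    if (is.na(g)) NA_real_ else sign(g)
  }
  well_gap <- function(T) well_gap_fast(params, T)
  bisect_gap <- function(lo, hi, s_lo) {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      sm <- sgn(well_gap(mid))
      if (is.na(sm) || sm == 0 || sm != s_lo) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }

  Ts <- seq(T_range[1], T_range[2], length.out = n_grid)
  gaps <- vapply(Ts, well_gap, numeric(1))
  signs <- vapply(gaps, sgn, numeric(1))
  ok <- which(!is.na(gaps))
  if (!length(ok))
    not_found(sprintf("no two-well structure found in T range [%g, %g]",
                      T_range[1], T_range[2]))

  # a sign change of the gap along a contiguous two-well run (possibly with
  # degenerate zero-gap points in between) brackets the degeneracy context
  nz <- ok[signs[ok] != 0]
  if (length(nz) > 1) {
    flip <- which(signs[nz[-length(nz)]] * signs[nz[-1]] < 0)
    for (i in flip) {
      if (all(seq(nz[i], nz[i + 1]) %in% ok))
        return(bisect_gap(Ts[nz[i]], Ts[nz[i + 1]], signs[nz[i]]))
    }
  }

  # no strict sign change on the grid: refine the upper boundary T_b of the
  # last two-well run (the metastable well may persist only on a T window
  # narrower than the grid) and probe geometrically toward it
  run_hi <- max(ok)
  T_hi <- Ts[run_hi]
  T_b_hi <- if (run_hi < n_grid) Ts[run_hi + 1] else T_range[2]
  lo <- T_hi; hi <- T_b_hi
  while (hi - lo > tol / 4) {
    mid <- (lo + hi) / 2
    if (is.na(well_gap(mid))) hi <- mid else lo <- mid
  }
  T_b <- lo
  nzi <- which(signs[ok] != 0)
  if (!length(nzi)) {
    # degenerate everywhere it is bistable (symmetric family): the
    # degeneracy context is the upper boundary of bistability
    return(T_b)
  }
  # bisect toward the flip inside (T_hi, T_b], treating "no second well"
  # and opposite signs alike as the upper side; accept the limit only if
  # the gap actually closes there
  s0 <- signs[ok][nzi[length(nzi)]]
  lo <- T_hi; hi <- T_b + (T_b - T_hi) * 1e-3
  while (hi - lo > tol / 4) {
    mid <- (lo + hi) / 2
    sm <- sgn(well_gap(mid))
    if (!is.na(sm) && sm == s0) lo <- mid else hi <- mid
  }
  g_end <- well_gap(lo)
  if (!is.na(g_end) && abs(g_end) <= 1e-6) return((lo + hi) / 2)
  not_found("wells never become degenerate on the search range")
}

# Energy gap between the upper and lower well of the landscape at context T
# (NA when fewer than two wells). Lean internal path used by the bisection
# in degeneracy_context_numeric.
well_gap_fast <- function(params, T) {
  a <- params$a0 * (T - params$T0)
  b <- params$b; h <- params$h_int
  r <- cubic_real_roots(h / b, a / b, -params$h_ext / b)
  for (k in 1:3) {
    g <- -params$h_ext + a * r + h * r^2 + b * r^3
    c2 <- a + 2 * h * r + 3 * b * r^2
    r <- r - ifelse(abs(c2) > 1e-300, g / c2, 0)
  }
  curv <- a + 2 * h * r + 3 * b * r^2
  w <- sort(r[curv > 1e-9])
  if (length(w) < 2) return(NA_real_)
  fw <- -params$h_ext * w + a / 2 * w^2 + h / 3 * w^3 + b / 4 * w^4
  gap <- fw[length(fw)] - fw[1]
  # below the floating-point noise floor of F the wells are degenerate
  if (abs(gap) <= 1e-13 * max(1, abs(fw))) gap <- 0
  gap
}

#' Analyze one sense-making landscape
#'
#' Full characterization of the landscape at one parameter set: stationary
#' points, the alert-protection / neutral / trust-explore roles (by sign of
#' `phi`), the perception bias `delta_phi = |phi_te| - |phi_ap|`, the
#' sense-making bias `delta_F = |F(phi_te)| - |F(phi_ap)|`, the
#' hypervigilance value `F(phi_ap)` and curiosity value `F(phi_te)`, the
#' critical context `T*` (when `h_ext = 0`), and the regime label.
#'
#' Biases are reported as `NA` (flagged, never silently zero) when one of
#' the two nonzero states does not exist. In the catastrophizing landscape
#' the neutral well stands in for the absent trust-explore state, so
#' `curiosity_value` is reported as exactly 0 there while `trust_explore`
#' stays absent; symmetrically for the communicative landscape and
#' `hypervigilance_value`.
#'
#' @inheritParams validate_parameters
#' @param tol Degeneracy tolerance on energies and on the neutrality of
#'   `phi`. Default `1e-6`.
#' @return An object of class `"landscape_analysis"`: list with elements
#'   `params`, `points`, `wells`, `alert_protection`, `neutral`,
#'   `trust_explore` (each a one-row data.frame or `NULL`), `delta_phi`,
#'   `delta_F`, `hypervigilance_value`, `curiosity_value`, `T_star`,
#'   `regime`, `tol`.
#' @examples
#' analyze_landscape(model_parameters(h_int = 1, T = 5.1, T0 = 5))$regime
#' @export
analyze_landscape <- function(params, tol = 1e-6) {
  validate_parameters(params)
  pts <- stationary_points(params, tol = min(tol, 1e-6))
  wells <- landscape_wells(pts, params)

  role_of <- function(phi) {
    if (abs(phi) <= tol) "neutral" else if (phi < 0) "alert_protection"
    else "trust_explore"
  }
  roles <- vapply(wells$phi, role_of, character(1))
  pick <- function(role) {
    i <- which(roles == role)
    if (!length(i)) return(NULL)
    wells[i[which.min(wells$F_value[i])], , drop = FALSE]
  }
  ap <- pick("alert_protection")
  te <- pick("trust_explore")
  neu <- pick("neutral")

  delta_phi <- delta_F <- NA_real_
  if (!is.null(ap) && !is.null(te)) {
    delta_phi <- abs(te$phi) - abs(ap$phi)
    delta_F <- abs(te$F_value) - abs(ap$F_value)
  }
  hyper <- if (!is.null(ap)) ap$F_value else if (!is.null(neu)) 0 else NA_real_
  curio <- if (!is.null(te)) te$F_value else if (!is.null(neu)) 0 else NA_real_

  out <- structure(list(
    params = params, points = pts, wells = wells,
    alert_protection = ap, neutral = neu, trust_explore = te,
    delta_phi = delta_phi, delta_F = delta_F,
    hypervigilance_value = hyper, curiosity_value = curio,
    T_star = if (params$h_ext == 0) critical_context(params) else NA_real_,
    regime = NA_character_, tol = tol), class = "landscape_analysis")
  out$regime <- classify_regime(out, tol)
  out
}

#' Classify the regime of a landscape
#'
#' Structural decision table over the wells of the landscape (count, signs,
#' degeneracy of energies), not over parameter thresholds, so it extends to
#' tilted (`h_ext != 0`) landscapes. At `h_ext = 0` the labels coincide with
#' the parameter bands: `T > T*` Zen, `T = T*` uncertainty with
#' pessimistic/optimistic bias, `T0 < T < T*` catastrophizing (or its
#' mirror, communicative), `T < T0` hypervigilance bias (or curiosity bias),
#' and for `h_int = 0` the second-order family Zen / uncertainty / baby.
#'
#' @param analysis A `"landscape_analysis"` object, or bare
#'   `"model_parameters"` (analyzed on the fly).
#' @param tol Degeneracy tolerance. Default `1e-6`.
#' @return A single regime label string, one of `"ZEN"`, `"UNCERTAINTY"`,
#'   `"BABY"`, `"UNCERTAINTY_PESSIMISTIC"`, `"UNCERTAINTY_OPTIMISTIC"`,
#'   `"CATASTROPHIZING"`, `"COMMUNICATIVE"`, `"HYPERVIGILANCE_BIAS"`,
#'   `"CURIOSITY_BIAS"`.
#' @export
classify_regime <- function(analysis, tol = 1e-6) {
  if (inherits(analysis, "model_parameters"))
    return(analyze_landscape(analysis, tol)$regime)
  stopifnot(inherits(analysis, "landscape_analysis"))
  w <- analysis$wells
  h_int <- analysis$params$h_int
  stopifnot(nrow(w) >= 1)          # b > 0 guarantees at least one well

  if (nrow(w) == 1) {
    phi <- w$phi[1]
    if (abs(phi) <= tol) {
      # flat quartic minimum at the exact critical context is the
      # uncertainty landscape; a strict minimum is Zen
      if (w$nature[1] == "inflection") return("UNCERTAINTY")
      return("ZEN")
    }
    # tilted monostable landscape: limit of the family whose dominant
    # state it is
    return(if (phi < 0) "CATASTROPHIZING" else "COMMUNICATIVE")
  }

  # two wells
  f1 <- w$F_value[1]; f2 <- w$F_value[2]
  phi1 <- w$phi[1]; phi2 <- w$phi[2]
  both_zero <- abs(f1) <= tol && abs(f2) <= tol
  if (both_zero) {
    if (abs(h_int) <= tol) return("UNCERTAINTY")
    nz <- if (abs(phi1) >= abs(phi2)) phi1 else phi2
    return(if (nz < 0) "UNCERTAINTY_PESSIMISTIC" else "UNCERTAINTY_OPTIMISTIC")
  }

  has_neutral <- abs(phi1) <= tol || abs(phi2) <= tol
  if (has_neutral) {
    other_i <- if (abs(phi1) <= tol) 2 else 1
    f_other <- w$F_value[other_i]; phi_other <- w$phi[other_i]
    if (f_other < -tol)
      return(if (phi_other < 0) "CATASTROPHIZING" else "COMMUNICATIVE")
    # metastable nonzero well above the neutral one: the neutral state is
    # the only likely perception
    return("ZEN")
  }

  if (phi1 < 0 && phi2 > 0) {
    dF <- abs(f2) - abs(f1)       # |F(te)| - |F(ap)|
    if (dF < -tol) return("HYPERVIGILANCE_BIAS")
    if (dF > tol) return("CURIOSITY_BIAS")
    dphi <- abs(phi2) - abs(phi1)
    if (abs(h_int) <= tol && abs(dphi) <= tol) return("BABY")
    if (dphi < -tol) return("UNCERTAINTY_PESSIMISTIC")
    if (dphi > tol) return("UNCERTAINTY_OPTIMISTIC")
    return("BABY")
  }
  # both wells on the same side of zero (strong tilt): dominant-state family
  g <- which.min(w$F_value)
  if (w$phi[g] < 0) "CATASTROPHIZING" else "COMMUNICATIVE"
}

#' Default-mode (saturated) perception states
#'
#' The perception minima of the landscape evaluated at complete absence of
#' sensory information (`T = 0`) and no expert tilt (`h_ext = 0`), holding
#' all other parameters. These are the saturated perceptions the mind falls
#' back to in complete default mode; they bound the hysteresis branches.
#'
#' @inheritParams validate_parameters
#' @return A named numeric vector `c(alert_protection = ..,
#'   trust_explore = ..)`; both `NA` (with a message) when `T0 <= 0`, in
#'   which case the `T = 0` landscape has no saturated double well.
#' @export
default_mode_states <- function(params) {
  validate_parameters(params)
  if (params$T0 <= 0) {
    message("T0 <= 0: the T = 0 landscape is not saturated; ",
            "no default-mode states exist.")
    return(c(alert_protection = NA_real_, trust_explore = NA_real_))
  }
  p0 <- modify_parameters(params, T = 0, h_ext = 0)
  w <- landscape_wells(stationary_points(p0), p0)
  c(alert_protection = min(w$phi), trust_explore = max(w$phi))
}

#' @export
print.landscape_analysis <- function(x, ...) {
  cat(sprintf("Sense-making landscape: regime %s\n", x$regime))
  cat(sprintf("  a = %g", effective_context_coefficient(x$params)))
  if (!is.na(x$T_star)) cat(sprintf(", T* = %g", x$T_star))
  cat("\nStationary points:\n")
  print.data.frame(x$points, row.names = FALSE, digits = 6)
  if (!is.na(x$delta_phi))
    cat(sprintf("  delta_phi = %.6g, delta_F = %.6g\n",
                x$delta_phi, x$delta_F))
  invisible(x)
}
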