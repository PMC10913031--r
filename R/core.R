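#' Sense-making free energy
#'
#' Evaluates \eqn{F(\phi) = -h_{ext}\phi + (a/2)\phi^2 + (h_{int}/3)\phi^3 +
#' (b/4)\phi^4} with \eqn{a = a_0 (T - T_0)}. `F` is minus the sense-making
#' `S`; minima of `F` are the most likely automatic perceptions. By
#' construction `F(0) = 0` for every parameter set, so depths of nonzero
#' states are always measured relative to the neutral perception.
#'
#' @param phi Perception value(s); vectorized.
#' @inheritParams validate_parameters
#' @return `F(phi)`, same length as `phi`.
#' @export
sense_making_energy <- function(phi, params) {
  a <- effective_context_coefficient(params)
  -params$h_ext * phi + a / 2 * phi^2 + params$h_int / 3 * phi^3 +
    params$b / 4 * phi^4
}

#' Gradient of the sense-making energy
#'
#' \eqn{dF/d\phi = -h_{ext} + a\phi + h_{int}\phi^2 + b\phi^3}. Its real
#' roots are the stationary perceptions; setting it to zero gives the
#' stationary condition \eqn{h_{ext} = a\phi + h_{int}\phi^2 + b\phi^3} from
#' which hysteresis branches are traced.
#'
#' @inheritParams sense_making_energy
#' @return `dF/dphi`, same length as `phi`.
#' @export
sense_making_gradient <- function(phi, params) {
  a <- effective_context_coefficient(params)
  -params$h_ext + a * phi + params$h_int * phi^2 + params$b * phi^3
}

#' Curvature of the sense-making energy
#'
#' \eqn{d^2F/d\phi^2 = a + 2h_{int}\phi + 3b\phi^2}; its sign classifies
#' stationary points as minima (stable perceptions) or maxima (watersheds
#' between basins).
#'
#' @inheritParams sense_making_energy
#' @return `d2F/dphi2`, same length as `phi`.
#' @export
sense_making_curvature <- function(phi, params) {
  a <- effective_context_coefficient(params)
  a + 2 * params$h_int * phi + 3 * params$b * phi^2
}

# Real roots of the monic cubic x^3 + c2 x^2 + c1 x + c0 = 0.
# Analytic depressed-cubic solution: trigonometric branch for three real
# roots, Cardano for one; near-zero discriminant handled by the exact
# double-root formulas so spinodal/critical degeneracies are not lost.
cubic_real_roots <- function(c2, c1, c0) {
  p <- c1 - c2^2 / 3
  q <- 2 * c2^3 / 27 - c2 * c1 / 3 + c0
  shift <- -c2 / 3
  disc <- -4 * p^3 - 27 * q^2
  # double-root detection must be relative to the root scale R^6, with
  # R ~ max(sqrt|p|, |q|^(1/3)): disc ~ 4|p|^3 is tiny for three distinct
  # small symmetric roots, which are not degenerate
  disc_scale <- max(abs(p)^3, q^2, 1e-300)
  if (p == 0 && q == 0) {
    t <- 0                                         # triple root
  } else if (abs(disc) <= 1e-12 * disc_scale) {
    if (abs(p) < 1e-150) {
      t <- -sign(q) * abs(q)^(1 / 3)
    } else {
      t <- c(3 * q / p, -3 * q / (2 * p))          # simple + double root
    }
  } else if (disc > 0) {
    m <- 2 * sqrt(-p / 3)                          # p < 0 guaranteed here
    arg <- 3 * q / (p * m)
    theta <- acos(pmin(1, pmax(-1, arg))) / 3
    t <- m * cos(theta - 2 * pi * (0:2) / 3)
  } else {
    s <- sqrt(q^2 / 4 + p^3 / 27)
    u <- -q / 2 + s
    v <- -q / 2 - s
    cbrt <- function(x) sign(x) * abs(x)^(1 / 3)
    t <- cbrt(u) + cbrt(v)
  }
  sort(unique(t + shift))
}

#' Stationary points of the sense-making landscape
#'
#' Finds all real roots of the gradient cubic analytically (depressed-cubic
#' trigonometric/Cardano solution) and polishes each with guarded Newton
#' steps to gradient tolerance `1e-10`. Roots closer than
#' `tol * (1 + |phi|)` are merged and reported once; each point carries its
#' energy, curvature and nature.
#'
#' @inheritParams validate_parameters
#' @param tol Merge tolerance for (near-)double roots. Default `1e-6`.
#' @param eps_curv Curvature dead-band for the nature label: curvature above
#'   `+eps_curv` is a `"minimum"`, below `-eps_curv` a `"maximum"`, and
#'   in between an `"inflection"` (degenerate point). Default `1e-9`.
#' @return A `data.frame` of class `"stationary_points"`, sorted by
#'   ascending `phi`, with columns `phi`, `F_value`, `curvature`, `nature`.
#'   A cubic gradient with `b > 0` always yields 1 to 3 points.
#' @examples
#' p <- model_parameters(h_int = 3, a0 = 1, b = 1, T = 7, T0 = 5)
#' stationary_points(p)   # phi = -2, -1, 0
#' @export
stationary_points <- function(params, tol = 1e-6, eps_curv = 1e-9) {
  validate_parameters(params)
  stopifnot(tol > 0)
  a <- effective_context_coefficient(params)
  b <- params$b
  roots <- cubic_real_roots(params$h_int / b, a / b, -params$h_ext / b)

  # Newton polish (guarded: keep the better iterate, few steps suffice)
  for (k in seq_len(4)) {
    g <- sense_making_gradient(roots, params)
    c2 <- sense_making_curvature(roots, params)
    step <- ifelse(abs(c2) > 1e-300, g / c2, 0)
    cand <- roots - step
    better <- abs(sense_making_gradient(cand, params)) < abs(g)
    roots <- ifelse(better, cand, roots)
    if (all(abs(sense_making_gradient(roots, params)) <= 1e-12)) break
  }
  roots <- sort(roots)

  # merge near-double roots
  keep <- roots[1]
  for (r in roots[-1]) {
    if (r - keep[length(keep)] > tol * (1 + abs(r))) keep <- c(keep, r)
  }

  curv <- sense_making_curvature(keep, params)
  nature <- ifelse(curv > eps_curv, "minimum",
                   ifelse(curv < -eps_curv, "maximum", "inflection"))
  out <- data.frame(phi = keep,
                    F_value = sense_making_energy(keep, params),
                    curvature = curv,
                    nature = nature,
                    stringsAsFactors = FALSE)
  class(out) <- c("stationary_points", "data.frame")
  out
}

# Wells of the landscape: stationary points that are local minima of F,
# including quartic-degenerate points whose curvature vanishes (e.g. the
# origin exactly at the second-order critical context). Excludes degenerate
# shoulders (double roots at spinodals), which are not basins.
landscape_wells <- function(pts, params, delta = NULL) {
  is_well <- pts$nature == "minimum"
  infl <- which(pts$nature == "inflection")
  if (length(infl)) {
    span <- max(1, diff(range(pts$phi)))
    if (is.null(delta)) delta <- 1e-3 * span
    for (i in infl) {
      f0 <- pts$F_value[i]
      is_well[i] <- sense_making_energy(pts$phi[i] - delta, params) > f0 &&
        sense_making_energy(pts$phi[i] + delta, params) > f0
    }
  }
  pts[is_well, , drop = FALSE]
}
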