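#' Spinodal fields of the tilted landscape
#'
#' Fields of expert information at which a metastable basin annihilates.
#' At a spinodal both the gradient and the curvature vanish: the curvature
#' quadratic \eqn{a + 2h_{int}\phi + 3b\phi^2 = 0} gives the two candidate
#' perceptions \eqn{\phi = (-h_{int} \pm \sqrt{h_{int}^2 - 3ab})/(3b)}, and
#' the stationary condition \eqn{h = a\phi + h_{int}\phi^2 + b\phi^3}
#' evaluated there gives the transition fields. The pair exists iff
#' \eqn{h_{int}^2 > 3ab}. `h_down` (at the larger-`phi` zero) is where the
#' trust-explore/upper basin annihilates on a downward field sweep; `h_up`
#' (at the smaller-`phi` zero) is where the alert-protection/lower basin
#' annihilates on an upward sweep. Always `h_down < h_up`.
#'
#' @inheritParams validate_parameters
#' @return An object of class `"spinodal_pair"` (list with `h_down`, `h_up`,
#'   `phi_down`, `phi_up`), or `NULL` when no bistable interval exists.
#' @examples
#' spinodal_fields(model_parameters(h_int = 3, T = 6, T0 = 5))
#' @export
spinodal_fields <- function(params) {
  validate_parameters(params)
  a <- effective_context_coefficient(params)
  h <- params$h_int; b <- params$b
  disc <- h^2 - 3 * a * b
  if (disc <= 0) return(NULL)
  s <- sqrt(disc)
  phi_small <- (-h - s) / (3 * b)
  phi_large <- (-h + s) / (3 * b)
  field_at <- function(phi) a * phi + h * phi^2 + b * phi^3
  structure(list(h_down = field_at(phi_large), h_up = field_at(phi_small),
                 phi_down = phi_large, phi_up = phi_small),
            class = "spinodal_pair")
}

#' @export
print.spinodal_pair <- function(x, ...) {
  cat(sprintf("Spinodal fields: h_down = %.6g (phi = %.6g), h_up = %.6g (phi = %.6g)\n",
              x$h_down, x$phi_down, x$h_up, x$phi_up))
  invisible(x)
}

# Wells of the landscape with h_ext overridden to h.
wells_at_field <- function(params, h) {
  p <- modify_parameters(params, h_ext = h)
  landscape_wells(stationary_points(p), p)
}

# Wells reachable from phi without crossing a maximum of the landscape
# (exact watershed criterion on a 1-D landscape).
basin_candidates <- function(pts, params, phi) {
  wells <- landscape_wells(pts, params)
  if (!nrow(wells)) return(wells)
  maxima <- pts$phi[pts$nature == "maximum"]
  reach <- vapply(wells$phi, function(w) {
    lo <- min(phi, w); hi <- max(phi, w)
    !any(maxima > lo & maxima < hi)
  }, logical(1))
  wells[reach, , drop = FALSE]
}

# Quasi-static continuation of the occupied state. The move from phi_prev
# to the new well is a jump (basin annihilation) when the path crosses the
# negative-curvature band of the new landscape: the occupied well can drift
# continuously only inside a convex region.
continue_state <- function(pts, params, phi_prev) {
  # a degenerate shoulder (double root, exactly at a spinodal) is the last
  # position of an annihilating well and is occupiable in passing
  wells <- landscape_wells(pts, params)
  shoulders <- pts[pts$nature == "inflection" &
                     !(pts$phi %in% wells$phi), , drop = FALSE]
  cand <- rbind(basin_candidates(pts, params, phi_prev), shoulders)
  if (nrow(cand)) {
    w <- cand[which.min(abs(cand$phi - phi_prev)), , drop = FALSE]
  } else {
    w <- wells[which.min(wells$F_value), , drop = FALSE]
  }
  a <- effective_context_coefficient(params)
  disc <- params$h_int^2 - 3 * a * params$b
  jump <- FALSE
  if (disc > 0) {
    z <- sort(c((-params$h_int - sqrt(disc)) / (3 * params$b),
                (-params$h_int + sqrt(disc)) / (3 * params$b)))
    lo <- min(phi_prev, w$phi); hi <- max(phi_prev, w$phi)
    overlap <- min(hi, z[2]) - max(lo, z[1])
    jump <- overlap > 1e-10 * max(1, abs(lo), abs(hi))
  }
  list(well = w, jump = jump)
}

#' Quasi-static sweep of one hysteresis branch
#'
#' Tracks the occupied perception minimum along an ordered grid of expert
#' fields `h_ext` in the zero-fluctuation quasi-static limit: at each field
#' the occupied state is the well continuously connected to the previous one
#' (no intervening maximum); when that basin annihilates the state jumps to
#' the global minimum of the new landscape and the jump position is
#' recorded.
#'
#' @inheritParams validate_parameters
#' @param h_grid Ordered (increasing or decreasing) vector of `h_ext`
#'   values; `params$h_ext` is overridden along the sweep.
#' @param initial_phi Starting perception; must lie in a basin of the
#'   landscape at `h_grid[1]` (i.e. not exactly on a watershed maximum).
#' @return An object of class `"hysteresis_branch"`: list with `direction`
#'   (`"up"` or `"down"`), `h_values`, `phi_values`, `jump_index` (or
#'   `NULL`).
#' @export
sweep_branch <- function(params, h_grid, initial_phi) {
  validate_parameters(params)
  if (!length(h_grid)) stop("empty h grid")
  direction <- if (length(h_grid) == 1 || h_grid[length(h_grid)] >= h_grid[1])
    "up" else "down"

  p1 <- modify_parameters(params, h_ext = h_grid[1])
  pts1 <- stationary_points(p1)
  maxima <- pts1$phi[pts1$nature == "maximum"]
  if (length(maxima) && min(abs(maxima - initial_phi)) < 1e-9)
    stop("initial_phi = ", initial_phi,
         " lies on a watershed (in no basin) at h = ", h_grid[1])
  cand <- basin_candidates(pts1, p1, initial_phi)
  if (!nrow(cand))
    stop("initial_phi = ", initial_phi,
         " lies in no basin of the landscape at h = ", h_grid[1])
  phi <- cand$phi[which.min(abs(cand$phi - initial_phi))]

  phis <- numeric(length(h_grid))
  phis[1] <- phi
  jump_index <- NULL
  for (i in seq_along(h_grid)[-1]) {
    p <- modify_parameters(params, h_ext = h_grid[i])
    st <- continue_state(stationary_points(p), p, phis[i - 1])
    phis[i] <- st$well$phi
    if (st$jump && is.null(jump_index)) jump_index <- i
  }
  structure(list(direction = direction, h_values = h_grid,
                 phi_values = phis, jump_index = jump_index),
            class = "hysteresis_branch")
}

#' Hysteresis (biopsychosocial) loop of perception vs expert information
#'
#' Sweeps the expert field `h_ext` quasi-statically upward from `h_min`
#' (starting in the lowest basin) and downward from `h_max` (starting in the
#' highest basin). When learned historical information makes the landscape
#' bistable the two branches differ between the spinodal fields and enclose
#' a loop; its area is computed by trapezoidal integration of the branch
#' difference over the common grid, with jumps contributing vertical
#' segments. The loop is the model's operationalization of a
#' biopsychosocial loop: perception (psycho) of a symptom (bio) driven by
#' expert information (social).
#'
#' @inheritParams validate_parameters
#' @param h_min,h_max Field range of the sweep; should bracket the spinodal
#'   fields when they exist (a warning is issued otherwise).
#' @param n_points Number of grid points (>= 50). Default 400.
#' @param dm_tol Tolerance for flagging branch values that reach the
#'   default-mode (saturated) perceptions. Default `1e-3`.
#' @return An object of class `"hysteresis_loop"`: list with `up_branch`,
#'   `down_branch`, `spinodals` (`NULL` if none), `area` (non-negative),
#'   `bistable` (flag), `dm_plateaus` (named pair, `NA` where no branch
#'   value reaches the corresponding saturated perception), `params`.
#' @examples
#' loop <- hysteresis_loop(model_parameters(h_int = 3, T = 6, T0 = 5),
#'                         h_min = -0.5, h_max = 2.5, n_points = 200)
#' loop$area
#' @export
hysteresis_loop <- function(params, h_min, h_max, n_points = 400,
                            dm_tol = 1e-3) {
  validate_parameters(params)
  stopifnot(h_min < h_max, n_points >= 50)
  sp <- spinodal_fields(params)
  if (!is.null(sp) && (h_min > sp$h_down || h_max < sp$h_up))
    warning(sprintf(
      "sweep range [%g, %g] does not bracket the spinodal fields [%g, %g]; the loop will be truncated",
      h_min, h_max, sp$h_down, sp$h_up))

  grid <- seq(h_min, h_max, length.out = n_points)
  if (!is.null(sp)) {
    # pin the jump verticals to the exact spinodal fields so the enclosed
    # area is stable under grid refinement
    extra <- c(sp$h_down - 1e-9, sp$h_down, sp$h_up, sp$h_up + 1e-9)
    grid <- sort(unique(c(grid, extra[extra > h_min & extra < h_max])))
  }
  w_lo <- wells_at_field(params, h_min)
  w_hi <- wells_at_field(params, h_max)
  up <- sweep_branch(params, grid, initial_phi = min(w_lo$phi))
  down <- sweep_branch(params, rev(grid), initial_phi = max(w_hi$phi))

  gap <- rev(down$phi_values) - up$phi_values
  if (max(abs(gap)) < 1e-8) {
    area <- 0; bistable <- FALSE
  } else {
    dh <- diff(grid)
    area <- sum(dh * (gap[-1] + gap[-length(gap)]) / 2)
    bistable <- TRUE
  }

  dm <- suppressMessages(default_mode_states(params))
  plateau <- function(target) {
    if (is.na(target)) return(NA_real_)
    vals <- c(up$phi_values, down$phi_values)
    hit <- vals[abs(vals - target) <= dm_tol]
    if (length(hit)) hit[1] else NA_real_
  }
  structure(list(up_branch = up, down_branch = down, spinodals = sp,
                 area = area, bistable = bistable,
                 dm_plateaus = c(alert_protection = plateau(dm[["alert_protection"]]),
                                 trust_explore = plateau(dm[["trust_explore"]])),
                 params = params),
            class = "hysteresis_loop")
}

#' Unstable (excluded) branch of the stationary condition
#'
#' For each field in the bistable interval, the middle root of the
#' stationary condition — the maximum separating the two basins. It has
#' negative slope `dphi/dh` and never belongs to the quasi-static loop; it
#' is provided for plotting (drawn dashed in [render_hysteresis_figure()]).
#'
#' @inheritParams validate_parameters
#' @param h_grid Fields at which to evaluate; values outside the bistable
#'   interval are dropped.
#' @return A `data.frame` with columns `h` and `phi`; empty when no
#'   bistable interval exists.
#' @export
unstable_branch <- function(params, h_grid) {
  validate_parameters(params)
  sp <- spinodal_fields(params)
  if (is.null(sp))
    return(data.frame(h = numeric(0), phi = numeric(0)))
  hs <- h_grid[h_grid >= sp$h_down & h_grid <= sp$h_up]
  phi <- vapply(hs, function(h) {
    p <- modify_parameters(params, h_ext = h)
    pts <- stationary_points(p)
    m <- pts$phi[pts$nature == "maximum"]
    if (length(m)) m[1] else NA_real_
  }, numeric(1))
  out <- data.frame(h = hs, phi = phi)
  out[!is.na(out$phi), , drop = FALSE]
}

#' @export
print.hysteresis_loop <- function(x, ...) {
  cat("Hysteresis loop of perception vs expert information\n")
  if (!is.null(x$spinodals))
    cat(sprintf("  h_down = %.6g, h_up = %.6g\n",
                x$spinodals$h_down, x$spinodals$h_up))
  cat(sprintf("  bistable: %s, loop area = %.6g\n", x$bistable, x$area))
  invisible(x)
}
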