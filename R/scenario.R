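#' Occupancy probabilities over landscape wells
#'
#' Gibbs weighting of the likely perceptions: each well `i` receives
#' probability proportional to `exp(-F_i / tau)`. The fluctuation scale
#' `tau` is a toolkit choice (the underlying model only orders states:
#' deeper sense-making minima are more likely); as `tau -> 0` the weight
#' concentrates on the global minimum, and degenerate wells split the
#' probability evenly. `tau` is echoed in the result so downstream output
#' never presents the weighting as model-prescribed.
#'
#' @param analysis A `"landscape_analysis"` object.
#' @param tau Positive fluctuation scale. Default 0.05.
#' @return Named numeric vector of probabilities (names are the state
#'   roles), summing to 1, with attribute `"tau"`.
#' @export
occupancy_probabilities <- function(analysis, tau = 0.05) {
  stopifnot(inherits(analysis, "landscape_analysis"), tau > 0)
  states <- list(alert_protection = analysis$alert_protection,
                 neutral = analysis$neutral,
                 trust_explore = analysis$trust_explore)
  states <- states[!vapply(states, is.null, logical(1))]
  if (!length(states)) stop("internal error: landscape has no wells")
  f <- vapply(states, function(s) s$F_value, numeric(1))
  w <- exp(-(f - min(f)) / tau)
  p <- w / sum(w)
  attr(p, "tau") <- tau
  p
}

#' Automatic attention placement
#'
#' Automatic (non-conscious) attention sits in the most likely perception:
#' the global minimum of the sense-making landscape. At a degeneracy within
#' `tol` the tie is broken by policy: `"trust_explore"` (default, matching
#' the convention of placing attention on the liveliness state),
#' `"alert_protection"`, or `"keep_previous"` (nearest to a previously
#' occupied perception, used inside scenarios to preserve hysteresis).
#'
#' @param analysis A `"landscape_analysis"` object.
#' @param tie_break Tie policy; see Details.
#' @param previous Previously occupied perception value, required for
#'   `tie_break = "keep_previous"`.
#' @param tol Degeneracy tolerance on energies. Default `1e-6`.
#' @return A one-row `data.frame` (a stationary point).
#' @export
automatic_attention <- function(analysis,
                                tie_break = c("trust_explore",
                                              "alert_protection",
                                              "keep_previous"),
                                previous = NULL, tol = 1e-6) {
  stopifnot(inherits(analysis, "landscape_analysis"))
  tie_break <- match.arg(tie_break)
  w <- analysis$wells
  fmin <- min(w$F_value)
  tied <- w[w$F_value <= fmin + tol, , drop = FALSE]
  if (nrow(tied) == 1) return(tied)
  sel <- switch(tie_break,
    trust_explore = which.max(tied$phi),
    alert_protection = which.min(tied$phi),
    keep_previous = {
      if (is.null(previous))
        stop("tie_break = 'keep_previous' requires a previous perception")
      which.min(abs(tied$phi - previous))
    })
  tied[sel, , drop = FALSE]
}

#' Conscious attention placement
#'
#' Conscious attention can be placed at any extremum of the landscape,
#' regardless of depth: one of the wells (by role) or the watershed
#' maximum.
#'
#' @param analysis A `"landscape_analysis"` object.
#' @param target One of `"alert_protection"`, `"neutral"`,
#'   `"trust_explore"`, `"maximum"`.
#' @return A one-row `data.frame` (a stationary point). Errors, naming the
#'   available states, when the requested extremum does not exist.
#' @export
conscious_attention <- function(analysis, target) {
  stopifnot(inherits(analysis, "landscape_analysis"))
  avail <- list(alert_protection = analysis$alert_protection,
                neutral = analysis$neutral,
                trust_explore = analysis$trust_explore)
  mx <- analysis$points[analysis$points$nature == "maximum", , drop = FALSE]
  if (nrow(mx)) avail$maximum <- mx[1, , drop = FALSE]
  avail <- avail[!vapply(avail, is.null, logical(1))]
  if (!target %in% names(avail))
    stop("state '", target, "' does not exist in this landscape; available: ",
         paste(names(avail), collapse = ", "))
  avail[[target]]
}

#' Define one scenario step
#'
#' A step changes control parameters either additively (`delta_*`) or by
#' absolute override; learning and unlearning in the model are exactly such
#' parameter changes. At least one change is required and the resulting
#' `T` must stay non-negative (validated when the scenario runs).
#'
#' @param label Free-text description (e.g. "nocebo message",
#'   "NBE session").
#' @param delta_h_ext,delta_h_int,delta_T Additive changes.
#' @param h_ext,h_int,T,T0,a0,b Absolute overrides (applied after deltas).
#' @return An object of class `"scenario_step"`.
#' @export
scenario_step <- function(label, delta_h_ext = 0, delta_h_int = 0,
                          delta_T = 0, h_ext = NULL, h_int = NULL, T = NULL,
                          T0 = NULL, a0 = NULL, b = NULL) {
  deltas <- c(delta_h_ext = delta_h_ext, delta_h_int = delta_h_int,
              delta_T = delta_T)
  overrides <- list(h_ext = h_ext, h_int = h_int, T = T, T0 = T0,
                    a0 = a0, b = b)
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  if (all(deltas == 0) && !length(overrides))
    stop("a scenario step must change at least one parameter")
  structure(list(label = as.character(label), deltas = deltas,
                 overrides = overrides), class = "scenario_step")
}

apply_step <- function(params, step) {
  params$h_ext <- params$h_ext + step$deltas[["delta_h_ext"]]
  params$h_int <- params$h_int + step$deltas[["delta_h_int"]]
  params$T <- params$T + step$deltas[["delta_T"]]
  for (nm in names(step$overrides))
    params[[nm]] <- as.numeric(step$overrides[[nm]])
  validate_parameters(params)
  params
}

#' Run a learning/unlearning scenario
#'
#' Applies an ordered sequence of parameter-change steps, re-analyzing the
#' landscape after each and carrying the occupied perception forward by
#' basin continuity — the same zero-fluctuation policy as
#' [sweep_branch()]. The occupied state changes between steps only when its
#' basin has been annihilated (a jump, flagged per step). This is what
#' makes scenarios hysteretic: a parameter cycle that crosses a spinodal
#' does not restore the original perception.
#'
#' @inheritParams validate_parameters
#' @param initial Starting `"model_parameters"`.
#' @param steps List of [scenario_step()] objects.
#' @param tie_break Tie policy for the initial automatic attention
#'   placement (see [automatic_attention()]).
#' @param initial_state Optional role (`"alert_protection"`, `"neutral"`,
#'   `"trust_explore"`) to start from instead of automatic attention.
#' @param tau Fluctuation scale reported with per-step occupancies.
#' @param tol Degeneracy tolerance.
#' @return An object of class `"trajectory"`: list with `records` (one
#'   entry per state, including the initial one: `params`, `analysis`,
#'   `occupied` stationary point, `occupancy`, `jump` flag, `label`) and a
#'   `summary` data.frame (one row per record: label, parameters, regime,
#'   occupied phi and F, role, jump).
#' @export
run_scenario <- function(initial, steps = list(),
                         tie_break = "trust_explore",
                         initial_state = NULL, tau = 0.05, tol = 1e-6) {
  validate_parameters(initial)
  if (inherits(steps, "scenario_step")) steps <- list(steps)
  an <- analyze_landscape(initial, tol)
  occ <- if (is.null(initial_state)) automatic_attention(an, tie_break, tol = tol)
         else conscious_attention(an, initial_state)

  records <- list(list(label = "initial", params = initial, analysis = an,
                       occupied = occ,
                       occupancy = occupancy_probabilities(an, tau),
                       jump = FALSE))
  params <- initial
  for (k in seq_along(steps)) {
    step <- steps[[k]]
    stopifnot(inherits(step, "scenario_step"))
    params <- tryCatch(apply_step(params, step), error = function(e)
      stop("invalid parameters at step ", k, " ('", step$label, "'): ",
           conditionMessage(e)))
    an <- analyze_landscape(params, tol)
    st <- continue_state(an$points, params, occ$phi)
    occ <- st$well
    jump <- st$jump
    records[[k + 1]] <- list(label = step$label, params = params,
                             analysis = an, occupied = occ,
                             occupancy = occupancy_probabilities(an, tau),
                             jump = jump)
  }

  role_of <- function(phi) {
    if (abs(phi) <= tol) "neutral" else if (phi < 0) "alert_protection"
    else "trust_explore"
  }
  summary <- do.call(rbind, lapply(records, function(r) {
    data.frame(label = r$label, h_ext = r$params$h_ext,
               h_int = r$params$h_int, a0 = r$params$a0, b = r$params$b,
               T = r$params$T, T0 = r$params$T0,
               regime = r$analysis$regime, phi = r$occupied$phi,
               F_value = r$occupied$F_value, role = role_of(r$occupied$phi),
               jump = r$jump, stringsAsFactors = FALSE)
  }))
  structure(list(records = records, summary = summary, tau = tau, tol = tol),
            class = "trajectory")
}

#' Detect a hysteretic (biopsychosocial) cycle in a trajectory
#'
#' Searches for the operational signature of a biopsychosocial loop: the
#' control parameters return (within `eps`) to an earlier record while the
#' occupied perception plays a different role. When found, the enclosing
#' `(h_ext, phi)` cycle — the sub-path from the earliest to the latest such
#' revisit (the whole path when the trajectory is closed) — is reported
#' together with its signed shoelace area.
#'
#' @param trajectory A `"trajectory"` with at least 3 records.
#' @param eps Parameter-matching tolerance. Default `1e-8`.
#' @return A list: `found` flag, `pairs` (two-column matrix of matching
#'   record indices), `cycle` (data.frame `h_ext`, `phi` of the enclosing
#'   sub-path), `signed_area`.
#' @export
detect_hysteretic_cycle <- function(trajectory, eps = 1e-8) {
  stopifnot(inherits(trajectory, "trajectory"))
  s <- trajectory$summary
  n <- nrow(s)
  if (n < 3) stop("trajectory needs at least 3 records")
  par_mat <- as.matrix(s[, c("h_ext", "h_int", "a0", "b", "T", "T0")])
  pairs <- NULL
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (max(abs(par_mat[i, ] - par_mat[j, ])) <= eps &&
        s$role[i] != s$role[j])
      pairs <- rbind(pairs, c(i, j))
  }
  if (is.null(pairs))
    return(list(found = FALSE, pairs = NULL, cycle = NULL, signed_area = 0))
  lo <- min(pairs[, 1]); hi <- max(pairs[, 2])
  # a closed parameter path encloses the full loop
  if (max(abs(par_mat[1, ] - par_mat[n, ])) <= eps) { lo <- 1; hi <- n }
  x <- s$h_ext[lo:hi]; y <- s$phi[lo:hi]
  m <- length(x)
  nxt <- c(2:m, 1)
  signed_area <- sum(x * y[nxt] - x[nxt] * y) / 2
  list(found = TRUE, pairs = pairs,
       cycle = data.frame(h_ext = x, phi = y), signed_area = signed_area)
}

#' Sample random parameter sets
#'
#' Deterministic (seeded) uniform sampler over per-parameter intervals,
#' used for property testing. Defaults: `a0, b` in `[0.2, 5]`,
#' `h_int, h_ext` in `[-5, 5]`, `T0` in `[0.5, 10]`, `T` in `[0, 12]`.
#'
#' @param seed Integer seed.
#' @param n Number of parameter sets.
#' @param ranges Named list of length-2 intervals overriding the defaults.
#' @return A list of `n` `"model_parameters"` objects.
#' @export
sample_random_parameters <- function(seed, n, ranges = list()) {
  defaults <- list(h_ext = c(-5, 5), h_int = c(-5, 5), a0 = c(0.2, 5),
                   b = c(0.2, 5), T = c(0, 12), T0 = c(0.5, 10))
  unknown <- setdiff(names(ranges), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s) in ranges: ", paste(unknown, collapse = ", "))
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (!is.numeric(r) || length(r) != 2 || r[1] > r[2])
      stop("invalid range for ", nm)
    defaults[[nm]] <- r
  }
  if (defaults$a0[1] <= 0 || defaults$b[1] <= 0 || defaults$T[1] < 0)
    stop("ranges must keep a0 > 0, b > 0 and T >= 0")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    draw <- function(nm) stats::runif(1, defaults[[nm]][1], defaults[[nm]][2])
    model_parameters(h_ext = draw("h_ext"), h_int = draw("h_int"),
                     a0 = draw("a0"), b = draw("b"), T = draw("T"),
                     T0 = draw("T0"))
  })
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Scenario trajectory: %d records (tau = %g)\n",
              nrow(x$summary), x$tau))
  print.data.frame(x$summary, row.names = FALSE, digits = 5)
  invisible(x)
}
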