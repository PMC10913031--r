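# Serialization: CSV / JSON / YAML, 12 significant digits, deterministic
# column and key order.

sig12 <- function(x) {
  if (is.numeric(x)) signif(x, 12) else
  if (is.list(x)) lapply(x, sig12) else x
}

fmt12 <- function(x) trimws(formatC(x, digits = 12, format = "g"))

write_csv12 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt12)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

config_schema <- list(
  parameters = c("h_ext", "h_int", "a0", "b", "T", "T0"),
  options = c("tol", "tau", "tie_break", "seed"),
  output = c("path", "format"),
  plots = c("landscape", "hysteresis"),
  scenario = c("initial_state", "steps"))

#' Load a run configuration
#'
#' Reads a YAML (or JSON, which YAML subsumes) configuration with the
#' sections `parameters` (the six control parameters), `options`
#' (`tol`, `tau`, `tie_break`, `seed`), `output` (`path`, `format`),
#' `plots` and `scenario` (`initial_state`, `steps` — a list of
#' [scenario_step()] records with `label` plus deltas/overrides). Unknown
#' keys are rejected with an error naming the key; configurations
#' round-trip losslessly through [save_config()].
#'
#' @param path File to read.
#' @return An object of class `"run_config"` (named list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (sec in names(cfg)) {
    if (sec == "scenario") {
      bad <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
      if (length(bad))
        stop("unknown configuration key(s) in scenario: ",
             paste(bad, collapse = ", "))
      step_keys <- c("label", "delta_h_ext", "delta_h_int", "delta_T",
                     "h_ext", "h_int", "T", "T0", "a0", "b")
      for (st in cfg$scenario$steps) {
        bad <- setdiff(names(st), step_keys)
        if (length(bad))
          stop("unknown configuration key(s) in scenario step: ",
               paste(bad, collapse = ", "))
      }
    } else {
      bad <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
      if (length(bad))
        stop("unknown configuration key(s) in ", sec, ": ",
             paste(bad, collapse = ", "))
    }
  }
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#'
#' @param config A `"run_config"` (or compatible named list).
#' @param path Destination file (YAML).
#' @return `path`, invisibly.
#' @rdname load_config
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_parameters <- function(config) {
  do.call(model_parameters, config$parameters)
}

config_steps <- function(config) {
  lapply(config$scenario$steps, function(st) do.call(scenario_step, st))
}

#' Export a landscape analysis
#'
#' CSV format writes one row per stationary point (`phi`, `F_value`,
#' `curvature`, `nature`, `role`); JSON writes the full record (parameters,
#' points, regime, biases, critical context). Numbers carry 12 significant
#' digits; column and key order is deterministic.
#'
#' @param analysis A `"landscape_analysis"`.
#' @param path Destination file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_landscape <- function(analysis, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(analysis, "landscape_analysis"))
  role_of <- function(phi, nature) {
    if (nature != "minimum" && nature != "inflection") return("maximum")
    if (abs(phi) <= analysis$tol) "neutral" else
      if (phi < 0) "alert_protection" else "trust_explore"
  }
  pts <- analysis$points
  pts$role <- mapply(role_of, pts$phi, pts$nature)
  if (format == "csv") {
    write_csv12(pts[, c("phi", "F_value", "curvature", "nature", "role")],
                path)
  } else {
    rec <- list(parameters = sig12(unclass(analysis$params)),
                regime = analysis$regime,
                points = sig12(as.list(pts[, c("phi", "F_value", "curvature",
                                               "nature", "role")])),
                delta_phi = sig12(analysis$delta_phi),
                delta_F = sig12(analysis$delta_F),
                hypervigilance_value = sig12(analysis$hypervigilance_value),
                curiosity_value = sig12(analysis$curiosity_value),
                T_star = sig12(analysis$T_star),
                tol = analysis$tol)
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Export a hysteresis loop
#'
#' CSV format stacks both branches with columns `direction`, `h_ext`,
#' `phi`; JSON writes the summary (`h_down`, `h_up`, `area`, `bistable`)
#' plus both branches. [import_loop()] reads the JSON back.
#'
#' @param loop A `"hysteresis_loop"`.
#' @param path Destination file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_loop <- function(loop, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(loop, "hysteresis_loop"))
  branches <- rbind(
    data.frame(direction = "up", h_ext = loop$up_branch$h_values,
               phi = loop$up_branch$phi_values),
    data.frame(direction = "down", h_ext = loop$down_branch$h_values,
               phi = loop$down_branch$phi_values))
  if (format == "csv") {
    write_csv12(branches, path)
  } else {
    rec <- list(h_down = sig12(loop$spinodals$h_down),
                h_up = sig12(loop$spinodals$h_up),
                area = sig12(loop$area), bistable = loop$bistable,
                dm_plateaus = sig12(as.list(loop$dm_plateaus)),
                parameters = sig12(unclass(loop$params)),
                branches = sig12(as.list(branches)))
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Re-import an exported hysteresis-loop summary
#'
#' @param path A JSON file written by [export_loop()].
#' @return Named list with `h_down`, `h_up`, `area`, `bistable`,
#'   `branches`.
#' @export
import_loop <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Export a scenario trajectory
#'
#' CSV format writes one row per record (label, parameters, regime,
#' occupied `phi`, occupancy, jump flag); JSON adds per-record stationary
#' points.
#'
#' @param trajectory A `"trajectory"`.
#' @param path Destination file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(trajectory, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(trajectory, "trajectory"))
  s <- trajectory$summary
  occ <- vapply(trajectory$records, function(r) {
    paste(sprintf("%s=%.6f", names(r$occupancy), r$occupancy),
          collapse = ";")
  }, character(1))
  s$occupancy <- occ
  if (format == "csv") {
    write_csv12(s, path)
  } else {
    recs <- lapply(trajectory$records, function(r) {
      list(label = r$label, parameters = sig12(unclass(r$params)),
           regime = r$analysis$regime,
           occupied = sig12(as.list(r$occupied)),
           occupancy = sig12(as.list(as.numeric(r$occupancy)) |>
                               stats::setNames(names(r$occupancy))),
           jump = r$jump)
    })
    jsonlite::write_json(list(tau = trajectory$tau, records = recs), path,
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  invisible(path)
}
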