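config_sections <- c("body", "passive", "muscle", "activation", "fluid",
                     "solver")

config_builders <- function() {
  list(body = body_plan, passive = passive_properties,
       muscle = muscle_params, activation = activation_wave,
       fluid = fluid_params)
}

#' Read a simulation configuration from a YAML file
#'
#' The file holds named sections `body`, `passive`, `muscle`, `activation`,
#' `fluid` and `solver`, each a mapping of parameter names to values;
#' every key must match a documented parameter of the corresponding
#' constructor (unknown keys are an error, so typos never pass silently),
#' and all constructor validation (units, ranges, e.g. `duty < 0.5`)
#' applies.  Missing sections and keys take the calibrated package
#' defaults; an empty file yields the full default configuration.
#'
#' @param path Path to the YAML file.
#' @return A [simulation_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must hold a YAML mapping",
                          call. = FALSE)
  unknown <- setdiff(names(raw), config_sections)
  if (length(unknown) > 0) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  builders <- config_builders()
  parts <- lapply(names(builders), function(sec) {
    args <- raw[[sec]]
    if (is.null(args)) args <- list()
    allowed <- names(formals(builders[[sec]]))
    bad <- setdiff(names(args), allowed)
    if (length(bad) > 0) {
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    do.call(builders[[sec]], args)
  })
  names(parts) <- names(builders)
  solver <- raw$solver
  if (is.null(solver)) solver <- list()
  allowed <- c("duration", "samples_per_cycle", "rtol", "atol", "seed")
  bad <- setdiff(names(solver), allowed)
  if (length(bad) > 0) {
    stop("unknown key(s) in section 'solver': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(simulation_config,
          c(list(plan = parts$body, passive = parts$passive,
                 muscle = parts$muscle, activation = parts$activation,
                 fluid = parts$fluid), solver))
}

#' Write a configuration to YAML
#'
#' Writes every parameter explicitly (including defaulted ones), in a
#' canonical key order, so that write -> read round-trips to an identical
#' configuration with an identical checksum.
#'
#' @param config A [simulation_config()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  as_plain <- function(x) lapply(unclass(x), function(v) v)
  body <- as_plain(config$plan)
  body$calibrated <- NULL   # derived flag, not a constructor argument
  out <- list(
    body = body,
    passive = as_plain(config$passive),
    muscle = as_plain(config$muscle),
    activation = as_plain(config$activation),
    fluid = as_plain(config$fluid),
    solver = list(duration = config$duration,
                  samples_per_cycle = config$samples_per_cycle,
                  rtol = config$rtol, atol = config$atol))
  if (!is.null(config$seed)) out$solver$seed <- config$seed
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Checksum of a configuration
#'
#' MD5 of the canonical YAML rendering; embedded in every output artifact
#' for provenance.
#'
#' @param config A [simulation_config()].
#' @return Hex string.
#' @export
config_checksum <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Export midlines to CSV
#'
#' One row per (time sample, segment) with columns `t` (s), `segment`,
#' `s` (segment centre arc position, BL), `x`, `y` (segment centre, m),
#' `phi` (rad), `kappa` (joint curvature at the segment's posterior joint,
#' 1/m; empty for the last segment), and the stimulus drive on each side at
#' the segment centre.  The first line is a comment embedding the config
#' checksum.
#'
#' @param traj A `swim_trajectory`.
#' @param path Output CSV path.
#' @param every Keep every `every`-th time sample.
#' @return The path, invisibly.
#' @export
export_midlines <- function(traj, path, every = 1L) {
  stopifnot(inherits(traj, "swim_trajectory"))
  idx <- seq(1, length(traj$time), by = every)
  n <- traj$body$n
  ell <- traj$body$ell
  kappa <- cbind((traj$phi[idx, -1, drop = FALSE] -
                    traj$phi[idx, -n, drop = FALSE]) / ell, NA_real_)
  wave <- traj$config$activation
  muscle <- traj$config$muscle
  s <- traj$body$s
  rows <- data.frame(
    t = rep(traj$time[idx], each = n),
    segment = rep(seq_len(n), times = length(idx)),
    s = rep(s, times = length(idx)),
    x = as.vector(t(traj$x[idx, , drop = FALSE])),
    y = as.vector(t(traj$y[idx, , drop = FALSE])),
    phi = as.vector(t(traj$phi[idx, , drop = FALSE])),
    kappa = as.vector(t(kappa)))
  rows$stim_l <- ifelse(rep(traj$body$has_muscle, length(idx)),
                        stim_drive(rows$s, "left", rows$t, wave, muscle), 0)
  rows$stim_r <- ifelse(rep(traj$body$has_muscle, length(idx)),
                        stim_drive(rows$s, "right", rows$t, wave, muscle), 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# lampswim midlines; t s, s BL, x/y m, phi rad, ",
                    "kappa 1/m; config_checksum=",
                    config_checksum(traj$config)), con)
  utils::write.csv(rows, con, row.names = FALSE)
  invisible(path)
}

#' Write a kinematic summary (or any named list of numbers) as JSON
#'
#' Numeric fields are formatted at fixed precision so identical inputs give
#' byte-identical files; the config checksum is embedded when a config is
#' supplied.
#'
#' @param x Named list (e.g. a `kinematics_summary`).
#' @param path Output path.
#' @param config Optional [simulation_config()] for provenance.
#' @return The path, invisibly.
#' @export
write_summary_json <- function(x, path, config = NULL) {
  out <- lapply(unclass(x), function(v) {
    if (is.numeric(v)) signif(v, 12) else v
  })
  if (!is.null(config)) out$config_checksum <- config_checksum(config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write / read fitted speed maps as JSON
#'
#' @param maps A [fit_speed_maps()] result.
#' @param path File path.
#' @return `read_speed_maps` returns a `speed_maps` object.
#' @export
write_speed_maps <- function(maps, path) {
  stopifnot(inherits(maps, "speed_maps"))
  out <- list(alpha = maps$alpha, beta = maps$beta,
              q0 = maps$q0, q1 = maps$q1, q2 = maps$q2,
              r_squared_f = maps$r_squared_f,
              r_squared_a = maps$r_squared_a,
              U_range = maps$U_range,
              maxima = maps$maxima)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_speed_maps
#' @export
read_speed_maps <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  maps <- raw
  maps$U_range <- as.numeric(raw$U_range)
  maps$f_of_U <- function(U) maps$alpha * U + maps$beta
  maps$A_of_U <- function(U) exp(maps$q0 + maps$q1 * U + maps$q2 * U^2)
  class(maps) <- "speed_maps"
  maps
}
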