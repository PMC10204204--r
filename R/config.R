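#' Build a full simulation configuration
#'
#' Returns the complete, resolved configuration list with sections `world`,
#' `coupling`, `adhesion`, `stiffness`, `rows`, `actuation` and `run`. Either
#' row may be `NULL` (the reference scenario has no setae). All lengths are
#' in units of the segment rest length dR; time is in units set by the
#' external-flow coupling and particle mass.
#'
#' @param short_row,long_row row specifications as returned by
#'   [row_spec()], or `NULL` for an absent row.
#' @param ... named overrides applied with [set_config_value()] using dotted
#'   paths, e.g. `run.t_end = 50`.
#' @return a validated configuration list of class `seta_config`.
#' @export
simulation_config <- function(short_row = NULL, long_row = NULL, ...) {
  cfg <- list(
    scenario = "custom",
    world = list(
      L_x = 40, L_y = 24, L_z = 20,
      dR = 1,
      mouth = list(L_mouth_x = 10, L_mouth_y = 1.5, L_mouth_z = 2.6),
      v_ext = c(1.2, 0, 0),
      boundary = "reinject"
    ),
    coupling = list(
      gamma_seta = 2.0, gamma_ext = 0.5, r_f = 0.8,
      gamma_s = 1.0, particle_mass = 1.0, cutoff_weight = 1e-4
    ),
    adhesion = list(a = 2, r_vdw = 0.5, tip_segments = 2),
    stiffness = list(hard = K_HARD, soft = K_SOFT),
    rows = list(short = short_row, long = long_row),
    run = list(
      t_end = 250, dt = 0.01, n_particles = 50,
      t_burn = 25, series_dt = 0.1, avalanche_gap = 0.5,
      density_bins = c(120, 80), injection_frac = 0.05
    )
  )
  dots <- list(...)
  for (nm in names(dots)) cfg <- set_config_value(cfg, nm, dots[[nm]])
  class(cfg) <- "seta_config"
  validate_config(cfg)
  cfg
}

#' Specification of one mirrored pair of seta rows
#'
#' A row is a set of `n_setae` equally spaced setae; every row comes as a
#' mirrored pair at y = +/- `row_offset_y`, both sweeping toward the mouth
#' midplane. Per-seta heterogeneity draws each seta's angular frequency
#' uniformly from `omega_jitter * omega0` and, if `random_phase`, its phase
#' uniformly from [0, 2 pi), using the run's seeded RNG.
#'
#' @param kind `"short"` (7 segments, inner rows) or `"long"` (15 segments,
#'   outer rows).
#' @param material stiffness preset: `"soft"`, `"hard"` or `"hard_soft_tips"`.
#' @param tip_adhesion Morse well depth U0 at the distal tip nodes.
#' @param phi_min,phi_max base sweep limits (radians; negative = toward the
#'   mouth).
#' @param n_setae setae per row.
#' @param row_offset_y distance of the pair from the mouth midplane.
#' @param n_segments segments per seta.
#' @param omega0 nominal sweep angular frequency.
#' @param stroke_asym recovery-to-power stroke duration ratio (1 = symmetric
#'   sinusoid; larger = faster sweep toward the mouth, slower return).
#' @param omega_jitter length-2 relative frequency range for per-seta jitter.
#' @param random_phase draw random initial phases per seta?
#' @param x_span length-2 interval over which bases are evenly spaced;
#'   `NULL` uses `L_x/2 +/- 4` for short rows and `L_x/2 +/- 7` for long.
#' @export
row_spec <- function(kind = c("short", "long"),
                     material = c("hard", "soft", "hard_soft_tips"),
                     tip_adhesion = 0,
                     phi_min = -0.4 * pi,
                     phi_max = if (kind == "short") 0.1 * pi else 0.3 * pi,
                     n_setae = 14,
                     row_offset_y = if (kind == "short") 6.5 else 20,
                     n_segments = if (kind == "short") 7 else 15,
                     omega0 = 1, omega_jitter = c(0.8, 1.2),
                     stroke_asym = 3, random_phase = TRUE, x_span = NULL) {
  kind <- match.arg(kind)
  material <- match.arg(material)
  list(kind = kind, material = material, tip_adhesion = tip_adhesion,
       phi_min = phi_min, phi_max = phi_max, n_setae = as.integer(n_setae),
       row_offset_y = row_offset_y, n_segments = as.integer(n_segments),
       omega0 = omega0, omega_jitter = omega_jitter,
       stroke_asym = stroke_asym, random_phase = random_phase, x_span = x_span)
}

config_schema <- function() {
  list(scenario = NA, world = list(L_x = NA, L_y = NA, L_z = NA, dR = NA,
         mouth = list(L_mouth_x = NA, L_mouth_y = NA, L_mouth_z = NA),
         v_ext = NA, boundary = NA),
       coupling = list(gamma_seta = NA, gamma_ext = NA, r_f = NA, gamma_s = NA,
         particle_mass = NA, cutoff_weight = NA),
       adhesion = list(a = NA, r_vdw = NA, tip_segments = NA),
       stiffness = list(hard = NA, soft = NA),
       rows = list(short = NA, long = NA),
       run = list(t_end = NA, dt = NA, n_particles = NA, t_burn = NA,
         series_dt = NA, avalanche_gap = NA, density_bins = NA,
         injection_frac = NA))
}

row_keys <- c("kind", "material", "tip_adhesion", "phi_min", "phi_max",
              "n_setae", "row_offset_y", "n_segments", "omega0",
              "omega_jitter", "stroke_asym", "random_phase", "x_span")

check_keys <- function(x, schema, where) {
  unknown <- setdiff(names(x), names(schema))
  if (length(unknown))
    stop("unknown configuration key(s) in ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(names(schema), names(x))
  if (length(missing))
    stop("missing configuration key(s) in ", where, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (nm in names(schema)) {
    if (is.list(schema[[nm]]))
      check_keys(x[[nm]], schema[[nm]], paste0(where, ".", nm))
  }
}

#' Validate a simulation configuration
#'
#' Checks the section/key structure (unknown or missing keys are rejected),
#' row specifications, actuation invariants, and that the mouth box lies
#' strictly inside the domain footprint.
#'
#' @param config a configuration list.
#' @return the config, invisibly; errors on any violation.
#' @export
validate_config <- function(config) {
  check_keys(unclass(config), config_schema(), "config")
  w <- config$world
  stopifnot(w$L_x > 0, w$L_y > 0, w$L_z > 0, w$dR > 0,
            length(w$v_ext) == 3, all(is.finite(w$v_ext)))
  if (!w$boundary %in% c("reinject", "periodic_x"))
    stop("world.boundary must be 'reinject' or 'periodic_x'")
  m <- w$mouth
  if (m$L_mouth_x <= 0 || m$L_mouth_y <= 0 || m$L_mouth_z <= 0)
    stop("mouth extents must be positive")
  if (w$L_x / 2 - m$L_mouth_x / 2 <= 0 || w$L_x / 2 + m$L_mouth_x / 2 >= w$L_x ||
      m$L_mouth_y >= w$L_y || m$L_mouth_z >= w$L_z)
    stop("mouth box must lie strictly inside the domain")
  cp <- config$coupling
  stopifnot(cp$gamma_seta > 0, cp$gamma_ext >= 0, cp$r_f > 0, cp$gamma_s > 0,
            cp$particle_mass > 0, cp$cutoff_weight > 0, cp$cutoff_weight < 1)
  stopifnot(config$adhesion$a > 0, config$adhesion$r_vdw > 0,
            config$adhesion$tip_segments >= 1)
  for (side in c("short", "long")) {
    r <- config$rows[[side]]
    if (is.null(r)) next
    unknown <- setdiff(names(r), row_keys)
    if (length(unknown))
      stop("unknown key(s) in rows.", side, ": ", paste(unknown, collapse = ", "))
    stopifnot(r$n_setae >= 1, r$n_segments >= 1, r$row_offset_y > 0)
    actuation_spec(r$phi_min, r$phi_max, r$omega0,
                   stroke_asym = r$stroke_asym %||% 1) # checks sweep invariants
    if (!r$material %in% c("soft", "hard", "hard_soft_tips"))
      stop("rows.", side, ".material must be soft, hard or hard_soft_tips")
    if (r$tip_adhesion < 0) stop("tip_adhesion must be >= 0")
  }
  run <- config$run
  stopifnot(run$t_end >= 0, run$dt > 0, run$n_particles >= 1,
            run$t_burn >= 0, run$series_dt >= run$dt,
            run$avalanche_gap > 0, length(run$density_bins) == 2,
            all(run$density_bins >= 1),
            run$injection_frac > 0, run$injection_frac <= 1)
  invisible(config)
}

#' Enumerate settable leaf paths of a configuration
#'
#' @param config a `seta_config`.
#' @return character vector of dotted paths usable with
#'   [set_config_value()] and sweep specifications.
#' @export
config_leaf_paths <- function(config) {
  rec <- function(x, prefix) {
    out <- character()
    for (nm in names(x)) {
      p <- if (prefix == "") nm else paste0(prefix, ".", nm)
      v <- x[[nm]]
      if (is.list(v)) out <- c(out, rec(v, p))
      else if (!is.null(v)) out <- c(out, p)
    }
    out
  }
  rec(unclass(config), "")
}

#' Set one configuration value by dotted path
#'
#' @param config a `seta_config` (or plain list with the same structure).
#' @param path dotted path such as `"rows.long.tip_adhesion"` or
#'   `"rows.short.phi_min"`.
#' @param value replacement value.
#' @return the modified configuration. Unknown paths raise an error listing
#'   the valid ones.
#' @export
set_config_value <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- config
  for (i in seq_along(keys)) {
    if (!is.list(node) || !keys[i] %in% names(node)) {
      valid <- config_leaf_paths(config)
      stop("unknown configuration path '", path, "'; valid paths are:\n  ",
           paste(valid, collapse = "\n  "), call. = FALSE)
    }
    node <- node[[keys[i]]]
  }
  config[[keys]] <- value
  config
}

#' Read a configuration from YAML
#'
#' @param path YAML file written by [write_config()] (or hand-written with
#'   the same sections). Unknown keys are rejected.
#' @return a validated `seta_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$rows)) cfg$rows <- list()
  cfg$rows <- list(short = cfg$rows$short, long = cfg$rows$long)
  for (side in c("short", "long")) {
    r <- cfg$rows[[side]]
    if (!is.null(r)) {
      r$n_setae <- as.integer(r$n_setae)
      r$n_segments <- as.integer(r$n_segments)
      cfg$rows[[side]] <- r
    }
  }
  cfg$run$density_bins <- as.numeric(cfg$run$density_bins)
  class(cfg) <- "seta_config"
  validate_config(cfg)
  cfg
}

#' Write a configuration to YAML at full double precision
#'
#' The echoed file round-trips: running [read_config()] on it reproduces the
#' original run bit-exactly for the same seed.
#'
#' @param config a `seta_config`.
#' @param path output file.
#' @export
write_config <- function(config, path) {
  txt <- yaml::as.yaml(unclass(config), precision = 17)
  writeLines(txt, path)
  invisible(path)
}

#' Digest of a resolved configuration
#'
#' Stable hash used for provenance in run logs and summaries.
#' @param config a `seta_config`.
#' @export
config_digest <- function(config) {
  rlang::hash(unclass(config))
}

#' @export
print.seta_config <- function(x, ...) {
  cat(sprintf("<seta_config> scenario '%s'\n", x$scenario))
  for (side in c("short", "long")) {
    r <- x$rows[[side]]
    if (is.null(r)) {
      cat(sprintf("  %s rows: absent\n", side))
    } else {
      cat(sprintf("  %s rows: 2 x %d setae, %d segments, %s, tip u0 = %g, phi in [%.3f, %.3f] rad\n",
                  side, r$n_setae, r$n_segments, r$material, r$tip_adhesion,
                  r$phi_min, r$phi_max))
    }
  }
  cat(sprintf("  domain %g x [%g] x %g, v_ext = (%g, %g, %g), N_p = %d, t_end = %g\n",
              x$world$L_x, x$world$L_y, x$world$L_z,
              x$world$v_ext[1], x$world$v_ext[2], x$world$v_ext[3],
              x$run$n_particles, x$run$t_end))
  invisible(x)
}
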