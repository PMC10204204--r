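#' Registry of named scenario presets
#'
#' The presets reproduce the simulated experimental program: short-seta
#' stiffness/adhesion variants, the combined short + long system, and the
#' long-seta adhesion levels. Short rows always use the near-optimal sweep
#' `phi_min = -0.4 pi`; the "adhesive" short variant carries strong tip
#' adhesion, and the long-seta adhesion levels are none,
#' intermediate and strong.
#'
#' @return named list of preset descriptors (`name`, `short_row`, `long_row`,
#'   `overrides`).
#' @export
preset_registry <- function() {
  short_opt <- function(tip_adhesion = U0_SHORT_TIP,
                        material = "hard_soft_tips")
    row_spec("short", material = material, tip_adhesion = tip_adhesion,
             phi_min = -0.4 * pi)
  long_row <- function(material, tip_adhesion = 0)
    row_spec("long", material = material, tip_adhesion = tip_adhesion,
             phi_min = -0.4 * pi)
  p <- function(name, short_row = NULL, long_row = NULL, overrides = list())
    list(name = name, short_row = short_row, long_row = long_row,
         overrides = overrides)
  presets <- list(
    p("reference_no_setae"),
    p("short_soft", short_opt(0, "soft")),
    p("short_hard_soft_tips", short_opt(0, "hard_soft_tips")),
    p("short_hard", short_opt(0, "hard")),
    p("short_hard_soft_tips_adhesive", short_opt()),
    p("combined_long_hard", short_opt(), long_row("hard")),
    p("combined_long_soft_adhesive", short_opt(),
      long_row("soft", U0_LEVELS[["strong"]])),
    p("combined_long_hard_soft_tips", short_opt(), long_row("hard_soft_tips")),
    p("combined_long_adh_none", short_opt(), long_row("hard", 0)),
    p("combined_long_adh_intermediate", short_opt(),
      long_row("hard", U0_LEVELS[["intermediate"]])),
    p("combined_long_adh_strong", short_opt(),
      long_row("hard", U0_LEVELS[["strong"]]))
  )
  names(presets) <- vapply(presets, `[[`, "", "name")
  presets
}

#' List the available scenario names
#' @export
list_scenarios <- function() names(preset_registry())

#' Configuration for a named scenario preset
#'
#' @param name a name from [list_scenarios()].
#' @param ... named overrides by dotted path, e.g. `run.t_end = 50`,
#'   `rows.long.tip_adhesion = 2`.
#' @return a `seta_config` (see [simulation_config()]).
#' @export
scenario_config <- function(name, ...) {
  reg <- preset_registry()
  if (!name %in% names(reg))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  pr <- reg[[name]]
  cfg <- simulation_config(short_row = pr$short_row, long_row = pr$long_row)
  cfg$scenario <- name
  for (nm in names(pr$overrides))
    cfg <- set_config_value(cfg, nm, pr$overrides[[nm]])
  dots <- list(...)
  for (nm in names(dots)) cfg <- set_config_value(cfg, nm, dots[[nm]])
  validate_config(cfg)
  cfg
}
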