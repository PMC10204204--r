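#' Run a one-parameter sweep over seeds
#'
#' Executes [run_simulation()] for every combination of a parameter value and
#' a seed, starting from a scenario preset, and returns a long-format table
#' with the end-of-run consumption and avalanche statistics. This is the
#' in-silico experimental design behind the adhesion and rotation-angle
#' sweeps.
#'
#' @param scenario scenario name from [list_scenarios()], or a `seta_config`
#'   to start from.
#' @param param dotted configuration path to vary, e.g.
#'   `"rows.long.tip_adhesion"` or `"rows.short.phi_min"`.
#' @param values numeric vector of parameter values (>= 1).
#' @param seeds integer vector of seeds (>= 1).
#' @param t_end end time of every run.
#' @param gap avalanche gap used for the summary columns.
#' @return data frame with one row per (value, seed): columns `scenario`,
#'   `parameter`, `value`, `seed`, `final_n_eaten`, `n_avalanches`,
#'   `mean_interval` (NA with fewer than 2 avalanches).
#' @export
run_sweep <- function(scenario, param, values, seeds, t_end = NULL,
                      gap = NULL) {
  base_cfg <- if (inherits(scenario, "seta_config")) scenario
              else scenario_config(scenario)
  stopifnot(length(values) >= 1, length(seeds) >= 1)
  if (is.null(t_end)) t_end <- base_cfg$run$t_end
  if (is.null(gap)) gap <- base_cfg$run$avalanche_gap
  rows <- list()
  for (v in values) {
    cfg <- set_config_value(base_cfg, param, v)
    validate_config(cfg)
    for (s in seeds) {
      run <- run_simulation(cfg, s, t_end)
      av <- detect_avalanches(run$events$t, gap)
      rows[[length(rows) + 1]] <- data.frame(
        scenario = base_cfg$scenario, parameter = param, value = v,
        seed = s, final_n_eaten = run$n_eaten,
        n_avalanches = nrow(av$avalanches),
        mean_interval = if (length(av$intervals) >= 1) mean(av$intervals)
                        else NA_real_)
    }
  }
  do.call(rbind, rows)
}
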