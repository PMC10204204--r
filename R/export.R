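#' Export a run or sweep table to a directory
#'
#' For a `seta_run`, writes: `n_eaten.csv` (sampled staircase, columns
#' `t,n_eaten`), `events.csv` (`t,particle_index`), `density_yz.rds`
#' (portable array) and `density_yz.txt` (plain-text matrix dump with axis
#' metadata in comment lines), `summary.json` (seed, config digest, final
#' count, avalanche statistics), `config.yaml` (full resolved configuration;
#' re-reading it reproduces the run bit-exactly), and `run.log`. For a sweep
#' table, writes `sweep.csv` and `summary.json`.
#'
#' @param result a `seta_run` or the data frame returned by [run_sweep()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_results <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  if (inherits(result, "seta_run")) export_run(result, out_dir)
  else if (is.data.frame(result)) export_sweep(result, out_dir)
  else stop("result must be a seta_run or a sweep data frame")
}

export_run <- function(run, out_dir) {
  paths <- file.path(out_dir, c("n_eaten.csv", "events.csv",
                                "density_yz.rds", "density_yz.txt",
                                "summary.json", "config.yaml", "run.log"))
  names(paths) <- basename(paths)
  write.csv(run$series, paths["n_eaten.csv"], row.names = FALSE)
  ev <- run$events
  names(ev) <- c("t", "particle_index")
  write.csv(ev, paths["events.csv"], row.names = FALSE)
  saveRDS(density_map(run, normalize = FALSE), paths["density_yz.rds"])
  con <- file(paths["density_yz.txt"], "w")
  writeLines(c(
    sprintf("# (y,z) particle density accumulated after burn-in; rows = y bins, columns = z bins"),
    sprintf("# y: %d bins over [%.6g, %.6g]", nrow(run$density_yz),
            min(run$y_breaks), max(run$y_breaks)),
    sprintf("# z: %d bins over [%.6g, %.6g]", ncol(run$density_yz),
            min(run$z_breaks), max(run$z_breaks))), con)
  utils::write.table(run$density_yz, con, row.names = FALSE,
                     col.names = FALSE)
  close(con)
  av <- detect_avalanches(run$events$t, run$meta$config$run$avalanche_gap)
  summary <- list(
    scenario = run$meta$scenario, seed = run$meta$seed,
    config_digest = run$meta$config_digest,
    t_end = run$meta$t_end, dt = run$meta$dt,
    final_n_eaten = run$n_eaten, n_events = nrow(run$events),
    n_avalanches = nrow(av$avalanches),
    mean_avalanche_interval = if (length(av$intervals)) mean(av$intervals)
                              else NA)
  jsonlite::write_json(summary, paths["summary.json"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_config(run$meta$config, paths["config.yaml"])
  writeLines(sprintf(
    "scenario=%s seed=%d digest=%s t_end=%g events=%d wall_time_s=%.2f",
    run$meta$scenario, run$meta$seed, run$meta$config_digest,
    run$meta$t_end, nrow(run$events), run$meta$wall_time),
    paths["run.log"])
  invisible(paths)
}

export_sweep <- function(tab, out_dir) {
  paths <- file.path(out_dir, c("sweep.csv", "summary.json"))
  names(paths) <- basename(paths)
  write.csv(tab, paths["sweep.csv"], row.names = FALSE)
  agg <- stats::aggregate(final_n_eaten ~ value, tab, mean)
  summary <- list(scenario = tab$scenario[1], parameter = tab$parameter[1],
                  n_runs = nrow(tab),
                  values = agg$value, mean_final_n_eaten = agg$final_n_eaten)
  jsonlite::write_json(summary, paths["summary.json"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
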