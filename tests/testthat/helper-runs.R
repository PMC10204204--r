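# Shared cache of full-length scenario runs, keyed by (config digest, seed),
# so that different test files can reuse the same simulations.
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(config, seed) {
  key <- paste(config_digest(config), seed, sep = "_")
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- run_simulation(config, seed)
  .run_cache[[key]]
}

finals_for <- function(scenario, seeds, ...) {
  cfg <- scenario_config(scenario, ...)
  vapply(seeds, function(s) cached_run(cfg, s)$n_eaten, 0L)
}

runs_for <- function(scenario, seeds, ...) {
  cfg <- scenario_config(scenario, ...)
  lapply(seeds, function(s) cached_run(cfg, s))
}

# one-sided paired Wilcoxon signed-rank p-value (normal approximation,
# continuity corrected; robust to ties)
paired_p_greater <- function(x, y) {
  suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                      alternative = "greater",
                                      exact = FALSE, correct = TRUE)$p.value)
}
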