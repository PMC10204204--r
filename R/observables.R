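#' Decompose capture events into avalanches
#'
#' Partitions a sorted sequence of capture times into maximal clusters in
#' which consecutive events are no more than `gap` apart. Each cluster is one
#' consumption avalanche; the intervals between successive avalanche starts
#' measure the quasi-periodicity of the delivery.
#'
#' @param event_times sorted numeric vector of capture times (a `seta_run`
#'   is also accepted).
#' @param gap maximum within-avalanche spacing (> 0).
#' @return an `avalanche_summary`: data frame `avalanches` with columns
#'   `start_t` and `size`, and the numeric vector `intervals` between
#'   avalanche starts. Sizes always sum to the number of events.
#' @export
detect_avalanches <- function(event_times, gap = 0.5) {
  if (inherits(event_times, "seta_run")) event_times <- event_times$events$t
  stopifnot(gap > 0, !is.unsorted(event_times))
  if (length(event_times) == 0) {
    return(structure(list(avalanches = data.frame(start_t = numeric(0),
                                                  size = integer(0)),
                          intervals = numeric(0), gap = gap),
                     class = "avalanche_summary"))
  }
  new_cluster <- c(TRUE, diff(event_times) > gap)
  id <- cumsum(new_cluster)
  starts <- event_times[new_cluster]
  sizes <- as.integer(tabulate(id))
  structure(list(avalanches = data.frame(start_t = starts, size = sizes),
                 intervals = diff(starts), gap = gap),
            class = "avalanche_summary")
}

#' @export
print.avalanche_summary <- function(x, ...) {
  n <- nrow(x$avalanches)
  cat(sprintf("<avalanche_summary> %d avalanche(s), %d event(s), gap = %g\n",
              n, sum(x$avalanches$size), x$gap))
  if (n > 1)
    cat(sprintf("  mean inter-avalanche interval %.3f\n", mean(x$intervals)))
  invisible(x)
}

#' Mean inter-avalanche interval relative to the sweep period
#'
#' Ratio of the mean interval between avalanche starts to the nominal sweep
#' period `2 pi / omega_0`. Mirrored rows can deliver twice per full
#' back-and-forth cycle, so values near 0.5 as well as near 1 indicate
#' period-locked delivery; the raw ratio is returned and interpretation is
#' left to the analyst.
#'
#' @param summary an `avalanche_summary` with at least 3 avalanches.
#' @param omega_0 nominal sweep angular frequency.
#' @export
mean_interval_vs_period <- function(summary, omega_0) {
  stopifnot(inherits(summary, "avalanche_summary"), omega_0 > 0)
  if (nrow(summary$avalanches) < 3)
    stop("need at least 3 avalanches to estimate the mean interval")
  mean(summary$intervals) / (2 * pi / omega_0)
}

#' Normalized (y,z) density map of a run
#'
#' @param run a `seta_run`.
#' @param normalize scale to a maximum of 1 (as in grayscale map exports)?
#' @return the density matrix (y bins x z bins) with `y`/`z` break attributes.
#' @export
density_map <- function(run, normalize = TRUE) {
  stopifnot(inherits(run, "seta_run"))
  d <- run$density_yz
  if (normalize && max(d) > 0) d <- d / max(d)
  attr(d, "y_breaks") <- run$y_breaks
  attr(d, "z_breaks") <- run$z_breaks
  d
}

#' Plot the consumption staircase of one or more runs
#'
#' @param x a `seta_run`.
#' @param ... further `seta_run`s to overlay.
#' @param col line colours.
#' @export
plot.seta_run <- function(x, ..., col = NULL) {
  runs <- c(list(x), Filter(function(r) inherits(r, "seta_run"), list(...)))
  if (is.null(col)) col <- seq_along(runs)
  xmax <- max(vapply(runs, function(r) max(r$series$t), 0))
  ymax <- max(1, vapply(runs, function(r) max(r$series$n_eaten), 0))
  graphics::plot(NULL, xlim = c(0, xmax), ylim = c(0, ymax),
                 xlab = "t", ylab = expression(N[eaten]))
  for (i in seq_along(runs))
    graphics::lines(runs[[i]]$series$t, runs[[i]]$series$n_eaten,
                    type = "s", col = col[i])
  invisible(x)
}

#' Grayscale density map in the (y,z) plane
#'
#' Darker shades mark higher time-accumulated particle density, normalized
#' to the maximum.
#'
#' @param run a `seta_run`.
#' @param ... passed to [graphics::image()].
#' @export
plot_density_map <- function(run, ...) {
  d <- density_map(run, normalize = TRUE)
  graphics::image(x = run$y_breaks, y = run$z_breaks, z = d,
                  col = grDevices::gray(seq(1, 0, length.out = 64)),
                  xlab = "y", ylab = "z", useRaster = TRUE, ...)
  invisible(run)
}
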