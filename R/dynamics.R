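world_params <- function(config) {
  w <- config$world
  cp <- config$coupling
  m <- w$mouth
  cx <- w$L_x / 2
  list(L_x = w$L_x, L_y = w$L_y, L_z = w$L_z,
       mouth_lo = c(cx - m$L_mouth_x / 2, -m$L_mouth_y, 0),
       mouth_hi = c(cx + m$L_mouth_x / 2, m$L_mouth_y, m$L_mouth_z),
       v_ext = as.numeric(w$v_ext),
       gamma_seta = cp$gamma_seta, gamma_ext = cp$gamma_ext,
       r_f = cp$r_f, r_cut = cp$r_f * log(1 / cp$cutoff_weight),
       particle_mass = cp$particle_mass, gamma_s = cp$gamma_s,
       dR = w$dR, morse_a = config$adhesion$a,
       morse_r_vdw = config$adhesion$r_vdw,
       periodic_x = identical(w$boundary, "periodic_x"),
       injection_frac = config$run$injection_frac)
}

# Build the full list of driven setae for a configuration, consuming the
# session RNG for per-seta frequency jitter and phases in a fixed order:
# kinds short then long, sides +1 then -1, bases by ascending x.
build_setae <- function(config) {
  setae <- list()
  dt <- config$run$dt
  gamma_s <- config$coupling$gamma_s
  for (kind in c("short", "long")) {
    r <- config$rows[[kind]]
    if (is.null(r)) next
    span <- r$x_span
    if (is.null(span))
      span <- config$world$L_x / 2 + (if (kind == "short") c(-4, 4) else c(-7, 7))
    xs <- if (r$n_setae == 1) mean(span) else
      seq(span[1], span[2], length.out = r$n_setae)
    for (side in c(1, -1)) {
      for (x in xs) {
        omega <- runif(1, r$omega_jitter[1] * r$omega0,
                       r$omega_jitter[2] * r$omega0)
        phase <- if (isTRUE(r$random_phase)) runif(1, 0, 2 * pi) else 0
        act <- actuation_spec(r$phi_min, r$phi_max, omega, phase,
                              stroke_asym = r$stroke_asym %||% 1)
        prof <- material_profile(r$n_segments, r$material, r$tip_adhesion,
                                 k_hard = config$stiffness$hard,
                                 k_soft = config$stiffness$soft,
                                 tip_segments = config$adhesion$tip_segments)
        ch <- seta_chain(c(x, side * r$row_offset_y, 0), r$n_segments,
                         profile = prof, dR = config$world$dR, side = side,
                         phi = base_angle(0, act))
        setae[[length(setae) + 1]] <- seta_state(ch, act)
      }
    }
  }
  setae
}

flatten_setae <- function(setae) {
  nc <- length(setae)
  nseg <- vapply(setae, function(s) s$chain$n_segments, 0L)
  nn <- nseg + 1L
  offset <- c(0L, cumsum(nn))[seq_len(nc)]
  seg_offset <- c(0L, cumsum(nseg))[seq_len(nc)]
  nodes <- do.call(rbind, c(lapply(setae, function(s) s$chain$nodes),
                            list(matrix(0, 0, 3))))
  node_vel <- do.call(rbind, c(lapply(setae, function(s) s$chain$node_vel),
                               list(matrix(0, 0, 3))))
  adh_node <- integer(0)
  adh_u0 <- numeric(0)
  for (c in seq_len(nc)) {
    u0 <- setae[[c]]$chain$profile$adhesion_u0
    i <- which(u0 > 0) # segment i (1-based) has distal node i
    adh_node <- c(adh_node, offset[c] + i)
    adh_u0 <- c(adh_u0, u0[i])
  }
  list(offset = offset, n_segments = nseg,
       base_x = vapply(setae, function(s) s$chain$base_point[1], 0),
       base_y = vapply(setae, function(s) s$chain$base_point[2], 0),
       side = vapply(setae, function(s) as.numeric(s$chain$side), 0),
       k_par = unlist(lapply(setae, function(s) s$chain$profile$k_par),
                      use.names = FALSE) %||% numeric(0),
       k_perp = unlist(lapply(setae, function(s) s$chain$profile$k_perp),
                       use.names = FALSE) %||% numeric(0),
       seg_offset = seg_offset,
       adh_node = adh_node, adh_u0 = adh_u0,
       omega = vapply(setae, function(s) s$actuation$omega, 0),
       phase = vapply(setae, function(s) s$actuation$phase, 0),
       phi_min = vapply(setae, function(s) s$actuation$phi_min, 0),
       phi_max = vapply(setae, function(s) s$actuation$phi_max, 0),
       stroke_asym = vapply(setae, function(s) s$actuation$stroke_asym %||% 1, 0),
       nodes = nodes, node_vel = node_vel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initialize a simulation state
#'
#' Seeds the RNG, builds all seta chains straight at their initial base
#' angle, and places the particles uniformly at random in the domain box with
#' velocity equal to the external flow. Identical `(config, seed)` pairs
#' produce bit-identical states and, through the deterministic stepper,
#' bit-identical runs.
#'
#' @param config a `seta_config` (see [simulation_config()],
#'   [scenario_config()]).
#' @param seed integer RNG seed.
#' @return a `seta_sim` state object.
#' @export
initialize_simulation <- function(config, seed) {
  validate_config(config)
  set.seed(seed)
  setae <- build_setae(config)
  np <- config$run$n_particles
  w <- config$world
  pos <- matrix(0, np, 3)
  for (p in seq_len(np)) {
    pos[p, 1] <- runif(1, 0, w$L_x)
    pos[p, 2] <- runif(1, -w$L_y, w$L_y)
    pos[p, 3] <- runif(1, 0, w$L_z)
  }
  vel <- matrix(rep(as.numeric(w$v_ext), each = np), np, 3)
  nb <- config$run$density_bins
  structure(list(
    t = 0, config = config, setae = setae,
    particles = list(pos = pos, vel = vel),
    n_eaten = 0L,
    events = data.frame(t = numeric(0), particle = integer(0)),
    density = matrix(0, nb[1], nb[2]),
    series = data.frame(t = 0, n_eaten = 0L),
    world = world_params(config), seed = seed
  ), class = "seta_sim")
}

#' Advance a simulation state with the compiled stepper
#'
#' Runs the coupled update [base drive -> chain relaxation -> particle step
#' -> boundary handling -> capture check -> density accumulation] at fixed
#' `dt` until `t >= t_until`.
#'
#' @param state a `seta_sim` state.
#' @param t_until target time.
#' @return the advanced state.
#' @export
advance_simulation <- function(state, t_until) {
  cfg <- state$config
  dt <- cfg$run$dt
  n_steps <- max(0L, as.integer(round((t_until - state$t) / dt)))
  if (n_steps == 0L) return(state)
  fl <- flatten_setae(state$setae)
  res <- cpp_run(fl, state$world,
                 list(n_steps = n_steps, dt = dt, t_burn = cfg$run$t_burn,
                      series_every = as.integer(round(cfg$run$series_dt / dt)),
                      record_density = TRUE),
                 state$particles$pos, state$particles$vel,
                 state$density, state$n_eaten, state$t)
  for (c in seq_along(state$setae)) {
    idx <- fl$offset[c] + seq_len(fl$n_segments[c] + 1L)
    ch <- state$setae[[c]]$chain
    ch$nodes <- res$nodes[idx, , drop = FALSE]
    ch$node_vel <- res$node_vel[idx, , drop = FALSE]
    state$setae[[c]]$chain <- ch
    state$setae[[c]]$prev_nodes <- ch$nodes
    state$setae[[c]]$current_phi <- base_angle(res$t_final,
                                               state$setae[[c]]$actuation)
  }
  state$particles$pos <- res$p_pos
  state$particles$vel <- res$p_vel
  state$n_eaten <- res$n_eaten
  if (length(res$event_t))
    state$events <- rbind(state$events,
                          data.frame(t = res$event_t, particle = res$event_p))
  if (length(res$series_t))
    state$series <- rbind(state$series,
                          data.frame(t = res$series_t, n_eaten = res$series_n))
  state$density <- res$density
  state$t <- res$t_final
  state
}

adhesive_nodes <- function(setae) {
  out <- list()
  for (s in setae) {
    u0 <- s$chain$profile$adhesion_u0
    for (i in which(u0 > 0))
      out[[length(out) + 1]] <- list(pos = s$chain$nodes[i + 1, ], u0 = u0[i])
  }
  out
}

#' One particle update (semi-implicit Euler)
#'
#' Reference R implementation of the particle sub-step, mirroring the
#' compiled stepper: each particle feels the seta velocity coupling, the
#' external-flow coupling and Morse adhesion from adhesive tip nodes, then
#' `v <- v + dt F / m` and `r <- r + dt v`. Particles do not interact with
#' each other.
#'
#' @param state a `seta_sim` state.
#' @param dt time step.
#' @return the updated state; errors (with the particle index) on non-finite
#'   forces.
#' @export
particle_step <- function(state, dt) {
  w <- state$world
  pos <- state$particles$pos
  vel <- state$particles$vel
  adh <- adhesive_nodes(state$setae)
  adh_cut2 <- (w$morse_r_vdw + 16 / w$morse_a)^2
  mp <- morse_params(1, w$morse_a, w$morse_r_vdw)
  for (p in seq_len(nrow(pos))) {
    f <- external_flow_force(vel[p, ], w$v_ext, w$gamma_ext)
    for (s in state$setae)
      f <- f + cpp_flow_coupling_force(pos[p, ], vel[p, ], s$chain$nodes,
                                       s$chain$node_vel, w$gamma_seta,
                                       w$r_f, w$r_cut)
    for (a in adh) {
      d2 <- sum((pos[p, ] - a$pos)^2)
      if (d2 <= adh_cut2 && d2 > 1e-24) {
        mp$u0 <- a$u0
        f <- f + morse_force(pos[p, ], a$pos, mp)
      }
    }
    if (any(!is.finite(f)))
      stop("non-finite force on particle ", p)
    vel[p, ] <- vel[p, ] + dt * f / w$particle_mass
    pos[p, ] <- pos[p, ] + dt * vel[p, ]
  }
  state$particles$pos <- pos
  state$particles$vel <- vel
  state
}

reinject <- function(w) {
  c(runif(1, 0, w$injection_frac * w$L_x),
    runif(1, -w$L_y, w$L_y),
    runif(1, 0, w$L_z))
}

#' Reinject particles that left the domain
#'
#' A particle crossing any domain face is reinjected at a uniform-random
#' position in the upstream inflow slab with velocity `v_ext` (with the
#' `periodic_x` boundary option, x wraps instead and only y/z exits
#' reinject). Draws use the run RNG in particle-index order.
#'
#' @param state a `seta_sim` state.
#' @return the updated state.
#' @export
handle_boundaries <- function(state) {
  w <- state$world
  pos <- state$particles$pos
  vel <- state$particles$vel
  for (p in seq_len(nrow(pos))) {
    if (w$periodic_x) pos[p, 1] <- pos[p, 1] %% w$L_x
    out <- pos[p, 1] < 0 || pos[p, 1] > w$L_x ||
      pos[p, 2] < -w$L_y || pos[p, 2] > w$L_y ||
      pos[p, 3] < 0 || pos[p, 3] > w$L_z
    if (out) {
      pos[p, ] <- reinject(w)
      vel[p, ] <- w$v_ext
    }
  }
  state$particles$pos <- pos
  state$particles$vel <- vel
  state
}

#' Count and reinject eaten particles
#'
#' Every particle inside the mouth box (half-open on all faces:
#' `min <= coord < max`) is recorded as eaten at the current state time,
#' increments the consumption counter, and is reinjected upstream like a
#' particle that left the domain. Simultaneous captures are processed in
#' particle-index order.
#'
#' @param state a `seta_sim` state.
#' @return the updated state.
#' @export
capture_check <- function(state) {
  w <- state$world
  pos <- state$particles$pos
  vel <- state$particles$vel
  for (p in seq_len(nrow(pos))) {
    if (all(pos[p, ] >= w$mouth_lo) && all(pos[p, ] < w$mouth_hi)) {
      state$n_eaten <- state$n_eaten + 1L
      state$events <- rbind(state$events,
                            data.frame(t = state$t, particle = p))
      pos[p, ] <- reinject(w)
      vel[p, ] <- w$v_ext
    }
  }
  state$particles$pos <- pos
  state$particles$vel <- vel
  state
}

#' Accumulate the (y,z) particle density after burn-in
#'
#' Bins every particle's (y,z) position into the state's density grid,
#' provided the state time has passed the burn-in `t_burn`. The y histogram
#' is the z-marginal of this grid.
#'
#' @param state a `seta_sim` state.
#' @param t_burn burn-in time before which nothing is accumulated.
#' @return the updated state.
#' @export
accumulate_density <- function(state, t_burn = state$config$run$t_burn) {
  if (state$t < t_burn) return(state)
  w <- state$world
  nb <- dim(state$density)
  pos <- state$particles$pos
  for (p in seq_len(nrow(pos))) {
    iy <- min(max(floor((pos[p, 2] + w$L_y) / (2 * w$L_y) * nb[1]), 0), nb[1] - 1)
    iz <- min(max(floor(pos[p, 3] / w$L_z * nb[2]), 0), nb[2] - 1)
    state$density[iy + 1, iz + 1] <- state$density[iy + 1, iz + 1] + 1
  }
  state
}

#' One full composite step in pure R
#'
#' Reference implementation of a single dt update, composing
#' [apply_base_drive()], [relax_chain()], [particle_step()],
#' [handle_boundaries()], [capture_check()] and [accumulate_density()] in
#' the same order as the compiled stepper (used to cross-check it).
#'
#' @param state a `seta_sim` state.
#' @param dt time step; defaults to the configured one.
#' @return the updated state.
#' @export
step_simulation <- function(state, dt = state$config$run$dt) {
  t_new <- state$t + dt
  gamma_s <- state$config$coupling$gamma_s
  for (i in seq_along(state$setae)) {
    ss <- apply_base_drive(state$setae[[i]], t_new)
    state$setae[[i]] <- relax_chain(ss, dt, gamma_s)
  }
  state <- particle_step(state, dt)
  state$t <- t_new
  state <- handle_boundaries(state)
  state <- capture_check(state)
  accumulate_density(state)
}

#' Run a scenario to completion
#'
#' Initializes from `(config, seed)` and advances to `t_end`, returning the
#' consumption staircase, the event log, the accumulated (y,z) density map
#' and provenance metadata. Identical `(config, seed)` pairs give identical
#' results.
#'
#' @param config a `seta_config`.
#' @param seed integer RNG seed.
#' @param t_end end time (defaults to the configured `run.t_end`).
#' @return an object of class `seta_run` with fields `events` (data frame of
#'   capture times and particle indices), `n_eaten`, `series` (sampled
#'   staircase), `density_yz`, `hist_y`, `final_state` and `meta`.
#' @export
run_simulation <- function(config, seed, t_end = config$run$t_end) {
  t_wall <- proc.time()[["elapsed"]]
  state <- initialize_simulation(config, seed)
  state <- advance_simulation(state, t_end)
  structure(list(
    events = state$events,
    n_eaten = state$n_eaten,
    series = state$series,
    density_yz = state$density,
    hist_y = rowSums(state$density),
    y_breaks = seq(-config$world$L_y, config$world$L_y,
                   length.out = nrow(state$density) + 1),
    z_breaks = seq(0, config$world$L_z, length.out = ncol(state$density) + 1),
    final_state = state,
    meta = list(seed = seed, scenario = config$scenario,
                config = config, config_digest = config_digest(config),
                t_end = t_end, dt = config$run$dt,
                n_events = nrow(state$events),
                wall_time = proc.time()[["elapsed"]] - t_wall)
  ), class = "seta_run")
}

#' Run a named scenario preset
#'
#' Convenience wrapper: `run_simulation(scenario_config(name, ...), seed)`.
#'
#' @param name scenario name from [list_scenarios()].
#' @param seed integer RNG seed.
#' @param t_end optional end-time override.
#' @param ... configuration overrides by dotted path.
#' @export
run_scenario <- function(name, seed, t_end = NULL, ...) {
  cfg <- scenario_config(name, ...)
  run_simulation(cfg, seed, t_end %||% cfg$run$t_end)
}

#' @export
print.seta_run <- function(x, ...) {
  cat(sprintf("<seta_run> scenario '%s', seed %d: %d particles eaten by t = %g\n",
              x$meta$scenario, x$meta$seed, x$n_eaten, x$meta$t_end))
  if (nrow(x$events))
    cat(sprintf("  first/last capture at t = %.2f / %.2f; wall time %.1f s\n",
                min(x$events$t), max(x$events$t), x$meta$wall_time))
  invisible(x)
}
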