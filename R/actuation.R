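#' Base angle of a driven seta at time t
#'
#' For a symmetric beat (`stroke_asym = 1`) this is the sinusoid
#' `phi(t) = mid + amp * sin(omega t + phase)` with
#' `mid = (phi_max + phi_min)/2` and `amp = (phi_max - phi_min)/2`; the range
#' is exactly `[phi_min, phi_max]` and the angular velocity vanishes smoothly
#' at the two turning ("stopping") points. For `stroke_asym > 1` the same
#' cosine arc is traversed with a time-warped phase, so the power stroke
#' toward `phi_min` is faster than the recovery stroke by that factor while
#' the stopping points stay smooth.
#'
#' @param t time (>= 0).
#' @param spec an [actuation_spec()].
#' @return base angle in radians.
#' @export
base_angle <- function(t, spec) {
  stopifnot(inherits(spec, "actuation_spec"), all(t >= 0))
  mid <- (spec$phi_max + spec$phi_min) / 2
  amp <- (spec$phi_max - spec$phi_min) / 2
  asym <- spec$stroke_asym %||% 1
  u <- (spec$omega * t + spec$phase - pi / 2) %% (2 * pi)
  fd <- 1 / (1 + asym) # fraction of the period spent in the power stroke
  w <- ifelse(u < 2 * pi * fd,
              u / (2 * fd),
              pi + (u - 2 * pi * fd) / (2 * (1 - fd)))
  mid + amp * cos(w)
}

#' Rotate the base segment of a seta to its angle at time t
#'
#' Places node 1 at `base + dR * (0, side * sin(phi), cos(phi))`, with phi
#' measured from +z in the (y,z) plane; the `side` sign mirrors the sweep so
#' both rows rotate toward the mouth midplane y = 0 for negative phi. Nodes
#' with index >= 2 are untouched; the pre-drive node positions are stored so
#' that [relax_chain()] can compute finite-difference velocities over the
#' full step.
#'
#' @param state a [seta_state()].
#' @param t time.
#' @return the updated `seta_kinematic_state`.
#' @export
apply_base_drive <- function(state, t) {
  stopifnot(inherits(state, "seta_kinematic_state"))
  phi <- base_angle(t, state$actuation)
  ch <- state$chain
  state$prev_nodes <- ch$nodes
  ch$nodes[2, ] <- ch$base_point +
    ch$dR * c(0, ch$side * sin(phi), cos(phi))
  state$chain <- ch
  state$current_phi <- phi
  state
}

#' Relax the free nodes of a driven chain
#'
#' Overdamped first-order dynamics `dr/dt = F_elastic / gamma_s` for nodes of
#' index >= 2 (node 0 is clamped at the base, node 1 is set by the drive),
#' advanced over one interval `dt` by a backward-Euler step (Newton solve
#' with a banded Jacobian, unconditionally stable for stiff segments; the
#' interval is bisected automatically in the rare case the Newton iteration
#' stalls). Nodes are reflected at the ground plane z = 0. Node
#' velocities are recorded as finite differences `(r_new - r_old)/dt` against
#' the positions stored by the last [apply_base_drive()], for use by the
#' particle--seta velocity coupling.
#'
#' @param state a [seta_state()] (normally after [apply_base_drive()]).
#' @param dt time interval (> 0).
#' @param gamma_s chain damping constant (> 0).
#' @return the updated state. Errors if any node moves more than `dR` in one
#'   interval (instability: reduce `dt` or increase `gamma_s`).
#' @export
relax_chain <- function(state, dt, gamma_s = 1) {
  stopifnot(inherits(state, "seta_kinematic_state"), dt > 0, gamma_s > 0)
  ch <- state$chain
  res <- cpp_relax_chain(ch$nodes, state$prev_nodes, ch$dR,
                         ch$profile$k_par, ch$profile$k_perp,
                         dt, gamma_s)
  ch$nodes <- res$nodes
  ch$node_vel <- res$velocities
  state$chain <- ch
  state$prev_nodes <- ch$nodes
  state
}
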