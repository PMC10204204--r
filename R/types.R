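#' Per-segment material profile of a seta
#'
#' Holds the longitudinal stiffness `k_par` (per segment), transverse
#' stiffness `k_perp` (acting at each segment's distal node), and the Morse
#' well depth `adhesion_u0` assigned to each segment's distal node (0 means
#' non-adhesive). Scalars are recycled to the segment count.
#'
#' @param n_segments integer number of segments in the chain.
#' @param k_par,k_perp non-negative stiffnesses, scalar or length `n_segments`.
#' @param adhesion_u0 non-negative Morse well depths, scalar or per segment.
#' @return an object of class `segment_profile`.
#' @export
segment_profile <- function(n_segments, k_par, k_perp = k_par, adhesion_u0 = 0) {
  n_segments <- as.integer(n_segments)
  stopifnot(n_segments >= 1)
  rec <- function(v, what) {
    if (length(v) == 1) v <- rep(as.numeric(v), n_segments)
    if (length(v) != n_segments)
      stop(what, " must have length 1 or n_segments (", n_segments, ")")
    if (any(!is.finite(v)) || any(v < 0))
      stop(what, " must be finite and >= 0")
    v
  }
  structure(list(n_segments = n_segments,
                 k_par = rec(k_par, "k_par"),
                 k_perp = rec(k_perp, "k_perp"),
                 adhesion_u0 = rec(adhesion_u0, "adhesion_u0")),
            class = "segment_profile")
}

#' Build a stiffness/adhesion profile from a named material preset
#'
#' `"soft"` uses the soft stiffness everywhere, `"hard"` the hard stiffness,
#' and `"hard_soft_tips"` is hard except for the distal `tip_segments`
#' segments, which are soft. `tip_adhesion` sets the Morse well depth of the
#' distal `tip_segments` nodes.
#'
#' @param n_segments integer number of segments.
#' @param material one of `"soft"`, `"hard"`, `"hard_soft_tips"`.
#' @param tip_adhesion Morse well depth U0 at the tip nodes (0 = none).
#' @param k_hard,k_soft the two stiffness levels (longitudinal = transverse).
#' @param tip_segments how many distal segments count as "tip".
#' @return a [segment_profile()].
#' @export
material_profile <- function(n_segments, material = c("hard", "soft", "hard_soft_tips"),
                             tip_adhesion = 0, k_hard = K_HARD, k_soft = K_SOFT,
                             tip_segments = 2) {
  material <- match.arg(material)
  n_segments <- as.integer(n_segments)
  tip <- seq_len(n_segments) > n_segments - tip_segments
  k <- switch(material,
              soft = rep(k_soft, n_segments),
              hard = rep(k_hard, n_segments),
              hard_soft_tips = ifelse(tip, k_soft, k_hard))
  u0 <- ifelse(tip, tip_adhesion, 0)
  segment_profile(n_segments, k_par = k, k_perp = k, adhesion_u0 = u0)
}

#' Morse adhesion parameters
#'
#' Short-range contact/adhesion law U(r) = u0 (1 - exp(-a (r - r_vdw)))^2
#' with well depth `u0`, inverse range `a`, and minimum position `r_vdw`.
#'
#' @param u0 well depth (>= 0).
#' @param a inverse interaction range (> 0).
#' @param r_vdw position of the potential minimum (> 0).
#' @export
morse_params <- function(u0, a, r_vdw) {
  stopifnot(is.finite(u0), u0 >= 0, is.finite(a), a > 0,
            is.finite(r_vdw), r_vdw > 0)
  structure(list(u0 = u0, a = a, r_vdw = r_vdw), class = "morse_params")
}

#' Base rotation law of a seta
#'
#' The base segment sweeps sinusoidally between `phi_min` (most swept toward
#' the mouth; negative angles point toward the mouth midplane) and `phi_max`,
#' measured from +z in the (y,z) plane. `phi_min` may not pass below the
#' ground plane (-pi/2).
#'
#' With `stroke_asym = 1` the sweep is a pure sinusoid. Larger values give a
#' ciliary-style beat: the power stroke (toward `phi_min`, i.e. toward the
#' mouth) takes `1/(1 + stroke_asym)` of the period and the recovery stroke
#' the rest, with smooth zero-velocity stopping points at both limits.
#'
#' @param phi_min,phi_max sweep limits in radians, `phi_min < phi_max`.
#' @param omega angular frequency of the back-and-forth sweep (> 0).
#' @param phase initial phase in radians.
#' @param stroke_asym ratio of recovery-stroke to power-stroke duration
#'   (>= 1; 1 = symmetric sinusoid).
#' @export
actuation_spec <- function(phi_min, phi_max, omega = 1, phase = 0,
                           stroke_asym = 1) {
  stopifnot(is.finite(phi_min), is.finite(phi_max), is.finite(omega),
            is.finite(phase), omega > 0, is.finite(stroke_asym),
            stroke_asym >= 1)
  if (!(phi_min < phi_max)) stop("phi_min must be < phi_max")
  if (phi_min < -pi / 2)
    stop("phi_min below -pi/2: the base segment cannot pass below the ground plane")
  structure(list(phi_min = phi_min, phi_max = phi_max,
                 omega = omega, phase = phase, stroke_asym = stroke_asym),
            class = "actuation_spec")
}

#' Construct a single seta chain
#'
#' Builds an ordered chain of `n_segments + 1` nodes of rest spacing `dR`,
#' clamped at `base_point` on the ground plane, laid out straight along the
#' direction given by angle `phi` (from +z, in the (y,z) plane, mirrored by
#' `side` so both rows sweep toward the mouth midplane y = 0).
#'
#' @param base_point numeric length-3 attachment point (z must be 0).
#' @param n_segments number of segments (15 for long setae, 7 for short).
#' @param profile a [segment_profile()]; defaults to a uniform hard profile.
#' @param dR segment rest length (the model length unit).
#' @param side +1 or -1: which side of the mouth midplane the row sits on.
#' @param phi initial base angle in radians.
#' @return an object of class `seta_chain` with node positions (a
#'   `(n_segments+1) x 3` matrix), finite-difference node velocities, and the
#'   material profile.
#' @export
seta_chain <- function(base_point, n_segments, profile = NULL, dR = 1,
                       side = 1, phi = 0) {
  base_point <- as.numeric(base_point)
  stopifnot(length(base_point) == 3, all(is.finite(base_point)),
            dR > 0, side %in% c(-1, 1))
  if (abs(base_point[3]) > 1e-12)
    stop("seta base must sit on the ground plane z = 0")
  n_segments <- as.integer(n_segments)
  if (is.null(profile)) profile <- segment_profile(n_segments, K_HARD)
  if (profile$n_segments != n_segments)
    stop("profile segment count does not match n_segments")
  dir <- c(0, side * sin(phi), cos(phi))
  nodes <- t(vapply(0:n_segments, function(j) base_point + j * dR * dir,
                    numeric(3)))
  structure(list(base_point = base_point, n_segments = n_segments, dR = dR,
                 nodes = nodes, node_vel = matrix(0, n_segments + 1, 3),
                 profile = profile, side = side),
            class = "seta_chain")
}

#' Kinematic state of one driven seta
#'
#' Pairs a [seta_chain()] with its [actuation_spec()] and the current base
#' angle, for use with [apply_base_drive()] and [relax_chain()].
#'
#' @param chain a [seta_chain()].
#' @param actuation an [actuation_spec()].
#' @param phi current base angle; defaults to the angle at t = 0.
#' @export
seta_state <- function(chain, actuation, phi = base_angle(0, actuation)) {
  stopifnot(inherits(chain, "seta_chain"), inherits(actuation, "actuation_spec"))
  structure(list(chain = chain, actuation = actuation, current_phi = phi,
                 prev_nodes = chain$nodes),
            class = "seta_kinematic_state")
}

#' @export
print.seta_chain <- function(x, ...) {
  cat(sprintf("<seta_chain> %d segments, dR = %g, base (%.2f, %.2f, %.2f), side %+d\n",
              x$n_segments, x$dR, x$base_point[1], x$base_point[2],
              x$base_point[3], x$side))
  adh <- sum(x$profile$adhesion_u0 > 0)
  cat(sprintf("  k_par range [%g, %g], %d adhesive node(s)\n",
              min(x$profile$k_par), max(x$profile$k_par), adh))
  invisible(x)
}
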