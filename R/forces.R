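#' Longitudinal bond force
#'
#' Force on `node_j` from the elastic bond (j,k), derived from the quartic
#' double-well bond potential U(l) = k_par/(8 dR^2) (l^2 - dR^2)^2 with
#' l = |node_j - node_k|. The force is linear with slope `k_par` for small
#' stretch and grows cubically at large stretch, restoring toward l = dR.
#'
#' @param node_j,node_k numeric length-3 node positions (must not coincide).
#' @param dR segment rest length.
#' @param k_par longitudinal stiffness of the bond.
#' @return numeric length-3 force on `node_j`; the force on `node_k` is its
#'   negative.
#' @export
longitudinal_force <- function(node_j, node_k, dR, k_par) {
  cpp_longitudinal_force(as.numeric(node_j), as.numeric(node_k), dR, k_par)
}

#' Transverse (midpoint-restoring) force
#'
#' Returns `k_perp * ((prev + next)/2 - node)`: zero when the node lies at the
#' midpoint of its neighbours. This is the literal per-node restoring form; it
#' is not a pure bending force and may carry a longitudinal component. Inside
#' [chain_elastic_forces()] the same term enters as a potential, which adds
#' momentum-conserving half-reactions on the two neighbours.
#'
#' @param prev,node,next_ numeric length-3 positions of the node and its
#'   neighbours.
#' @param k_perp transverse stiffness.
#' @export
transverse_force <- function(prev, node, next_, k_perp) {
  cpp_transverse_force(as.numeric(prev), as.numeric(node), as.numeric(next_),
                       k_perp)
}

#' All elastic forces on a chain
#'
#' Exact negative gradient of the chain's elastic energy: the sum over bonds
#' of the quartic double-well longitudinal potential plus, for every interior
#' node, a quadratic penalty on its deviation from the midpoint of its
#' neighbours (stiffness `k_perp` of the segment whose distal node it is).
#' Forces are returned for every node, including the clamped base node 0
#' (whose position the integrators never update); for an isolated unclamped
#' chain they sum to zero.
#'
#' @param chain a [seta_chain()].
#' @return `(n_segments + 1) x 3` matrix of per-node forces.
#' @export
chain_elastic_forces <- function(chain) {
  stopifnot(inherits(chain, "seta_chain"))
  cpp_chain_elastic_forces(chain$nodes, chain$dR,
                           chain$profile$k_par, chain$profile$k_perp)
}

#' Viscous particle--seta velocity coupling
#'
#' Hydrodynamic surrogate: the force on a particle is
#' `sum_j gamma_seta (v_j - p_vel) exp(-|p_pos - r_j| / r_f)` over the chain
#' nodes, pulling the particle velocity toward the local filament velocity
#' with exponentially decaying weight. Pairs beyond `r_cut` may be skipped;
#' the default cutoff keeps the neglected weight below 1e-4.
#'
#' @param p_pos,p_vel particle position and velocity (length 3).
#' @param seg_positions,seg_velocities `n x 3` matrices of node positions and
#'   velocities.
#' @param gamma_seta coupling strength.
#' @param r_f exponential decay length.
#' @param r_cut cutoff radius; `Inf` disables the cutoff.
#' @export
flow_coupling_force <- function(p_pos, p_vel, seg_positions, seg_velocities,
                                gamma_seta, r_f,
                                r_cut = r_f * log(1e4)) {
  seg_positions <- rbind(seg_positions)
  seg_velocities <- rbind(seg_velocities)
  stopifnot(nrow(seg_positions) == nrow(seg_velocities))
  if (!is.finite(r_cut)) r_cut <- -1
  cpp_flow_coupling_force(as.numeric(p_pos), as.numeric(p_vel),
                          seg_positions, seg_velocities, gamma_seta, r_f, r_cut)
}

#' Coupling of a particle to the uniform external flow
#'
#' @param p_vel particle velocity.
#' @param v_ext external flow velocity.
#' @param gamma_ext coupling strength.
#' @return `gamma_ext * (v_ext - p_vel)`.
#' @export
external_flow_force <- function(p_vel, v_ext, gamma_ext) {
  gamma_ext * (as.numeric(v_ext) - as.numeric(p_vel))
}

#' Morse adhesion force on a particle
#'
#' Negative gradient of U(r) = u0 (1 - exp(-a (r - r_vdw)))^2 at the
#' particle--node distance r: attractive for r > r_vdw, repulsive for
#' r < r_vdw, zero at the minimum.
#'
#' @param p_pos particle position.
#' @param node_pos adhesive node position (must not coincide with `p_pos`).
#' @param params a [morse_params()].
#' @export
morse_force <- function(p_pos, node_pos, params) {
  stopifnot(inherits(params, "morse_params"))
  cpp_morse_force(as.numeric(p_pos), as.numeric(node_pos),
                  params$u0, params$a, params$r_vdw)
}
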