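# Small builders shared across test files. All fixtures are generated in
# code; nothing is read from disk.

rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

random_rotation <- function() {
  # QR of a random Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# central-difference gradient of a scalar potential of one 3-vector argument
num_grad <- function(f, x, h = 1e-6) {
  vapply(1:3, function(i) {
    e <- numeric(3); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, 0)
}

# longitudinal double-well bond potential (oracle form)
u_long <- function(rj, rk, dR, k) {
  l2 <- sum((rj - rk)^2)
  k / (8 * dR^2) * (l2 - dR^2)^2
}

u_morse <- function(r, u0, a, rv) u0 * (1 - exp(-a * (r - rv)))^2

# a small straight test chain along an arbitrary direction
make_chain <- function(n = 5, k = 50, dR = 1, dir = c(0, 0, 1), u0_tip = 0) {
  dir <- dir / sqrt(sum(dir^2))
  prof <- segment_profile(n, k, k, c(rep(0, n - 2), u0_tip, u0_tip))
  ch <- seta_chain(c(0, 0, 0), n, prof, dR = dR, side = 1, phi = 0)
  ch$nodes <- t(vapply(0:n, function(j) j * dR * dir, numeric(3)))
  ch
}

# minimal fast configuration (2 setae per short row, few particles)
tiny_config <- function(short = TRUE, long = FALSE, n_particles = 8,
                        t_end = 2, ...) {
  sr <- if (short) row_spec("short", n_setae = 2) else NULL
  lr <- if (long) row_spec("long", n_setae = 2) else NULL
  simulation_config(short_row = sr, long_row = lr,
                    run.n_particles = n_particles, run.t_end = t_end, ...)
}
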