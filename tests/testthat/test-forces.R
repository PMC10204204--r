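test_that("longitudinal force vanishes at rest length and restores toward it", {
  dR <- 1.3
  a <- c(0.2, -0.4, 1.1)
  dir <- c(1, 2, -2) / 3
  expect_equal(longitudinal_force(a + dR * dir, a, dR, 7), c(0, 0, 0),
               tolerance = 1e-12)
  # linearization slope k_par: |F| / eps -> k_par as eps -> 0
  k <- 11
  slopes <- vapply(c(1e-3, 1e-4, 1e-5), function(eps) {
    f <- longitudinal_force(a + (dR + eps) * dir, a, dR, k)
    sqrt(sum(f^2)) / eps
  }, 0)
  expect_equal(slopes[3], k, tolerance = 1e-4)
  expect_true(abs(slopes[3] - k) < abs(slopes[1] - k) + 1e-9)
})

test_that("longitudinal force at l = 2 dR has magnitude 3 k dR and pulls inward", {
  dR <- 0.8; k <- 5
  rk <- c(1, 1, 1); dir <- rand_unit()
  rj <- rk + 2 * dR * dir
  f <- longitudinal_force(rj, rk, dR, k)
  expect_equal(sqrt(sum(f^2)), 3 * k * dR, tolerance = 1e-10)
  expect_lt(sum(f * dir), 0) # compressive: directed from j toward k
  # cross-check against central differences of the double-well potential
  g <- num_grad(function(x) u_long(x, rk, dR, k), rj)
  expect_equal(f, -g, tolerance = 1e-5)
})

test_that("coincident nodes are rejected", {
  expect_error(longitudinal_force(c(1, 2, 3), c(1, 2, 3), 1, 1), "coincident")
  expect_error(morse_force(c(0, 0, 0), c(0, 0, 0), morse_params(1, 2, 0.5)),
               "coincident")
})

test_that("transverse force is midpoint restoration", {
  # collinear equidistant nodes -> zero
  p <- c(0, 0, 0); n <- c(1, 1, 1); q <- c(2, 2, 2)
  expect_equal(transverse_force(p, n, q, 3), c(0, 0, 0))
  # perpendicular displacement d -> force k*|d| back toward the line
  d <- c(0, 0.3, -0.2)
  f <- transverse_force(p, n + d, q, 3)
  expect_equal(f, -3 * d, tolerance = 1e-12)
  # k_perp = 0 -> zero for any geometry
  expect_equal(transverse_force(rnorm(3), rnorm(3), rnorm(3), 0), c(0, 0, 0))
})

test_that("chain elastic forces: straight chain at rest is force-free", {
  ch <- make_chain(6, k = 40, dir = c(0.3, -0.5, 1))
  f <- chain_elastic_forces(ch)
  expect_equal(max(abs(f)), 0, tolerance = 1e-12)
})

test_that("uniformly stretched chain: interior cancels, ends pulled inward", {
  n <- 5; dR <- 1; k <- 20; eps <- 0.05
  ch <- make_chain(n, k, dR)
  ch$nodes <- ch$nodes * (1 + eps) # all bonds at dR*(1+eps) along +z
  f <- chain_elastic_forces(ch)
  expect_equal(max(abs(f[2:n, ])), 0, tolerance = 1e-10)
  expect_lt(f[n + 1, 3], 0)  # end node pulled back toward the chain
  expect_gt(f[1, 3], 0)
})

test_that("bend at one interior node acts locally", {
  n <- 7
  ch <- make_chain(n, k = 30)
  m <- 4 # displace node index m (0-based: nodes row m+1)
  ch$nodes[m + 1, 1] <- ch$nodes[m + 1, 1] + 1e-3
  # the per-node midpoint-restoring force is nonzero exactly at the three
  # nodes whose neighbour stencil contains the displaced node
  tf <- vapply(1:(n - 1), function(j)
    sqrt(sum(transverse_force(ch$nodes[j, ], ch$nodes[j + 1, ],
                              ch$nodes[j + 2, ], 30)^2)), 0)
  expect_setequal(which(tf > 1e-12), c(m - 1, m, m + 1))
  # the full chain gradient adds the momentum-conserving reactions, which
  # reach one node further on each side and no further
  f <- chain_elastic_forces(ch)
  touched <- which(rowSums(abs(f)) > 1e-12) - 1
  expect_true(all(touched %in% (m - 2):(m + 2)))
  expect_gte(sqrt(sum(f[m + 1, ]^2)), max(abs(f[-(m + 1), ])))
})

test_that("chain forces are a consistent gradient: antisymmetry and zero total force", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    ch <- make_chain(n, k = runif(1, 5, 200))
    ch$nodes <- ch$nodes + matrix(rnorm(3 * (n + 1), sd = 0.2), n + 1, 3)
    f <- chain_elastic_forces(ch)
    expect_lt(max(abs(colSums(f))), 1e-10)
  }
})

test_that("bond forces on the two nodes are equal and opposite", {
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    f1 <- longitudinal_force(a, b, 1, 13)
    f2 <- longitudinal_force(b, a, 1, 13)
    expect_equal(f1, -f2, tolerance = 1e-12)
  }
})

test_that("forces equal minus the numerical gradient of their potentials", {
  set.seed(11)
  dR <- 1
  for (i in 1:100) {
    k <- runif(1, 1, 100)
    rj <- rnorm(3); rk <- rj + runif(1, 0.4, 2.5) * rand_unit()
    f <- longitudinal_force(rj, rk, dR, k)
    g <- num_grad(function(x) u_long(x, rk, dR, k), rj, h = 1e-6 * dR)
    expect_equal(f, -g, tolerance = 1e-6 * max(1, sqrt(sum(g^2))))
    mp <- morse_params(runif(1, 0.5, 5), runif(1, 1, 4), runif(1, 0.3, 1))
    p <- rnorm(3); q <- p + runif(1, 0.4, 3) * rand_unit()
    fm <- morse_force(p, q, mp)
    gm <- num_grad(function(x) u_morse(sqrt(sum((x - q)^2)), mp$u0, mp$a,
                                       mp$r_vdw), p, h = 1e-6 * dR)
    expect_equal(fm, -gm, tolerance = 1e-6 * max(1, sqrt(sum(gm^2))))
  }
})

test_that("force laws are rotationally invariant", {
  set.seed(3)
  for (i in 1:10) {
    rot <- random_rotation()
    a <- rnorm(3); b <- a + runif(1, 0.5, 2) * rand_unit()
    f <- longitudinal_force(a, b, 1, 17)
    fr <- longitudinal_force(as.numeric(rot %*% a), as.numeric(rot %*% b), 1, 17)
    expect_equal(fr, as.numeric(rot %*% f), tolerance = 1e-9)
    mp <- morse_params(2, 2, 0.5)
    fm <- morse_force(a, b, mp)
    fmr <- morse_force(as.numeric(rot %*% a), as.numeric(rot %*% b), mp)
    expect_equal(fmr, as.numeric(rot %*% fm), tolerance = 1e-9)
    n <- 5
    ch <- make_chain(n, 25)
    ch$nodes <- ch$nodes + matrix(rnorm(3 * (n + 1), sd = 0.15), n + 1, 3)
    f1 <- chain_elastic_forces(ch)
    ch2 <- ch
    ch2$nodes <- ch$nodes %*% t(rot)
    f2 <- chain_elastic_forces(ch2)
    expect_equal(f2, f1 %*% t(rot), tolerance = 1e-9)
  }
})

test_that("Morse force: zero at the minimum, sign flip across r_vdw, decay at range", {
  mp <- morse_params(2.5, 2, 0.6)
  p0 <- c(1, -2, 0.5)
  dir <- rand_unit()
  at <- function(r) morse_force(p0 + r * dir, p0, mp)
  expect_equal(at(mp$r_vdw), c(0, 0, 0), tolerance = 1e-12)
  del <- 0.05
  expect_gt(sum(at(mp$r_vdw - del) * dir), 0)  # repulsive inside
  expect_lt(sum(at(mp$r_vdw + del) * dir), 0)  # attractive outside
  expect_lt(sqrt(sum(at(mp$r_vdw + 20 / mp$a)^2)), 1e-7)
  # u0 = 0 -> zero everywhere
  expect_equal(morse_force(c(1, 1, 1), c(0, 0, 0), morse_params(0, 2, 0.5)),
               c(0, 0, 0))
})

test_that("flow coupling equilibrates velocities with exponential distance weight", {
  gp <- 1.7; rf <- 1.5
  pos <- matrix(rnorm(15), 5, 3)
  vel <- matrix(rnorm(15), 5, 3)
  p <- c(0, 0, 0)
  # particle moving with every segment -> zero force
  vsame <- vel[1, ]
  expect_equal(flow_coupling_force(pos[1, ], vsame, pos[1, , drop = FALSE],
                                   rbind(vsame), gp, rf), c(0, 0, 0))
  # single segment at distance 0 with relative velocity u -> gamma * u
  u <- c(0.4, -1, 2)
  expect_equal(flow_coupling_force(p, c(0, 0, 0), rbind(p), rbind(u), gp, rf),
               gp * u, tolerance = 1e-12)
  # at distance r_f the weight is exp(-1)
  q <- p + rf * rand_unit()
  expect_equal(flow_coupling_force(p, c(0, 0, 0), rbind(q), rbind(u), gp, rf),
               gp * exp(-1) * u, tolerance = 1e-12)
})

test_that("flow-coupling cutoff changes the force by less than 1e-3 relative", {
  set.seed(5)
  rf <- 1.5
  for (i in 1:20) {
    pos <- matrix(runif(60, -12, 12), 20, 3)
    vel <- matrix(rnorm(60), 20, 3)
    p <- runif(3, -12, 12); v <- rnorm(3)
    full <- flow_coupling_force(p, v, pos, vel, 1, rf, r_cut = Inf)
    cut <- flow_coupling_force(p, v, pos, vel, 1, rf)
    expect_lt(sqrt(sum((full - cut)^2)), 1e-3 * max(1, sqrt(sum(full^2))))
  }
})

test_that("external flow force is linear drag toward v_ext", {
  expect_equal(external_flow_force(c(1.2, 0, 0), c(1.2, 0, 0), 0.5), c(0, 0, 0))
  expect_equal(external_flow_force(c(0, 0, 0), c(1.2, 0, 0), 0.7),
               0.7 * c(1.2, 0, 0))
  expect_equal(external_flow_force(rnorm(3), rnorm(3), 0), c(0, 0, 0))
})
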