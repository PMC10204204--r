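test_that("initialization places particles in the domain moving with the flow", {
  cfg <- tiny_config(n_particles = 50)
  st <- initialize_simulation(cfg, 123)
  p <- st$particles$pos
  expect_equal(nrow(p), 50)
  expect_true(all(p[, 1] >= 0 & p[, 1] <= cfg$world$L_x))
  expect_true(all(abs(p[, 2]) <= cfg$world$L_y))
  expect_true(all(p[, 3] >= 0 & p[, 3] <= cfg$world$L_z))
  expect_true(all(st$particles$vel[, 1] == 1.2))
  expect_true(all(st$particles$vel[, 2:3] == 0))
  # same seed twice -> identical state
  st2 <- initialize_simulation(cfg, 123)
  expect_identical(st$particles$pos, st2$particles$pos)
  expect_identical(st$setae[[1]]$chain$nodes, st2$setae[[1]]$chain$nodes)
})

test_that("setae are built straight at their initial base angle with dR spacing", {
  cfg <- tiny_config()
  st <- initialize_simulation(cfg, 9)
  for (ss in st$setae) {
    bl <- sqrt(rowSums(diff(ss$chain$nodes)^2))
    expect_equal(bl, rep(cfg$world$dR, ss$chain$n_segments), tolerance = 1e-9)
    expect_equal(ss$chain$nodes[1, ], ss$chain$base_point)
  }
})

test_that("a free particle relaxes exponentially toward the external flow", {
  cfg <- tiny_config(short = FALSE, n_particles = 1)
  st <- initialize_simulation(cfg, 1)
  st$particles$pos[1, ] <- c(5, 0, 10)
  st$particles$vel[1, ] <- c(0, 0, 0)
  dt <- cfg$run$dt
  rate <- cfg$coupling$gamma_ext / cfg$coupling$particle_mass
  v <- 0
  for (i in 1:400) {
    st <- particle_step(st, dt)
    # discrete-time closed form of the linear drag update
    v <- v + dt * rate * (1.2 - v)
    expect_equal(st$particles$vel[1, 1], v, tolerance = 1e-12)
  }
  expect_equal(st$particles$vel[1, 1], 1.2 * (1 - (1 - dt * rate)^400),
               tolerance = 1e-9)
  expect_true(st$particles$vel[1, 1] < 1.2) # monotone approach from below
})

test_that("particle at v_ext with no setae advects in a straight line", {
  cfg <- tiny_config(short = FALSE, n_particles = 1)
  st <- initialize_simulation(cfg, 1)
  st$particles$pos[1, ] <- c(2, 3, 4)
  for (i in 1:100) st <- particle_step(st, 0.01)
  expect_equal(st$particles$pos[1, ], c(2 + 1.2, 3, 4), tolerance = 1e-9)
})

test_that("boundary handling reinjects leavers upstream with flow velocity", {
  cfg <- tiny_config(short = FALSE, n_particles = 3)
  st <- initialize_simulation(cfg, 5)
  st$particles$pos[1, ] <- c(cfg$world$L_x + 1, 0, 5)  # left downstream
  st$particles$pos[2, ] <- c(10, 0, 5)                  # inside
  st$particles$pos[3, ] <- c(10, cfg$world$L_y + 2, 5)  # left sideways
  inside_before <- st$particles$pos[2, ]
  st <- handle_boundaries(st)
  p <- st$particles$pos
  expect_equal(p[2, ], inside_before)
  for (i in c(1, 3)) {
    expect_lte(p[i, 1], cfg$run$injection_frac * cfg$world$L_x)
    expect_gte(p[i, 1], 0)
    expect_equal(st$particles$vel[i, ], c(1.2, 0, 0))
  }
  # reproducible given the seed
  st2 <- initialize_simulation(cfg, 5)
  st2$particles$pos <- rbind(c(cfg$world$L_x + 1, 0, 5), c(10, 0, 5),
                             c(10, cfg$world$L_y + 2, 5))
  st2 <- handle_boundaries(st2)
  expect_identical(st$particles$pos, st2$particles$pos)
})

test_that("capture uses a half-open mouth box and particle-index order", {
  cfg <- tiny_config(short = FALSE, n_particles = 4)
  st <- initialize_simulation(cfg, 2)
  w <- st$world
  center <- (w$mouth_lo + w$mouth_hi) / 2
  on_max_x_face <- c(w$mouth_hi[1], center[2], center[3])
  st$particles$pos[1, ] <- center
  st$particles$pos[2, ] <- on_max_x_face   # exactly on max face: not eaten
  st$particles$pos[3, ] <- center + c(0.1, 0, 0)
  st$particles$pos[4, ] <- c(5, 10, 10)
  st$t <- 7
  st <- capture_check(st)
  expect_equal(st$n_eaten, 2L)
  expect_equal(st$events$particle, c(1L, 3L)) # index order, same timestamp
  expect_equal(st$events$t, c(7, 7))
  expect_equal(st$particles$pos[2, ], on_max_x_face)
})

test_that("run contract: t_end 0, event-log consistency, monotone staircase", {
  cfg <- tiny_config(n_particles = 10)
  r0 <- run_simulation(cfg, 3, t_end = 0)
  expect_equal(r0$n_eaten, 0L)
  expect_equal(nrow(r0$events), 0L)
  r <- run_simulation(cfg, 3, t_end = 5)
  expect_equal(nrow(r$events), r$n_eaten)
  expect_true(all(diff(r$series$n_eaten) >= 0))
  expect_equal(r$series$n_eaten[nrow(r$series)], r$n_eaten)
  # particle count conserved
  expect_equal(nrow(r$final_state$particles$pos), 10)
})

test_that("identical (config, seed) give bit-identical runs; prefixes agree", {
  cfg <- tiny_config(n_particles = 12, t_end = 4)
  a <- run_simulation(cfg, 11)
  b <- run_simulation(cfg, 11)
  expect_identical(a$events, b$events)
  expect_identical(a$final_state$particles$pos, b$final_state$particles$pos)
  expect_identical(a$density_yz, b$density_yz)
  # doubling t_end reproduces the first half exactly
  long <- run_simulation(cfg, 11, t_end = 8)
  expect_identical(long$events[long$events$t <= 4 + 1e-12, ], a$events)
  half <- long$series[long$series$t <= 4 + 1e-9, ]
  expect_identical(half$n_eaten, a$series$n_eaten)
})

test_that("compiled stepper matches the composite R step operations", {
  cfg <- tiny_config(n_particles = 6, run.t_burn = 0)
  # place the mouth so a capture + reinjection happens during the window
  stR <- initialize_simulation(cfg, 21)
  stC <- initialize_simulation(cfg, 21)
  dt <- cfg$run$dt
  n <- 40
  stC <- advance_simulation(stC, n * dt)
  for (i in 1:n) stR <- step_simulation(stR)
  expect_equal(stR$particles$pos, stC$particles$pos, tolerance = 1e-10)
  expect_equal(stR$particles$vel, stC$particles$vel, tolerance = 1e-10)
  expect_equal(stR$setae[[1]]$chain$nodes, stC$setae[[1]]$chain$nodes,
               tolerance = 1e-10)
  expect_equal(stR$n_eaten, stC$n_eaten)
  expect_equal(stR$density, stC$density)
})

test_that("no spontaneous transport: still water, no setae, nobody is eaten", {
  cfg <- tiny_config(short = FALSE, n_particles = 30, t_end = 10,
                     world.v_ext = c(0, 0, 0))
  st <- initialize_simulation(cfg, 8)
  # move any particle that happened to start inside the mouth out of it
  w <- st$world
  inside <- st$particles$pos[, 1] >= w$mouth_lo[1] &
    st$particles$pos[, 1] < w$mouth_hi[1] &
    st$particles$pos[, 2] >= w$mouth_lo[2] &
    st$particles$pos[, 2] < w$mouth_hi[2] &
    st$particles$pos[, 3] < w$mouth_hi[3]
  st$particles$pos[inside, 3] <- w$mouth_hi[3] + 1
  st <- advance_simulation(st, 10)
  expect_equal(st$n_eaten, 0L)
})

test_that("halving dt changes the reference capture count by less than 10%", {
  finals <- sapply(1:5, function(s) {
    cfg1 <- simulation_config(run.t_end = 60)
    cfg2 <- simulation_config(run.t_end = 60, run.dt = 0.005)
    c(run_simulation(cfg1, s)$n_eaten, run_simulation(cfg2, s)$n_eaten)
  })
  m <- rowMeans(finals)
  expect_lt(abs(m[1] - m[2]), 0.1 * max(1, m[1]))
})

test_that("periodic-x boundary wraps instead of reinjecting in x", {
  cfg <- tiny_config(short = FALSE, n_particles = 1,
                     world.boundary = "periodic_x")
  st <- initialize_simulation(cfg, 1)
  st$particles$pos[1, ] <- c(cfg$world$L_x - 0.05, 3, 5)
  st$particles$vel[1, ] <- c(1.2, 0, 0)
  st <- advance_simulation(st, 0.1)
  expect_lt(st$particles$pos[1, 1], 1)
  expect_equal(st$particles$pos[1, 2], 3, tolerance = 0.01)
})

test_that("mouth outside the domain is rejected at configuration time", {
  expect_error(simulation_config(world.mouth.L_mouth_y = 30), "mouth")
  expect_error(simulation_config(world.mouth.L_mouth_x = 50), "mouth")
})
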