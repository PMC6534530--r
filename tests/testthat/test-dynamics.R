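# Torus kinematics, velocity sums, integration, convergence statistic.

test_that("minimum-image displacement picks the shortest representative", {
  expect_identical(min_image_displacement(c(0.3, 0.3), c(0.3, 0.3)), c(0, 0))
  expect_equal(min_image_displacement(c(0.9, 0.5), c(0.1, 0.5)), c(-0.2, 0))
  expect_equal(min_image_displacement(c(0.1, 0.9), c(0.9, 0.1)),
               c(0.2, -0.2))
  set.seed(21)
  a <- cbind(runif(1e4), runif(1e4)); b <- cbind(runif(1e4), runif(1e4))
  d <- min_image_displacement(a, b)
  expect_lte(max(abs(d)), 0.5)
  expect_true(all(d >= -0.5 & d < 0.5))
})

test_that("two-particle velocities are equal-and-opposite and separating", {
  f <- homogeneous_field(pi / 2)
  m <- force_preset("kc2012")
  st <- particle_state(rbind(c(0.5, 0.4), c(0.5, 0.6)))
  v <- rhs_velocities(st, f, m)
  expect_equal(v[1, ], -v[2, ], tolerance = 1e-15)
  expect_lt(max(abs(v[, 1])), 1e-20)  # vertical up to cos(pi/2) roundoff
  # separation 0.2 along s: f_s > 0 means they repel
  expect_lt(v[1, 2], 0)
  expect_gt(v[2, 2], 0)
  ax <- axis_coefficients(m, 0.2)
  expect_equal(v[1, 2], ax$f_s * (-0.2) / 2, tolerance = 1e-12)
})

test_that("particles beyond the cutoff do not interact", {
  f <- homogeneous_field(pi / 2)
  m <- force_preset("kc2012", cutoff_radius = 0.1)
  st <- particle_state(rbind(c(0.2, 0.5), c(0.8, 0.5)))
  expect_identical(rhs_velocities(st, f, m), matrix(0, 2, 2))
  expect_identical(rhs_velocities_celllist(st, f, m), matrix(0, 2, 2))
})

test_that("cell-list velocities match the brute-force reference", {
  f <- homogeneous_field(pi / 2)
  m <- force_preset("kc2012", cutoff_radius = 0.1)
  for (seed in 1:10) {
    st <- uniform_random_init(200, seed)
    v_ref <- rhs_velocities(st, f, m)
    v_cl <- rhs_velocities_celllist(st, f, m)
    expect_lt(max(abs(v_ref - v_cl)), 1e-12)
  }
  # also on an inhomogeneous field and the oscillator family
  fd <- singular_field(list(singular_point(c(0.5, 0.5), "delta")))
  mo <- force_preset("oscillator2014", cutoff_radius = 0.2)
  st <- uniform_random_init(150, 99)
  expect_lt(max(abs(rhs_velocities(st, fd, mo) -
                    rhs_velocities_celllist(st, fd, mo))), 1e-12)
})

test_that("cell list finds torus-adjacent pairs across the seam", {
  f <- homogeneous_field(pi / 2)
  m <- force_preset("kc2012", cutoff_radius = 0.1)
  st <- particle_state(rbind(c(0.005, 0.005), c(0.995, 0.995)))
  v <- rhs_velocities_celllist(st, f, m, cells_per_side = 10)
  expect_gt(max(abs(v)), 0)  # interaction found despite index distance
  expect_equal(v, rhs_velocities(st, f, m), tolerance = 1e-14)
})

test_that("single particle and invalid cell grids are handled", {
  f <- homogeneous_field(pi / 2)
  m <- force_preset("kc2012", cutoff_radius = 0.1)
  st <- particle_state(matrix(c(0.4, 0.4), 1, 2))
  expect_identical(rhs_velocities_celllist(st, f, m), matrix(0, 1, 2))
  expect_error(rhs_velocities_celllist(st, f, m, cells_per_side = 20),
               "cell edge")
})

test_that("center of mass is conserved on homogeneous fields", {
  f <- homogeneous_field(0.9)
  m <- force_preset("kc2012")
  st <- uniform_random_init(80, 5)
  v <- rhs_velocities(st, f, m)
  expect_lt(max(abs(colMeans(v))), 1e-15)
})

test_that("euler step wraps positions and advances time", {
  f <- homogeneous_field(pi / 2)
  m <- force_preset("kc2012", cutoff_radius = 0.1)
  cfg <- sim_config(dt = 0.2, n_steps = 1)
  # far-apart particles: zero velocity, state unchanged
  st <- particle_state(rbind(c(0.2, 0.2), c(0.7, 0.7)))
  out <- step_particles(st, f, m, cfg)
  expect_equal(out$positions, st$positions)
  expect_equal(out$time, 0.2)
  # wrapping with a manual velocity field
  rhs_const <- function(state, field, model)
    matrix(c(0.1, 0), nrow(state$positions), 2, byrow = TRUE)
  st2 <- particle_state(matrix(c(0.99, 0.5), 1, 2))
  out2 <- step_particles(st2, f, m, cfg, rhs = rhs_const)
  expect_equal(out2$positions[1, ], c(0.01, 0.5), tolerance = 1e-15)
})

test_that("fixed-step Dormand-Prince is higher order than Euler", {
  f <- homogeneous_field(pi / 2)
  m <- force_preset("kc2012")
  st <- uniform_random_init(40, 3)
  # reference: 20 Dormand-Prince substeps at dt/20
  ref <- st
  cfg_fine <- sim_config(dt = 0.01, integrator = "rk_dopri")
  for (i in 1:20) ref <- step_particles(ref, f, m, cfg_fine,
                                        rhs = rhs_velocities)
  e1 <- step_particles(st, f, m, sim_config(dt = 0.2), rhs = rhs_velocities)
  r1 <- step_particles(st, f, m, sim_config(dt = 0.2, integrator = "rk_dopri"),
                       rhs = rhs_velocities)
  err_euler <- max(abs(torus_err(e1$positions, ref$positions)))
  err_dopri <- max(abs(torus_err(r1$positions, ref$positions)))
  expect_lt(err_dopri, err_euler / 10)
})

test_that("tau metric sums minimum-image L1 displacements", {
  p1 <- particle_state(rbind(c(0.1, 0.1), c(0.5, 0.5), c(0.999, 0.3)))
  expect_identical(tau_metric(p1, p1), 0)
  p2 <- particle_state(rbind(c(0.101, 0.098), c(0.5, 0.5), c(0.999, 0.3)))
  expect_equal(tau_metric(p1, p2), 0.003, tolerance = 1e-12)
  # seam crossing counts the short way around
  p3 <- particle_state(rbind(c(0.1, 0.1), c(0.5, 0.5), c(0.001, 0.3)))
  expect_equal(tau_metric(p1, p3), 0.002, tolerance = 1e-12)
  expect_error(tau_metric(p1, particle_state(matrix(0.2, 2, 2))), "differ")
})

test_that("per-particle displacement is tau over N", {
  expect_equal(per_particle_displacement(1.0e-5, 600), 1.0e-5 / 600)
  expect_equal(signif(per_particle_displacement(1.0e-5, 600), 2), 1.7e-8)
})

test_that("integration is deterministic and respects n_steps = 0", {
  f <- homogeneous_field(pi / 2)
  m <- force_preset("kc2012", cutoff_radius = 0.2)
  st <- uniform_random_init(60, 17)
  cfg0 <- sim_config(n_steps = 0)
  expect_identical(integrate_particles(st, f, m, cfg0)$final$positions,
                   st$positions)
  cfg <- sim_config(n_steps = 30, snapshot_every = 10)
  o1 <- integrate_particles(st, f, m, cfg)
  o2 <- integrate_particles(st, f, m, cfg)
  expect_identical(o1$final$positions, o2$final$positions)
  expect_identical(o1$tau_trace, o2$tau_trace)
  expect_length(o1$snapshots, 3)
  expect_equal(o1$final$time, 30 * 0.2)
})

test_that("line configurations are fixed points of the integration", {
  st <- line_configuration(4, 40)
  f <- homogeneous_field(pi / 2)
  m <- force_preset("kc2012")
  out <- integrate_particles(st, f, m, sim_config(n_steps = 100))
  expect_lt(max(abs(torus_err(out$final$positions, st$positions))), 1e-12)
})

test_that("early stopping triggers on the tau threshold", {
  st <- line_configuration(2, 20)  # stationary: tau = 0 after one step
  f <- homogeneous_field(pi / 2)
  m <- force_preset("kc2012")
  out <- integrate_particles(st, f, m,
                             sim_config(n_steps = 500, converge_tol = 1e-14))
  expect_lt(out$steps_run, 5)
})

test_that("translation invariance of trajectories on homogeneous fields", {
  f <- homogeneous_field(pi / 2)
  m <- force_preset("kc2012", cutoff_radius = 0.2)
  st <- uniform_random_init(50, 23)
  z <- c(0.37, 0.81)
  st_shift <- particle_state(st$positions + rep(z, each = 50))
  cfg <- sim_config(n_steps = 50)
  o1 <- integrate_particles(st, f, m, cfg)
  o2 <- integrate_particles(st_shift, f, m, cfg)
  shifted <- o1$final$positions + rep(z, each = 50)
  expect_lt(max(abs(torus_err(o2$final$positions, shifted))), 1e-10)
})

test_that("trajectories are invariant under sign flips of a sampled field", {
  g <- make_angle_map("single_delta", 64)
  # flipping theta -> theta + pi changes s -> -s but not the line field;
  # angles are normalized mod pi so construct the flip through the embedding
  set.seed(31)
  flip <- matrix(sample(c(0, pi), 64 * 64, replace = TRUE), 64, 64)
  g2 <- angle_grid(g$angles + flip)
  expect_equal(g2$angles, g$angles, tolerance = 1e-12)
  f1 <- sampled_field(g); f2 <- sampled_field(g2)
  st <- uniform_random_init(40, 32)
  m <- force_preset("kc-reparam", cutoff_radius = 0.2)
  cfg <- sim_config(n_steps = 10)
  expect_identical(integrate_particles(st, f1, m, cfg)$final$positions,
                   integrate_particles(st, f2, m, cfg)$final$positions)
})

test_that("uniform initial data is reproducible and uniform", {
  s1 <- uniform_random_init(2400, 77)
  s2 <- uniform_random_init(2400, 77)
  expect_identical(s1$positions, s2$positions)
  expect_true(all(s1$positions >= 0 & s1$positions < 1))
  ks <- suppressWarnings(stats::ks.test(s1$positions[, 1], "punif"))
  expect_gt(ks$p.value, 0.01)
  ks2 <- suppressWarnings(stats::ks.test(s1$positions[, 2], "punif"))
  expect_gt(ks2$p.value, 0.01)
})

test_that("circle initial data places particles equiangularly", {
  st <- circle_init(4, c(0.5, 0.5), 0.005)
  expect_equal(st$positions,
               rbind(c(0.505, 0.5), c(0.5, 0.505), c(0.495, 0.5),
                     c(0.5, 0.495)),
               tolerance = 1e-15)
  st2 <- circle_init(600)
  r <- sqrt(rowSums(sweep(st2$positions, 2, c(0.5, 0.5))^2))
  expect_equal(r, rep(0.005, 600), tolerance = 1e-12)
})
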