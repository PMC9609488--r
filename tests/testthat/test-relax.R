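test_that("elasticity maps to bond, angle, and contact stiffnesses", {
  st <- stiffness_from_elasticity(1, 0.3, 1, 1, r0 = 1)
  expect_equal(st$kb, pi / 4)
  expect_equal(st$ktheta / st$kb, 1 / 8) # ratio d^2/8 at equal r0
  st2 <- stiffness_from_elasticity(2, 0.3, 1, 1, r0 = 1)
  expect_gt(st2$kc, st$kc)
  expect_gt(st$kc, 0)
  # standard-inertia switch halves the angle stiffness
  st3 <- stiffness_from_elasticity(1, 0.3, 1, 1, r0 = 1, standard_inertia = TRUE)
  expect_equal(st3$ktheta, st$ktheta / 2)
})

test_that("bond forces are harmonic with the printed factor 2 and reaction symmetry", {
  d <- make_dimer(stretch = 0)
  expect_equal(max(abs(bond_forces(d))), 0)
  d2 <- make_dimer(stretch = 0.3)
  f <- bond_forces(d2)
  expect_equal(f[1, 1], 2 * 1 * 0.3, tolerance = 1e-12) # pulled toward j
  expect_equal(f[1, ] + f[2, ], c(0, 0, 0))
})

test_that("angle forces vanish at equilibrium and sum to zero", {
  # trio with a 90-degree rest angle
  pos <- rbind(c(5, 6, 5), c(5, 5, 5), c(6, 5, 5))
  sys <- make_spheres(pos, radii = rep(0.01, 3))
  sys$angles <- matrix(c(1L, 2L, 3L), 1)
  sys$theta0 <- pi / 2
  sys$ktheta <- 1
  expect_lt(max(abs(angle_forces(sys))), 1e-12)
  # perturbed angle: restoring forces, zero net force, near-zero torque at
  # equal arm lengths
  sys$positions[3, ] <- c(5 + cos(0.2), 5 + sin(0.2), 5)
  f <- angle_forces(sys)
  expect_gt(max(abs(f)), 0)
  expect_lt(max(abs(colSums(f))), 1e-12)
  rij <- sys$positions[1, ] - sys$positions[2, ]
  rkj <- sys$positions[3, ] - sys$positions[2, ]
  torque <- cross3v(rij, f[1, ]) + cross3v(rkj, f[3, ])
  expect_lt(max(abs(torque)), 1e-10)
})


test_that("soft contact force has the sinusoidal profile with a soft core", {
  r <- 0.25
  two <- function(dist) {
    s <- make_spheres(rbind(c(5, 5, 5), c(5 + dist, 5, 5)), radii = c(r, r))
    contact_forces(s)
  }
  rc <- 2 * r
  expect_equal(max(abs(two(rc + 1e-6))), 0)            # zero at cutoff
  expect_equal(max(abs(two(1e-9))), 0, tolerance = 1e-6) # soft core
  # maximum magnitude at half the cutoff
  kc <- 1 / 16 * 0.3^(1 / 3) * sqrt(r)
  f_half <- two(rc / 2)
  # particle 1 sits at lower x, so repulsion pushes it toward -x
  expect_equal(f_half[1, 1], -pi * kc / rc, tolerance = 1e-9)
  expect_gt(abs(f_half[1, 1]), abs(two(0.3 * rc)[1, 1]))
  expect_gt(abs(f_half[1, 1]), abs(two(0.7 * rc)[1, 1]))
})

test_that("Stokes drag is linear in viscosity, diameter, and velocity", {
  s <- make_spheres(matrix(c(5, 5, 5), 1), radii = 0.25)
  s$velocities[1, ] <- c(1, -2, 0.5)
  f1 <- drag_forces(s, 0.4)
  expect_equal(f1[1, ], -3 * pi * 0.4 * 0.5 * c(1, -2, 0.5))
  expect_equal(drag_forces(s, 0.8), 2 * f1)
  s$velocities[] <- 0
  expect_equal(max(abs(drag_forces(s, 0.4))), 0)
})

test_that("percent fiber overlap matches sphere-lens geometry and Monte Carlo", {
  # two equal coincident spheres: lens = one sphere volume -> 50%
  s <- make_spheres(rbind(c(5, 5, 5), c(5, 5, 5 + 1e-12)), radii = c(0.5, 0.5))
  expect_equal(percent_fiber_overlap(s), 50, tolerance = 1e-6)
  s2 <- make_spheres(rbind(c(2, 2, 2), c(8, 8, 8)), radii = c(0.5, 0.5))
  expect_equal(percent_fiber_overlap(s2), 0)

  # random overlapping configuration vs Monte-Carlo pair-overlap volume,
  # sampled over the spheres' tight bounding box
  set.seed(501)
  pos <- 4.5 + matrix(runif(15, 0, 1.2), 5, 3)
  radii <- runif(5, 0.3, 0.6)
  s3 <- make_spheres(pos, radii)
  pfo <- percent_fiber_overlap(s3)
  lens_total <- pfo / 100 * sum(4 / 3 * pi * radii^3)
  lo <- apply(pos - radii, 2, min); hi <- apply(pos + radii, 2, max)
  m <- 2e6
  pts <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]),
               runif(m, lo[3], hi[3]))
  k <- rowSums(vapply(1:5, function(i)
    as.integer(rowSums(sweep(pts, 2, pos[i, ])^2) < radii[i]^2), integer(m)))
  mc <- sum(choose(k, 2)) / m * prod(hi - lo)
  expect_lt(abs(lens_total - mc), 0.01 * mc)
})

test_that("velocity Verlet conserves energy undamped and decays when damped", {
  # free particle moves uniformly
  s <- make_spheres(matrix(c(5, 5, 5), 1), radii = 0.25)
  s$velocities[1, ] <- c(0.1, 0, 0)
  p <- mechanics_params(viscosity = 0, dt = 0.05)
  s2 <- step_velocity_verlet(s, p, n_steps = 100)
  expect_equal(s2$positions[1, 1], 5 + 0.1 * 100 * 0.05, tolerance = 1e-9)

  # undamped stretched dimer: energy conserved to 0.1% over 1e4 steps
  d <- make_dimer(stretch = 0.2)
  pd <- mechanics_params(viscosity = 0, dt = 0.02 * sqrt(1 / d$kb[1]))
  e0 <- system_energy(d, pd)
  d2 <- step_velocity_verlet(d, pd, n_steps = 10000)
  expect_lt(abs(system_energy(d2, pd) - e0) / e0, 0.001)

  # damped free particle: exponential velocity decay at rate 3 pi eta d / m
  sf <- make_spheres(matrix(c(5, 5, 5), 1), radii = 0.25)
  sf$velocities[1, 1] <- 1
  eta <- 0.3
  pf <- mechanics_params(viscosity = eta, dt = 0.01)
  sf2 <- step_velocity_verlet(sf, pf, n_steps = 300)
  expect_equal(sf2$velocities[1, 1], exp(-3 * pi * eta * 0.5 * 3), tolerance = 0.05)
})

test_that("internal forces obey Newton's third law on full networks", {
  set.seed(502)
  spec <- small_spec(phi = 0.08, tau = 1.3, box = 5)
  net <- build_network(spec)
  sys <- discretize_network(net)
  f <- bond_forces(sys) + angle_forces(sys) + contact_forces(sys)
  scale <- max(abs(f))
  expect_lt(max(abs(colSums(f))) / scale, 1e-10)
})

test_that("relaxation removes overlap between crossing fibers and leaves clean networks alone", {
  # two straight crossing fibers through the box center
  mk <- function() {
    spec <- network_spec(6, 0.02, 0.4, 0, 4, 0, tau_mean = 1, tau_std = 0)
    net <- suppressWarnings(build_network(spec))
    net$fibers <- list(
      fiber_path(cbind(seq(1, 5, by = 0.2), 3, 3), 0.4),
      fiber_path(cbind(3, seq(1, 5, by = 0.2), 3.1), 0.4))
    net$prescribed <- realized_fibers(net)[, c("diameter", "length", "tau",
                                               "nx", "ny", "nz")]
    net
  }
  net <- mk()
  p <- mechanics_params(fixed_end_steps = 500, max_steps = 20000,
                        stop_below = 1e-4)
  rx <- relax(net, p)
  expect_lt(tail(rx$pfo_trace$pfo, 1), 0.05 * rx$pfo_trace$pfo[1])

  # a single fiber has no non-excluded overlap: nothing should move
  net1 <- mk()
  net1$fibers <- net1$fibers[1]
  net1$prescribed <- net1$prescribed[1, ]
  rx1 <- relax(net1, mechanics_params(fixed_end_steps = 100, max_steps = 3000))
  expect_equal(max(rx1$pfo_trace$pfo), 0)
  expect_lt(max(rx1$mean_changes), 0.1)
})

test_that("the overlap trace decreases on average and the report has sane fields", {
  set.seed(503)
  spec <- small_spec(phi = 0.15, tau = 1.2, box = 5)
  net <- build_network(spec)
  rx <- relax(net, mechanics_params(fixed_end_steps = 2000, max_steps = 12000))
  tr <- rx$pfo_trace$pfo
  expect_lt(tail(tr, 1), tr[1])
  # monotone-on-average: smoothed trace decreasing after warmup
  sm <- stats::filter(tr, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) < 0.05 * tr[1]))
  expect_named(rx$mean_changes, c("length", "tau", "orientation"))
  expect_true(all(rx$change_report$length_change >= 0))
  expect_equal(nrow(rx$change_report), length(net$fibers))
})
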