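test_that("concentration selector inverts the walk's end-to-end statistics", {
  # independent oracle: solve the same model with plain grid search over
  # rho and an independent Langevin evaluation
  tau <- 1.5
  n <- steps_for_walk(tau, 20)
  rho_grid <- seq(1e-4, 1 - 1e-9, length.out = 2e5)
  tau_grid <- 1 / sqrt(rho_grid^2 + (1 - rho_grid^2) / n) *
    (1 + (1 - rho_grid^2) / (n * rho_grid^2))
  rho_star <- rho_grid[which.min(abs(tau_grid - tau))]
  kap <- kappa_for_tortuosity(1.5)
  expect_equal(1 / tanh(kap) - 1 / kap, rho_star, tolerance = 1e-4)

  # monotone decreasing; diverges toward tau = 1
  expect_gt(kappa_for_tortuosity(1.2), kappa_for_tortuosity(2.0))
  expect_gt(kappa_for_tortuosity(1.001), 1e3)
  expect_error(kappa_for_tortuosity(1), "> 1")
  expect_warning(kappa_for_tortuosity(3.6), "calibrated range")
})

test_that("step-count rules follow the minimum-step and beta-multiplier formulas", {
  expect_identical(min_steps(2), 3L)
  expect_identical(min_steps(1), 2L)   # ceiling of 1.5
  expect_identical(min_steps(3), 6L)   # ceiling of 5.5
  expect_identical(steps_for_walk(2, 20), 60L)
  expect_identical(steps_for_walk(2, 1), min_steps(2))
  expect_identical(steps_for_walk(1.5, 5), 11L)
  expect_error(steps_for_walk(2, 0.5), "beta")
})

test_that("VMF walks have exact step lengths and ideal-chain limits", {
  set.seed(301)
  w <- vmf_walk(2, 40, 0.25, mean_dir = c(0, 0, 1), origin = c(1, 2, 3))
  expect_equal(nrow(w), 41L)
  expect_equal(w[1, ], c(1, 2, 3))
  seg <- sqrt(rowSums(diff(w)^2))
  expect_true(all(abs(seg - 0.25) < 1e-12))

  # high concentration: nearly straight raw path
  ws <- vmf_walk(300, 40, 0.25)
  expect_lt(measure_tortuosity(ws), 1.01)

  # kappa = 0: ideal chain, E[ee^2] = N * step^2
  ee2 <- replicate(1000, {
    w0 <- vmf_walk(0, 30, 1)
    sum((w0[31, ] - w0[1, ])^2)
  })
  expect_equal(mean(ee2), 30, tolerance = 3 * sd(ee2) / sqrt(1000) / 30)
})

test_that("spline smoothing preserves endpoints, spacing, and straight lines", {
  line <- cbind(seq(0, 5, length.out = 6), 0, 0)
  s <- smooth_spline_path(line, 0.2)
  expect_equal(measure_tortuosity(s), 1, tolerance = 1e-9)
  expect_equal(s[1, ], line[1, ])
  expect_equal(s[nrow(s), ], line[6, ])

  set.seed(302)
  raw <- vmf_walk(3, 20, 0.5)
  sm <- smooth_spline_path(raw, 0.1)
  expect_equal(sm[1, ], raw[1, ])
  expect_equal(sm[nrow(sm), ], raw[21, ], tolerance = 1e-9)
  seg <- sqrt(rowSums(diff(sm)^2))
  # interior spacing close to the requested step; ends may differ
  interior <- seg[2:(length(seg) - 2)]
  expect_true(all(interior < 1.6 * 0.1) && all(interior > 0.4 * 0.1))
  expect_error(smooth_spline_path(raw[1:2, ], 0.1), "3 points")
})

test_that("tortuosity measurement matches analytic curves", {
  line <- cbind(seq(0, 1, length.out = 10), 0, 0)
  expect_equal(measure_tortuosity(line), 1)
  # half circle: arc/chord = pi/2
  a <- seq(0, pi, length.out = 181)
  semi <- cbind(cos(a), sin(a), 0)
  expect_equal(measure_tortuosity(semi), pi / 2, tolerance = 1e-3)
  set.seed(303)
  for (i in 1:5) {
    p <- matrix(rnorm(30), 10, 3)
    expect_gte(measure_tortuosity(p), 1)
  }
  expect_error(measure_tortuosity(rbind(c(0, 0, 0), c(1, 1, 1), c(0, 0, 0))),
               "degenerate")
})

test_that("screened fiber generation hits the tortuosity target", {
  # degenerate target: straight fiber without any walk
  f1 <- generate_fiber(5, 1.0)
  expect_equal(f1$tau, 1)
  expect_equal(f1$contour_length, 5, tolerance = 1e-9)

  set.seed(304)
  taus <- replicate(400, generate_fiber(10, 1.5)$tau)
  expect_true(all(abs(taus - 1.5) / 1.5 <= 0.05 + 1e-12))
  expect_lt(abs(mean(taus) - 1.5) / 1.5, 0.01)
})

test_that("unscreened walks recover the target mean tortuosity within 10 percent", {
  set.seed(305)
  for (target in c(1.1, 1.3, 1.7, 2.2)) {
    n <- steps_for_walk(target, 20)
    kap <- kappa_for_tortuosity(target)
    taus <- replicate(500, {
      raw <- vmf_walk(kap, n, 10 / n)
      measure_tortuosity(smooth_spline_path(raw, 10 / n / 4))
    })
    expect_lt(abs(mean(taus) - target) / target, 0.10)
  }
})

test_that("too few steps cap the achievable tortuosity regardless of concentration", {
  set.seed(306)
  target <- 3
  n_low <- min_steps(target) - 2L  # below the minimum
  means <- vapply(c(2, 0.5, 0.1, 0.01), function(kap) {
    mean(replicate(150, measure_tortuosity(
      smooth_spline_path(vmf_walk(kap, n_low, 10 / n_low), 10 / n_low / 4))))
  }, numeric(1))
  # decreasing kappa plateaus below the target
  expect_true(all(means < target))
  expect_lt(abs(means[4] - means[3]) / means[3], 0.10)
})

test_that("a larger step multiplier narrows the realized tortuosity spread", {
  set.seed(307)
  mape <- function(beta) {
    n <- steps_for_walk(1.5, beta)
    kap <- kappa_for_tortuosity(1.5, beta)
    taus <- replicate(250, measure_tortuosity(
      smooth_spline_path(vmf_walk(kap, n, 10 / n), 10 / n / 4)))
    mean(abs(taus - 1.5) / 1.5)
  }
  expect_gt(mape(5), mape(20))
})

test_that("the spline resolution has negligible effect on realized tortuosity", {
  n <- steps_for_walk(1.4, 20)
  kap <- kappa_for_tortuosity(1.4)
  step <- 10 / n
  # common random walks across settings: only the spline step varies
  mean_tau <- vapply(c(step / 2, step / 8, step / 20), function(cs) {
    set.seed(308)
    mean(replicate(200, measure_tortuosity(
      smooth_spline_path(vmf_walk(kap, n, step), cs))))
  }, numeric(1))
  # the residual is the spline-overshoot construction tolerance (finer
  # resampling keeps slightly more of the spline's arc length)
  expect_lt(diff(range(mean_tau)) / mean(mean_tau), 0.03)
})
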