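test_that("gamma moment matching inverts mean and standard deviation", {
  p <- gamma_params_from_moments(2, 1)
  expect_equal(p$k_shape, 4)
  expect_equal(p$theta_scale, 0.5)
  p1 <- gamma_params_from_moments(1, 1) # exponential special case
  expect_equal(p1$k_shape, 1)
  expect_equal(p1$theta_scale, 1)
  expect_error(gamma_params_from_moments(-1, 1), "positive")
  expect_error(gamma_params_from_moments(2, 0), "positive")

  set.seed(101)
  x <- rgamma(1e5, shape = p$k_shape, scale = p$theta_scale)
  expect_lt(abs(mean(x) - 2), 3 * sd(x) / sqrt(1e5))
  expect_lt(abs(sd(x) - 1), 0.02)
})

test_that("truncated lognormal moment matching and sampling respect the tau >= 1 support", {
  p0 <- suppressMessages(lognormal_params_from_moments(1.5, 0))
  expect_equal(p0$m_ln, log(1.5))
  expect_equal(p0$s_ln, 0)
  # frozen from the closed-form moment match at mean 2, sd 1
  p <- suppressMessages(lognormal_params_from_moments(2, 1))
  expect_equal(p$m_ln, 0.5815754, tolerance = 1e-6)
  expect_equal(p$s_ln, 0.4723807, tolerance = 1e-6)
  expect_error(lognormal_params_from_moments(0.9, 0.1), ">= 1")
  expect_message(lognormal_params_from_moments(1.3, 0.2), "truncated")

  set.seed(102)
  x <- sample_trunc_lognormal(p, 2e4)
  expect_true(all(x >= 1))
})

test_that("rejection sampling reproduces uniform, point-mass, and gamma targets", {
  set.seed(103)
  u <- sample_rejection(function(x) rep(1, length(x)),
                        sampling_domain(0, 1), n = 1e4)
  expect_true(all(u >= 0 & u <= 1))
  expect_lt(abs(mean(u) - 0.5), 3 / sqrt(12 * 1e4))

  h <- cbind(center = c(1, 2, 3, 4), value = c(0, 0, 5, 0))
  x <- sample_rejection(h, n = 500)
  expect_true(all(x > 2 & x < 4)) # interpolation spreads into adjacent bins

  # gamma target (shape 4, scale 0.5): mean 2
  dens <- function(x) dgamma(x, shape = 4, scale = 0.5)
  dom <- sampling_domain(0, 2 + 6 * 1)
  g <- sample_rejection(dens, dom, n = 1e5)
  expect_lt(abs(mean(g) - 2), 3 * 1 / sqrt(1e5))
  # two-sample agreement with the direct sampler
  ks <- suppressWarnings(ks.test(g, rgamma(1e5, shape = 4, scale = 0.5)))
  expect_gt(ks$p.value, 0.001)

  expect_error(sample_rejection(function(x) rep(0, length(x)),
                                sampling_domain(0, 1), n = 10), "mass")
})

test_that("3D de la Vallee Poussin sampler matches its density moments", {
  set.seed(104)
  iso <- sample_vp(vp_params(vp_kernel(c(0, 0, 1), 0)), 1e5)
  expect_equal(dim(iso), c(1e5, 3))
  expect_true(all(abs(rowSums(iso^2) - 1) < 1e-12))
  expect_lt(sqrt(sum(colMeans(iso)^2)), 0.01) # mean resultant ~ 0

  v <- sample_vp(vp_params(vp_kernel(c(0, 0, 1), 6)), 1e5)
  # E[(n.m)^2] = (2k+1)/(2k+3) for a single kernel
  expect_equal(mean(v[, 3]^2), 13 / 15, tolerance = 0.005)
  # dominant eigenvector of the second-moment tensor aligns with the axis
  ev <- eigen(crossprod(v) / nrow(v))$vectors[, 1]
  expect_lt(acos(abs(ev[3])) * 180 / pi, 2)
  # antipodal symmetry: all odd moments vanish
  expect_lt(max(abs(colMeans(v))), 0.01)
})

test_that("von Mises-Fisher sampler matches closed-form and quadrature moments", {
  set.seed(105)
  u <- sample_vmf(vmf_params(c(0, 0, 1), 0), 1e5)
  expect_lt(sqrt(sum(colMeans(u)^2)), 0.01)

  v <- sample_vmf(vmf_params(c(0, 0, 1), 5), 1e5)
  meancos_exact <- 1 / tanh(5) - 1 / 5
  # quadrature of the polar marginal agrees with the closed form
  q <- integrate(function(x) x * exp(5 * x), -1, 1)$value /
    integrate(function(x) exp(5 * x), -1, 1)$value
  expect_equal(q, meancos_exact, tolerance = 1e-8)
  expect_equal(mean(v[, 3]), meancos_exact, tolerance = 3 * 0.6 / sqrt(1e5) / 0.6)

  w <- sample_vmf(vmf_params(c(1, 0, 0), 300), 1e4)
  expect_true(all(acos(pmin(1, w[, 1])) < 15 * pi / 180))
})

test_that("2D VP density is normalized on [0, pi) with its mode at the kernel angle", {
  expect_equal(vp_pdf_2d(0.3, list(theta_vp = 1, k2d = 0)), 1 / pi)
  for (k in c(1, 5, 15)) {
    int <- integrate(function(t) vp_pdf_2d(t, list(theta_vp = pi / 2, k2d = k)),
                     0, pi, rel.tol = 1e-10)$value
    expect_equal(int, 1, tolerance = 1e-6)
  }
  th <- seq(0, pi, length.out = 361)
  d <- vp_pdf_2d(th, list(theta_vp = 1.1, k2d = 5))
  expect_equal(th[which.max(d)], 1.1, tolerance = pi / 360)
})

test_that("samplers are reproducible under a fixed seed", {
  set.seed(42); a <- sample_vp(vp_params(vp_kernel(c(0, 0, 1), 3)), 100)
  set.seed(42); b <- sample_vp(vp_params(vp_kernel(c(0, 0, 1), 3)), 100)
  expect_identical(a, b)
  set.seed(42); c1 <- sample_vmf(vmf_params(c(1, 0, 0), 2), 50)
  set.seed(42); c2 <- sample_vmf(vmf_params(c(1, 0, 0), 2), 50)
  expect_identical(c1, c2)
})
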