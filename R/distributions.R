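#' Gamma parameters from mean and standard deviation
#'
#' Moment-matches a gamma distribution to a prescribed mean and standard
#' deviation. Fiber diameters and lengths in stochastic fiber-network models
#' are conventionally gamma distributed; practitioners report the first two
#' moments, from which shape and scale follow as
#' \eqn{k = \langle X\rangle^2 / \mathrm{std}(X)^2} and
#' \eqn{\theta = \mathrm{std}(X)^2 / \langle X\rangle}.
#'
#' @param mean Prescribed mean, > 0.
#' @param std Prescribed standard deviation, > 0.
#' @return An object of class `"gamma_params"`: list with `k_shape` and
#'   `theta_scale`.
#' @examples
#' gamma_params_from_moments(2, 1)  # shape 4, scale 0.5
#' @export
gamma_params_from_moments <- function(mean, std) {
  stopifnot(is.numeric(mean), is.numeric(std), length(mean) == 1L, length(std) == 1L)
  if (!is.finite(mean) || mean <= 0) stop("'mean' must be a positive number")
  if (!is.finite(std) || std <= 0) stop("'std' must be a positive number")
  structure(list(k_shape = mean^2 / std^2, theta_scale = std^2 / mean),
            class = "gamma_params")
}

#' Truncated-lognormal parameters from tortuosity moments
#'
#' Moment-matches a lognormal distribution to a prescribed mean and standard
#' deviation of fiber tortuosity. Because tortuosity is bounded below by 1
#' the distribution is truncated at 1 when sampled, so the moment match is
#' approximate (the approximation is good when the mass below 1 is small);
#' a message records this.
#'
#' @param mean_tau Prescribed mean tortuosity, >= 1.
#' @param std_tau Prescribed standard deviation of tortuosity, >= 0.
#' @return An object of class `"trunc_lognormal_params"`: list with `m_ln`,
#'   `s_ln` and `lower_bound = 1`.
#' @export
lognormal_params_from_moments <- function(mean_tau, std_tau) {
  stopifnot(length(mean_tau) == 1L, length(std_tau) == 1L)
  if (!is.finite(mean_tau) || mean_tau < 1) stop("'mean_tau' must be >= 1")
  if (!is.finite(std_tau) || std_tau < 0) stop("'std_tau' must be >= 0")
  if (std_tau == 0) {
    m_ln <- log(mean_tau); s_ln <- 0
  } else {
    m_ln <- log(mean_tau^2 / sqrt(std_tau^2 + mean_tau^2))
    s_ln <- sqrt(log(std_tau^2 / mean_tau^2 + 1))
    message("lognormal_params_from_moments: distribution is truncated at tau = 1; ",
            "moment match is approximate")
  }
  structure(list(m_ln = m_ln, s_ln = s_ln, lower_bound = 1),
            class = "trunc_lognormal_params")
}

#' Sample fiber tortuosities from a truncated lognormal
#'
#' Samples the lognormal and redraws any value below the truncation bound,
#' so all returned tortuosities are >= 1.
#'
#' @param params A `"trunc_lognormal_params"` object.
#' @param n Number of samples.
#' @return Numeric vector of length `n`, all >= 1.
#' @export
sample_trunc_lognormal <- function(params, n) {
  stopifnot(inherits(params, "trunc_lognormal_params"), n >= 0)
  if (n == 0) return(numeric(0))
  if (params$s_ln == 0) return(rep(exp(params$m_ln), n))
  out <- stats::rlnorm(n, params$m_ln, params$s_ln)
  bad <- out < params$lower_bound
  while (any(bad)) {
    out[bad] <- stats::rlnorm(sum(bad), params$m_ln, params$s_ln)
    bad <- out < params$lower_bound
  }
  out
}

#' Define a scalar sampling domain
#'
#' Builds the `[a, b]` interval used by [sample_rejection()]. For densities
#' with infinite support the convention is `a = mean - 6 sd`,
#' `b = mean + 6 sd`; for finite support the support bounds; for histograms
#' the outer bin edges.
#'
#' @param lower,upper Domain bounds, `lower < upper`.
#' @param source `"density"` or `"histogram"`.
#' @return An object of class `"sampling_domain"`.
#' @export
sampling_domain <- function(lower, upper, source = c("density", "histogram")) {
  source <- match.arg(source)
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    stop("need finite bounds with lower < upper")
  structure(list(lower = lower, upper = upper, source = source),
            class = "sampling_domain")
}

#' Domain implied by a histogram
#'
#' @param hist Two-column histogram (bin centers, values).
#' @return A `"sampling_domain"` spanning the outer bin edges, assuming
#'   equal-width bins.
#' @export
histogram_domain <- function(hist) {
  hist <- as.matrix(hist)
  x <- hist[, 1]
  if (nrow(hist) < 2) stop("histogram needs at least two bins")
  w <- stats::median(diff(x))
  sampling_domain(min(x) - w / 2, max(x) + w / 2, "histogram")
}

# Evaluate a histogram by linear interpolation between bin centers,
# constant extrapolation inside the outer half-bins.
histogram_interpolator <- function(hist) {
  hist <- as.matrix(hist)
  if (any(hist[, 2] < 0)) stop("histogram values must be nonnegative")
  x <- hist[, 1]; y <- hist[, 2]
  function(q) stats::approx(x, y, xout = q, rule = 2)$y
}

#' Rejection sampling from a density or histogram
#'
#' Draws scalar samples from an arbitrary nonnegative target by uniform
#' proposal over a bounded domain: a candidate `X'` uniform on `[a, b]` is
#' accepted when a second uniform draw on `[0, max(target)]` falls below
#' `target(X')`. Histogram targets are evaluated by linear interpolation
#' between bin centers.
#'
#' @param target Either a function (density, not necessarily normalized) or
#'   a two-column matrix/data frame of (bin center, value) histogram data.
#' @param domain A `"sampling_domain"`; defaults to the histogram's own
#'   domain when `target` is a histogram.
#' @param n Number of samples.
#' @param max_target Optional known maximum of the target over the domain;
#'   computed on a fine grid if omitted.
#' @return Numeric vector of `n` samples in `[a, b]`.
#' @export
sample_rejection <- function(target, domain = NULL, n = 1L, max_target = NULL) {
  if (!is.function(target)) {
    hist <- as.matrix(target)
    if (is.null(domain)) domain <- histogram_domain(hist)
    f <- histogram_interpolator(hist)
    if (is.null(max_target)) max_target <- max(hist[, 2])
  } else {
    if (is.null(domain)) stop("a sampling domain is required for density targets")
    f <- target
    if (is.null(max_target)) {
      grid <- seq(domain$lower, domain$upper, length.out = 4096L)
      fg <- f(grid)
      i <- which.max(fg)
      lo <- grid[max(1L, i - 2L)]; hi <- grid[min(length(grid), i + 2L)]
      max_target <- max(fg[i],
                        stats::optimize(f, c(lo, hi), maximum = TRUE)$objective)
    }
  }
  if (!is.finite(max_target)) stop("target is unbounded on the domain")
  if (max_target <= 0) stop("target has no mass on the domain")
  a <- domain$lower; b <- domain$upper
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 64L)
    x <- stats::runif(m, a, b)
    p <- stats::runif(m, 0, max_target)
    fx <- f(x)
    if (any(fx > max_target * 1.001))
      stop("target exceeds its stated maximum on the domain")
    acc <- x[p < fx]
    take <- min(length(acc), n - got)
    if (take > 0) {
      out[(got + 1L):(got + take)] <- acc[seq_len(take)]
      got <- got + take
    }
  }
  out
}

#' de la Vallee Poussin kernel
#'
#' One kernel of the antipodally symmetric de la Vallee Poussin (VP)
#' orientation distribution on the unit sphere,
#' \eqn{p(\hat n) = \frac{2k+1}{4\pi} (\hat n\cdot\hat m)^{2k}}.
#' `k3d = 0` is isotropic; larger `k3d` concentrates mass along the mean
#' axis \eqn{\pm\hat m}.
#'
#' @param mean_axis Unit 3-vector (normalized internally).
#' @param k3d Orientation strength, >= 0.
#' @return An object of class `"vp_kernel"`.
#' @export
vp_kernel <- function(mean_axis, k3d) {
  mean_axis <- as.numeric(mean_axis)
  if (length(mean_axis) != 3 || !all(is.finite(mean_axis)))
    stop("'mean_axis' must be a finite 3-vector")
  nrm <- sqrt(sum(mean_axis^2))
  if (nrm == 0) stop("'mean_axis' must be nonzero")
  if (!is.finite(k3d) || k3d < 0) stop("'k3d' must be >= 0")
  structure(list(mean_axis = mean_axis / nrm, k3d = k3d), class = "vp_kernel")
}

#' Superposed de la Vallee Poussin orientation distribution
#'
#' A mixture of VP kernels with equal weights; one kernel models transverse
#' isotropy, two orthotropy, three hexagonal symmetry.
#'
#' @param kernels List of [vp_kernel()] objects (or a single kernel).
#' @return An object of class `"vp_params"` with elements `kernels` and `n_vp`.
#' @export
vp_params <- function(kernels) {
  if (inherits(kernels, "vp_kernel")) kernels <- list(kernels)
  stopifnot(length(kernels) >= 1, all(vapply(kernels, inherits, TRUE, "vp_kernel")))
  structure(list(kernels = kernels, n_vp = length(kernels)), class = "vp_params")
}

#' VP mixture density on the unit sphere
#'
#' @param vectors n-by-3 matrix of unit vectors.
#' @param params A `"vp_params"` object.
#' @return Density values (integrate to 1 over the sphere).
#' @export
vp_pdf_3d <- function(vectors, params) {
  stopifnot(inherits(params, "vp_params"))
  v <- rbind(vectors)
  dens <- numeric(nrow(v))
  for (ker in params$kernels) {
    u <- as.numeric(v %*% ker$mean_axis)
    dens <- dens + (2 * ker$k3d + 1) / (4 * pi * params$n_vp) * (u^2)^ker$k3d
  }
  dens
}

#' Sample 3D orientations from a VP mixture
#'
#' Spherical rejection sampling: proposals uniform on the sphere, envelope
#' equal to the mixture density at perfect alignment (its global maximum),
#' \eqn{\sum_i (2k_i+1)/(4\pi N)}. Exact; the acceptance rate for a single
#' kernel is \eqn{1/(2k+1)}.
#'
#' @param params A `"vp_params"` object.
#' @param n Number of unit vectors to draw.
#' @return n-by-3 matrix of unit vectors.
#' @export
sample_vp <- function(params, n) {
  stopifnot(inherits(params, "vp_params"), n >= 0)
  if (n == 0) return(matrix(numeric(0), 0, 3))
  envelope <- sum(vapply(params$kernels, function(k) 2 * k$k3d + 1, 0)) /
    (4 * pi * params$n_vp)
  out <- matrix(NA_real_, n, 3)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 64L)
    cand <- runif_sphere(m)
    p <- stats::runif(m, 0, envelope)
    acc <- cand[p < vp_pdf_3d(cand, params), , drop = FALSE]
    take <- min(nrow(acc), n - got)
    if (take > 0) {
      out[(got + 1L):(got + take), ] <- acc[seq_len(take), , drop = FALSE]
      got <- got + take
    }
  }
  out
}

#' Uniform random unit vectors
#'
#' @param n Number of vectors.
#' @return n-by-3 matrix of unit vectors uniform on the sphere.
#' @export
runif_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' von Mises--Fisher parameters
#'
#' @param mean_dir Unit 3-vector, the preferred direction (normalized
#'   internally).
#' @param kappa Concentration, >= 0; 0 is uniform on the sphere.
#' @return An object of class `"vmf_params"`.
#' @export
vmf_params <- function(mean_dir, kappa) {
  mean_dir <- as.numeric(mean_dir)
  if (length(mean_dir) != 3 || !all(is.finite(mean_dir)))
    stop("'mean_dir' must be a finite 3-vector")
  nrm <- sqrt(sum(mean_dir^2))
  if (nrm == 0) stop("'mean_dir' must be nonzero")
  if (!is.finite(kappa) || kappa < 0) stop("'kappa' must be >= 0")
  structure(list(mean_dir = mean_dir / nrm, kappa = kappa), class = "vmf_params")
}

#' Sample from the von Mises--Fisher distribution
#'
#' Exact inverse-CDF sampling of the polar cosine
#' \eqn{w = 1 + \log(v + (1-v)e^{-2\kappa})/\kappa} (numerically stable for
#' large \eqn{\kappa}), with uniform azimuth, rotated onto the mean
#' direction. `kappa = 0` yields uniform samples on the sphere.
#'
#' @param params A `"vmf_params"` object.
#' @param n Number of unit vectors.
#' @return n-by-3 matrix of unit vectors.
#' @export
sample_vmf <- function(params, n) {
  stopifnot(inherits(params, "vmf_params"), n >= 0)
  if (n == 0) return(matrix(numeric(0), 0, 3))
  kappa <- params$kappa
  if (kappa == 0) {
    w <- stats::runif(n, -1, 1)
  } else {
    v <- stats::runif(n)
    w <- 1 + log(v + (1 - v) * exp(-2 * kappa)) / kappa
    w <- pmin(1, pmax(-1, w))
  }
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - w^2))
  local <- cbind(r * cos(phi), r * sin(phi), w)
  local %*% t(rotation_to(params$mean_dir))
}

# Rotation matrix mapping the +z axis onto unit vector 'to'.
rotation_to <- function(to) {
  z <- c(0, 0, 1)
  c_ <- sum(z * to)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  v <- c(z[2] * to[3] - z[3] * to[2],
         z[3] * to[1] - z[1] * to[3],
         z[1] * to[2] - z[2] * to[1])
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' In-plane (2D) de la Vallee Poussin mixture density
#'
#' The polar-angle form of the VP distribution restricted to a measurement
#' plane, used to fit 2D orientation histograms:
#' \deqn{p(\theta) = \sum_i \frac{\Gamma(k_i+1)}{\sqrt{\pi}\,\Gamma(k_i+1/2)\,N}
#'   \cos^{2k_i}(\theta-\theta_{i})}
#' which integrates to 1 over \eqn{[0,\pi)}. Angles are antipodally folded.
#'
#' @param theta Angles in radians.
#' @param kernels2d List of `list(theta_vp =, k2d =)` kernels, or a
#'   two-column matrix with columns (theta_vp, k2d).
#' @return Density values at `theta`.
#' @export
vp_pdf_2d <- function(theta, kernels2d) {
  kernels2d <- as_kernels2d(kernels2d)
  dens <- numeric(length(theta))
  n <- length(kernels2d)
  for (ker in kernels2d) {
    k <- ker$k2d
    const <- exp(lgamma(k + 1) - lgamma(k + 0.5)) / sqrt(pi)
    dens <- dens + const / n * (cos(theta - ker$theta_vp)^2)^k
  }
  dens
}

as_kernels2d <- function(kernels2d) {
  if (is.matrix(kernels2d) || is.data.frame(kernels2d)) {
    kernels2d <- as.matrix(kernels2d)
    kernels2d <- lapply(seq_len(nrow(kernels2d)), function(i)
      list(theta_vp = kernels2d[i, 1], k2d = kernels2d[i, 2]))
  }
  if (!is.null(kernels2d$theta_vp)) kernels2d <- list(kernels2d)
  for (ker in kernels2d) {
    if (!is.finite(ker$k2d) || ker$k2d < 0) stop("'k2d' must be >= 0")
  }
  kernels2d
}
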