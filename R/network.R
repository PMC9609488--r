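#' Specification of a stochastic fiber network
#'
#' Collects everything needed to build a network: a periodic cubic domain
#' of side `box_length`, a target fiber volume fraction, the first two
#' moments of the fiber diameter and length distributions (gamma
#' distributed), an orientation distribution (a [vp_params()] mixture), and
#' a tortuosity distribution (either moment parameters for a truncated
#' lognormal, or a two-column histogram which then takes precedence).
#'
#' @param box_length Domain side length L, > 0.
#' @param volume_fraction Fiber volume fraction in (0, 1).
#' @param diameter_mean,diameter_std Moments of the fiber diameter.
#' @param length_mean,length_std Moments of the fiber length.
#' @param orientation A `"vp_params"` object (default: single isotropic
#'   kernel).
#' @param tau_mean,tau_std Moments of the tortuosity distribution.
#' @param tau_histogram Optional two-column (tau, density) histogram; when
#'   supplied it is sampled directly instead of the fitted lognormal.
#' @param beta VMF step multiplier used for every fiber.
#' @param diameter_floor Redraw diameters below this value (default
#'   `diameter_mean / 5`; set to 0 to disable). Keeps the voxel grid of the
#'   pore analysis bounded, since its edge is tied to the smallest
#'   diameter.
#' @param spline_factor Particle spacing of each smoothed fiber as a
#'   fraction of its diameter (default 0.5, so consecutive beads of the
#'   bead-chain representation overlap).
#' @param rescale_length Rescale each accepted fiber to its drawn length
#'   exactly (see [generate_fiber()]); off by default.
#' @return An object of class `"network_spec"`.
#' @export
network_spec <- function(box_length, volume_fraction,
                         diameter_mean, diameter_std,
                         length_mean, length_std,
                         orientation = vp_params(vp_kernel(c(0, 0, 1), 0)),
                         tau_mean = 1, tau_std = 0, tau_histogram = NULL,
                         beta = 20, diameter_floor = diameter_mean / 5,
                         spline_factor = 0.5, rescale_length = FALSE) {
  stopifnot(box_length > 0, volume_fraction > 0, volume_fraction < 1,
            diameter_mean > 0, length_mean > 0,
            diameter_std >= 0, length_std >= 0, tau_mean >= 1, tau_std >= 0)
  if (!inherits(orientation, "vp_params")) stop("'orientation' must be vp_params")
  structure(list(box_length = box_length, volume_fraction = volume_fraction,
                 diameter_mean = diameter_mean, diameter_std = diameter_std,
                 length_mean = length_mean, length_std = length_std,
                 orientation = orientation,
                 tau_mean = tau_mean, tau_std = tau_std,
                 tau_histogram = tau_histogram,
                 beta = beta, diameter_floor = diameter_floor,
                 spline_factor = spline_factor,
                 rescale_length = rescale_length),
            class = "network_spec")
}

#' Estimated fiber count for a network specification
#'
#' Treating fibers as cylinders of mean length and diameter, the count
#' needed to reach the target volume fraction is
#' \eqn{N_f \approx 4 V \phi_f / (\pi \langle l\rangle \langle d\rangle^2)},
#' rounded to the nearest whole number.
#'
#' @param spec A `"network_spec"`.
#' @return Integer fiber count (warns when 0).
#' @export
estimate_fiber_count <- function(spec) {
  v <- spec$box_length^3
  n <- round(4 * v * spec$volume_fraction /
               (pi * spec$length_mean * spec$diameter_mean^2))
  if (n == 0) warning("specification implies an empty network (0 fibers)")
  as.integer(n)
}

#' Uniform fiber seed positions
#'
#' @param n Number of seeds.
#' @param box_length Domain side length.
#' @return n-by-3 matrix of points uniform in `[0, box_length]^3`.
#' @export
seed_positions <- function(n, box_length) {
  stopifnot(n >= 0, box_length > 0)
  matrix(stats::runif(3 * n, 0, box_length), ncol = 3)
}

#' Mean orientation of a polyline
#'
#' The normalized average of the segment unit tangents; for a straight
#' path this is the segment direction. Sign is canonicalized so the
#' component of largest magnitude is positive (orientations are
#' antipodally symmetric).
#'
#' @param points n-by-3 matrix (or a `"fiber_path"`).
#' @return Unit 3-vector.
#' @export
mean_orientation <- function(points) {
  if (inherits(points, "fiber_path")) points <- points$points
  points <- rbind(points)
  if (nrow(points) < 2) stop("need at least 2 points")
  d <- diff(points)
  len <- sqrt(rowSums(d^2))
  keep <- len > 0
  if (!any(keep)) stop("degenerate path: all points coincident")
  tangents <- d[keep, , drop = FALSE] / len[keep]
  m <- colMeans(tangents)
  nm <- sqrt(sum(m^2))
  if (nm < 1e-12) stop("degenerate orientation: tangents cancel (closed loop?)")
  m <- m / nm
  if (m[which.max(abs(m))] < 0) m <- -m
  m
}

#' Build a stochastic fiber network
#'
#' Draws per-fiber diameters and lengths from moment-matched gamma
#' distributions, orientations from the VP mixture, tortuosities from the
#' truncated lognormal (or directly from a histogram when supplied), and
#' grows each fiber as a screened, smoothed VMF random walk starting at a
#' uniformly placed seed. Fibers may extend beyond the box; wrapping into
#' the periodic domain is deferred to the relaxation stage.
#'
#' @param spec A `"network_spec"`.
#' @param max_tries Per-fiber screening budget passed to [generate_fiber()].
#' @return An object of class `"fiber_network"`: list with `fibers` (list
#'   of `"fiber_path"`), `spec`, and `prescribed` (data frame of drawn
#'   per-fiber parameters: `diameter`, `length`, `tau`, orientation
#'   components).
#' @export
build_network <- function(spec, max_tries = 1000L) {
  stopifnot(inherits(spec, "network_spec"))
  n <- estimate_fiber_count(spec)
  if (n == 0) stop("empty network: specification implies 0 fibers")
  gp_d <- if (spec$diameter_std > 0)
    gamma_params_from_moments(spec$diameter_mean, spec$diameter_std) else NULL
  gp_l <- if (spec$length_std > 0)
    gamma_params_from_moments(spec$length_mean, spec$length_std) else NULL

  d <- if (is.null(gp_d)) rep(spec$diameter_mean, n)
       else stats::rgamma(n, shape = gp_d$k_shape, scale = gp_d$theta_scale)
  if (spec$diameter_floor > 0 && !is.null(gp_d)) {
    bad <- d < spec$diameter_floor
    while (any(bad)) {
      d[bad] <- stats::rgamma(sum(bad), shape = gp_d$k_shape,
                              scale = gp_d$theta_scale)
      bad <- d < spec$diameter_floor
    }
  }
  l <- if (is.null(gp_l)) rep(spec$length_mean, n)
       else stats::rgamma(n, shape = gp_l$k_shape, scale = gp_l$theta_scale)
  # a fiber must be at least a few particles long
  lmin <- 3 * spec$spline_factor * d
  l <- pmax(l, lmin)

  orient <- sample_vp(spec$orientation, n)
  tau <- if (!is.null(spec$tau_histogram)) {
    pmax(1, sample_rejection(spec$tau_histogram, n = n))
  } else if (spec$tau_std > 0) {
    lp <- suppressMessages(lognormal_params_from_moments(spec$tau_mean, spec$tau_std))
    sample_trunc_lognormal(lp, n)
  } else rep(spec$tau_mean, n)

  seeds <- seed_positions(n, spec$box_length)
  fibers <- vector("list", n)
  for (i in seq_len(n)) {
    fibers[[i]] <- generate_fiber(l[i], tau[i], orientation = orient[i, ],
                                  origin = seeds[i, ], diameter = d[i],
                                  beta = spec$beta,
                                  spline_step = spec$spline_factor * d[i],
                                  rescale_length = spec$rescale_length,
                                  max_tries = max_tries)
  }
  prescribed <- data.frame(diameter = d, length = l, tau = tau,
                           nx = orient[, 1], ny = orient[, 2], nz = orient[, 3])
  structure(list(fibers = fibers, spec = spec, prescribed = prescribed),
            class = "fiber_network")
}

#' @export
print.fiber_network <- function(x, ...) {
  cat("Stochastic fiber network:", length(x$fibers), "fibers in a periodic box of side",
      format(x$spec$box_length), "\n")
  ch <- characterize(x, fit_orientation = FALSE)
  cat(sprintf("  realized volume fraction %.4f (target %.4f)\n",
              ch$volume_fraction, x$spec$volume_fraction))
  cat(sprintf("  <d> = %.3g, <l> = %.3g, <tau> = %.3g\n",
              ch$diameter_mean, ch$length_mean, ch$tau_mean))
  invisible(x)
}

#' Realized per-fiber measurements of a network
#'
#' @param network A `"fiber_network"`.
#' @return Data frame with per-fiber realized `diameter`, `length`, `tau`,
#'   and mean-orientation components.
#' @export
realized_fibers <- function(network) {
  f <- network$fibers
  data.frame(
    diameter = vapply(f, function(p) p$diameter, 0),
    length = vapply(f, function(p) p$contour_length, 0),
    tau = vapply(f, function(p) p$tau, 0),
    t(vapply(f, function(p) p$mean_orientation, numeric(3))) |>
      `colnames<-`(c("nx", "ny", "nz"))
  )
}

#' Characterize a network against its prescription
#'
#' Computes the realized volume fraction (sum of cylinder volumes over the
#' box volume), moments of the realized diameter/length/tortuosity, mean
#' absolute percentage error (MAPE) between prescribed and realized
#' per-fiber lengths and tortuosities, and (optionally) projected
#' orientation fits on the three coordinate planes with corrected 3D
#' strengths.
#'
#' @param network A `"fiber_network"`.
#' @param fit_orientation Fit projected 2D VP mixtures on the coordinate
#'   planes (slower).
#' @param scaling_mode Passed to [correct_k2d_to_k3d()].
#' @return A list summary.
#' @export
characterize <- function(network, fit_orientation = TRUE,
                         scaling_mode = "table") {
  r <- realized_fibers(network)
  p <- network$prescribed
  v <- network$spec$box_length^3
  out <- list(
    n_fibers = nrow(r),
    volume_fraction = sum(pi / 4 * r$diameter^2 * r$length) / v,
    diameter_mean = mean(r$diameter), diameter_std = stats::sd(r$diameter),
    length_mean = mean(r$length), length_std = stats::sd(r$length),
    tau_mean = mean(r$tau), tau_std = stats::sd(r$tau),
    length_mape = 100 * mean(abs(r$length - p$length) / p$length),
    tau_mape = 100 * mean(abs(r$tau - p$tau) / p$tau)
  )
  if (fit_orientation) {
    n_vp <- network$spec$orientation$n_vp
    normals <- list(xy = c(0, 0, 1), xz = c(0, 1, 0), yz = c(1, 0, 0))
    vecs <- as.matrix(r[, c("nx", "ny", "nz")])
    out$orientation_planes <- lapply(normals, function(nrm) {
      theta <- project_orientations(vecs, projection_setup(plane_normal = nrm))
      fit <- fit_vp_2d(bin_angles(theta), n_vp = n_vp)
      k2d <- vapply(fit$kernels2d, `[[`, 0, "k2d")
      list(fit = fit, k2d = k2d,
           k3d = as.numeric(correct_k2d_to_k3d(k2d, n_vp,
                                               scaling_mode = scaling_mode)))
    })
  }
  out
}
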