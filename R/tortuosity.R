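#' VMF concentration for a target fiber tortuosity
#'
#' Selects the von Mises--Fisher concentration so that a fixed-mean VMF
#' random walk of `n_steps` equal steps has expected tortuosity
#' `tau_target`. The selection inverts the walk's end-to-end statistics:
#' for i.i.d. steps with mean resultant \eqn{\rho(\kappa) = \coth\kappa -
#' 1/\kappa} (the Langevin function),
#' \deqn{E[\|ee\|^2] = \Delta^2\left(N^2\rho^2 + N(1-\rho^2)\right)}
#' so the expected tortuosity is approximately
#' \eqn{\tau \approx (\rho^2 + (1-\rho^2)/N)^{-1/2}}, plus a first-order
#' correction \eqn{(1-\rho^2)/(N\rho^2)} for the fluctuation of the
#' end-to-end distance (validated by simulation to within a few percent of
#' the target over \eqn{\tau \in [1.05, 3.5]}). Both \eqn{\rho} and
#' \eqn{\kappa} are obtained by numerical root finding, so the mapping is
#' deterministic and exact for the model above. \eqn{\kappa \to \infty} as
#' \eqn{\tau \to 1^+} (straight fibers) and the mapping decreases
#' monotonically in `tau_target`. Targets beyond 3.5 are extrapolation and
#' trigger a warning.
#'
#' @param tau_target Expected tortuosity, > 1.
#' @param beta Step multiplier used to determine the step count when
#'   `n_steps` is not given (see [steps_for_walk()]).
#' @param n_steps Number of walk steps; defaults to
#'   `steps_for_walk(tau_target, beta)`.
#' @return The VMF concentration kappa (0 when even a fully random walk of
#'   `n_steps` steps cannot reach the target, with a warning).
#' @export
kappa_for_tortuosity <- function(tau_target, beta = 20, n_steps = NULL) {
  if (any(tau_target <= 1))
    stop("'tau_target' must be > 1 (kappa diverges at tau = 1)")
  if (any(tau_target > 3.5))
    warning("tau_target > 3.5 is outside the calibrated range; extrapolating")
  vapply(tau_target, function(tau) {
    n <- if (is.null(n_steps)) steps_for_walk(tau, beta) else as.integer(n_steps)
    # expected tortuosity of a walk with mean resultant rho, incl. the
    # first-order end-to-end fluctuation correction
    tau_of_rho <- function(rho) {
      1 / sqrt(rho^2 + (1 - rho^2) / n) * (1 + (1 - rho^2) / (n * rho^2))
    }
    if (tau_of_rho(1e-8) < tau) {
      warning("n_steps = ", n, " cannot reach tau = ", tau,
              "; returning kappa = 0")
      return(0)
    }
    rho <- stats::uniroot(function(r) tau_of_rho(r) - tau,
                          c(1e-8, 1 - 1e-12), tol = 1e-12)$root
    langevin <- function(k) 1 / tanh(k) - 1 / k
    stats::uniroot(function(k) langevin(k) - rho, c(1e-9, 1e7),
                   tol = 1e-10)$root
  }, numeric(1))
}

#' Minimum number of VMF steps for a target tortuosity
#'
#' A random walk cannot realize tortuosity \eqn{\tau} with fewer than
#' \eqn{\tau^2/2 + 1} steps; below this, decreasing the concentration no
#' longer increases the realized tortuosity (the "inaccessible region").
#' The value is rounded up since steps are integral.
#'
#' @param tau_target Target tortuosity, >= 1.
#' @return Integer minimum step count.
#' @export
min_steps <- function(tau_target) {
  if (any(tau_target < 1)) stop("'tau_target' must be >= 1")
  as.integer(ceiling(tau_target^2 / 2 + 1))
}

#' Number of VMF steps for a walk, with oversampling factor beta
#'
#' `ceiling(beta * (tau^2/2 + 1))`. Using more steps than the minimum
#' (`beta > 1`) narrows the spread of realized tortuosity around the
#' target; `beta = 20` is the standard choice.
#'
#' @param tau_target Target tortuosity, >= 1.
#' @param beta Step multiplier, >= 1.
#' @return Integer step count.
#' @export
steps_for_walk <- function(tau_target, beta = 20) {
  if (any(beta < 1)) stop("'beta' must be >= 1")
  if (any(tau_target < 1)) stop("'tau_target' must be >= 1")
  as.integer(ceiling(beta * (tau_target^2 / 2 + 1)))
}

#' von Mises--Fisher random walk
#'
#' Generates a raw polyline by repeatedly drawing a step direction from the
#' VMF distribution about a fixed mean direction and stepping a constant
#' distance: \eqn{x_i = x_{i-1} + \Delta\,\hat n_i}. Every step direction
#' (including the first) is drawn from the same distribution.
#'
#' @param kappa VMF concentration, >= 0.
#' @param n_steps Number of steps, >= 2.
#' @param step_size Step length, > 0.
#' @param mean_dir Unit 3-vector, the walk's preferred direction.
#' @param origin Starting point (3-vector).
#' @return (n_steps + 1)-by-3 matrix of points, first row = `origin`.
#' @export
vmf_walk <- function(kappa, n_steps, step_size, mean_dir = c(0, 0, 1),
                     origin = c(0, 0, 0)) {
  stopifnot(n_steps >= 2, step_size > 0)
  dirs <- sample_vmf(vmf_params(mean_dir, kappa), n_steps)
  pts <- apply(dirs * step_size, 2, cumsum)
  if (n_steps == 1L) pts <- matrix(pts, 1)
  rbind(origin, sweep(pts, 2, origin, `+`))
}

#' Smooth a polyline with a cubic spline and resample at fixed arc length
#'
#' Interpolates each coordinate with a cubic spline parameterized by
#' cumulative chord length, then resamples the densely evaluated curve at
#' (approximately) equal arc-length intervals `spline_step`. Endpoints are
#' preserved exactly; the final segment is generally shorter than
#' `spline_step`.
#'
#' @param points n-by-3 matrix of raw walk points, n >= 3.
#' @param spline_step Target spacing of the resampled points.
#' @param oversample Dense-evaluation factor used to approximate arc length.
#' @return m-by-3 matrix of resampled points.
#' @export
smooth_spline_path <- function(points, spline_step, oversample = 20L) {
  points <- rbind(points)
  if (nrow(points) < 3) stop("need at least 3 points to spline")
  if (spline_step <= 0) stop("'spline_step' must be > 0")
  seg <- sqrt(rowSums(diff(points)^2))
  t <- c(0, cumsum(seg))
  if (any(seg == 0)) { # drop coincident points, keep a valid parameterization
    keep <- c(TRUE, seg > 0)
    points <- points[keep, , drop = FALSE]
    if (nrow(points) < 3) return(points)
    seg <- sqrt(rowSums(diff(points)^2))
    t <- c(0, cumsum(seg))
  }
  n_dense <- max(nrow(points) * oversample, 50L)
  td <- seq(0, t[length(t)], length.out = n_dense)
  dense <- vapply(1:3, function(j)
    stats::spline(t, points[, j], xout = td, method = "fmm")$y,
    numeric(n_dense))
  arc <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  total <- arc[length(arc)]
  # equal arc-length stations; the final segment absorbs the remainder and
  # stays between 0.5 and 1.5 spline_step so no degenerate short bond occurs
  k <- max(1L, floor(total / spline_step))
  s_out <- seq_len(k - 1L) * spline_step
  if (total - (k - 1L) * spline_step >= 1.5 * spline_step)
    s_out <- c(s_out, k * spline_step)
  s_out <- c(0, s_out, total)
  out <- vapply(1:3, function(j)
    stats::approx(arc, dense[, j], xout = s_out)$y, numeric(length(s_out)))
  out[1, ] <- points[1, ]
  out[nrow(out), ] <- points[nrow(points), ]
  # the spline can overshoot at sharp walk corners, folding arc-equidistant
  # stations onto nearly coincident chord positions; thin interior points so
  # consecutive spacing never collapses (keeps bead-chain bonds well scaled)
  if (nrow(out) > 2) {
    keep <- rep(TRUE, nrow(out))
    last <- 1L
    for (i in 2:(nrow(out) - 1L)) {
      if (sqrt(sum((out[i, ] - out[last, ])^2)) < 0.45 * spline_step)
        keep[i] <- FALSE
      else last <- i
    }
    if (sqrt(sum((out[nrow(out), ] - out[last, ])^2)) < 0.45 * spline_step &&
        last > 1L)
      keep[last] <- FALSE
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Tortuosity of a polyline
#'
#' Arc length divided by end-to-end distance; >= 1, with 1 for a straight
#' path.
#'
#' @param points n-by-3 matrix, n >= 2 (or a `"fiber_path"` object).
#' @return The tortuosity.
#' @export
measure_tortuosity <- function(points) {
  if (inherits(points, "fiber_path")) points <- points$points
  points <- rbind(points)
  if (nrow(points) < 2) stop("need at least 2 points")
  ee <- sqrt(sum((points[nrow(points), ] - points[1, ])^2))
  if (ee == 0) stop("degenerate path: coincident endpoints")
  sum(sqrt(rowSums(diff(points)^2))) / ee
}

#' Construct a fiber path object
#'
#' @param points Polyline coordinates.
#' @param diameter Fiber diameter.
#' @return An object of class `"fiber_path"` with fields `points`,
#'   `diameter`, `contour_length`, `end_to_end`, `tau`, `mean_orientation`.
#' @export
fiber_path <- function(points, diameter) {
  points <- rbind(points)
  seg <- sqrt(rowSums(diff(points)^2))
  ee <- sqrt(sum((points[nrow(points), ] - points[1, ])^2))
  structure(list(points = points, diameter = diameter,
                 contour_length = sum(seg), end_to_end = ee,
                 tau = if (ee > 0) sum(seg) / ee else NA_real_,
                 mean_orientation = mean_orientation(points)),
            class = "fiber_path")
}

#' Generate one fiber with prescribed length, tortuosity, and orientation
#'
#' Builds a curvilinear fiber as a smoothed VMF random walk: the
#' concentration comes from [kappa_for_tortuosity()], the step count from
#' [steps_for_walk()], and the step size is `length / n_steps`. Walks whose
#' realized tortuosity misses the target by more than `tol` (relative) are
#' discarded and redrawn (screening); the number of rejections is recorded.
#' Targets within `tol/2` of 1 bypass the walk and return a straight
#' segment, since the concentration diverges at tau = 1.
#'
#' @param length Fiber contour length target, > 0.
#' @param tau_target Target tortuosity, >= 1.
#' @param orientation Unit 3-vector, the fiber's mean direction.
#' @param origin Walk origin (the fiber seed).
#' @param diameter Fiber diameter stored on the path.
#' @param beta Step multiplier (default 20).
#' @param spline_step Spacing of the smoothed path; default `length / (4 *
#'   n_steps)` and never larger than the walk step.
#' @param tol Relative screening tolerance (default 0.05).
#' @param rescale_length Scale the accepted path about its origin so the
#'   realized contour length equals `length` exactly (tortuosity is scale
#'   invariant). Off by default: the raw smoothed walk deviates from the
#'   nominal length by the spline-overshoot construction tolerance of a
#'   few percent.
#' @param max_tries Maximum number of walks before giving up.
#' @return A `"fiber_path"` with attributes `"rejections"`, `"kappa"`,
#'   `"n_steps"`.
#' @export
generate_fiber <- function(length, tau_target, orientation = c(0, 0, 1),
                           origin = c(0, 0, 0), diameter = 1, beta = 20,
                           spline_step = NULL, tol = 0.05,
                           rescale_length = FALSE, max_tries = 1000L) {
  stopifnot(length > 0, tau_target >= 1)
  orientation <- orientation / sqrt(sum(orientation^2))
  if (tau_target < 1 + tol / 2) {
    step <- if (is.null(spline_step)) length / 20 else spline_step
    n_pts <- max(2L, ceiling(length / step) + 1L)
    s <- seq(0, length, length.out = n_pts)
    pts <- outer(s, orientation)
    pts <- sweep(pts, 2, origin, `+`)
    path <- fiber_path(pts, diameter)
    attr(path, "rejections") <- 0L
    attr(path, "kappa") <- Inf
    attr(path, "n_steps") <- 0L
    return(path)
  }
  n_steps <- steps_for_walk(tau_target, beta)
  if (!is.null(spline_step)) {
    # the walk step must not be finer than the bead spacing, or resampling
    # would cut corners and bias the realized tortuosity; short fibers thus
    # run at an effective beta below the requested one
    n_steps <- min(n_steps, max(min_steps(tau_target), floor(length / spline_step)))
  }
  kappa <- kappa_for_tortuosity(tau_target, beta, n_steps = n_steps)
  step_size <- length / n_steps
  if (is.null(spline_step)) spline_step <- max(step_size / 4, length / 2000)
  spline_step <- min(spline_step, step_size)
  for (try in seq_len(max_tries)) {
    raw <- vmf_walk(kappa, n_steps, step_size, mean_dir = orientation,
                    origin = origin)
    pts <- smooth_spline_path(raw, spline_step)
    tau <- measure_tortuosity(pts)
    if (abs(tau - tau_target) / tau_target <= tol) {
      if (rescale_length) {
        arc <- sum(sqrt(rowSums(diff(pts)^2)))
        pts <- sweep(sweep(pts, 2, origin) * (length / arc), 2, origin, `+`)
      }
      path <- fiber_path(pts, diameter)
      attr(path, "rejections") <- try - 1L
      attr(path, "kappa") <- kappa
      attr(path, "n_steps") <- n_steps
      return(path)
    }
  }
  stop("screening failed: no walk within tolerance after ", max_tries,
       " attempts (tau_target = ", tau_target, ")")
}
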