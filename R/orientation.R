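#' Projection setup for 2D orientation measurements
#'
#' Describes how a 3D orientation distribution is observed: the observer
#' looks along `plane_normal`, so orientations are projected onto its
#' orthogonal complement (the "projection plane"). `psi` is the tilt angle
#' between the distribution's mean axis and that plane; it controls the
#' projection distortion of the measured angle histogram.
#'
#' @param plane_normal Unit 3-vector, the viewing axis (default +z).
#' @param psi Tilt angle in radians, in `[0, pi/2]`.
#' @param psi_range Optional `c(psi1, psi2)` for measurements averaged over
#'   a range of tilts.
#' @return An object of class `"projection_setup"`.
#' @export
projection_setup <- function(plane_normal = c(0, 0, 1), psi = 0, psi_range = NULL) {
  plane_normal <- as.numeric(plane_normal)
  stopifnot(length(plane_normal) == 3)
  nrm <- sqrt(sum(plane_normal^2))
  if (nrm == 0) stop("'plane_normal' must be nonzero")
  if (!is.finite(psi) || psi < 0 || psi > pi / 2)
    stop("'psi' must be in [0, pi/2]")
  structure(list(plane_normal = plane_normal / nrm, psi = psi,
                 psi_range = psi_range),
            class = "projection_setup")
}

#' Project 3D orientations onto a measurement plane
#'
#' Returns the in-plane polar angle of each orientation after removing the
#' component along the plane normal, folded into `[0, pi)` so that
#' antipodal orientations map to the same angle. Vectors (numerically)
#' parallel to the plane normal have no in-plane direction and are dropped;
#' the count of dropped vectors is attached as attribute `"n_dropped"`.
#'
#' @param vectors n-by-3 matrix of unit vectors.
#' @param setup A `"projection_setup"` (default: observer along +z).
#' @param tol In-plane norm below which a vector counts as parallel to the
#'   normal.
#' @return Numeric vector of angles in radians in `[0, pi)`.
#' @export
project_orientations <- function(vectors, setup = projection_setup(), tol = 1e-9) {
  v <- rbind(vectors)
  nrm <- setup$plane_normal
  # orthonormal in-plane basis (e1, e2)
  ref <- if (abs(nrm[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * nrm) * nrm
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  # default +z observer: use (x, y) axes directly so in-plane angles are
  # the usual azimuths
  if (all(nrm == c(0, 0, 1))) { e1 <- c(1, 0, 0); e2 <- c(0, 1, 0) }
  a <- as.numeric(v %*% e1)
  b <- as.numeric(v %*% e2)
  inplane <- sqrt(a^2 + b^2)
  keep <- inplane > tol
  if (!any(keep)) stop("all orientations are parallel to the plane normal")
  theta <- atan2(b[keep], a[keep]) %% pi
  structure(theta, n_dropped = sum(!keep))
}

#' Fit a 2D VP mixture to an angle histogram
#'
#' Least-squares fit of the in-plane de la Vallee Poussin mixture density
#' ([vp_pdf_2d()]) to a (angle, density) histogram on `[0, pi)`. The
#' histogram is renormalized to unit mass before fitting. Because the
#' objective is multimodal in the kernel angles, the fit is multi-started:
#' kernel angles are seeded at the histogram's `n_vp` largest local maxima
#' and jittered, strengths start at 1.
#'
#' @param histogram Two-column matrix/data frame: bin centers (radians on
#'   `[0, pi)`) and nonnegative densities or counts.
#' @param n_vp Number of kernels to fit.
#' @param init Optional list of `list(theta_vp =, k2d =)` initial kernels.
#' @param shared_k If `TRUE`, all kernels share one strength parameter
#'   (symmetric materials such as stone wool or cross-laid polyester).
#' @param n_starts Number of multi-starts (jittered angle seeds).
#' @return An object of class `"fit2d_result"`: list with `kernels2d`
#'   (list of `theta_vp`/`k2d`), `residual` (sum of squared density
#'   errors), and `n_vp`.
#' @export
fit_vp_2d <- function(histogram, n_vp = 1L, init = NULL, shared_k = FALSE,
                      n_starts = 10L) {
  h <- as.matrix(histogram)
  if (any(h[, 2] < 0)) stop("histogram densities must be nonnegative")
  theta <- h[, 1] %% pi
  y <- h[, 2]
  if (sum(y) <= 0) stop("histogram has no mass")
  # renormalize to unit mass over [0, pi)
  w <- if (nrow(h) > 1) stats::median(diff(sort(theta))) else pi
  y <- y / (sum(y) * w)

  obj <- function(par) {
    ang <- par[seq_len(n_vp)] %% pi
    ks <- if (shared_k) rep(par[n_vp + 1L], n_vp) else par[n_vp + seq_len(n_vp)]
    if (any(ks < 0)) return(1e10)
    kern <- lapply(seq_len(n_vp), function(i) list(theta_vp = ang[i], k2d = ks[i]))
    sum((vp_pdf_2d(theta, kern) - y)^2)
  }

  starts <- list()
  if (!is.null(init)) {
    init <- as_kernels2d(init)
    starts[[1]] <- c(vapply(init, `[[`, 0, "theta_vp"),
                     if (shared_k) init[[1]]$k2d else vapply(init, `[[`, 0, "k2d"))
  } else {
    peaks <- local_maxima_angles(theta, y, n_vp)
    base <- c(peaks, rep(1, if (shared_k) 1L else n_vp))
    starts[[1]] <- base
    for (s in seq_len(max(0L, n_starts - 1L))) {
      jit <- base
      jit[seq_len(n_vp)] <- (jit[seq_len(n_vp)] +
                               stats::runif(n_vp, -pi / 8, pi / 8)) %% pi
      starts[[s + 1L]] <- jit
    }
  }

  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("2D VP fit failed to converge from all starts")
  ang <- best$par[seq_len(n_vp)] %% pi
  ks <- if (shared_k) rep(best$par[n_vp + 1L], n_vp) else best$par[n_vp + seq_len(n_vp)]
  kernels <- lapply(order(ang), function(i)
    list(theta_vp = ang[i], k2d = max(0, ks[i])))
  structure(list(kernels2d = kernels, residual = best$value, n_vp = n_vp),
            class = "fit2d_result")
}

# n largest local maxima of a (periodic) binned density, kept apart by an
# exclusion radius so adjacent bins of one peak do not both seed kernels;
# falls back to the largest remaining bins when there are fewer maxima.
local_maxima_angles <- function(theta, y, n) {
  ord <- order(theta)
  th <- theta[ord]; yy <- y[ord]
  m <- length(yy)
  if (m < 3) return(rep(th[which.max(yy)], n))
  prev <- c(m, seq_len(m - 1)); nxt <- c(2:m, 1)
  is_max <- yy >= yy[prev] & yy >= yy[nxt]
  cand <- which(is_max)[order(yy[is_max], decreasing = TRUE)]
  cand <- c(cand, order(yy, decreasing = TRUE))
  binw <- stats::median(diff(th))
  min_sep <- max(2.5 * binw, pi / (6 * n))
  circ_dist <- function(a, b) pmin(abs(a - b), pi - abs(a - b))
  picked <- numeric(0)
  for (i in cand) {
    if (length(picked) == n) break
    if (all(circ_dist(th[i], picked) > min_sep) || length(picked) == 0)
      picked <- c(picked, th[i])
  }
  if (length(picked) < n)
    picked <- c(picked, rep(th[which.max(yy)], n - length(picked)))
  picked
}

#' Correct a measured 2D orientation strength to 3D
#'
#' Undoes the projection distortion of imaged orientation histograms: a 3D
#' VP mixture with per-kernel strength `k3d`, observed in projection with
#' its mean axis tilted `psi` out of the measurement plane, fits to a 2D
#' strength `k2d` that overestimates the true concentration. The default
#' `"table"` mode inverts
#' \deqn{k^{2D} = \frac{8\cos^2\psi}{3\sqrt{N_{VP}}}\,k^{3D}}
#' i.e. `k3d = 3 sqrt(n_vp) / (8 cos^2 psi) * k2d`. The alternative
#' `"literal"` mode uses `n_vp` (not its square root) in the numerator,
#' `k3d = 3 / (8 n_vp cos^2 psi) * k2d`; the two agree for a single kernel
#' but differ for multi-kernel symmetries (see the package vignette for why
#' `"table"` is the self-consistent default).
#'
#' @param k2d Measured 2D strength(s), >= 0.
#' @param n_vp Kernel count of the mixture.
#' @param psi Tilt angle in radians, < pi/2.
#' @param scaling_mode `"table"` (default) or `"literal"`.
#' @return Corrected `k3d` value(s) with attribute `"scaling_mode"`.
#' @examples
#' correct_k2d_to_k3d(0.98, 1)        # 0.37 (fibrin-like)
#' correct_k2d_to_k3d(5.25, 3)        # 3.41 (stone-wool-like)
#' correct_k2d_to_k3d(8, 1, psi = pi / 4)  # 6
#' @export
correct_k2d_to_k3d <- function(k2d, n_vp = 1L, psi = 0,
                               scaling_mode = c("table", "literal")) {
  scaling_mode <- match.arg(scaling_mode)
  if (any(k2d < 0)) stop("'k2d' must be >= 0")
  if (!is.finite(psi) || psi < 0 || psi >= pi / 2)
    stop("'psi' must be in [0, pi/2); psi = pi/2 is a degenerate projection")
  fac <- if (scaling_mode == "table") 3 * sqrt(n_vp) / (8 * cos(psi)^2)
         else 3 / (8 * n_vp * cos(psi)^2)
  structure(fac * k2d, scaling_mode = scaling_mode)
}

#' Expected measured 2D strength averaged over a tilt range
#'
#' When orientation measurements are taken at tilts spanning
#' `[psi1, psi2]`, the expected mean measured 2D strength is the average of
#' `8 k3d cos^2(psi) / (3 n_vp)` over the range:
#' \deqn{\bar k^{2D} = \frac{4 k^{3D}}{3 N_{VP}}
#'   \left(1 + \frac{\sin\Psi_2\cos\Psi_2 - \sin\Psi_1\cos\Psi_1}
#'   {\Psi_2 - \Psi_1}\right)}
#' For a range spanning an integer multiple of pi this reduces to
#' `4 k3d / (3 n_vp)`.
#'
#' @param k3d True 3D strength, >= 0.
#' @param n_vp Kernel count.
#' @param psi1,psi2 Tilt range in radians, `psi1 != psi2`.
#' @return Mean measured `k2d` over the range.
#' @export
average_k2d_over_psi <- function(k3d, n_vp = 1L, psi1, psi2) {
  if (any(k3d < 0)) stop("'k3d' must be >= 0")
  if (psi1 == psi2) stop("zero-width tilt range")
  4 * k3d / (3 * n_vp) *
    (1 + (sin(psi2) * cos(psi2) - sin(psi1) * cos(psi1)) / (psi2 - psi1))
}

#' Simulate the projection-and-fit measurement of a 3D VP distribution
#'
#' Draws `n` orientations from a single-kernel 3D VP distribution whose
#' mean axis is tilted `psi` out of the projection plane, projects them
#' onto the plane, bins the in-plane angles, and fits the single-kernel 2D
#' VP density. This is the numerical experiment behind the
#' projection-distortion correction.
#'
#' @param k3d True 3D orientation strength.
#' @param psi Tilt in radians.
#' @param n Number of sampled orientations.
#' @param bins Number of histogram bins on `[0, pi)`.
#' @return List with `k2d` (fitted), `fit` (the `"fit2d_result"`), and
#'   `histogram`.
#' @export
measure_projected_k2d <- function(k3d, psi = 0, n = 1e5, bins = 36L) {
  mean_axis <- c(cos(psi), 0, sin(psi))
  samp <- sample_vp(vp_params(vp_kernel(mean_axis, k3d)), n)
  theta <- project_orientations(samp, projection_setup(psi = psi))
  h <- bin_angles(theta, bins)
  fit <- fit_vp_2d(h, n_vp = 1L)
  list(k2d = fit$kernels2d[[1]]$k2d, fit = fit, histogram = h)
}

#' Bin angles on `[0, pi)` into a density histogram
#'
#' @param theta Angles in radians.
#' @param bins Number of equal-width bins.
#' @return Two-column matrix (bin center, density).
#' @export
bin_angles <- function(theta, bins = 36L) {
  edges <- seq(0, pi, length.out = bins + 1L)
  counts <- tabulate(findInterval(theta %% pi, edges, rightmost.closed = TRUE),
                     nbins = bins)
  width <- pi / bins
  cbind(center = edges[-length(edges)] + width / 2,
        density = counts / (sum(counts) * width))
}
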