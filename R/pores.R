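#' Voxelize a network or particle system
#'
#' Rasterizes the bead-chain representation of a network onto a cubic
#' voxel lattice over the periodic box: a voxel is marked occupied when its
#' center lies within `radius + h*sqrt(3)/2` of a particle center (the
#' partial-containment criterion). The voxel edge should not exceed one
#' fifth of the smallest fiber diameter so that every fiber spans several
#' voxels.
#'
#' @param x A `"fiber_network"` or `"particle_system"`.
#' @param h Voxel edge length; default = smallest fiber diameter / 5.
#' @param containment `"center"` (default) marks a voxel occupied when its
#'   center lies inside a particle, which is unbiased in expectation;
#'   `"partial"` marks any voxel the particle touches (center within
#'   `radius + h*sqrt(3)/2`), which systematically inflates the occupied
#'   volume by about `(1 + h*sqrt(3)/d)^3` and thereby biases pore sizes
#'   low at high volume fraction (see the vignette calibration).
#' @param max_voxels Memory guard: error if the grid would exceed this many
#'   voxels (suggesting a larger `h` or a diameter floor).
#' @return An object of class `"voxel_grid"`: list with `edge`, `n` (voxels
#'   per side), `occupancy` (3D 0/1 array), `box_length`, `edt` (NULL until
#'   [distance_transform()]).
#' @export
voxelize <- function(x, h = NULL, containment = c("center", "partial"),
                     max_voxels = 2.5e8) {
  containment <- match.arg(containment)
  if (inherits(x, "fiber_network")) x <- discretize_network(x)
  stopifnot(inherits(x, "particle_system"))
  if (is.null(h)) h <- min(x$diam) / 5
  if (h <= 0) stop("'h' must be > 0")
  L <- x$box_length
  n <- max(1L, as.integer(round(L / h)))
  h <- L / n  # exact periodic tiling
  if (as.double(n)^3 > max_voxels)
    stop("voxel grid would need ", n, "^3 voxels; increase 'h' or enable the ",
         "diameter floor")
  occ <- voxelize_cpp(x$positions %% L, x$radii, L, h, n,
                      partial = containment == "partial")
  structure(list(edge = h, n = n,
                 occupancy = array(occ, dim = c(n, n, n)),
                 box_length = L, edt = NULL),
            class = "voxel_grid")
}

#' Periodic Euclidean distance transform
#'
#' Fills the grid's `edt` field with the exact Euclidean distance (in
#' length units) from each voxel to the nearest occupied voxel under the
#' periodic metric. Occupied voxels get distance 0.
#'
#' @param grid A `"voxel_grid"` with at least one occupied voxel.
#' @return The grid with `edt` filled (3D array).
#' @export
distance_transform <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  n <- grid$n
  edt <- edt_periodic_cpp(as.integer(grid$occupancy), n, n, n, grid$edge)
  grid$edt <- array(edt, dim = c(n, n, n))
  grid
}

#' Detect pores by watershed on the negated distance transform
#'
#' Pores are the basins of the watershed of the negated EDT: each basin's
#' minimum (a local maximum of the EDT) marks a pore center, and the pore
#' diameter is derived from the EDT value there. Basins whose depth below
#' the meeting ridge is less than `merge_depth` (default one voxel edge)
#' are merged to suppress voxelization artifacts.
#'
#' @param grid A `"voxel_grid"`; the EDT is computed on the fly if absent.
#' @param diameter_convention `"inscribed-sphere"` (default): pore diameter
#'   = 2 x EDT value (the EDT value is an inscribed-sphere radius);
#'   `"edt-value"`: use the raw EDT value. The default is calibrated
#'   against the mean-pore-size scaling laws (see the vignette).
#' @param merge_depth Basin merge depth; default `grid$edge`.
#' @return An object of class `"pore_set"`: data frame with pore center
#'   coordinates `x, y, z`, `diameter`, and basin `voxels`; attributes
#'   `"mean_diameter"` and `"diameter_convention"`. Zero rows (with a
#'   warning) when the grid has no empty voxels.
#' @export
find_pores <- function(grid, diameter_convention = c("inscribed-sphere", "edt-value"),
                       merge_depth = NULL) {
  diameter_convention <- match.arg(diameter_convention)
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(grid$edt)) grid <- distance_transform(grid)
  if (is.null(merge_depth)) merge_depth <- grid$edge
  n <- grid$n
  ws <- watershed_pores_cpp(as.numeric(grid$edt), n, n, n, merge_depth,
                            periodic = TRUE)
  if (length(ws$index) == 0) {
    warning("no empty voxels: no pores detected")
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      diameter = numeric(0), voxels = integer(0))
  } else {
    idx <- ws$index
    ix <- idx %% n; iy <- (idx %/% n) %% n; iz <- idx %/% (n * n)
    scale <- if (diameter_convention == "inscribed-sphere") 2 else 1
    out <- data.frame(x = (ix + 0.5) * grid$edge,
                      y = (iy + 0.5) * grid$edge,
                      z = (iz + 0.5) * grid$edge,
                      diameter = scale * ws$value,
                      voxels = ws$size)
    out <- out[order(-out$diameter), ]
    rownames(out) <- NULL
  }
  structure(out, class = c("pore_set", "data.frame"),
            mean_diameter = if (nrow(out)) mean(out$diameter) else NA_real_,
            diameter_convention = diameter_convention)
}

#' Measure the mean pore diameter of a network
#'
#' Convenience pipeline: voxelize, distance transform, watershed.
#'
#' @param network A `"fiber_network"` (typically relaxed).
#' @param h Voxel edge (default smallest diameter / 5).
#' @param ... Passed to [find_pores()].
#' @return List with `mean_diameter`, `pores` (the `"pore_set"`), `grid`.
#' @export
measure_pores <- function(network, h = NULL, ...) {
  grid <- distance_transform(voxelize(network, h = h))
  pores <- find_pores(grid, ...)
  list(mean_diameter = attr(pores, "mean_diameter"), pores = pores, grid = grid)
}

#' Closed-form mean pore diameter predictors
#'
#' Three nested empirical predictors of the mean pore diameter of a
#' fibrous material:
#' `"diameter"`: \eqn{\langle d_p\rangle \approx 2\langle d_f\rangle}
#' (about 60\% error);
#' `"diameter-phi"`: \eqn{\langle d_p\rangle \approx
#' \langle d_f\rangle/\sqrt{\phi_f}} (about 40\% error);
#' `"diameter-phi-tau"`: \eqn{\langle d_p\rangle \approx \langle d_f\rangle
#' (1/\sqrt{\phi_f} - 0.05\langle\tau_f\rangle)} (about 20\% error).
#'
#' @param mean_df Mean fiber diameter, > 0.
#' @param phi Fiber volume fraction in (0, 1); required for the last two
#'   models.
#' @param mean_tau Mean fiber tortuosity; required for the last model.
#' @param model Which predictor to evaluate.
#' @return Predicted mean pore diameter, with attribute `"error_band"`
#'   (the predictor's approximate relative error).
#' @export
predict_mean_pore <- function(mean_df, phi = NULL, mean_tau = NULL,
                              model = c("diameter", "diameter-phi",
                                        "diameter-phi-tau")) {
  model <- match.arg(model)
  stopifnot(mean_df > 0)
  if (model != "diameter") {
    if (is.null(phi) || phi <= 0 || phi >= 1)
      stop("'phi' in (0, 1) is required for this model")
  }
  if (model == "diameter-phi-tau" && (is.null(mean_tau) || mean_tau < 1))
    stop("'mean_tau' >= 1 is required for this model")
  out <- switch(model,
    "diameter" = 2 * mean_df,
    "diameter-phi" = mean_df / sqrt(phi),
    "diameter-phi-tau" = mean_df * (1 / sqrt(phi) - 0.05 * mean_tau))
  band <- c("diameter" = 0.6, "diameter-phi" = 0.4, "diameter-phi-tau" = 0.2)
  structure(out, error_band = unname(band[model]))
}

#' Scaling-law regression of mean pore size on structure parameters
#'
#' Log--log regressions of the measured mean pore diameter on mean fiber
#' diameter and on volume fraction across an ensemble of networks. The
#' expected exponents are +1 for diameter and -1/2 for volume fraction.
#'
#' @param ensemble Data frame with columns `mean_dp`, `mean_df`, `phi`.
#' @return List with `df_slope`, `phi_slope`, their confidence intervals,
#'   and the fitted `lm` objects.
#' @export
pore_scaling_regression <- function(ensemble) {
  need <- c("mean_dp", "mean_df", "phi")
  if (!all(need %in% names(ensemble))) stop("ensemble needs columns: ",
                                            paste(need, collapse = ", "))
  if (length(unique(ensemble$mean_df)) < 2 || length(unique(ensemble$phi)) < 2)
    stop("rank deficiency: need variation in both mean_df and phi")
  fit <- stats::lm(log(mean_dp) ~ log(mean_df) + log(phi), data = ensemble)
  ci <- stats::confint(fit)
  list(df_slope = unname(stats::coef(fit)["log(mean_df)"]),
       phi_slope = unname(stats::coef(fit)["log(phi)"]),
       df_slope_ci = ci["log(mean_df)", ],
       phi_slope_ci = ci["log(phi)", ],
       fit = fit)
}
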