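#' Synthesize experimental-like histogram fixtures
#'
#' Generates the kind of digitized 2D orientation and tortuosity
#' histograms that accompany published characterizations of fibrous
#' materials, from known ground-truth parameters, so that fitting and
#' recovery can be exercised without any external data. Orientation cases
#' are 2D de la Vallee Poussin mixtures with multiplicative noise:
#' `"fibrin"` (1 kernel, k2d = 0.98), `"stonewool"` (3 kernels 60 degrees
#' apart, k2d = 5.25 each), `"polyester"` (2 orthogonal kernels, k2d =
#' 2.50 each), `"collagen"` (2 kernels, k2d = 4.00 and 2.20). Tortuosity
#' cases are truncated lognormals: `"collagen-tau"` (mean 1.1),
#' `"sintered-metal-tau"` (mean 1.6, long tail to ~3.5), `"fiberboard-tau"`
#' (mean 2.2).
#'
#' @param case Fixture name.
#' @param dir Output directory (created if needed); `NULL` returns the
#'   data without writing files.
#' @param bins Histogram bins.
#' @param noise Multiplicative noise standard deviation (lognormal).
#' @return List with `histogram` (matrix), `truth` (generating
#'   parameters), and when `dir` is given, `files` (histogram file plus a
#'   YAML sidecar recording the truth).
#' @export
make_fixtures <- function(case = c("fibrin", "stonewool", "polyester",
                                   "collagen", "collagen-tau",
                                   "sintered-metal-tau", "fiberboard-tau"),
                          dir = NULL, bins = 36L, noise = 0.05) {
  case <- match.arg(case)
  orient_cases <- list(
    fibrin = list(theta_vp = pi / 2, k2d = 0.98),
    stonewool = list(theta_vp = pi / 2 + c(-pi / 3, 0, pi / 3),
                     k2d = c(5.25, 5.25, 5.25)),
    polyester = list(theta_vp = c(pi / 4, 3 * pi / 4), k2d = c(2.50, 2.50)),
    collagen = list(theta_vp = c(pi / 3, 2 * pi / 3), k2d = c(4.00, 2.20))
  )
  tau_cases <- list(
    "collagen-tau" = list(mean = 1.1, sd = 0.05),
    "sintered-metal-tau" = list(mean = 1.6, sd = 0.45),
    "fiberboard-tau" = list(mean = 2.2, sd = 0.35)
  )
  if (case %in% names(orient_cases)) {
    p <- orient_cases[[case]]
    kern <- lapply(seq_along(p$k2d), function(i)
      list(theta_vp = p$theta_vp[i], k2d = p$k2d[i]))
    centers <- seq(pi / (2 * bins), pi - pi / (2 * bins), length.out = bins)
    dens <- vp_pdf_2d(centers, kern)
    dens <- dens * stats::rlnorm(bins, 0, noise)
    hist <- cbind(center = centers, value = dens)
    truth <- list(case = case, type = "orientation", n_vp = length(kern),
                  theta_vp_deg = p$theta_vp * 180 / pi, k2d = p$k2d)
    angles <- TRUE
  } else {
    p <- tau_cases[[case]]
    lp <- suppressMessages(lognormal_params_from_moments(p$mean, p$sd))
    samples <- sample_trunc_lognormal(lp, 20000L)
    brk <- seq(1, max(samples) + 1e-9, length.out = bins + 1L)
    h <- graphics::hist(samples, breaks = brk, plot = FALSE)
    hist <- cbind(center = h$mids, value = h$density)
    truth <- list(case = case, type = "tortuosity", mean_tau = p$mean,
                  std_tau = p$sd, m_ln = lp$m_ln, s_ln = lp$s_ln)
    angles <- FALSE
  }
  out <- list(histogram = hist, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    hfile <- file.path(dir, paste0(case, "-histogram.csv"))
    sfile <- file.path(dir, paste0(case, "-truth.yaml"))
    write_histogram(hist, hfile, angles = angles,
                    comment = paste("synthetic", truth$type, "fixture:", case))
    yaml::write_yaml(truth, sfile)
    out$files <- c(histogram = hfile, truth = sfile)
  }
  out
}
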