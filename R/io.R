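#' Read a two-column histogram file
#'
#' The interchange format for digitized experimental histograms: two
#' whitespace- or comma-delimited columns (bin center, density or count),
#' optional header, comment lines starting with `#`. Angle histograms are
#' stored in degrees on disk and converted to radians on read.
#'
#' @param path File path.
#' @param angles If `TRUE`, the first column is interpreted as degrees and
#'   converted to radians.
#' @return Two-column numeric matrix with columns `center`, `value`.
#' @export
read_histogram <- function(path, angles = FALSE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  con <- textConnection(lines)
  on.exit(close(con))
  first <- scan(con, what = "character", nlines = 1, quiet = TRUE, sep = if (grepl(",", lines[1])) "," else "")
  header <- suppressWarnings(any(is.na(as.numeric(first))))
  df <- utils::read.table(text = lines, header = header,
                          sep = if (grepl(",", lines[1])) "," else "")
  m <- as.matrix(df[, 1:2])
  colnames(m) <- c("center", "value")
  if (angles) m[, 1] <- m[, 1] * pi / 180
  m
}

#' Write a two-column histogram file
#'
#' @param hist Two-column matrix (center, value).
#' @param path Output path.
#' @param angles If `TRUE`, convert the first column from radians to
#'   degrees before writing.
#' @param comment Optional comment line(s) written at the top.
#' @export
write_histogram <- function(hist, path, angles = FALSE, comment = NULL) {
  hist <- as.matrix(hist)
  if (angles) hist[, 1] <- hist[, 1] * 180 / pi
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines("center,value", con)
  utils::write.table(format(hist, digits = 17, trim = TRUE), con, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write network fiber table
#'
#' Per-fiber prescribed and realized parameters as comma-delimited text.
#'
#' @param network A `"fiber_network"`.
#' @param path Output path.
#' @return The combined data frame, invisibly.
#' @export
write_fiber_table <- function(network, path) {
  p <- network$prescribed
  r <- realized_fibers(network)
  df <- data.frame(id = seq_len(nrow(p)),
                   diameter = p$diameter,
                   length_prescribed = p$length, length_realized = r$length,
                   tau_prescribed = p$tau, tau_realized = r$tau,
                   nx_prescribed = p$nx, ny_prescribed = p$ny, nz_prescribed = p$nz,
                   nx_realized = r$nx, ny_realized = r$ny, nz_realized = r$nz)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Write particle coordinates in extended XYZ format
#'
#' One atom per particle with columns element, x, y, z, radius.
#'
#' @param system A `"particle_system"`.
#' @param path Output path.
#' @export
write_xyz <- function(system, path) {
  n <- nrow(system$positions)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(n), "fiber network particles: x y z radius"), con)
  writeLines(sprintf("C %.10g %.10g %.10g %.10g",
                     system$positions[, 1], system$positions[, 2],
                     system$positions[, 3], system$radii), con)
  invisible(path)
}

#' Write fiber centerlines as VTK legacy polydata
#'
#' One polyline per fiber; usable in ParaView.
#'
#' @param network A `"fiber_network"`.
#' @param path Output path.
#' @export
write_vtk_polylines <- function(network, path) {
  pts <- do.call(rbind, lapply(network$fibers, `[[`, "points"))
  counts <- vapply(network$fibers, function(f) nrow(f$points), 0L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "fiber network centerlines",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(pts))), con)
  writeLines(sprintf("%.10g %.10g %.10g", pts[, 1], pts[, 2], pts[, 3]), con)
  writeLines(sprintf("LINES %d %d", length(counts), sum(counts) + length(counts)),
             con)
  offset <- 0L
  for (m in counts) {
    writeLines(paste(c(m, offset:(offset + m - 1L)), collapse = " "), con)
    offset <- offset + m
  }
  invisible(path)
}

#' Write a voxel grid as VTK legacy structured points
#'
#' Exports the occupancy (and the EDT when present) for visualization.
#'
#' @param grid A `"voxel_grid"`.
#' @param path Output path.
#' @export
write_vtk_image <- function(grid, path) {
  n <- grid$n
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "fiber network voxel grid",
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", n, n, n),
               sprintf("ORIGIN %.10g %.10g %.10g", grid$edge / 2, grid$edge / 2,
                       grid$edge / 2),
               sprintf("SPACING %.10g %.10g %.10g", grid$edge, grid$edge,
                       grid$edge),
               sprintf("POINT_DATA %d", n^3),
               "SCALARS occupancy int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(grid$occupancy)), con)
  if (!is.null(grid$edt)) {
    writeLines(c("SCALARS edt double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.10g", as.numeric(grid$edt)), con)
  }
  invisible(path)
}

#' Write a pore list as delimited text
#'
#' @param pores A `"pore_set"`.
#' @param path Output path.
#' @export
write_pore_table <- function(pores, path) {
  utils::write.csv(format(as.data.frame(pores), digits = 17, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Builds a [network_spec()] (and optional [mechanics_params()]) from a
#' YAML file. Recognized top-level keys: `seed`, `network` (fields of
#' `network_spec`, with `orientation` given as a list of
#' `{axis: [x,y,z], k3d:}` kernels), and `mechanics` (fields of
#' `mechanics_params`). Unknown keys raise a validation error.
#'
#' @param path YAML file path.
#' @return List with `spec`, `mechanics`, `seed`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), c("seed", "network", "mechanics"))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (is.null(cfg$network)) stop("config needs a 'network' section")
  net <- cfg$network
  known <- c("box_length", "volume_fraction", "diameter_mean", "diameter_std",
             "length_mean", "length_std", "orientation", "tau_mean", "tau_std",
             "tau_histogram", "beta", "diameter_floor", "spline_factor",
             "rescale_length")
  bad <- setdiff(names(net), known)
  if (length(bad)) stop("unknown network config keys: ",
                        paste(bad, collapse = ", "))
  if (!is.null(net$orientation)) {
    kernels <- lapply(net$orientation, function(k)
      vp_kernel(as.numeric(k$axis), k$k3d))
    net$orientation <- vp_params(kernels)
  }
  if (!is.null(net$tau_histogram) && is.character(net$tau_histogram))
    net$tau_histogram <- read_histogram(net$tau_histogram)
  spec <- do.call(network_spec, net)
  mech <- if (is.null(cfg$mechanics)) mechanics_params()
          else do.call(mechanics_params, cfg$mechanics)
  list(spec = spec, mechanics = mech, seed = cfg$seed)
}
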