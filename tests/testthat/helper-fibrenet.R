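# Small builders shared across tests.

# a bead dimer joined by one bond (separation = r0 + stretch)
make_dimer <- function(stretch = 0, r0 = 1.2, kb = 1, diam = 0.5, box = 10) {
  structure(list(
    positions = matrix(c(4, 5, 5, 4 + r0 + stretch, 5, 5), 2, 3, byrow = TRUE),
    velocities = matrix(0, 2, 3),
    radii = rep(diam / 2, 2), diam = rep(diam, 2), masses = c(1, 1),
    bonds = matrix(c(1L, 2L), 1), r0 = r0, kb = kb,
    angles = matrix(integer(0), 0, 3), theta0 = numeric(0), ktheta = numeric(0),
    fiber_id = c(1L, 2L), chain_idx = c(1L, 1L), fixed_idx = integer(0),
    box_length = box), class = "particle_system")
}

# free spheres (all contact-eligible), positions n x 3
make_spheres <- function(positions, radii, box = 10) {
  n <- nrow(positions)
  structure(list(
    positions = positions, velocities = matrix(0, n, 3),
    radii = radii, diam = 2 * radii, masses = rep(1, n),
    bonds = matrix(integer(0), 0, 2), r0 = numeric(0), kb = numeric(0),
    angles = matrix(integer(0), 0, 3), theta0 = numeric(0), ktheta = numeric(0),
    fiber_id = seq_len(n), chain_idx = rep(1L, n), fixed_idx = integer(0),
    box_length = box), class = "particle_system")
}

# a small quick-to-build network specification
small_spec <- function(phi = 0.1, tau = 1.2, tau_sd = 0.1, k3d = 0,
                       box = 6, dmean = 0.5, dsd = 0.05, lmean = 3, lsd = 0.4) {
  network_spec(box_length = box, volume_fraction = phi,
               diameter_mean = dmean, diameter_std = dsd,
               length_mean = lmean, length_std = lsd,
               orientation = vp_params(vp_kernel(c(0, 0, 1), k3d)),
               tau_mean = tau, tau_std = tau_sd)
}

# brute-force periodic EDT for small grids
brute_edt <- function(occ, h) {
  n <- dim(occ)[1]
  sites <- which(occ == 1, arr.ind = TRUE) - 1
  coords <- as.matrix(expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1)))
  vapply(seq_len(nrow(coords)), function(i) {
    dd <- abs(sweep(sites, 2, as.numeric(coords[i, ]), "-"))
    dd <- pmin(dd, n - dd)
    h * sqrt(min(rowSums(dd^2)))
  }, numeric(1))
}

# strict 26-neighbourhood local maxima of a periodic 3D field (> 0 only)
brute_local_maxima <- function(edt) {
  n <- dim(edt)[1]
  wrap <- function(i) ((i - 1) %% n) + 1
  out <- NULL
  for (x in 1:n) for (y in 1:n) for (z in 1:n) {
    v <- edt[x, y, z]
    if (v <= 0) next
    ismax <- TRUE
    for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
      if (ox == 0 && oy == 0 && oz == 0) next
      if (edt[wrap(x + ox), wrap(y + oy), wrap(z + oz)] >= v) { ismax <- FALSE; break }
    }
    if (ismax) out <- rbind(out, c(x, y, z, v))
  }
  out
}

cross3v <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
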