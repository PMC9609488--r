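#' Mechanics parameters for the non-penetration relaxation
#'
#' Physical parameters of the damped bead-spring dynamics. Only the relaxed
#' geometry matters, not absolute force scales, so the defaults use
#' normalized units: unit elastic modulus and particle mass, Poisson ratio
#' 0.3, and a viscosity chosen so a bonded dimer is lightly damped
#' (damping ratio about 0.1): the early contact-driven dynamics is
#' energetic, and light damping removes overlap fastest while the Stokes
#' drag still equilibrates the system.
#' The time step defaults to \eqn{0.02\sqrt{m/k_b^{max}}}, well inside the
#' stability limit of the stiffest bond.
#'
#' @param youngs Fiber elastic modulus E.
#' @param poisson Poisson ratio nu.
#' @param viscosity Fluid viscosity eta for Stokes drag; `NULL` picks the
#'   moderately damped default once the system is known.
#' @param particle_mass Mass per particle (uniform).
#' @param dt Time step; `NULL` for the default rule.
#' @param fixed_end_steps Steps during which fiber ends are frozen
#'   (default 10000), restraining rigid rotations during the initial
#'   high-energy phase.
#' @param max_steps Hard step cap.
#' @param stop_tolerance Relative change of the percent fiber overlap over
#'   the trailing window below which the run stops (after the ends are
#'   released).
#' @param window_steps Width of the plateau-detection window in steps.
#' @param pfo_every Interval (steps) at which the overlap is recorded.
#' @param stop_below Absolute PFO (percent) below which the overlap counts
#'   as removed and the run stops.
#' @return An object of class `"mechanics_params"`.
#' @export
mechanics_params <- function(youngs = 1, poisson = 0.3, viscosity = NULL,
                             particle_mass = 1, dt = NULL,
                             fixed_end_steps = 10000L, max_steps = 100000L,
                             stop_tolerance = 1e-3, window_steps = 2000L,
                             pfo_every = 200L, stop_below = 0.05) {
  stopifnot(youngs > 0, poisson > 0, particle_mass > 0,
            fixed_end_steps >= 0, max_steps > 0, stop_tolerance > 0,
            stop_below >= 0)
  structure(list(youngs = youngs, poisson = poisson, viscosity = viscosity,
                 particle_mass = particle_mass, dt = dt,
                 fixed_end_steps = as.integer(fixed_end_steps),
                 max_steps = as.integer(max_steps),
                 stop_tolerance = stop_tolerance,
                 window_steps = as.integer(window_steps),
                 pfo_every = as.integer(pfo_every),
                 stop_below = stop_below),
            class = "mechanics_params")
}

#' Stiffnesses from linear elasticity
#'
#' Maps the fiber elastic modulus to the bead-chain stiffnesses: bond
#' stiffness \eqn{k_b = EA/R_0} with cross-section \eqn{A = \pi d^2/4};
#' angle stiffness \eqn{k_\theta = EI/R_0} with second moment of area
#' \eqn{I = \pi d^4/32} by default (`standard_inertia = TRUE` switches to
#' the textbook \eqn{\pi d^4/64}); and a Hertz-like contact stiffness
#' \eqn{k_c = (E/16)\,\nu^{1/3}\sqrt{R}} with effective radius
#' \eqn{1/R = 1/d_i + 1/d_j}.
#'
#' @param youngs Elastic modulus E.
#' @param poisson Poisson ratio nu.
#' @param df_i,df_j Diameters of the two particles (equal within a fiber).
#' @param r0 Equilibrium bond length.
#' @param standard_inertia Use I = pi d^4/64 instead of pi d^4/32.
#' @return List with `kb`, `ktheta`, `kc`.
#' @export
stiffness_from_elasticity <- function(youngs, poisson, df_i, df_j = df_i, r0,
                                      standard_inertia = FALSE) {
  stopifnot(youngs > 0, poisson > 0, df_i > 0, df_j > 0, r0 > 0)
  inertia_div <- if (standard_inertia) 64 else 32
  reff <- df_i * df_j / (df_i + df_j)
  list(kb = youngs * (pi / 4 * df_i^2) / r0,
       ktheta = youngs * (pi / inertia_div * df_i^4) / r0,
       kc = youngs / 16 * poisson^(1 / 3) * sqrt(reff))
}

#' Discretize a network into a bead-chain particle system
#'
#' Each fiber becomes a chain of spherical particles at the smoothed-walk
#' points (radius = half the fiber diameter), wrapped into the periodic
#' box. Bonds connect consecutive particles with equilibrium length equal
#' to their initial separation; angle potentials act on consecutive trios
#' with equilibrium angle equal to the initial angle, so the prescribed
#' fiber shape is the stress-free state. Contact forces skip bonded pairs
#' and angle trios.
#'
#' @param network A `"fiber_network"`.
#' @param params A `"mechanics_params"`.
#' @return An object of class `"particle_system"`.
#' @export
discretize_network <- function(network, params = mechanics_params()) {
  L <- network$spec$box_length
  pos_list <- list(); fiber_id <- integer(0); chain_idx <- integer(0)
  diam <- numeric(0); ends <- integer(0)
  bonds <- list(); angles <- list()
  kb <- numeric(0); ktheta <- numeric(0); r0 <- numeric(0); theta0 <- numeric(0)
  offset <- 0L
  for (fi in seq_along(network$fibers)) {
    f <- network$fibers[[fi]]
    pts <- f$points
    m <- nrow(pts)
    pos_list[[fi]] <- pts
    fiber_id <- c(fiber_id, rep.int(fi, m))
    chain_idx <- c(chain_idx, seq_len(m))
    diam <- c(diam, rep.int(f$diameter, m))
    ends <- c(ends, offset + 1L, offset + m)
    if (m >= 2) {
      seg <- sqrt(rowSums(diff(pts)^2))
      bi <- cbind(offset + seq_len(m - 1L), offset + seq_len(m - 1L) + 1L)
      bonds[[fi]] <- bi
      r0 <- c(r0, seg)
      kb <- c(kb, params$youngs * (pi / 4 * f$diameter^2) / seg)
    }
    if (m >= 3) {
      ai <- cbind(offset + seq_len(m - 2L), offset + seq_len(m - 2L) + 1L,
                  offset + seq_len(m - 2L) + 2L)
      angles[[fi]] <- ai
      v1 <- pts[seq_len(m - 2L), , drop = FALSE] - pts[seq_len(m - 2L) + 1L, , drop = FALSE]
      v2 <- pts[seq_len(m - 2L) + 2L, , drop = FALSE] - pts[seq_len(m - 2L) + 1L, , drop = FALSE]
      cth <- rowSums(v1 * v2) / (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
      theta0 <- c(theta0, acos(pmin(1, pmax(-1, cth))))
      seg <- sqrt(rowSums(diff(pts)^2))
      r0_mean <- (seg[seq_len(m - 2L)] + seg[seq_len(m - 2L) + 1L]) / 2
      ktheta <- c(ktheta, params$youngs * (pi / 32 * f$diameter^4) / r0_mean)
    }
    offset <- offset + m
  }
  pos <- do.call(rbind, pos_list)
  pos <- pos %% L
  bonds <- if (length(bonds)) do.call(rbind, bonds) else matrix(integer(0), 0, 2)
  angles <- if (length(angles)) do.call(rbind, angles) else matrix(integer(0), 0, 3)
  structure(list(positions = pos,
                 velocities = matrix(0, nrow(pos), 3),
                 radii = diam / 2, diam = diam,
                 masses = rep(params$particle_mass, nrow(pos)),
                 bonds = bonds, r0 = r0, kb = kb,
                 angles = angles, theta0 = theta0, ktheta = ktheta,
                 fiber_id = fiber_id, chain_idx = chain_idx,
                 fixed_idx = ends, box_length = L),
            class = "particle_system")
}

# fill in derived defaults (dt, viscosity) once the system is known
resolve_mechanics <- function(system, params) {
  if (is.null(params$dt)) {
    kb_max <- if (length(system$kb)) max(system$kb) else 1
    params$dt <- 0.02 * sqrt(min(system$masses) / kb_max)
  }
  if (is.null(params$viscosity)) {
    kb_max <- if (length(system$kb)) max(system$kb) else 1
    # underdamped dimer (damping ratio ~ 0.1): c = 0.2 sqrt(2 kb m); the
    # initial contact-driven phase is energetic (hence the frozen fiber
    # ends) and light damping lets overlaps resolve quickly
    params$viscosity <- 0.2 * sqrt(2 * kb_max * min(system$masses)) /
      (3 * pi * max(system$diam))
  }
  params
}

#' Per-particle bond forces
#' @param system A `"particle_system"`.
#' @return n-by-3 force matrix.
#' @export
bond_forces <- function(system) {
  bond_forces_cpp(system$positions, system$bonds, system$r0, system$kb,
                  system$box_length)
}

#' Per-particle angle forces
#' @param system A `"particle_system"`.
#' @return n-by-3 force matrix.
#' @export
angle_forces <- function(system) {
  angle_forces_cpp(system$positions, system$angles, system$theta0,
                   system$ktheta, system$box_length)
}

#' Per-particle soft contact forces
#' @param system A `"particle_system"`.
#' @param params A `"mechanics_params"` (for E and nu).
#' @return n-by-3 force matrix.
#' @export
contact_forces <- function(system, params = mechanics_params()) {
  contact_forces_cpp(system$positions, system$diam, system$fiber_id,
                     system$chain_idx, params$youngs, params$poisson,
                     system$box_length)
}

#' Per-particle Stokes drag forces
#' @param system A `"particle_system"`.
#' @param eta Fluid viscosity.
#' @return n-by-3 force matrix.
#' @export
drag_forces <- function(system, eta) {
  drag_forces_cpp(system$velocities, system$diam, eta)
}

#' Percent fiber overlap of a particle system
#'
#' Total pairwise sphere--sphere intersection (lens) volume over
#' non-excluded pairs, divided by the total sphere volume, times 100.
#'
#' @param system A `"particle_system"`.
#' @return PFO in percent.
#' @export
percent_fiber_overlap <- function(system) {
  pfo_cpp(system$positions, system$radii, system$fiber_id, system$chain_idx,
          system$box_length)
}

#' Advance a particle system by velocity-Verlet steps
#'
#' R-level stepping driver (one force evaluation per half-kick), intended
#' for small systems and numerical experiments; [relax()] runs the whole
#' loop in compiled code.
#'
#' @param system A `"particle_system"`.
#' @param params A `"mechanics_params"`; a `NULL` viscosity here means no
#'   drag.
#' @param n_steps Number of steps to take.
#' @param frozen Freeze the `fixed_idx` particles during these steps.
#' @return The advanced system.
#' @export
step_velocity_verlet <- function(system, params = mechanics_params(), n_steps = 1L,
                                 frozen = FALSE) {
  eta <- if (is.null(params$viscosity)) 0 else params$viscosity
  dt <- params$dt
  if (is.null(dt)) dt <- resolve_mechanics(system, params)$dt
  L <- system$box_length
  forces <- function() {
    total_forces_cpp(system$positions, system$velocities, system$bonds,
                     system$r0, system$kb, system$angles, system$theta0,
                     system$ktheta, system$diam, system$fiber_id,
                     system$chain_idx, params$youngs, params$poisson, eta,
                     L)$forces
  }
  fixed <- if (frozen) system$fixed_idx else integer(0)
  f <- forces()
  for (s in seq_len(n_steps)) {
    a <- f / system$masses
    system$velocities <- system$velocities + 0.5 * dt * a
    if (length(fixed)) system$velocities[fixed, ] <- 0
    system$positions <- (system$positions + dt * system$velocities) %% L
    f <- forces()
    system$velocities <- system$velocities + 0.5 * dt * (f / system$masses)
    if (length(fixed)) system$velocities[fixed, ] <- 0
  }
  if (any(!is.finite(system$positions)))
    stop("instability: non-finite positions (dt = ", dt, " too large)")
  system
}

#' Total mechanical energy of a particle system
#'
#' Kinetic plus bond, angle, and contact potential energy (drag is
#' non-conservative and excluded).
#'
#' @param system A `"particle_system"`.
#' @param params A `"mechanics_params"`.
#' @return Energy (scalar).
#' @export
system_energy <- function(system, params = mechanics_params()) {
  pot <- total_forces_cpp(system$positions, system$velocities, system$bonds,
                          system$r0, system$kb, system$angles, system$theta0,
                          system$ktheta, system$diam, system$fiber_id,
                          system$chain_idx, params$youngs, params$poisson, 0,
                          system$box_length, with_energy = TRUE)$potential
  kin <- 0.5 * sum(system$masses * rowSums(system$velocities^2))
  pot + kin
}

#' Enforce non-penetration by damped dynamics
#'
#' Discretizes the network into a bead-chain particle system and runs
#' damped velocity-Verlet dynamics with bond, angle, soft-contact, and
#' Stokes drag forces until the percent fiber overlap (PFO) plateaus.
#' Fiber ends are frozen for the first `fixed_end_steps` steps. If the
#' integration goes unstable the time step is halved and the run restarts
#' (up to 3 times).
#'
#' @param network A `"fiber_network"`.
#' @param params A `"mechanics_params"`.
#' @return A list of class `"relax_result"`: `network` (relaxed copy with
#'   rebuilt fiber paths), `pfo_trace` (data frame step/pfo), `system`
#'   (final particle system), and `change_report` (per-fiber absolute
#'   percent changes in length, tortuosity, and orientation, plus means).
#' @export
relax <- function(network, params = mechanics_params()) {
  system <- discretize_network(network, params)
  params <- resolve_mechanics(system, params)
  dt <- params$dt
  res <- NULL
  for (attempt in 1:4) {
    res <- tryCatch(
      relax_cpp(system$positions, system$radii, system$diam, system$masses,
                system$bonds, system$r0, system$kb,
                system$angles, system$theta0, system$ktheta,
                system$fiber_id, system$chain_idx, system$fixed_idx,
                params$youngs, params$poisson, params$viscosity,
                system$box_length, dt,
                params$fixed_end_steps, params$max_steps,
                params$stop_tolerance, params$pfo_every, params$window_steps,
                params$stop_below),
      error = function(e) {
        if (grepl("instability", conditionMessage(e)) && attempt < 4) NULL
        else stop(e)
      })
    if (!is.null(res)) break
    dt <- dt / 2
  }
  system$positions <- res$positions
  system$velocities <- res$velocities

  relaxed <- rebuild_network(network, system)
  before <- realized_fibers(network)
  after <- realized_fibers(relaxed)
  dot <- abs(rowSums(before[, c("nx", "ny", "nz")] * after[, c("nx", "ny", "nz")]))
  angle_deg <- acos(pmin(1, dot)) * 180 / pi
  report <- data.frame(
    fiber = seq_len(nrow(before)),
    length_change = 100 * abs(after$length - before$length) / before$length,
    tau_change = 100 * abs(after$tau - before$tau) / before$tau,
    orientation_change = 100 * angle_deg / 90
  )
  structure(list(network = relaxed,
                 pfo_trace = data.frame(step = res$pfo_step, pfo = res$pfo),
                 system = system,
                 change_report = report,
                 mean_changes = c(length = mean(report$length_change),
                                  tau = mean(report$tau_change),
                                  orientation = mean(report$orientation_change)),
                 dt = dt, steps = res$steps),
            class = "relax_result")
}

# rebuild fiber paths from (wrapped) particle positions by unwrapping each
# chain with minimum-image steps from its first particle
rebuild_network <- function(network, system) {
  L <- system$box_length
  relaxed <- network
  for (fi in seq_along(network$fibers)) {
    sel <- system$fiber_id == fi
    pts <- system$positions[sel, , drop = FALSE]
    if (nrow(pts) > 1) {
      d <- diff(pts)
      d <- d - L * round(d / L)
      steps <- rbind(d[1, ])
      if (nrow(d) > 1) steps <- apply(d, 2, cumsum)
      pts <- rbind(pts[1, ], sweep(rbind(steps), 2, pts[1, ], `+`))
    }
    relaxed$fibers[[fi]] <- fiber_path(pts, network$fibers[[fi]]$diameter)
  }
  relaxed
}
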