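# Overdamped magnetophoretic particle tracing between the two magnets.
#
# The driving force on a magnetizable bead of radius r_p in a fluid of
# relative permeability mu_f is
#   F = 2 pi r_p^3 mu0 mu_f * (mu_p - mu_f)/(mu_p + 2 mu_f) * grad(|H|^2),
# the dipole (Clausius-Mossotti) magnetophoresis closure. Inertia is
# neglected: beads of this size reach terminal velocity in ~ns, so the motion
# is pure Stokes drift v = F / (6 pi eta r_p).

KB <- 1.380649e-23

#' Magnetic nanoparticle physical parameters
#'
#' Defaults describe the 250 nm dextran-coated iron-oxide beads used for
#' collagen alignment: radius 125 nm, density 5240 kg/m^3, magnetic
#' susceptibility 6.27.
#'
#' @param radius Particle radius (m).
#' @param susceptibility Dimensionless volume susceptibility chi_p.
#' @param density Particle density (kg/m^3).
#' @return A `particle_spec` list; `mu_rel = 1 + chi_p`.
#' @export
particle_spec <- function(radius = 125e-9, susceptibility = 6.27,
                          density = 5240) {
  stopifnot(radius > 0, density > 0)
  mu_rel <- 1 + susceptibility
  if (mu_rel <= 0) stop("relative permeability must be positive")
  structure(list(radius = radius, susceptibility = susceptibility,
                 density = density, mu_rel = mu_rel),
            class = "particle_spec")
}

#' Suspending-fluid parameters (defaults: water at 37 C scale)
#'
#' @param susceptibility chi_f, dimensionless (0 for an effectively
#'   nonmagnetic medium).
#' @param viscosity Dynamic viscosity (Pa s); default 1.0e-3.
#' @param temperature Kelvin, used only when Brownian motion is enabled.
#' @return A `fluid_spec` list; `mu_rel = 1 + chi_f`.
#' @export
fluid_spec <- function(susceptibility = 0, viscosity = 1.0e-3,
                       temperature = 310) {
  stopifnot(viscosity > 0, temperature > 0)
  structure(list(susceptibility = susceptibility, viscosity = viscosity,
                 temperature = temperature, mu_rel = 1 + susceptibility),
            class = "fluid_spec")
}

#' Simulation configuration
#'
#' @param dt Time step (s); default 0.01.
#' @param t_end End time (s); default 0.1.
#' @param n_particles Number of beads.
#' @param rng_seed Integer seed; fixes the initial droplet draw (and Brownian
#'   kicks) exactly.
#' @param droplet_volume Initial droplet volume (m^3); default 1e-7 (100 ul).
#' @param well Axis-aligned box `list(lo, hi)` (m); default a cube of side
#'   8 mm centered at the origin.
#' @param brownian Add Brownian displacements (default FALSE; the deterministic
#'   drift dominates at these field gradients).
#' @return A `sim_config` list.
#' @export
sim_config <- function(dt = 0.01, t_end = 0.1, n_particles = 1000,
                       rng_seed = 1, droplet_volume = 1e-7,
                       well = list(lo = c(-4e-3, -4e-3, -4e-3),
                                   hi = c(4e-3, 4e-3, 4e-3)),
                       brownian = FALSE) {
  stopifnot(dt > 0, t_end >= dt, n_particles >= 1, droplet_volume > 0)
  structure(list(dt = dt, t_end = t_end, n_particles = n_particles,
                 rng_seed = as.integer(rng_seed),
                 droplet_volume = droplet_volume, well = well,
                 brownian = brownian),
            class = "sim_config")
}

#' Magnetophoretic force on a bead
#'
#' F = 2 pi r_p^3 mu0 mu_f ((mu_p - mu_f) / (mu_p + 2 mu_f)) grad(|H|^2),
#' with mu_p and mu_f relative permeabilities and grad(|H|^2) in A^2/m^3.
#'
#' @param p A [particle_spec()].
#' @param f A [fluid_spec()].
#' @param gradH2 Length-3 vector or n x 3 matrix (A^2/m^3).
#' @return Force in newtons, same shape as `gradH2`.
#' @export
magnetophoretic_force <- function(p, f, gradH2) {
  denom <- p$mu_rel + 2 * f$mu_rel
  if (abs(denom) < .Machine$double.eps)
    stop("nonphysical permeabilities: mu_p + 2 mu_f = 0")
  cm <- (p$mu_rel - f$mu_rel) / denom
  2 * pi * p$radius^3 * MU0 * f$mu_rel * cm * gradH2
}

#' Stokes drift velocity of a bead under a force
#'
#' @param F Force (N), vector or n x 3 matrix.
#' @param p A [particle_spec()].
#' @param f A [fluid_spec()].
#' @return v = F / (6 pi eta r_p) in m/s.
#' @export
drift_velocity <- function(F, p, f) {
  F / (6 * pi * f$viscosity * p$radius)
}

#' Seed beads uniformly in a central droplet
#'
#' Positions are drawn uniformly from a sphere whose volume equals
#' `droplet_volume`, centered in the well; the draw is a pure function of
#' `rng_seed`.
#'
#' @param cfg A [sim_config()].
#' @return A `particle_ensemble`: `positions` (n x 3, m), `droplet_radius`,
#'   `well`.
#' @export
initialize_ensemble <- function(cfg) {
  R <- (3 * cfg$droplet_volume / (4 * pi))^(1 / 3)
  ctr <- (cfg$well$lo + cfg$well$hi) / 2
  side <- cfg$well$hi - cfg$well$lo
  if (2 * R > min(side)) stop("droplet does not fit inside the well")
  n <- cfg$n_particles
  pos <- withr::with_seed(cfg$rng_seed, {
    u <- matrix(stats::rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    r <- R * stats::runif(n)^(1 / 3)
    sweep(u * r, 2, ctr, `+`)
  })
  structure(list(positions = pos, droplet_radius = R, well = cfg$well,
                 center = ctr),
            class = "particle_ensemble")
}

# Reflect coordinates into [lo, hi] (single bounce; steps are tiny).
.reflect <- function(x, lo, hi) {
  for (d in 1:3) {
    under <- x[, d] < lo[d]
    x[under, d] <- 2 * lo[d] - x[under, d]
    over <- x[, d] > hi[d]
    x[over, d] <- 2 * hi[d] - x[over, d]
  }
  x
}

#' Trace bead trajectories through the device field
#'
#' Explicit-Euler overdamped update `x <- x + v(x) dt` for `t_end / dt` steps,
#' with the drift velocity from [magnetophoretic_force()] and
#' [drift_velocity()], reflective well walls, and (optionally) Brownian kicks
#' of per-axis variance `2 D dt`, `D = kT / (6 pi eta r_p)`.
#'
#' A `force_field` override (function n x 3 -> n x 3 newtons) replaces the
#' device force; this is a test harness hook for analytically known fields.
#'
#' @param device A calibrated [magnet_device()] (ignored when `force_field`
#'   is given).
#' @param cfg A [sim_config()].
#' @param p A [particle_spec()].
#' @param f A [fluid_spec()].
#' @param force_field Optional function(P) -> n x 3 force matrix.
#' @param init_positions Optional n x 3 matrix of starting positions (m),
#'   replacing the droplet draw (positions must lie inside the well).
#' @return A `trajectory_set`: `positions` array (steps+1, n, 3), `start`,
#'   `end` (n x 3), `dt`, `times`.
#' @export
run_simulation <- function(device, cfg, p = particle_spec(),
                           f = fluid_spec(), force_field = NULL,
                           init_positions = NULL) {
  x <- if (is.null(init_positions)) initialize_ensemble(cfg)$positions
       else .as_points(init_positions)
  lo <- cfg$well$lo; hi <- cfg$well$hi
  if (any(x < matrix(lo, nrow(x), 3, byrow = TRUE)) ||
      any(x > matrix(hi, nrow(x), 3, byrow = TRUE)))
    stop("particle initialized outside the well")
  nsteps <- round(cfg$t_end / cfg$dt)
  n <- nrow(x)
  traj <- array(NA_real_, c(nsteps + 1, n, 3))
  traj[1, , ] <- x
  mob <- 1 / (6 * pi * f$viscosity * p$radius)
  if (cfg$brownian) {
    D <- KB * f$temperature * mob
    sig <- sqrt(2 * D * cfg$dt)
    # Brownian stream drawn up front, seeded independently of initialization
    kicks <- withr::with_seed(cfg$rng_seed + 1L,
      array(stats::rnorm(nsteps * n * 3, sd = sig), c(nsteps, n, 3)))
  }
  for (s in seq_len(nsteps)) {
    Fm <- if (is.null(force_field)) {
      magnetophoretic_force(p, f, device_gradH2(device, x))
    } else {
      force_field(x)
    }
    x <- x + Fm * mob * cfg$dt
    if (cfg$brownian) x <- x + kicks[s, , ]
    x <- .reflect(x, lo, hi)
    traj[s + 1, , ] <- x
  }
  structure(list(positions = traj, start = traj[1, , , drop = TRUE],
                 end = traj[nsteps + 1, , , drop = TRUE],
                 dt = cfg$dt, times = seq(0, by = cfg$dt, length.out = nsteps + 1)),
            class = "trajectory_set")
}

#' Net-motion directionality of a trajectory set
#'
#' Each bead's net displacement (end minus start) is converted to an angle
#' theta = atan2(dx_field, dy_orthogonal) in degrees, folded mod 180 into
#' [0, 180). The convention measures from the axis orthogonal to the applied
#' field: displacement along the field axis gives 90 deg, along the in-plane
#' orthogonal axis 0 deg. Beads with zero net displacement are excluded and
#' counted.
#'
#' @param traj A `trajectory_set` from [run_simulation()].
#' @param bin_width Histogram bin width in degrees (default 0.5).
#' @return A `motion_directionality`: `angles` (deg), `histogram` (data frame
#'   of bin_start, bin_end, count), `median`, `mode_bin` (center of densest
#'   bin, deg), `n_excluded`.
#' @export
motion_directionality <- function(traj, bin_width = 0.5) {
  d <- traj$end - traj$start
  if (is.null(dim(d))) d <- matrix(d, 1, 3)
  moved <- rowSums(d^2) > 0
  n_excluded <- sum(!moved)
  if (!any(moved)) stop("degenerate run: all net displacements are zero")
  d <- d[moved, , drop = FALSE]
  theta <- atan2(d[, 1], d[, 2]) * 180 / pi
  theta <- theta %% 180
  edges <- seq(0, 180, by = bin_width)
  counts <- as.vector(table(cut(theta, edges, right = FALSE,
                                include.lowest = TRUE)))
  hist <- data.frame(bin_start = edges[-length(edges)],
                     bin_end = edges[-1], count = counts)
  mode_bin <- hist$bin_start[which.max(hist$count)] + bin_width / 2
  structure(list(angles = theta, histogram = hist,
                 median = stats::median(theta), mode_bin = mode_bin,
                 n_excluded = n_excluded),
            class = "motion_directionality")
}
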