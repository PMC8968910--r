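# Analytic magnetostatics for a pair of facing cuboid permanent magnets.
#
# Coordinate frame: field axis = x, image-transect axis = y, optical axis = z;
# the device midpoint (center of the gap) is the origin.

#' Vacuum permeability (T m / A)
#' @keywords internal
MU0 <- 4e-7 * pi

#' Create a cuboid permanent-magnet block
#'
#' A uniformly magnetized rectangular block described in its own local frame,
#' where the magnetization points along the local z axis. The exterior field is
#' the classical closed-form (equivalent surface charge) solution for a
#' uniformly magnetized cuboid.
#'
#' @param dim Numeric length-3: full extents (m) along the local x, y, z axes.
#'   The magnetization is along local z, so `dim[3]` is the pole-to-pole depth.
#' @param remanence Residual flux density Br (T); must be >= 0.
#' @param center Block center in the global frame (m).
#' @param magnetization_axis Unit vector (global frame) of the magnetization.
#' @param polarity +1 or -1 along `magnetization_axis`.
#' @return An object of class `magnet_block`.
#' @export
magnet_block <- function(dim, remanence, center = c(0, 0, 0),
                         magnetization_axis = c(0, 0, 1), polarity = 1) {
  dim <- as.numeric(dim)
  stopifnot(length(dim) == 3, all(is.finite(dim)))
  if (any(dim <= 0)) stop("all block dimensions must be > 0")
  if (remanence < 0) stop("remanence must be >= 0")
  if (!polarity %in% c(-1, 1)) stop("polarity must be +1 or -1")
  axis <- as.numeric(magnetization_axis)
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm - 1) > 1e-8) stop("magnetization_axis must be a unit vector")
  axis <- axis / nrm
  structure(list(dim = dim, remanence = as.numeric(remanence),
                 center = as.numeric(center), axis = axis,
                 polarity = polarity, rot = .frame_from_axis(axis)),
            class = "magnet_block")
}

# Orthonormal frame whose third column is `axis` (local z -> global axis).
.frame_from_axis <- function(axis) {
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  cbind(e1, e2, axis, deparse.level = 0)
}

# Closed-form field of a cuboid magnetized along local +z, remanence Br,
# half-dimensions (a, b, c), evaluated at local points P (n x 3).
# Sign convention validated against surface-charge quadrature.
.cuboid_field_local <- function(P, a, b, c, Br) {
  x <- P[, 1]; y <- P[, 2]; z <- P[, 3]
  C <- Br / (4 * pi)
  Bx <- By <- Bz <- numeric(length(x))
  xs <- cbind(x + a, x - a)
  ys <- cbind(y + b, y - b)
  zs <- cbind(z + c, z - c)
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    s <- (-1)^(i + j + k)
    r <- sqrt(xs[, i]^2 + ys[, j]^2 + zs[, k]^2)
    Bx <- Bx + s * log(pmax(r - ys[, j], 1e-300))
    By <- By + s * log(pmax(r - xs[, i], 1e-300))
    Bz <- Bz + s * atan2(xs[, i] * ys[, j], zs[, k] * r)
  }
  cbind(C * Bx, C * By, C * Bz)
}

.as_points <- function(point) {
  if (is.matrix(point)) {
    stopifnot(ncol(point) == 3)
    point
  } else {
    stopifnot(length(point) == 3)
    matrix(as.numeric(point), 1, 3)
  }
}

.inside_block <- function(block, P) {
  L <- sweep(P, 2, block$center) %*% block$rot # local coordinates
  abs(L[, 1]) < block$dim[1] / 2 &
    abs(L[, 2]) < block$dim[2] / 2 &
    abs(L[, 3]) < block$dim[3] / 2
}

#' Magnetic flux density of a single cuboid block
#'
#' @param block A [magnet_block()].
#' @param point A length-3 vector or an n x 3 matrix of points (m), none
#'   strictly inside the block.
#' @return B in tesla: a length-3 vector for a single point, otherwise an
#'   n x 3 matrix.
#' @export
field_of_block <- function(block, point) {
  P <- .as_points(point)
  if (any(.inside_block(block, P)))
    stop("field is undefined strictly inside the magnet block")
  L <- sweep(P, 2, block$center) %*% block$rot
  Bl <- .cuboid_field_local(L, block$dim[1] / 2, block$dim[2] / 2,
                            block$dim[3] / 2,
                            block$polarity * block$remanence)
  B <- Bl %*% t(block$rot)
  if (!is.matrix(point)) B[1, ] else B
}

#' Create the two-magnet alignment device
#'
#' Two identical cuboid magnets face each other pole-to-pole across a gap along
#' the device x axis (the field axis), mirror-symmetric about the gap midplane.
#' Both blocks are magnetized in the same +x direction, so the north face of
#' one magnet faces the south face of the other and the gap fields add.
#'
#' @param magnet_length Magnet extent along y (m); default 40 mm.
#' @param magnet_width Magnet extent along z (m); default 20 mm.
#' @param magnet_depth Pole-to-pole extent along x (m); default 10 mm (the
#'   depth is not fixed by the device drawing; calibration absorbs it).
#' @param gap Face-to-face gap along x (m); default 7.2 mm.
#' @param remanence Br of each block (T); default 1.31 T (nominal N42).
#' @param sample_region Axis-aligned box, list with `lo` and `hi` (m);
#'   default an 8 x 8 x 2 mm box centered at the origin.
#' @return An object of class `magnet_device`.
#' @export
magnet_device <- function(magnet_length = 40e-3, magnet_width = 20e-3,
                          magnet_depth = 10e-3, gap = 7.2e-3,
                          remanence = 1.31,
                          sample_region = list(lo = c(-4e-3, -4e-3, -1e-3),
                                               hi = c(4e-3, 4e-3, 1e-3))) {
  stopifnot(gap > 0)
  off <- gap / 2 + magnet_depth / 2
  dims <- c(magnet_length, magnet_width, magnet_depth) # local x,y,z
  axis <- c(1, 0, 0)
  m1 <- magnet_block(dims, remanence, center = c(-off, 0, 0),
                     magnetization_axis = axis)
  m2 <- magnet_block(dims, remanence, center = c(off, 0, 0),
                     magnetization_axis = axis)
  structure(list(magnets = list(m1, m2), gap = gap,
                 field_axis = c(1, 0, 0), sample_region = sample_region),
            class = "magnet_device")
}

#' @export
print.magnet_device <- function(x, ...) {
  b <- device_field(x, c(0, 0, 0))
  cat(sprintf(
    "magnet_device: 2 cuboid blocks %s mm, gap %.2f mm, Br %.4f T\n",
    paste(format(x$magnets[[1]]$dim * 1e3, trim = TRUE), collapse = " x "),
    x$gap * 1e3, x$magnets[[1]]$remanence))
  cat(sprintf("  midpoint |B| = %.3f mT\n", sqrt(sum(b$B^2)) * 1e3))
  invisible(x)
}

#' Flux density of the device at a set of points
#'
#' Superposition of the two blocks. Vectorized over points.
#'
#' @param device A [magnet_device()].
#' @param P n x 3 matrix of points (m), all outside both blocks.
#' @return n x 3 matrix of B (T).
#' @export
device_B <- function(device, P) {
  P <- .as_points(P)
  field_of_block(device$magnets[[1]], P) +
    field_of_block(device$magnets[[2]], P)
}

#' Field sample at a point: B, H, and the gradient of |H|^2
#'
#' H = B / mu0 in the nonmagnetic gap medium. The gradient of |H|^2 (the
#' driving quantity of magnetophoresis) is computed by central differences of
#' the scalar |H|^2 with step `h`.
#'
#' @param device A [magnet_device()].
#' @param point Length-3 point (m), outside both blocks.
#' @param h Central-difference step (m); default 1e-5.
#' @return A list of class `field_sample` with `point`, `B` (T), `H` (A/m)
#'   and `gradH2` (A^2/m^3).
#' @export
device_field <- function(device, point, h = 1e-5) {
  B <- device_B(device, matrix(point, 1, 3))[1, ]
  g <- device_gradH2(device, matrix(point, 1, 3), h = h)[1, ]
  structure(list(point = as.numeric(point), B = B, H = B / MU0, gradH2 = g),
            class = "field_sample")
}

#' Gradient of |H|^2 at a set of points (central differences)
#'
#' @param device A [magnet_device()].
#' @param P n x 3 matrix of points (m).
#' @param h Step (m).
#' @return n x 3 matrix of grad(|H|^2) in A^2/m^3.
#' @export
device_gradH2 <- function(device, P, h = 1e-5) {
  P <- .as_points(P)
  h2 <- function(Q) rowSums(device_B(device, Q)^2) / MU0^2
  g <- matrix(0, nrow(P), 3)
  for (d in 1:3) {
    e <- matrix(0, nrow(P), 3)
    e[, d] <- h
    g[, d] <- (h2(P + e) - h2(P - e)) / (2 * h)
  }
  g
}

#' Calibrate the device remanence to a target midpoint field
#'
#' The field is linear in remanence, so scaling Br by
#' `target / |B(midpoint)|` matches the target exactly while leaving every
#' field-line direction (and hence every simulated motion angle) unchanged.
#'
#' @param device A [magnet_device()].
#' @param target_B_midpoint Target |B| at the device midpoint (T);
#'   default 51 mT, the center of the 50-52 mT window measured for the
#'   experimental device.
#' @return A calibrated `magnet_device`.
#' @export
calibrate_device <- function(device, target_B_midpoint = 51e-3) {
  if (target_B_midpoint <= 0) stop("target_B_midpoint must be > 0")
  B0 <- sqrt(sum(device_B(device, c(0, 0, 0))^2))
  if (B0 <= 0) stop("target unreachable: device has zero midpoint field")
  k <- target_B_midpoint / B0
  for (i in 1:2) device$magnets[[i]]$remanence <-
    device$magnets[[i]]$remanence * k
  device
}

#' Mean gradient magnitude of |B| across the sample region
#'
#' Reported for comparison with the gradient quoted for the experimental
#' device (not an asserted quantity: it depends on geometry details the device
#' description leaves open). Grid points falling inside a magnet are skipped.
#'
#' @param device A [magnet_device()].
#' @param n Grid points per axis (length-3 or scalar).
#' @param h Central-difference step (m).
#' @return Mean of |grad |B|| over the grid, in T/m.
#' @export
sample_region_gradient <- function(device, n = c(7, 7, 3), h = 1e-5) {
  n <- rep(n, length.out = 3)
  sr <- device$sample_region
  gx <- seq(sr$lo[1], sr$hi[1], length.out = n[1])
  gy <- seq(sr$lo[2], sr$hi[2], length.out = n[2])
  gz <- seq(sr$lo[3], sr$hi[3], length.out = n[3])
  P <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  inside <- .inside_block(device$magnets[[1]], P) |
    .inside_block(device$magnets[[2]], P)
  # also skip points within one step of a block face
  for (e in list(c(h,0,0), c(-h,0,0), c(0,h,0), c(0,-h,0), c(0,0,h), c(0,0,-h)))
    inside <- inside | .inside_block(device$magnets[[1]], sweep(P, 2, -e)) |
      .inside_block(device$magnets[[2]], sweep(P, 2, -e))
  P <- P[!inside, , drop = FALSE]
  bmag <- function(Q) sqrt(rowSums(device_B(device, Q)^2))
  g <- matrix(0, nrow(P), 3)
  for (d in 1:3) {
    e <- matrix(0, nrow(P), 3)
    e[, d] <- h
    g[, d] <- (bmag(P + e) - bmag(P - e)) / (2 * h)
  }
  mean(sqrt(rowSums(g^2)))
}

#' Export a CSV grid of the device field
#'
#' Writes columns x, y, z, Bx, By, Bz, Bmag (SI units) for a regular grid
#' over the sample region; grid points inside a magnet are omitted.
#'
#' @param device A [magnet_device()].
#' @param path Output CSV path.
#' @param n Grid points per axis.
#' @return Invisibly, the data frame written.
#' @export
export_fieldmap <- function(device, path, n = c(11, 11, 3)) {
  n <- rep(n, length.out = 3)
  sr <- device$sample_region
  P <- as.matrix(expand.grid(
    x = seq(sr$lo[1], sr$hi[1], length.out = n[1]),
    y = seq(sr$lo[2], sr$hi[2], length.out = n[2]),
    z = seq(sr$lo[3], sr$hi[3], length.out = n[3])))
  inside <- .inside_block(device$magnets[[1]], P) |
    .inside_block(device$magnets[[2]], P)
  P <- P[!inside, , drop = FALSE]
  B <- device_B(device, P)
  df <- data.frame(x = P[, 1], y = P[, 2], z = P[, 3],
                   Bx = B[, 1], By = B[, 2], Bz = B[, 3],
                   Bmag = sqrt(rowSums(B^2)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Build a device from a YAML configuration
#'
#' Recognized keys (all optional, units as in [magnet_device()] but lengths in
#' mm and the calibration target in mT): `magnet_length_mm`, `magnet_width_mm`,
#' `magnet_depth_mm`, `gap_mm`, `remanence_T`, `target_B_mT`.
#'
#' @param path YAML file path, or a pre-parsed list.
#' @return A calibrated `magnet_device` (calibration applied iff
#'   `target_B_mT` is present).
#' @export
device_from_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  dv <- magnet_device(
    magnet_length = (cfg$magnet_length_mm %||% 40) * 1e-3,
    magnet_width = (cfg$magnet_width_mm %||% 20) * 1e-3,
    magnet_depth = (cfg$magnet_depth_mm %||% 10) * 1e-3,
    gap = (cfg$gap_mm %||% 7.2) * 1e-3,
    remanence = cfg$remanence_T %||% 1.31)
  if (!is.null(cfg$target_B_mT))
    dv <- calibrate_device(dv, cfg$target_B_mT * 1e-3)
  dv
}

`%||%` <- function(a, b) if (is.null(a)) b else a
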