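# Seeded synthetic micrograph generators with ground truth.
#
# Every generator is a pure function of its scene spec (seed included) and
# returns both the rendered image and the ground truth used to render it, so
# the analysis modules can be tested by parameter recovery without any of the
# study's raw micrographs. Rendering uses additive line/ellipse profiles with
# Gaussian cross-sections; no optical PSF is simulated.

#' Scene specification for the synthetic generators
#'
#' @param kind One of `"aligned_fibers"`, `"isotropic_fibers"`,
#'   `"mnp_strings"`, `"segmented_gel"`, `"actin_cells"`, `"noise"`.
#' @param size Image size in pixels, `c(rows, cols)`; default 256 x 256.
#' @param pixel_size_um Micrometers per pixel; default 1.61.
#' @param orientation_mean Mean structure orientation (deg, 0 = across the
#'   image width); default 90 (along the field axis).
#' @param orientation_spread SD of the wrapped-Gaussian orientation noise
#'   (deg); 0 means perfectly aligned.
#' @param density Number of fibers / strings per scene; default 120.
#' @param gaps Data frame `position_um`, `width_um` of dark bands for
#'   `segmented_gel` scenes (positions are left edges along the width).
#' @param n_cells,aspect_ratio Cell count and elongation for `actin_cells`.
#' @param noise_sd Additive Gaussian noise SD relative to signal amplitude.
#' @param isotropic Draw orientations uniformly on [0, 180) instead of from
#'   the wrapped Gaussian.
#' @param seed Integer seed; fixes the output exactly.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(kind = "aligned_fibers", size = c(256, 256),
                       pixel_size_um = 1.61, orientation_mean = 90,
                       orientation_spread = 5, density = 120,
                       gaps = NULL, n_cells = 50, aspect_ratio = 4,
                       noise_sd = 0.05, isotropic = FALSE, seed = 1) {
  kinds <- c("aligned_fibers", "isotropic_fibers", "mnp_strings",
             "segmented_gel", "actin_cells", "noise")
  kind <- match.arg(kind, kinds)
  stopifnot(orientation_spread >= 0, pixel_size_um > 0, length(size) == 2)
  if (!is.null(gaps)) stopifnot(all(gaps$width_um > 0))
  if (kind == "isotropic_fibers") isotropic <- TRUE
  structure(list(kind = kind, size = as.integer(size),
                 pixel_size_um = pixel_size_um,
                 orientation_mean = orientation_mean,
                 orientation_spread = orientation_spread,
                 density = density, gaps = gaps, n_cells = n_cells,
                 aspect_ratio = aspect_ratio, noise_sd = noise_sd,
                 isotropic = isotropic, seed = as.integer(seed)),
            class = "scene_spec")
}

.draw_orientations <- function(n, spec) {
  if (spec$isotropic) stats::runif(n, 0, 180)
  else (stats::rnorm(n, spec$orientation_mean, spec$orientation_spread)) %% 180
}

# Additive render of line segments with Gaussian cross-section.
# Orientation theta in degrees: 0 = along columns (x), angles grow toward rows.
.render_fibers <- function(nr, nc, cx, cy, theta_deg, len, width, amp) {
  img <- matrix(0, nr, nc)
  X <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  Y <- matrix(seq_len(nr), nr, nc)
  for (i in seq_along(cx)) {
    th <- theta_deg[i] * pi / 180
    dx <- X - cx[i]
    dy <- Y - cy[i]
    u <- dx * cos(th) + dy * sin(th)   # along fiber
    v <- -dx * sin(th) + dy * cos(th)  # across fiber
    cap <- pmin(pmax((len[i] / 2 + 1 - abs(u)), 0), 1) # soft end caps
    img <- img + amp[i] * exp(-v^2 / (2 * width[i]^2)) * cap
  }
  img
}

.finish_scene <- function(img, spec, truth, invert = FALSE, base = 0) {
  nr <- spec$size[1]; nc <- spec$size[2]
  amp <- max(img) - min(img)
  if (amp == 0) amp <- 1
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(nr * nc, sd = spec$noise_sd * amp), nr, nc)
  if (invert) img <- max(img) - img
  img <- img + base
  list(image = gray_image(img, pixel_size_um = spec$pixel_size_um),
       truth = truth)
}

#' Generate a fibrous-texture image (aligned or isotropic collagen)
#'
#' Renders `density` anti-aliased line segments whose orientations are drawn
#' from a wrapped Gaussian (mean, spread) or uniformly for isotropic scenes,
#' plus additive Gaussian noise. With `density = 0` and `noise_sd = 0` the
#' scene is returned flagged blank.
#'
#' @param spec A [scene_spec()].
#' @return List `image` (a [gray_image()]) and `truth` (`ground_truth` list
#'   with the per-fiber orientations and the distribution parameters).
#' @export
generate_fiber_image <- function(spec) {
  withr::with_seed(spec$seed, {
    nr <- spec$size[1]; nc <- spec$size[2]
    n <- spec$density
    if (n == 0 && spec$noise_sd == 0) {
      truth <- list(kind = spec$kind, blank = TRUE, orientations = numeric(0))
      return(list(image = gray_image(matrix(0, nr, nc),
                                     pixel_size_um = spec$pixel_size_um),
                  truth = truth))
    }
    th <- .draw_orientations(n, spec)
    img <- .render_fibers(nr, nc,
                          cx = stats::runif(n, 1, nc),
                          cy = stats::runif(n, 1, nr),
                          theta_deg = th,
                          len = stats::runif(n, 0.5, 1.0) * max(nr, nc),
                          width = stats::runif(n, 1.0, 2.0),
                          amp = stats::runif(n, 0.5, 1))
    truth <- list(kind = spec$kind, blank = FALSE,
                  orientation_mean = spec$orientation_mean,
                  orientation_spread = spec$orientation_spread,
                  isotropic = spec$isotropic, orientations = th)
    .finish_scene(img, spec, truth)
  })
}

#' Generate an MNP-string image (dark strings on a bright background)
#'
#' Emulates light micrographs of magnetically chained nanoparticle strings:
#' thin dark elongated strings at wrapped-Gaussian orientations on a bright
#' background.
#'
#' @param spec A [scene_spec()]; `density` is the string count (default
#'   spec value works well with ~60).
#' @return List `image`, `truth` as in [generate_fiber_image()].
#' @export
generate_mnp_string_image <- function(spec) {
  withr::with_seed(spec$seed, {
    nr <- spec$size[1]; nc <- spec$size[2]
    n <- spec$density
    th <- .draw_orientations(n, spec)
    img <- .render_fibers(nr, nc,
                          cx = stats::runif(n, 1, nc),
                          cy = stats::runif(n, 1, nr),
                          theta_deg = th,
                          len = stats::runif(n, 0.15, 0.45) * max(nr, nc),
                          width = stats::runif(n, 0.8, 1.4),
                          amp = stats::runif(n, 0.6, 1))
    truth <- list(kind = "mnp_strings", blank = FALSE,
                  orientation_mean = spec$orientation_mean,
                  orientation_spread = spec$orientation_spread,
                  isotropic = spec$isotropic, orientations = th)
    .finish_scene(img, spec, truth, invert = TRUE)
  })
}

#' Generate a gel image with dark inter-fiber gap bands
#'
#' A bright fibrous background (fibers along the field axis, i.e. 90 deg) is
#' crossed by vertical dark bands at the stated positions and widths (um along
#' the image width). Overlapping or adjacent bands merge in the ground truth.
#' `truth$gap_count` counts only merged bands whose rendered pixel width is at
#' least `min_len_um` at the scene's pixel size — the same qualifying rule the
#' segmentation metric applies.
#'
#' @param spec A [scene_spec()] with a `gaps` data frame.
#' @param min_len_um Qualifying length for the ground-truth count (default 15).
#' @return List `image`, `truth` (`gap_count`, `band_columns` logical mask).
#' @export
generate_segmented_gel <- function(spec, min_len_um = 15) {
  withr::with_seed(spec$seed, {
    nr <- spec$size[1]; nc <- spec$size[2]
    ps <- spec$pixel_size_um
    gaps <- spec$gaps
    if (!is.null(gaps) && nrow(gaps) > 0 &&
        any(gaps$position_um + gaps$width_um > nc * ps + 1e-9))
      stop("gap layout does not fit in the image width")
    # bright fibrous background: near-vertical fibers, clamped well above the
    # 25% threshold so only the deliberate bands qualify as gaps
    n <- spec$density
    th <- (stats::rnorm(n, 90, 4)) %% 180
    tex <- .render_fibers(nr, nc,
                          cx = stats::runif(n, 1, nc),
                          cy = stats::runif(n, 1, nr),
                          theta_deg = th,
                          len = stats::runif(n, 0.5, 1.0) * nr,
                          width = stats::runif(n, 1.5, 3.0),
                          amp = stats::runif(n, 0.5, 1))
    tex <- tex / max(max(tex), 1e-12)
    img <- 120 + 100 * tex # background in [120, 220]
    dark <- rep(FALSE, nc)
    if (!is.null(gaps) && nrow(gaps) > 0) {
      px_centers <- (seq_len(nc) - 0.5) * ps
      for (i in seq_len(nrow(gaps)))
        dark <- dark | (px_centers >= gaps$position_um[i] &
                        px_centers < gaps$position_um[i] + gaps$width_um[i])
    }
    img[, dark] <- 5
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, sd = spec$noise_sd * 100),
                          nr, nc)
    # ground truth from the rendered mask, same rule as the metric
    r <- rle(dark)
    qual <- r$values & (r$lengths * ps >= min_len_um)
    truth <- list(kind = "segmented_gel", gap_count = sum(qual),
                  band_columns = dark)
    list(image = gray_image(img, pixel_size_um = ps), truth = truth)
  })
}

#' Gap layout for a dosing-series group
#'
#' Maps an MNP dose level to a number of evenly spaced dark bands, a simple
#' stand-in for the observed dose-dependent striation. Widths alternate a bit
#' around `width_um` but never drop below the qualifying length.
#'
#' @param n_gaps Number of bands.
#' @param image_width_um Width of the target image (um).
#' @param width_um Nominal band width (um, default 20).
#' @return A `gaps` data frame for [scene_spec()].
#' @export
gap_layout <- function(n_gaps, image_width_um, width_um = 20) {
  if (n_gaps == 0)
    return(data.frame(position_um = numeric(0), width_um = numeric(0)))
  centers <- image_width_um * (seq_len(n_gaps) - 0.5) / n_gaps
  w <- width_um + 4 * (seq_len(n_gaps) %% 2)
  data.frame(position_um = centers - w / 2, width_um = w)
}

#' Generate an f-actin image of elongated cells
#'
#' Renders `n_cells` soft-edged elliptical cells with the stated aspect ratio
#' at orientations drawn from the spec distribution (all at the mean when
#' `orientation_spread = 0`; uniform when `isotropic`). Round cells
#' (`aspect_ratio = 1`) carry no orientation information and the truth is
#' flagged accordingly.
#'
#' @param spec A [scene_spec()].
#' @return List `image`, `truth` (per-cell orientations,
#'   `orientation_informative` flag).
#' @export
generate_actin_image <- function(spec) {
  if (spec$n_cells < 1) stop("need at least one cell")
  withr::with_seed(spec$seed, {
    nr <- spec$size[1]; nc <- spec$size[2]
    n <- spec$n_cells
    th <- .draw_orientations(n, spec)
    a_l <- 9 * sqrt(spec$aspect_ratio)  # semi-major (px)
    a_s <- 9 / sqrt(spec$aspect_ratio)  # semi-minor
    cx <- stats::runif(n, 1, nc)
    cy <- stats::runif(n, 1, nr)
    X <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    Y <- matrix(seq_len(nr), nr, nc)
    img <- matrix(0, nr, nc)
    for (i in seq_len(n)) {
      thr <- th[i] * pi / 180
      u <- (X - cx[i]) * cos(thr) + (Y - cy[i]) * sin(thr)
      v <- -(X - cx[i]) * sin(thr) + (Y - cy[i]) * cos(thr)
      q <- (u / a_l)^2 + (v / a_s)^2
      img <- img + exp(-3 * q)
    }
    truth <- list(kind = "actin_cells", orientations = th,
                  orientation_mean = spec$orientation_mean,
                  orientation_spread = spec$orientation_spread,
                  isotropic = spec$isotropic,
                  orientation_informative = spec$aspect_ratio != 1)
    .finish_scene(img, spec, truth)
  })
}

#' Dispatch a scene spec to its generator
#'
#' @param spec A [scene_spec()].
#' @return List `image`, `truth`.
#' @export
generate_scene <- function(spec) {
  switch(spec$kind,
    aligned_fibers = ,
    isotropic_fibers = generate_fiber_image(spec),
    mnp_strings = generate_mnp_string_image(spec),
    segmented_gel = generate_segmented_gel(spec),
    actin_cells = generate_actin_image(spec),
    noise = withr::with_seed(spec$seed, {
      nr <- spec$size[1]; nc <- spec$size[2]
      list(image = gray_image(matrix(stats::rnorm(nr * nc), nr, nc),
                              pixel_size_um = spec$pixel_size_um),
           truth = list(kind = "noise"))
    }))
}

#' Rotate an image by an angle (bilinear interpolation about the center)
#'
#' Used for rotation-equivariance checks of the directionality estimator.
#' Pixels sampled from outside the source are filled with the image mean.
#'
#' @param img A [gray_image()] or matrix.
#' @param angle_deg Rotation of the image content, in the same angular
#'   convention as the directionality histogram (a structure at theta moves
#'   to theta + angle).
#' @return A rotated `gray_image` of the same size.
#' @export
rotate_image <- function(img, angle_deg) {
  m <- unclass(img)
  nr <- nrow(m); nc <- ncol(m)
  a <- -angle_deg * pi / 180 # inverse map
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  X <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  Y <- matrix(seq_len(nr), nr, nc) - cy
  xs <- X * cos(a) - Y * sin(a) + cx
  ys <- X * sin(a) + Y * cos(a) + cy
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  fill <- mean(m)
  at <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    out <- matrix(fill, nr, nc)
    out[ok] <- m[cbind(r[ok], c[ok])]
    out
  }
  out <- (1 - fx) * (1 - fy) * at(y0, x0) +
    fx * (1 - fy) * at(y0, x0 + 1) +
    (1 - fx) * fy * at(y0 + 1, x0) +
    fx * fy * at(y0 + 1, x0 + 1)
  gray_image(out, pixel_size_um = pixel_size(img))
}
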