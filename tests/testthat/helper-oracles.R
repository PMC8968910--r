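# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

MU0_T <- 4e-7 * pi

# Surface-charge quadrature for a cuboid magnetized along local z with
# remanence Br and half-dims (a, b, c): midpoint rule over the two pole faces.
quadrature_block_field <- function(p, a, b, c, Br, n = 200) {
  M <- Br / MU0_T
  xs <- seq(-a, a, length.out = n + 1); xs <- (xs[-1] + xs[-(n + 1)]) / 2
  ys <- seq(-b, b, length.out = n + 1); ys <- (ys[-1] + ys[-(n + 1)]) / 2
  dA <- (2 * a / n) * (2 * b / n)
  g <- expand.grid(xp = xs, yp = ys)
  H <- c(0, 0, 0)
  for (zc in c(c, -c)) {
    sig <- if (zc > 0) M else -M
    dx <- p[1] - g$xp; dy <- p[2] - g$yp; dz <- p[3] - zc
    r3 <- (dx^2 + dy^2 + dz^2)^1.5
    H <- H + sig * dA / (4 * pi) * c(sum(dx / r3), sum(dy / r3), sum(dz / r3))
  }
  MU0_T * H
}

# grad(|H|^2) via the curl-free identity 2 J^T H, with the Jacobian of B
# taken by central differences of the field components (different structure
# and step than the package path, which differences the scalar |H|^2).
jacobian_gradH2 <- function(device, p, h = 1e-6) {
  B0 <- device_B(device, matrix(p, 1, 3))[1, ]
  J <- matrix(0, 3, 3)
  for (d in 1:3) {
    e <- c(0, 0, 0); e[d] <- h
    J[, d] <- (device_B(device, matrix(p + e, 1, 3))[1, ] -
               device_B(device, matrix(p - e, 1, 3))[1, ]) / (2 * h)
  }
  as.numeric(2 * t(J) %*% B0) / MU0_T^2
}

# Brute-force run-length scan: position-by-position state machine, no rle.
brute_force_segments <- function(values, excluded, pixel_size_um,
                                 threshold_frac = 0.25, min_len_um = 15) {
  thr <- threshold_frac * max(values[!excluded])
  spans <- NULL
  run <- 0L
  for (i in seq_along(values)) {
    if (!excluded[i] && values[i] < thr) {
      run <- run + 1L
    } else {
      if (run > 0L && run * pixel_size_um >= min_len_um)
        spans <- rbind(spans, c(i - run, i - 1L))
      run <- 0L
    }
  }
  if (run > 0L && run * pixel_size_um >= min_len_um)
    spans <- rbind(spans, c(length(values) - run + 1L, length(values)))
  list(count = if (is.null(spans)) 0L else nrow(spans), spans = spans,
       threshold = thr)
}

make_transect <- function(values, pixel_size_um = 1) {
  img <- gray_image(rbind(values, values), pixel_size_um = pixel_size_um)
  extract_transect(img)
}

# Embed a scene in a larger mean-filled canvas so rotation never clips
# content.
pad_scene <- function(img, N = 256) {
  m <- unclass(img)
  canvas <- matrix(mean(m), N, N)
  o <- (N - nrow(m)) %/% 2
  canvas[o + seq_len(nrow(m)), o + seq_len(ncol(m))] <- m
  gray_image(canvas, pixel_size_um = attr(img, "pixel_size_um"))
}

peak_bin_center <- function(hist) {
  i <- which.max(hist$amount)
  (hist$bin_start_deg[i] + hist$bin_end_deg[i]) / 2
}

# signed circular difference of two orientations, in (-90, 90]
ang_diff <- function(a, b) ((a - b + 90) %% 180) - 90

default_calibrated_device <- function(target = 52.3e-3) {
  calibrate_device(magnet_device(), target)
}
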