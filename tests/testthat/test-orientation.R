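# Fourier directionality histogram, Gaussian fitting, anisotropy calls,
# binarization, averaging.

test_that("gratings land in the correct orientation bins", {
  N <- 128
  stripes_along_rows <- gray_image(
    matrix(sin(2 * pi * 8 * (1:N) / N), N, N, byrow = TRUE))
  h <- fourier_directionality(stripes_along_rows)
  expect_true(peak_bin_center(h) >= 88 && peak_bin_center(h) <= 92)

  stripes_along_cols <- gray_image(matrix(sin(2 * pi * 8 * (1:N) / N), N, N))
  h0 <- fourier_directionality(stripes_along_cols)
  expect_lt(min(abs(c(peak_bin_center(h0), peak_bin_center(h0) - 180))), 3)
})

test_that("histograms are normalized, 90-binned, and small images rejected", {
  sc <- generate_fiber_image(scene_spec(seed = 1))
  h <- fourier_directionality(sc$image)
  expect_equal(nrow(h), 90)
  expect_equal(sum(h$amount), 1, tolerance = 1e-9)
  expect_true(all(h$amount >= 0))
  expect_error(fourier_directionality(gray_image(matrix(1, 32, 32))),
               "64 x 64")
})

test_that("constant images error by default or flag a uniform histogram", {
  flat <- gray_image(matrix(5, 64, 64))
  expect_error(fourier_directionality(flat), "constant")
  h <- fourier_directionality(flat, on_constant = "uniform")
  expect_true(attr(h, "degenerate"))
  expect_equal(h$amount, rep(1 / 90, 90))
})

test_that("white noise never concentrates: no bin above 3x uniform over 10
          seeds", {
  for (s in 1:10) {
    sc <- generate_scene(scene_spec(kind = "noise", seed = s))
    h <- fourier_directionality(sc$image)
    expect_lt(max(h$amount), 3 / 90)
  }
})

test_that("peak location is rotation-equivariant on padded scenes", {
  for (case in list(c(2, 20), c(4, 30), c(6, 45))) {
    sc <- generate_fiber_image(scene_spec(size = c(170, 170),
                                          orientation_mean = 60,
                                          orientation_spread = 3,
                                          seed = case[1]))
    img <- pad_scene(sc$image)
    f1 <- fit_gaussian(fourier_directionality(img))
    f2 <- fit_gaussian(fourier_directionality(rotate_image(img, case[2])))
    expect_lt(abs(ang_diff(f2$center, f1$center + case[2])), 2)
  }
})

test_that("gaussian fit recovers exactly-sampled parameters and flags the
          degenerate cases", {
  centers <- seq(1, 179, by = 2)
  y <- 0.002 + 0.05 * exp(-(centers - 88)^2 / (2 * 5^2))
  h <- magnegel:::.make_hist(y / sum(y), 2)
  f <- fit_gaussian(h)
  expect_true(f$converged)
  expect_lt(abs(f$center - 88), 0.5)
  expect_lt(abs(f$sd - 5), 0.5)
  expect_gt(f$goodness, 0.99)

  # wrap-around: peak near 0 must be recovered mod 180
  yw <- 0.002 + 0.05 * exp(-(ang_diff(centers, 2))^2 / (2 * 6^2))
  fw <- fit_gaussian(magnegel:::.make_hist(yw / sum(yw), 2))
  expect_lt(abs(ang_diff(fw$center, 2)), 0.5)

  fu <- fit_gaussian(magnegel:::.make_hist(rep(1 / 90, 90), 2))
  expect_false(fu$converged)
  expect_equal(fu$amplitude, 0)
})

test_that("noisy gaussian histograms give an unbiased center over
          replicates", {
  centers <- seq(1, 179, by = 2)
  set.seed(99)
  est <- replicate(10, {
    y <- 0.002 + 0.05 * exp(-(centers - 88)^2 / (2 * 5^2)) +
      abs(rnorm(90, sd = 0.002))
    fit_gaussian(magnegel:::.make_hist(y / sum(y), 2))$center
  })
  expect_lt(abs(mean(est) - 88), 1)
})

test_that("anisotropy calls: aligned yes, isotropic no, bimodal no", {
  sa <- generate_fiber_image(scene_spec(orientation_mean = 90,
                                        orientation_spread = 5, seed = 2))
  ha <- fourier_directionality(sa$image)
  ca <- classify_anisotropy(fit_gaussian(ha), ha)
  expect_true(ca$is_anisotropic)
  expect_lt(abs(ang_diff(ca$peak_center, 90)), 5)

  si <- generate_fiber_image(scene_spec(kind = "isotropic_fibers", seed = 2))
  hi <- fourier_directionality(si$image)
  ci <- classify_anisotropy(fit_gaussian(hi), hi)
  expect_false(ci$is_anisotropic)
  expect_true(is.na(ci$peak_center))

  s45 <- generate_fiber_image(scene_spec(orientation_mean = 45,
                                         orientation_spread = 3,
                                         density = 60, seed = 6))
  s135 <- generate_fiber_image(scene_spec(orientation_mean = 135,
                                          orientation_spread = 3,
                                          density = 60, seed = 7))
  bim <- gray_image(unclass(s45$image) + unclass(s135$image),
                    pixel_size_um = 1.61)
  hb <- fourier_directionality(bim)
  expect_false(classify_anisotropy(fit_gaussian(hb), hb)$is_anisotropic)
})

test_that("otsu binarization separates a two-level image exactly and errors
          on flat input", {
  m <- matrix(20, 64, 64)
  m[, 33:64] <- 200
  b <- binarize_actin(gray_image(m))
  expect_equal(unique(as.numeric(b[, 1:32])), 0)
  expect_equal(unique(as.numeric(b[, 33:64])), 1)
  expect_error(binarize_actin(gray_image(matrix(7, 64, 64))),
               "single-valued")
})

test_that("directionality is invariant to intensity inversion", {
  sc <- generate_mnp_string_image(scene_spec(kind = "mnp_strings",
                                             density = 60, seed = 3))
  h1 <- fourier_directionality(sc$image)
  inv <- gray_image(max(sc$image) - unclass(sc$image), pixel_size_um = 1.61)
  h2 <- fourier_directionality(inv)
  expect_equal(h1$amount, h2$amount, tolerance = 1e-12)
})

test_that("histogram averaging is idempotent, renormalizing, and strict about
          binning", {
  sc <- generate_fiber_image(scene_spec(seed = 4))
  h <- fourier_directionality(sc$image)
  avg <- average_histograms(list(h, h, h))
  expect_equal(avg$amount, h$amount, tolerance = 1e-12)

  a <- rep(0, 90); a[10] <- 1
  b <- rep(0, 90); b[60] <- 1
  m <- average_histograms(list(magnegel:::.make_hist(a, 2),
                               magnegel:::.make_hist(b, 2)))
  expect_equal(m$amount[c(10, 60)], c(0.5, 0.5))
  expect_equal(sum(m$amount), 1)

  h4 <- magnegel:::.make_hist(rep(1 / 45, 45), 4)
  expect_error(average_histograms(list(h, h4)), "mixed binning")
})

test_that("averaging replicate gels tightens the peak-location spread", {
  single <- sapply(1:8, function(s) {
    sc <- generate_fiber_image(scene_spec(orientation_spread = 8, seed = s))
    fit_gaussian(fourier_directionality(sc$image))$center
  })
  averaged <- sapply(1:8, function(s) {
    hs <- lapply(0:2, function(k) {
      sc <- generate_fiber_image(scene_spec(orientation_spread = 8,
                                            seed = 100 * s + k))
      fourier_directionality(sc$image)
    })
    fit_gaussian(average_histograms(hs))$center
  })
  expect_lt(sd(ang_diff(averaged, 90)), sd(ang_diff(single, 90)) + 1)
})
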