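# Synthetic scene generators: determinism, ground-truth consistency, and
# parameter recovery through the analysis modules.

test_that("every generator is a pure function of its spec", {
  for (kind in c("aligned_fibers", "isotropic_fibers", "mnp_strings",
                 "actin_cells", "noise")) {
    sp <- scene_spec(kind = kind, seed = 7)
    a <- generate_scene(sp)
    b <- generate_scene(sp)
    expect_identical(unclass(a$image), unclass(b$image), label = kind)
  }
  spg <- scene_spec(kind = "segmented_gel", gaps = gap_layout(3, 256 * 1.61),
                    seed = 7)
  expect_identical(unclass(generate_scene(spg)$image),
                   unclass(generate_scene(spg)$image))
  # generators leave the caller's RNG stream alone
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_scene(scene_spec(seed = 1)))
  expect_identical(runif(1), before)
})

test_that("tightly aligned fiber scenes recover their orientation", {
  sc <- generate_fiber_image(scene_spec(orientation_mean = 90,
                                        orientation_spread = 0, seed = 11))
  expect_true(all(sc$truth$orientations == 90))
  h <- fourier_directionality(sc$image)
  f <- fit_gaussian(h)
  expect_lt(abs(ang_diff(f$center, 90)), 2)
  expect_true(classify_anisotropy(f, h)$is_anisotropic)
})

test_that("isotropic scenes are called isotropic", {
  sc <- generate_fiber_image(scene_spec(kind = "isotropic_fibers", seed = 12))
  h <- fourier_directionality(sc$image)
  expect_false(classify_anisotropy(fit_gaussian(h), h)$is_anisotropic)
})

test_that("blank scenes are flagged", {
  sc <- generate_fiber_image(scene_spec(density = 0, noise_sd = 0, seed = 1))
  expect_true(sc$truth$blank)
  expect_equal(max(sc$image), min(sc$image))
})

test_that("segmented-gel ground truth agrees with the segmentation metric", {
  sp <- scene_spec(kind = "segmented_gel",
                   gaps = data.frame(position_um = c(50, 150, 300),
                                     width_um = c(20, 30, 10)),
                   seed = 4)
  g <- generate_segmented_gel(sp)
  expect_equal(g$truth$gap_count, 2) # the 10 um band is below 15 um
  expect_equal(count_segments(extract_transect(g$image))$gap_count, 2)

  g0 <- generate_segmented_gel(scene_spec(kind = "segmented_gel", seed = 4))
  expect_equal(g0$truth$gap_count, 0)

  # overlapping bands merge in the ground truth
  gov <- generate_segmented_gel(scene_spec(
    kind = "segmented_gel",
    gaps = data.frame(position_um = c(100, 110), width_um = c(20, 20)),
    seed = 4))
  expect_equal(gov$truth$gap_count, 1)

  expect_error(generate_segmented_gel(scene_spec(
    kind = "segmented_gel",
    gaps = data.frame(position_um = 400, width_um = 50), seed = 1)),
    "fit")
})

test_that("a dose series of gap frequencies is strictly increasing in truth
          and recovered by the metric", {
  truth <- meas <- numeric(5)
  for (i in 1:5) {
    ng <- i - 1
    g <- generate_segmented_gel(scene_spec(
      kind = "segmented_gel", gaps = gap_layout(ng, 256 * 1.61),
      seed = 20 + i))
    truth[i] <- g$truth$gap_count
    meas[i] <- count_segments(extract_transect(g$image))$gap_count
  }
  expect_true(all(diff(truth) > 0))
  expect_equal(meas, truth)
})

test_that("mnp string scenes recover their mean and order their spreads", {
  tight <- generate_mnp_string_image(scene_spec(kind = "mnp_strings",
                                                density = 60,
                                                orientation_spread = 2,
                                                seed = 3))
  f_tight <- fit_gaussian(fourier_directionality(tight$image))
  expect_lt(abs(ang_diff(f_tight$center, 90)), 2)

  wide <- generate_mnp_string_image(scene_spec(kind = "mnp_strings",
                                               density = 60,
                                               orientation_spread = 30,
                                               seed = 3))
  f_wide <- fit_gaussian(fourier_directionality(wide$image))
  expect_gt(f_wide$sd, f_tight$sd)
})

test_that("actin scenes: aligned cells recover 90, uniform cells are
          isotropic, round cells carry no orientation", {
  sa <- generate_actin_image(scene_spec(kind = "actin_cells",
                                        orientation_spread = 0,
                                        n_cells = 50, seed = 2))
  expect_true(sa$truth$orientation_informative)
  hb <- fourier_directionality(binarize_actin(sa$image))
  fb <- fit_gaussian(hb)
  expect_lt(abs(ang_diff(fb$center, 90)), 2)
  expect_true(classify_anisotropy(fb, hb)$is_anisotropic)

  su <- generate_actin_image(scene_spec(kind = "actin_cells",
                                        isotropic = TRUE, n_cells = 50,
                                        seed = 2))
  hu <- fourier_directionality(binarize_actin(su$image))
  expect_false(classify_anisotropy(fit_gaussian(hu), hu)$is_anisotropic)

  sr <- generate_actin_image(scene_spec(kind = "actin_cells",
                                        aspect_ratio = 1, n_cells = 50,
                                        seed = 2))
  expect_false(sr$truth$orientation_informative)
  expect_error(generate_actin_image(scene_spec(kind = "actin_cells",
                                               n_cells = 0)), "one cell")
})

test_that("fitted spread is monotone in generator spread", {
  sds <- sapply(c(2, 5, 10), function(sp) {
    median(sapply(1:5, function(s) {
      sc <- generate_fiber_image(scene_spec(orientation_spread = sp,
                                            seed = 40 + s))
      fit_gaussian(fourier_directionality(sc$image))$sd
    }))
  })
  expect_true(all(diff(sds) > 0))
})
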