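# rendered scenes reused across this file
sc_rpe <- make_clean_scene("RPE", size = 512L, seed = 2)
cfg <- default_config()

test_that("quality mask: constant images fail, zero threshold passes all", {
  flat <- matrix(0.5, 128, 128)
  q <- build_quality_mask(flat, cfg$quality, s_px = 14)
  expect_false(any(q))
  p0 <- cfg$quality; p0$energy_threshold <- 0
  expect_true(all(build_quality_mask(flat, p0, s_px = 14)))
})

test_that("quality mask rejects an out-of-focus quadrant", {
  img <- sc_rpe$record$pixels
  s <- sc_rpe$spacing_px
  blurred <- aomosaic:::gauss_blur_cpp(img, 2.5 * s)
  img2 <- img
  img2[1:256, 1:256] <- blurred[1:256, 1:256]
  q <- build_quality_mask(img2, cfg$quality, s_px = s)
  # compare away from the transition band of the energy window
  band <- ceiling(3 * s)
  in_blur <- matrix(FALSE, 512, 512); in_blur[1:256, 1:256] <- TRUE
  core_blur <- matrix(FALSE, 512, 512)
  core_blur[1:(256 - band), 1:(256 - band)] <- TRUE
  core_sharp <- matrix(FALSE, 512, 512)
  core_sharp[(256 + band):512, (256 + band):512] <- TRUE
  expect_lt(mean(q[core_blur]), 0.01)
  expect_gt(mean(q[core_sharp]), 0.99)
})

test_that("vessel mask finds dark ribbons and nothing else", {
  # no vessels rendered -> essentially no vessel pixels
  v0 <- build_vessel_mask(sc_rpe$record, cfg$vessel)
  expect_lt(mean(v0), 0.01)
  # all-bright image -> none
  expect_false(any(build_vessel_mask(matrix(0.9, 256, 256), cfg$vessel)))
  # rendered ribbon: footprint overlap
  m <- mosaic_model("RPE", age_slope = 0, n_vessels = 2,
                    blur_fraction_base = 0, blur_fraction_per_year = 0,
                    nonmosaic_fraction_base = 0,
                    nonmosaic_fraction_per_year = 0)
  eye <- eye_meta("E", "OD", 40, "male", 24)
  sc <- render_mosaic_image(eye, c(0, 0), m, seed = 5, image_size = 512L)
  v <- build_vessel_mask(sc$record, cfg$vessel)
  jac <- sum(v & sc$masks$vessel) / sum(v | sc$masks$vessel)
  expect_gte(jac, 0.7)
})

test_that("mosaic mask keeps clean mosaic and drops structureless noise", {
  q <- build_quality_mask(sc_rpe$record, cfg$quality, s_px = sc_rpe$spacing_px)
  v <- build_vessel_mask(sc_rpe$record, cfg$vessel)
  ms <- build_mosaic_mask(sc_rpe$record, q, v, "RPE", cfg$mosaic,
                          s_px = sc_rpe$spacing_px)
  expect_gte(mean(ms$mosaic), 0.95)
  # constructive containment
  expect_true(all(ms$mosaic <= (ms$quality_visible & !ms$vessel)))

  # scene with a structureless (but sharp) patch: excluded from mosaic
  m <- mosaic_model("RPE", age_slope = 0, n_vessels = 0,
                    blur_fraction_base = 0, blur_fraction_per_year = 0,
                    nonmosaic_fraction_base = 0.15,
                    nonmosaic_fraction_per_year = 0)
  eye <- eye_meta("E", "OD", 40, "male", 24)
  sc <- render_mosaic_image(eye, c(0, 0), m, seed = 6, image_size = 512L)
  q2 <- build_quality_mask(sc$record, cfg$quality, s_px = sc$spacing_px)
  v2 <- build_vessel_mask(sc$record, cfg$vessel)
  ms2 <- build_mosaic_mask(sc$record, q2, v2, "RPE", cfg$mosaic,
                           s_px = sc$spacing_px)
  patch <- sc$masks$quality_visible & !sc$masks$mosaic  # ground-truth patch
  core <- erode_mask(patch, ceiling(2.5 * sc$spacing_px))
  expect_lt(mean(ms2$mosaic[core]), 0.1)
  # and the noise patch stays "visible" (in focus) for the quality layer
  expect_gt(mean(q2[core]), 0.9)
})

test_that("visible mosaic area ratio matches constructed and generated truth", {
  n <- 64
  q <- matrix(TRUE, n, n); v <- matrix(FALSE, n, n)
  full <- mask_set(q, v, matrix(TRUE, n, n))
  expect_equal(visible_mosaic_area_ratio(full), 1.0)
  half <- matrix(FALSE, n, n); half[, 1:32] <- TRUE
  expect_equal(visible_mosaic_area_ratio(mask_set(q, v, half)), 0.5)
  # undefined when nothing is visible
  none <- mask_set(matrix(FALSE, n, n), v, matrix(FALSE, n, n))
  expect_error(visible_mosaic_area_ratio(none), "undefined")

  # generator-configured non-mosaic fraction p -> ratio ~= 1 - p
  p <- 0.2
  m <- mosaic_model("PR", ecc_slope = 0, age_slope = 0, n_vessels = 0,
                    blur_fraction_base = 0, blur_fraction_per_year = 0,
                    nonmosaic_fraction_base = p,
                    nonmosaic_fraction_per_year = 0)
  eye <- eye_meta("E", "OD", 40, "male", 24)
  sc <- render_mosaic_image(eye, c(5, 0), m, seed = 8, image_size = 512L)
  expect_lt(abs(visible_mosaic_area_ratio(sc$masks) - (1 - p)), 0.05)
})

test_that("masked fraction and mask_set invariants hold", {
  ms <- make_fraction_masks(32, 0.25)
  expect_equal(masked_fraction(ms), 0.75)
  # mosaic is forced inside quality & !vessel
  q <- matrix(TRUE, 16, 16); q[1:8, ] <- FALSE
  ms2 <- mask_set(q, matrix(FALSE, 16, 16), matrix(TRUE, 16, 16))
  expect_true(all(ms2$mosaic <= q))
})
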