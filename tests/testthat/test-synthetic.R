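test_that("cohort generation is reproducible and respects the design", {
  cfg <- cohort_config(n_participants = 6)
  a <- generate_cohort(cfg, seed = 3)
  b <- generate_cohort(cfg, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(cfg, seed = 4)))

  expect_true(all(a$eyes$age >= 23 & a$eyes$age <= 80))
  expect_true(all(a$eyes$axial_length_mm > 1.82))
  expect_true(all(a$eyes$side %in% c("OD", "OS")))
  # one manifest row per eye x zone x modality
  expect_equal(nrow(a$manifest), nrow(a$eyes) * 5 * 2)
  expect_true(all(table(a$manifest$eye_id) == 10))

  empty <- generate_cohort(cohort_config(n_participants = 0), seed = 1)
  expect_equal(nrow(empty$eyes), 0)
  expect_equal(nrow(empty$manifest), 0)
})

test_that("rendering is a pure function of configuration and seed", {
  eye <- eye_meta("d_OD", "OD", 35, "male", 24)
  m <- mosaic_model("RPE")
  s1 <- render_mosaic_image(eye, c(0, 0), m, seed = 21, image_size = 256L)
  s2 <- render_mosaic_image(eye, c(0, 0), m, seed = 21, image_size = 256L)
  expect_identical(s1$record$pixels, s2$record$pixels)
  expect_identical(s1$centroids, s2$centroids)
  s3 <- render_mosaic_image(eye, c(0, 0), m, seed = 22, image_size = 256L)
  expect_false(identical(s1$record$pixels, s3$record$pixels))
})

test_that("lattice construction hits the requested density", {
  for (d in c(4000, 6313, 10207, 12000)) {
    sc <- make_clean_scene("RPE", density = d, size = 512L, seed = 31,
                           center = c(0, 0))
    area_mm2 <- (512 * sc$record$pixel_size_um / 1000)^2
    expect_lt(abs(nrow(sc$centroids) / area_mm2 - d) / d, 0.02)
  }
})

test_that("an eccentricity-sloped density field is laid down as configured", {
  eye <- eye_meta("s_OD", "OD", 40, "female", 24)
  m <- mosaic_model("PR", base_density = 10207, ecc_slope = -600,
                    age_slope = 0, n_vessels = 0, blur_fraction_base = 0,
                    blur_fraction_per_year = 0, nonmosaic_fraction_base = 0,
                    nonmosaic_fraction_per_year = 0)
  sc <- render_mosaic_image(eye, c(5, 0), m, seed = 41, image_size = 1024L)
  cen <- sc$centroids
  deg <- pixel_to_global_degrees(cen$row_px, cen$col_px, sc$record)
  ecc <- abs(signed_eccentricity(deg[, 1], deg[, 2]))
  ps_mm <- sc$record$pixel_size_um / 1000
  # count cells in vertical strips (the density varies along x)
  breaks <- seq(0, 1024, by = 128)
  for (k in seq_len(length(breaks) - 1)) {
    sel <- cen$col_px >= breaks[k] & cen$col_px < breaks[k + 1]
    strip_area <- 128 * 1024 * ps_mm^2
    got <- sum(sel) / strip_area
    mid_col <- (breaks[k] + breaks[k + 1]) / 2
    mid_deg <- pixel_to_global_degrees(511.5, mid_col, sc$record)
    want <- 10207 - 600 * (abs(signed_eccentricity(mid_deg[1, 1],
                                                   mid_deg[1, 2])) - 2.5)
    expect_lt(abs(got - want) / want, 0.05)
  }
})

test_that("sub-resolution densities are rejected", {
  eye <- eye_meta("r_OD", "OD", 40, "female", 24)
  m <- clean_mosaic_model("PR", 5e5, min_density = 5e5)
  expect_error(render_mosaic_image(eye, c(0, 0), m, seed = 1,
                                   image_size = 256L),
               "below pixel resolution")
})

test_that("rater matrices behave like the error model says", {
  truth <- c(80, 120, 60, 95, 150, 70, 110, 85)
  perfect <- generate_rater_matrix(truth, k = 5, miss_rate = 0,
                                   extra_rate = 0, seed = 2)
  expect_true(all(perfect == truth))
  expect_equal(icc3k(perfect + matrix(rnorm(40, 0, 1e-9), 8, 5))$icc, 1,
               tolerance = 1e-3)
  expect_error(generate_rater_matrix(truth, k = 1), "at least 2")
  expect_identical(generate_rater_matrix(truth, seed = 7),
                   generate_rater_matrix(truth, seed = 7))

  # realistic error rates on 90 heterogeneous patches keep agreement high
  set.seed(13)
  big_truth <- rpois(90, lambda = runif(90, 40, 160))
  m <- generate_rater_matrix(big_truth, k = 5, miss_rate = 0.05,
                             extra_rate = 0.05, seed = 17)
  expect_gt(icc3k(m)$icc, 0.7)
})

test_that("whole-cohort simulation writes a consistent file set", {
  dir <- tempfile("simcohort")
  cfg <- cohort_config(n_participants = 1, both_eyes_fraction = 0,
                       zones = list(c(0, 0)))
  sim <- simulate_cohort(cfg, seed = 5, image_size = 128L, output_dir = dir)
  expect_equal(length(sim$scenes), nrow(sim$manifest))
  expect_true(file.exists(file.path(dir, "eyes.csv")))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "provenance.yaml")))
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_true(all(file.exists(man$path)))
  # round-trip: written image equals the rendered one at 16-bit precision
  img <- read_ao_image(man$path[1])
  expect_lt(max(abs(img - sim$scenes[[man$image_id[1]]]$record$pixels)),
            1 / 65535)
  unlink(dir, recursive = TRUE)
})
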