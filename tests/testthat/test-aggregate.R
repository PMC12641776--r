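eye <- eye_meta("agg_OD", "OD", 40, "female", 24)
img2048 <- image_record(eye, "RPE", center_deg = c(0, 0), image_size = 2048L)

test_that("over-masking exclusion uses a strict 90% threshold", {
  expect_false(exclude_overmasked_images(make_fraction_masks(100, 0.09)))  # 91% masked
  expect_true(exclude_overmasked_images(make_fraction_masks(100, 0.10)))   # 90% masked
  expect_true(exclude_overmasked_images(make_fraction_masks(100, 1)))      # unmasked
})

test_that("grid squares honor the 200-cell filter exactly", {
  masks <- make_fraction_masks(2048, 1)
  c199 <- make_tile_cells(199, 2, 3)
  c200 <- make_tile_cells(200, 2, 3, seed = 2)
  expect_equal(nrow(grid_summaries(c199, masks, img2048)), 0)
  gs <- grid_summaries(c200, masks, img2048)
  expect_equal(nrow(gs), 1)
  expect_equal(gs$n_cells, 200)
  expect_equal(gs$grid_i, 2)
  expect_equal(gs$grid_j, 3)
  # lowering the threshold can only retain more squares
  gs_low <- grid_summaries(c199, masks, img2048, min_cells = 100L)
  expect_gte(nrow(gs_low), nrow(grid_summaries(c199, masks, img2048)))
})

test_that("grid summaries measure density and centroid geometry correctly", {
  masks <- make_fraction_masks(2048, 1)
  ps <- img2048$pixel_size_um
  cells <- make_tile_cells(300, 0, 0, seed = 3)
  gs <- grid_summaries(cells, masks, img2048)
  tile_mm2 <- 256^2 * ps^2 / 1e6
  expect_equal(gs$visible_area_mm2, tile_mm2)
  expect_equal(gs$local_density, 300 / tile_mm2)
  # tile-center coordinate: pixel (127.5, 127.5) of an OD eye at fixation
  deg <- pixel_to_global_degrees(127.5, 127.5, img2048)
  expect_equal(gs$x_deg, unname(deg[1, "x_deg"]))
  expect_equal(gs$y_deg, unname(deg[1, "y_deg"]))
  expect_equal(gs$eccentricity_deg,
               unname(signed_eccentricity(deg[1, 1], deg[1, 2])))
  # every cell lands in exactly one square
  expect_equal(sum(gs$n_cells), nrow(cells))
})

test_that("density and mean area are dual on a fully visible uniform tile", {
  sc <- make_clean_scene("RPE", size = 512L, seed = 12, center = c(0, 0))
  res <- analyze_image(sc$record, default_config(), masks = sc$masks)
  gs <- grid_summaries(res$cells, sc$masks, sc$record, grid_px = 256L,
                       min_cells = 100L)
  expect_gt(nrow(gs), 0)
  duality <- gs$local_density * gs$mean_area_um2 / 1e6
  expect_true(all(abs(duality - 1) < 0.05))
})

test_that("photoreceptor central exclusion removes the open band only", {
  rec <- data.frame(eccentricity_deg = c(0, -2.49, 2.49, 2.5, -2.5, 3, -7))
  out <- pr_central_exclusion(rec, modality = "PR")
  expect_equal(out$eccentricity_deg, c(2.5, -2.5, 3, -7))
  # idempotent
  expect_equal(pr_central_exclusion(out, modality = "PR"), out,
               ignore_attr = TRUE)
  # other modalities untouched
  expect_equal(pr_central_exclusion(rec, modality = "RPE"), rec)
})

test_that("eccentricity profile bins, averages and conserves counts", {
  # hand-built six-summary fixture in two bins of a [-10, 10] / 25-bin grid
  sm <- data.frame(
    eccentricity_deg = c(-9.7, -9.2, -9.0, 5.05, 5.10, 5.15),
    local_density = c(6000, 6200, 6400, 7000, 7200, 7400),
    mean_area_um2 = c(150, 152, 154, 160, 162, 164),
    mean_perimeter_um = rep(47, 6), mean_neighbors = rep(6, 6))
  pf <- eccentricity_profile(sm)
  expect_equal(nrow(pf), 25)
  expect_equal(sum(pf$n), 6)
  # bin width 0.8: -9.7, -9.2, -9.0 fall in bins 1 and 2
  expect_equal(pf$n[1], 1)
  expect_equal(pf$mean_local_density[1], 6000)
  expect_equal(pf$n[2], 2)
  expect_equal(pf$mean_local_density[2], mean(c(6200, 6400)))
  expect_equal(pf$sd_local_density[2], sd(c(6200, 6400)))
  b <- which(pf$n == 3)
  expect_equal(pf$mean_mean_area_um2[b], 162)
  # empty bins report zero count and missing means
  expect_true(all(is.na(pf$mean_local_density[pf$n == 0])))

  # single-eccentricity input populates exactly one bin
  one <- sm[4:6, ]; one$eccentricity_deg <- 3.14
  pf1 <- eccentricity_profile(one)
  expect_equal(sum(pf1$n > 0), 1)
  expect_equal(pf1$mean_local_density[pf1$n > 0], mean(one$local_density))
})

test_that("density heatmap smooths conservatively and keeps symmetry", {
  # single populated location, no smoothing -> a delta raster
  s1 <- data.frame(x_deg = 0.1, y_deg = 0.1, local_density = 5000)
  h1 <- density_heatmap(s1, sigma_deg = 0)
  expect_equal(sum(!is.na(h1$z)), 1)
  expect_equal(h1$z[!is.na(h1$z)], 5000)

  # fully populated support: smoothing preserves total mass within 1%
  g <- expand.grid(x = seq(-5, 5, by = 0.8375), y = seq(-5, 5, by = 0.8375))
  g$local_density <- 6000 + 500 * exp(-(g$x^2 + g$y^2) / 4)
  h2 <- density_heatmap(data.frame(x_deg = g$x, y_deg = g$y,
                                   local_density = g$local_density))
  h2n <- density_heatmap(data.frame(x_deg = g$x, y_deg = g$y,
                                    local_density = g$local_density),
                         sigma_deg = 0)
  pop0 <- !is.na(h2n$z)  # the originally populated support
  expect_lt(abs(sum(h2$z[pop0]) - sum(h2n$z[pop0])) / sum(h2n$z[pop0]), 0.01)

  # mirror-symmetric input -> mirror-symmetric map
  sym <- data.frame(x_deg = c(-3, 3, -3, 3), y_deg = c(-3, -3, 3, 3),
                    local_density = c(1000, 1000, 1000, 1000))
  hs <- density_heatmap(sym)
  expect_equal(hs$z, hs$z[rev(seq_along(hs$x)), ])
  expect_equal(hs$z, hs$z[, rev(seq_along(hs$y))])
})

test_that("rectangle matching pairs one-to-one within tolerance", {
  base <- data.frame(
    x_deg = rep(seq(-2, 2, by = 0.8375), each = 3),
    y_deg = rep(c(-1, 0, 1), times = 5))
  rpe <- base
  rpe$eccentricity_deg <- signed_eccentricity(rpe$x_deg, rpe$y_deg)
  rpe$local_density <- 6300 + seq_len(nrow(rpe))
  rpe$mean_area_um2 <- 150; rpe$mean_perimeter_um <- 47; rpe$mean_neighbors <- 6
  pr <- rpe
  pr$local_density <- 1.6 * rpe$local_density

  mt <- match_rpe_pr_rectangles(rpe, pr)
  expect_equal(nrow(mt), nrow(rpe))
  expect_equal(mt$ratio_local_density, rep(1.6, nrow(rpe)))

  # diagonal offset beyond the tolerance -> nothing matches
  pr2 <- pr
  pr2$x_deg <- pr2$x_deg + 0.3
  pr2$y_deg <- pr2$y_deg + 0.3
  expect_warning(mt2 <- match_rpe_pr_rectangles(rpe, pr2), "match")
  expect_equal(nrow(mt2), 0)
})
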