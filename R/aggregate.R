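#' Image-level exclusion by mask coverage
#'
#' An acquisition is excluded from the normative analysis when more than 90%
#' of its area is masked (strictly greater), i.e. when too little mosaic is
#' visible for reliable morphometry.
#'
#' @param masks A [mask_set()].
#' @param threshold Masked-fraction threshold, default 0.90.
#' @return `TRUE` to keep the image, `FALSE` to exclude it.
#' @export
exclude_overmasked_images <- function(masks, threshold = 0.90) {
  masked_fraction(masks) <= threshold
}

#' Aggregate cells into fixed 256x256-pixel grid squares
#'
#' Divides the image into square grid tiles, assigns every cell to exactly
#' one tile by its centroid pixel, and summarizes each tile: cell count,
#' mosaic-visible area, local density (count / visible area), and the means
#' of the per-cell morphometric descriptors over non-boundary cells. Tiles
#' with fewer than `min_cells` cells are dropped (small islands of detections
#' inside masked areas are unreliable), as are tiles with no visible area.
#' The cell-count filter counts all detected cells, including boundary-
#' flagged ones.
#'
#' @param cells Data.frame from [voronoi_morphometry()] (columns `row_px`,
#'   `col_px`, `area_um2`, `perimeter_um`, `n_neighbors`, `boundary_flag`).
#' @param masks A [mask_set()]; visible area per tile is measured on the
#'   mosaic layer.
#' @param image An [image_record()] (geometry + pixel size).
#' @param grid_px Tile side in pixels, default 256.
#' @param min_cells Minimum cells per retained tile, default 200.
#' @return Data.frame with one row per retained tile: `grid_i`, `grid_j`
#'   (0-based, row-major from the top-left), `x_deg`, `y_deg` (tile-center
#'   global coordinates), `eccentricity_deg`, `n_cells`, `visible_area_mm2`,
#'   `local_density`, `mean_area_um2`, `mean_perimeter_um`, `mean_neighbors`,
#'   `n_interior` (non-boundary cells behind the means).
#' @export
grid_summaries <- function(cells, masks, image, grid_px = 256L,
                           min_cells = 200L) {
  stopifnot(inherits(masks, "mask_set"), inherits(image, "image_record"))
  n <- image$image_size
  ps <- image$pixel_size_um
  ng <- n %/% grid_px
  if (ng * grid_px != n) stop("image size must be a multiple of grid_px")

  gi <- pmin(floor(cells$row_px / grid_px), ng - 1)
  gj <- pmin(floor(cells$col_px / grid_px), ng - 1)
  key <- gi * ng + gj

  rows <- list()
  for (i in seq_len(ng) - 1L) {
    ri <- (i * grid_px + 1):((i + 1) * grid_px)
    for (j in seq_len(ng) - 1L) {
      ci <- (j * grid_px + 1):((j + 1) * grid_px)
      in_tile <- key == i * ng + j
      n_cells <- sum(in_tile)
      if (n_cells < min_cells) next
      vis_px <- sum(masks$mosaic[ri, ci])
      if (vis_px == 0) next
      vis_mm2 <- vis_px * ps^2 / 1e6
      cen_px <- c(i, j) * grid_px + (grid_px - 1) / 2
      deg <- pixel_to_global_degrees(cen_px[1], cen_px[2], image)
      interior <- in_tile & !cells$boundary_flag
      rows[[length(rows) + 1]] <- data.frame(
        grid_i = i, grid_j = j, x_deg = deg[1], y_deg = deg[2],
        eccentricity_deg = signed_eccentricity(deg[1], deg[2]),
        n_cells = n_cells, visible_area_mm2 = vis_mm2,
        local_density = n_cells / vis_mm2,
        mean_area_um2 = if (any(interior)) mean(cells$area_um2[interior]) else NA_real_,
        mean_perimeter_um = if (any(interior)) mean(cells$perimeter_um[interior]) else NA_real_,
        mean_neighbors = if (any(interior)) mean(cells$n_neighbors[interior]) else NA_real_,
        n_interior = sum(interior)
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(grid_i = integer(0), grid_j = integer(0),
                      x_deg = numeric(0), y_deg = numeric(0),
                      eccentricity_deg = numeric(0), n_cells = integer(0),
                      visible_area_mm2 = numeric(0), local_density = numeric(0),
                      mean_area_um2 = numeric(0), mean_perimeter_um = numeric(0),
                      mean_neighbors = numeric(0), n_interior = integer(0)))
  }
  do.call(rbind, rows)
}

#' Central-eccentricity exclusion for photoreceptor records
#'
#' Removes photoreceptor records detected strictly inside the central
#' eccentricity band (`-band < e < band`, open interval: records exactly at
#' the band edge are retained), where the optical resolution of the device is
#' insufficient for cone measurement. Records of other modalities pass
#' through untouched, and the operation is idempotent.
#'
#' @param records Data.frame with an `eccentricity_deg` column (cells or grid
#'   summaries).
#' @param modality Modality of the records; filtering applies only to
#'   `"PR"`.
#' @param band Half-width of the exclusion band in degrees, default 2.5.
#' @return The filtered data.frame.
#' @export
pr_central_exclusion <- function(records, modality = "PR", band = 2.5) {
  if (modality != "PR") return(records)
  keep <- !(records$eccentricity_deg > -band & records$eccentricity_deg < band)
  records[keep, , drop = FALSE]
}

#' Eccentricity profile of morphometric descriptors
#'
#' Quantizes the signed eccentricity of grid summaries into `n_bins`
#' equal-width bins across `range_deg` and reports, per bin, the count,
#' arithmetic mean and standard deviation of each descriptor. Empty bins are
#' reported with count 0 and missing means. (Profile plots conventionally use
#' error bars of width two standard deviations.)
#'
#' @param summaries Data.frame from [grid_summaries()] (needs
#'   `eccentricity_deg` plus the descriptor columns).
#' @param n_bins Number of equal-width bins, default 25.
#' @param range_deg Length-2 numeric range of signed eccentricities covered,
#'   default `c(-10, 10)`.
#' @param descriptors Character vector of descriptor columns to profile.
#' @return Data.frame with `bin`, `ecc_lo`, `ecc_hi`, `ecc_mid`, `n`, and
#'   `mean_<d>` / `sd_<d>` per descriptor.
#' @export
eccentricity_profile <- function(summaries, n_bins = 25L,
                                 range_deg = c(-10, 10),
                                 descriptors = c("local_density",
                                                 "mean_area_um2",
                                                 "mean_perimeter_um",
                                                 "mean_neighbors")) {
  if (nrow(summaries) < 1) stop("need at least one retained summary")
  edges <- seq(range_deg[1], range_deg[2], length.out = n_bins + 1)
  e <- summaries$eccentricity_deg
  in_range <- e >= range_deg[1] & e <= range_deg[2]
  bin <- findInterval(e, edges, rightmost.closed = TRUE)
  out <- data.frame(bin = seq_len(n_bins),
                    ecc_lo = edges[-(n_bins + 1)], ecc_hi = edges[-1])
  out$ecc_mid <- (out$ecc_lo + out$ecc_hi) / 2
  out$n <- vapply(seq_len(n_bins),
                  function(b) sum(in_range & bin == b), integer(1))
  for (d in descriptors) {
    v <- summaries[[d]]
    out[[paste0("mean_", d)]] <- vapply(seq_len(n_bins), function(b) {
      x <- v[in_range & bin == b]
      if (length(x)) mean(x, na.rm = TRUE) else NA_real_
    }, numeric(1))
    out[[paste0("sd_", d)]] <- vapply(seq_len(n_bins), function(b) {
      x <- v[in_range & bin == b]
      if (length(x) > 1) stats::sd(x, na.rm = TRUE) else NA_real_
    }, numeric(1))
  }
  attr(out, "edges") <- edges
  out
}

#' Spatial heatmap of a grid-summary descriptor
#'
#' Bins summaries on the global coordinate plane (one raster per eye side is
#' the intended use), averages the descriptor per bin, and applies Gaussian
#' smoothing with a sigma of about one sampling distance. Smoothing is
#' support-normalized (Nadaraya-Watson): empty bins far from any sample stay
#' missing rather than being interpolated.
#'
#' @param summaries Data.frame with `x_deg`, `y_deg` and the descriptor.
#' @param descriptor Column to map, default `"local_density"`.
#' @param bin_deg Bin (sampling) pitch in degrees; default 0.8375, one grid
#'   square.
#' @param sigma_deg Smoothing sigma in degrees, default equal to `bin_deg`;
#'   use 0 for no smoothing.
#' @param range_deg Range covered in both axes, default `c(-10, 10)`.
#' @param min_weight Support below which a smoothed bin is reported missing.
#' @return List with `x`, `y` (bin centers) and `z` (matrix, rows = x bins,
#'   cols = y bins, `NA` where unsupported).
#' @export
density_heatmap <- function(summaries, descriptor = "local_density",
                            bin_deg = 0.8375, sigma_deg = bin_deg,
                            range_deg = c(-10, 10), min_weight = 1e-3) {
  edges <- seq(range_deg[1], range_deg[2], by = bin_deg)
  if (edges[length(edges)] < range_deg[2]) edges <- c(edges, range_deg[2])
  nb <- length(edges) - 1
  ctr <- (edges[-1] + edges[-(nb + 1)]) / 2
  ix <- findInterval(summaries$x_deg, edges, rightmost.closed = TRUE)
  iy <- findInterval(summaries$y_deg, edges, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix <= nb & iy >= 1 & iy <= nb &
    is.finite(summaries[[descriptor]])
  val <- matrix(0, nb, nb)
  cnt <- matrix(0, nb, nb)
  for (k in which(ok)) {
    val[ix[k], iy[k]] <- val[ix[k], iy[k]] + summaries[[descriptor]][k]
    cnt[ix[k], iy[k]] <- cnt[ix[k], iy[k]] + 1
  }
  has <- cnt > 0
  mean_map <- matrix(NA_real_, nb, nb)
  mean_map[has] <- val[has] / cnt[has]
  if (sigma_deg > 0) {
    s_bins <- sigma_deg / bin_deg
    num <- gauss_blur_cpp(ifelse(has, mean_map, 0), s_bins)
    den <- gauss_blur_cpp(has * 1, s_bins)
    sm <- matrix(NA_real_, nb, nb)
    sel <- den > min_weight
    sm[sel] <- num[sel] / den[sel]
    mean_map <- sm
  }
  list(x = ctr, y = ctr, z = mean_map)
}

#' Match RPE and photoreceptor grid rectangles and form descriptor ratios
#'
#' For one eye imaged in both modalities, pairs each photoreceptor grid
#' square with the RPE grid square whose center is closest, accepting a pair
#' only when the centroid distance is below `tol_deg` (greedy nearest-first,
#' one-to-one). Unmatched rectangles are dropped. For every matched pair the
#' PR/RPE ratio of each descriptor is computed, and pairs are labelled with
#' the RPE rectangle's eccentricity for binning.
#'
#' @param rpe,pr Data.frames from [grid_summaries()] for the same eye.
#' @param tol_deg Maximum centroid distance in degrees, default half a grid
#'   square (0.41875).
#' @param descriptors Descriptor columns to ratio.
#' @return Data.frame of matched pairs with `eccentricity_deg`, the matched
#'   centroid distance, and `ratio_<d>` columns; zero rows (with a warning)
#'   when nothing matches.
#' @export
match_rpe_pr_rectangles <- function(rpe, pr, tol_deg = 0.41875,
                                    descriptors = c("local_density",
                                                    "mean_area_um2",
                                                    "mean_perimeter_um",
                                                    "mean_neighbors")) {
  empty <- data.frame(eccentricity_deg = numeric(0), dist_deg = numeric(0))
  for (d in descriptors) empty[[paste0("ratio_", d)]] <- numeric(0)
  if (nrow(rpe) == 0 || nrow(pr) == 0) {
    warning("no rectangles to match")
    return(empty)
  }
  dmat <- outer(rpe$x_deg, pr$x_deg, "-")^2 + outer(rpe$y_deg, pr$y_deg, "-")^2
  dmat <- sqrt(dmat)
  pairs <- which(dmat < tol_deg, arr.ind = TRUE)
  if (!nrow(pairs)) {
    warning("no rectangles matched within tolerance")
    return(empty)
  }
  ord <- order(dmat[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  used_r <- logical(nrow(rpe))
  used_p <- logical(nrow(pr))
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (used_r[i] || used_p[j]) next
    used_r[i] <- TRUE; used_p[j] <- TRUE
    row <- data.frame(eccentricity_deg = rpe$eccentricity_deg[i],
                      dist_deg = dmat[i, j])
    for (d in descriptors) row[[paste0("ratio_", d)]] <- pr[[d]][j] / rpe[[d]][i]
    rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, rows)
}
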