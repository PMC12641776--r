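#' Masked Voronoi morphometry of detected cell centroids
#'
#' Builds the planar Voronoi tessellation of the detected centroids, clips
#' every region to the image rectangle, and measures each cell: region area
#' (um^2), perimeter (um), and the number of neighbors (regions sharing an
#' edge of positive length). Regions that touch the image rectangle, or whose
#' polygon reaches outside the mosaic mask, are flagged as boundary cells;
#' downstream morphometric summaries use non-boundary cells only, while cell
#' counts (density) include them.
#'
#' Mask membership is decided by the centroid's raster position (regions are
#' not re-clipped to the mask), so the tessellation depends only on the
#' centroids and the frame.
#'
#' @param centroids Two-column matrix or data.frame of 0-based pixel
#'   coordinates (`row_px`, `col_px`). At least 4 distinct points.
#' @param pixel_size_um Pixel size in micrometres.
#' @param image_size Side length of the (square) image in pixels; defaults to
#'   the mask dimension when `masks` is given.
#' @param masks Optional [mask_set()] used to flag cells whose region touches
#'   masked-out raster area.
#' @return A data.frame with one row per retained (deduplicated) centroid:
#'   `row_px`, `col_px`, `area_um2`, `perimeter_um`, `n_neighbors`,
#'   `boundary_flag`. The list of neighbor indices (row indices into the
#'   returned frame) is attached as attribute `"neighbors"`, and the clipped
#'   region polygons (x = col, y = row, pixel units) as attribute
#'   `"polygons"`.
#' @export
voronoi_morphometry <- function(centroids, pixel_size_um, image_size = NULL,
                                masks = NULL) {
  cen <- as.matrix(centroids)[, 1:2, drop = FALSE]
  storage.mode(cen) <- "double"
  if (is.null(image_size)) {
    if (is.null(masks)) stop("image_size or masks must be supplied")
    image_size <- nrow(masks$mosaic)
  }
  dup <- duplicated(cen)
  if (any(dup)) {
    warning(sprintf("removed %d duplicate centroid(s)", sum(dup)))
    cen <- cen[!dup, , drop = FALSE]
  }
  if (nrow(cen) < 4) stop("insufficient points: need >= 4 distinct centroids")

  # image rectangle spans the pixel extents: centers 0..N-1, edges -0.5..N-0.5
  lo <- -0.5
  hi <- image_size - 0.5
  vc <- voronoi_cells_cpp(cen[, 2], cen[, 1], lo, hi, lo, hi,
                          return_polygons = TRUE)

  boundary <- vc$touches_rect
  if (!is.null(masks)) {
    stopifnot(inherits(masks, "mask_set"))
    n <- image_size
    for (i in seq_len(nrow(cen))) {
      if (boundary[i]) next
      p <- vc$polygons[[i]]
      rr <- pmin(pmax(round(p[, 2]), 0), n - 1) + 1
      cc <- pmin(pmax(round(p[, 1]), 0), n - 1) + 1
      if (any(!masks$mosaic[cbind(rr, cc)])) boundary[i] <- TRUE
    }
  }

  out <- data.frame(
    row_px = cen[, 1], col_px = cen[, 2],
    area_um2 = vc$area * pixel_size_um^2,
    perimeter_um = vc$perimeter * pixel_size_um,
    n_neighbors = vapply(vc$neighbors, length, integer(1)),
    boundary_flag = as.logical(boundary)
  )
  attr(out, "neighbors") <- vc$neighbors
  attr(out, "polygons") <- vc$polygons
  out
}
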