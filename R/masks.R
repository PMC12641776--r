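#' Layered analysis masks for one acquisition
#'
#' A `mask_set` holds three boolean rasters aligned with the image:
#' `quality_visible` (in-focus, analyzable), `vessel` (retinal vessel), and
#' `mosaic` (target cellular structure clearly present). The mosaic layer is
#' always constrained to `quality_visible & !vessel`.
#'
#' @param quality_visible,vessel,mosaic Logical matrices of identical size.
#' @return An object of class `mask_set`.
#' @export
mask_set <- function(quality_visible, vessel, mosaic) {
  stopifnot(is.logical(quality_visible), is.logical(vessel), is.logical(mosaic),
            all(dim(quality_visible) == dim(vessel)),
            all(dim(quality_visible) == dim(mosaic)))
  mosaic <- mosaic & quality_visible & !vessel
  structure(list(quality_visible = quality_visible, vessel = vessel,
                 mosaic = mosaic), class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set> %dx%d px: quality %.1f%%, vessel %.1f%%, mosaic %.1f%%\n",
              nrow(x$mosaic), ncol(x$mosaic), 100 * mean(x$quality_visible),
              100 * mean(x$vessel), 100 * mean(x$mosaic)))
  invisible(x)
}

#' Fraction of the image excluded from cell measurement
#'
#' One minus the fraction of pixels in the mosaic layer.
#'
#' @param masks A [mask_set()].
#' @return Masked fraction in `[0, 1]`.
#' @export
masked_fraction <- function(masks) {
  stopifnot(inherits(masks, "mask_set"))
  1 - mean(masks$mosaic)
}

# expected cell spacing (px) for a modality: hexagonal-packing relation
# density = 2 / (sqrt(3) s^2), density in cells/mm^2, pixel size in um
expected_spacing_px <- function(density_mm2, pixel_size_um) {
  d_um2 <- density_mm2 / 1e6
  sqrt(2 / (sqrt(3) * d_um2)) / pixel_size_um
}

# morphological closing (max then min) with a square structuring element
mask_close <- function(mask, r) {
  if (r < 1) return(mask)
  m <- max_filter_cpp(mask * 1, as.integer(r))
  -max_filter_cpp(-m, as.integer(r)) > 0.5
}

mask_open <- function(mask, r) {
  if (r < 1) return(mask)
  m <- -max_filter_cpp(-(mask * 1), as.integer(r))
  max_filter_cpp(m, as.integer(r)) > 0.5
}

# band-pass (difference-of-Gaussians) response tuned to the expected cell
# spacing; positive on bright blobs at that scale
dog_response <- function(img, s_px, sigma_frac = c(0.25, 0.5)) {
  gauss_blur_cpp(img, sigma_frac[1] * s_px) -
    gauss_blur_cpp(img, sigma_frac[2] * s_px)
}

#' Quality (focus/visibility) mask
#'
#' Marks pixels as analyzable where a local sharpness statistic — the
#' windowed mean square of a high-pass residual — exceeds an absolute
#' threshold, then closes small holes morphologically. Out-of-focus or blurred
#' regions lose their fine-scale energy and fall below the threshold; a
#' constant image is entirely non-analyzable.
#'
#' @param image An [image_record()] with pixels, or a numeric matrix.
#' @param params List of detector parameters (see [default_config()]
#'   `$quality`): `highpass_sigma_frac`, `window_frac` (both in units of the
#'   expected cell spacing), `energy_threshold`, `close_radius_frac`.
#' @param s_px Expected cell spacing in pixels; computed from the image
#'   modality when an `image_record` is given.
#' @return Logical matrix, `TRUE` = analyzable.
#' @export
build_quality_mask <- function(image, params = default_config()$quality,
                               s_px = NULL) {
  img <- if (inherits(image, "image_record")) image$pixels else image
  if (is.null(s_px)) s_px <- spacing_for_image(image)
  hp <- img - gauss_blur_cpp(img, params$highpass_sigma_frac * s_px)
  e <- box_mean_cpp(hp^2, as.integer(round(params$window_frac * s_px)))
  q <- e >= params$energy_threshold
  mask_close(q, round(params$close_radius_frac * s_px))
}

#' Vessel mask
#'
#' Detects retinal vessels as wide, dark, elongated structures: the image is
#' smoothed at the vessel scale (suppressing the cellular texture), pixels
#' substantially darker than the image median are marked, and connected
#' components are kept only when they are large and elongated (ratio of
#' principal second moments above a minimum).
#'
#' @param image An [image_record()] or numeric matrix.
#' @param params List (see [default_config()] `$vessel`): `smooth_sigma_px`,
#'   `dark_fraction` (threshold as a fraction of the smoothed median),
#'   `min_area_px`, `min_elongation`, and `dilate_px` (optional growth of the
#'   detected core to cover the penumbra; 0 disables).
#' @return Logical matrix, `TRUE` = vessel.
#' @export
build_vessel_mask <- function(image, params = default_config()$vessel) {
  img <- if (inherits(image, "image_record")) image$pixels else image
  v <- gauss_blur_cpp(img, params$smooth_sigma_px)
  med <- stats::median(v)
  raw <- v < params$dark_fraction * med
  if (!any(raw)) return(raw)
  lab <- label_components_cpp(raw)
  keep <- logical(max(lab))
  idx <- which(lab > 0)
  if (length(idx)) {
    comp <- lab[idx]
    rr <- (idx - 1) %% nrow(img)
    cc <- (idx - 1) %/% nrow(img)
    for (k in seq_len(max(lab))) {
      sel <- comp == k
      n <- sum(sel)
      if (n < params$min_area_px) next
      cv <- stats::cov(cbind(rr[sel], cc[sel]))
      ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
      if (ev[2] <= 0 || sqrt(ev[1] / ev[2]) >= params$min_elongation) {
        keep[k] <- TRUE
      }
    }
  }
  out <- matrix(FALSE, nrow(img), ncol(img))
  out[idx[keep[lab[idx]]]] <- TRUE
  # the threshold finds the dark vessel core; grow it to cover the
  # penumbra where cells are still obscured
  if (any(out) && params$dilate_px > 0) {
    out <- max_filter_cpp(out * 1, as.integer(params$dilate_px)) > 0.5
  }
  out
}

#' Mosaic mask
#'
#' Restricts the analyzable area to regions where the target cellular
#' structure is actually present: within `quality & !vessel`, a pixel belongs
#' to the mosaic when the local energy of the band-pass (cell-spacing-tuned)
#' response is a sufficiently large fraction of the local high-frequency
#' energy — a periodicity criterion that rejects structureless noise, which
#' spreads its energy across all frequencies — and exceeds an absolute floor.
#'
#' @param image An [image_record()] or numeric matrix.
#' @param quality,vessel Logical rasters from [build_quality_mask()] and
#'   [build_vessel_mask()].
#' @param modality `"RPE"` or `"PR"` (taken from the record when available).
#' @param params List (see [default_config()] `$mosaic`):
#'   `band_ratio_threshold`, `energy_floor`, `close_radius_frac`,
#'   `open_radius_frac`, plus the quality-stage `highpass_sigma_frac`.
#' @param s_px Expected cell spacing in pixels.
#' @return A [mask_set()].
#' @export
build_mosaic_mask <- function(image, quality, vessel, modality = NULL,
                              params = default_config()$mosaic, s_px = NULL) {
  img <- if (inherits(image, "image_record")) image$pixels else image
  if (is.null(modality) && inherits(image, "image_record")) {
    modality <- image$modality
  }
  if (is.null(s_px)) s_px <- spacing_for_image(image, modality)
  resp <- dog_response(img, s_px)
  w <- as.integer(round(2 * s_px))
  e_band <- box_mean_cpp(resp^2, w)
  hp <- img - gauss_blur_cpp(img, params$highpass_sigma_frac * s_px)
  e_tot <- box_mean_cpp(hp^2, w)
  ratio <- e_band / pmax(e_tot, 1e-12)
  m <- quality & !vessel & ratio >= params$band_ratio_threshold &
    e_band >= params$energy_floor
  m <- mask_close(m, round(params$close_radius_frac * s_px))
  m <- mask_open(m, round(params$open_radius_frac * s_px))
  mask_set(quality_visible = quality, vessel = vessel, mosaic = m)
}

#' Visible cell mosaic area ratio
#'
#' The area classified as cellular mosaic divided by the total analyzable
#' (in-focus, non-vessel) area of the image. By normalizing to the visible
#' area only, the ratio tracks the biological presence of a regular mosaic
#' rather than acquisition quality.
#'
#' @param masks A [mask_set()].
#' @return Fraction in `[0, 1]`.
#' @export
visible_mosaic_area_ratio <- function(masks) {
  stopifnot(inherits(masks, "mask_set"))
  denom <- sum(masks$quality_visible & !masks$vessel)
  if (denom == 0) stop("undefined ratio: no visible area")
  sum(masks$mosaic) / denom
}

# expected spacing helper for image records
spacing_for_image <- function(image, modality = NULL, config = default_config()) {
  if (inherits(image, "image_record")) {
    modality <- image$modality
    ps <- image$pixel_size_um
  } else {
    if (is.null(modality)) modality <- "RPE"
    ps <- config$pixel_size_fallback_um
  }
  expected_spacing_px(config$expected_density[[modality]], ps)
}
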