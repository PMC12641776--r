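#' Retinal magnification: pixel size from axial length
#'
#' Converts the axial length of an eye into the retinal size of one image
#' pixel, using the Bennett-Littmann linear magnification model
#' \deqn{\mathrm{pixel\ size}(\mu m) = 0.504 \times 0.01306 \times
#'   (\mathrm{AL}_{mm} - 1.82) \times 6.5,}
#' i.e. the q-factor `0.01306 * (AL - 1.82)` (mm per degree, scaled) times the
#' device's angular pixel pitch. The mapping is strictly increasing and linear
#' in axial length and vanishes at the 1.82 mm nodal-point offset.
#'
#' @param axial_length Axial length of the eye in mm. Must exceed 1.82.
#' @return Pixel size in micrometres per pixel.
#' @examples
#' bennett_littmann_pixel_size(24)
#' @export
bennett_littmann_pixel_size <- function(axial_length) {
  if (any(!is.finite(axial_length)) || any(axial_length <= 1.82)) {
    stop("invalid biometry: axial_length must be finite and > 1.82 mm")
  }
  0.504 * 0.01306 * (axial_length - 1.82) * 6.5
}

#' Eye metadata record
#'
#' @param eye_id Identifier.
#' @param side `"OD"` (right) or `"OS"` (left).
#' @param age Age in years (>= 0).
#' @param gender `"female"` or `"male"`.
#' @param axial_length Axial length in mm (> 1.82).
#' @param spherical_equivalent Optional refraction in diopters.
#' @param visual_acuity Optional decimal visual acuity.
#' @return An object of class `eye_meta`.
#' @export
eye_meta <- function(eye_id, side, age, gender, axial_length,
                     spherical_equivalent = NA_real_,
                     visual_acuity = NA_real_) {
  side <- match.arg(side, c("OD", "OS"))
  gender <- match.arg(gender, c("female", "male"))
  stopifnot(age >= 0)
  if (axial_length <= 1.82) stop("invalid biometry: axial_length must be > 1.82 mm")
  structure(list(eye_id = as.character(eye_id), side = side, age = age,
                 gender = gender, axial_length = axial_length,
                 spherical_equivalent = spherical_equivalent,
                 visual_acuity = visual_acuity),
            class = "eye_meta")
}

#' One adaptive-optics acquisition
#'
#' Bundles the pixel raster with the metadata needed to interpret it: the eye,
#' the imaging modality, and the fixation-relative position of the image
#' center in degrees. The pixel size in micrometres is derived from the eye's
#' axial length and never stored independently.
#'
#' @param eye An [eye_meta()] object.
#' @param modality `"RPE"` or `"PR"`.
#' @param pixels Square numeric matrix of nonnegative intensities
#'   (rows = image rows). May be `NULL` for geometry-only records.
#' @param center_deg Length-2 numeric, (x, y) of the image center in degrees
#'   relative to the fixation target (+x temporal, +y superior).
#' @param fov_deg Field of view in degrees (square), default 6.7.
#' @param image_size Side length in pixels; taken from `pixels` when supplied.
#' @return An object of class `image_record`.
#' @export
image_record <- function(eye, modality, pixels = NULL, center_deg = c(0, 0),
                         fov_deg = 6.7, image_size = 2048L) {
  stopifnot(inherits(eye, "eye_meta"), fov_deg > 0, length(center_deg) == 2)
  modality <- match.arg(modality, c("RPE", "PR"))
  if (!is.null(pixels)) {
    stopifnot(is.matrix(pixels), nrow(pixels) == ncol(pixels))
    if (any(pixels < 0)) stop("pixel intensities must be nonnegative")
    image_size <- nrow(pixels)
  }
  structure(list(eye = eye, modality = modality, pixels = pixels,
                 center_deg = as.numeric(center_deg), fov_deg = fov_deg,
                 image_size = as.integer(image_size),
                 pixel_size_um = bennett_littmann_pixel_size(eye$axial_length)),
            class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record> eye %s (%s), %s mode, %dx%d px, %.2f deg FOV\n",
              x$eye$eye_id, x$eye$side, x$modality, x$image_size,
              x$image_size, x$fov_deg))
  cat(sprintf("  center (%.2f, %.2f) deg; pixel size %.4f um\n",
              x$center_deg[1], x$center_deg[2], x$pixel_size_um))
  invisible(x)
}

#' Map pixel indices to fixation-relative degrees
#'
#' Converts image pixel positions to global macular coordinates in degrees
#' relative to the fixation target. Pixel indices are 0-based and refer to
#' pixel centers, so the image center sits at index `(N-1)/2` in each axis.
#' The horizontal axis is mirrored between right (OD) and left (OS) eyes so
#' that +x points to the temporal retina for both sides; +y points to the
#' superior retina, with row index increasing downward.
#'
#' @param row,col 0-based pixel indices (vectors allowed), in `[0, N)`.
#' @param image An [image_record()].
#' @return A two-column matrix with columns `x_deg`, `y_deg`.
#' @export
pixel_to_global_degrees <- function(row, col, image) {
  n <- image$image_size
  if (any(row < 0 | row >= n) || any(col < 0 | col >= n)) {
    stop("pixel index out of bounds")
  }
  scale <- image$fov_deg / n
  c0 <- (n - 1) / 2
  dx <- (col - c0) * scale
  dy <- -(row - c0) * scale
  if (image$eye$side == "OS") dx <- -dx
  cbind(x_deg = image$center_deg[1] + dx, y_deg = image$center_deg[2] + dy)
}

#' Signed retinal eccentricity
#'
#' Radial distance from the fixation-estimated foveal center, signed by the
#' horizontal coordinate so that the temporal side is positive and the nasal
#' side negative: `e = sign(x) * sqrt(x^2 + y^2)`, with `sign(0)` taken as +1
#' so that `e = 0` occurs only at the exact origin.
#'
#' @param x,y Coordinates in degrees (vectors allowed).
#' @return Signed eccentricity in degrees.
#' @examples
#' signed_eccentricity(3, 4)   # +5
#' signed_eccentricity(-3, 4)  # -5
#' @export
signed_eccentricity <- function(x, y) {
  s <- ifelse(x < 0, -1, 1)
  s * sqrt(x^2 + y^2)
}
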