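#' Read an adaptive-optics image file
#'
#' Reads a 16-bit grayscale TIFF or PNG into a numeric matrix of intensities
#' in `[0, 1]` (multi-channel files are averaged to grayscale).
#'
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @return Numeric matrix.
#' @export
read_ao_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  img
}

#' Write an image or mask
#'
#' Images are written as 16-bit TIFF; masks (logical matrices) as single-
#' channel 0/255 PNG.
#'
#' @param x Numeric matrix in `[0, 1]` or logical matrix.
#' @param path Destination path (`.tif`/`.tiff` or `.png`).
#' @return Invisibly, the path.
#' @export
write_ao_image <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (is.logical(x)) {
    png::writePNG(x * 1, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(pmin(pmax(x, 0), 1), path, bits.per.sample = 16)
  } else {
    png::writePNG(pmin(pmax(x, 0), 1), path)
  }
  invisible(path)
}

#' Read eye metadata and image manifest CSVs
#'
#' @param eyes_csv CSV with columns `eye_id`, `side`, `age`, `gender`,
#'   `axial_length_mm` (and optionally `spherical_equivalent`,
#'   `visual_acuity`).
#' @param manifest_csv CSV with columns `image_id`, `eye_id`, `modality`,
#'   `center_x_deg`, `center_y_deg`, `path`.
#' @return List with data.frames `eyes` and `manifest`.
#' @export
read_study_tables <- function(eyes_csv, manifest_csv) {
  eyes <- utils::read.csv(eyes_csv, stringsAsFactors = FALSE)
  need <- c("eye_id", "side", "age", "gender", "axial_length_mm")
  if (!all(need %in% names(eyes))) {
    stop("eyes CSV must contain: ", paste(need, collapse = ", "))
  }
  manifest <- utils::read.csv(manifest_csv, stringsAsFactors = FALSE)
  list(eyes = eyes, manifest = manifest)
}

#' Build image records from study tables
#'
#' Joins the manifest to the eye table, reads each image file, and returns
#' the list of [image_record()] objects ready for [run_pipeline()]. Eyes
#' without a valid axial length are skipped with a message, since
#' magnification scaling is impossible for them.
#'
#' @param tables List from [read_study_tables()].
#' @param fov_deg Field of view, default 6.7.
#' @return Named list of image records (names = image ids).
#' @export
load_image_records <- function(tables, fov_deg = 6.7) {
  out <- list()
  for (i in seq_len(nrow(tables$manifest))) {
    m <- tables$manifest[i, ]
    e <- tables$eyes[tables$eyes$eye_id == m$eye_id, ]
    if (nrow(e) != 1 || !is.finite(e$axial_length_mm) ||
        e$axial_length_mm <= 1.82) {
      message("skipping ", m$image_id, ": no usable axial length")
      next
    }
    eye <- eye_meta(e$eye_id, e$side, e$age, e$gender, e$axial_length_mm,
                    if ("spherical_equivalent" %in% names(e))
                      e$spherical_equivalent else NA_real_,
                    if ("visual_acuity" %in% names(e))
                      e$visual_acuity else NA_real_)
    out[[m$image_id]] <- image_record(eye, m$modality,
                                      pixels = read_ao_image(m$path),
                                      center_deg = c(m$center_x_deg,
                                                     m$center_y_deg),
                                      fov_deg = fov_deg)
  }
  out
}
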