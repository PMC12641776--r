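#' Detect cell centroids inside the mosaic mask
#'
#' Classical blob detection matched to the expected cell spacing of the
#' modality: a difference-of-Gaussians band-pass response (computed on the
#' image for photoreceptor dots, on the inverted image for the dim centers of
#' the RPE honeycomb) followed by local-maxima extraction with a minimum
#' separation constraint and an adaptive amplitude threshold. Only maxima
#' whose pixel lies inside the mosaic mask are returned.
#'
#' @param image An [image_record()] with pixels.
#' @param masks A [mask_set()]; detection is restricted to `masks$mosaic`.
#' @param params Detector parameters (see [default_config()] `$detector`):
#'   `dog_sigma_frac` (two fractions of the expected spacing),
#'   `minsep_frac` (minimum separation as a fraction of the spacing, enforced
#'   as a Chebyshev-window non-maximum suppression),
#'   `response_threshold_frac` (threshold as a fraction of the 99th percentile
#'   of the in-mosaic response).
#' @param s_px Expected cell spacing in pixels (derived from the record's
#'   modality and pixel size when omitted).
#' @return Two-column matrix of 0-based pixel indices (`row_px`, `col_px`),
#'   one row per detected centroid. Empty matrix when the mosaic mask is
#'   empty.
#' @export
detect_centroids <- function(image, masks, params = default_config()$detector,
                             s_px = NULL) {
  stopifnot(inherits(image, "image_record"), inherits(masks, "mask_set"))
  empty <- matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("row_px", "col_px")))
  if (!any(masks$mosaic)) return(empty)
  if (is.null(s_px)) s_px <- spacing_for_image(image)
  img <- image$pixels
  resp <- dog_response(img, s_px, params$dog_sigma_frac)
  if (image$modality == "RPE") resp <- -resp  # honeycomb centers are dim
  r <- max(1L, as.integer(round(params$minsep_frac * s_px / sqrt(2))))
  mx <- max_filter_cpp(resp, r)
  thr <- params$response_threshold_frac *
    stats::quantile(resp[masks$mosaic], 0.99, names = FALSE)
  cand <- which(resp >= mx & masks$mosaic & resp > thr)
  if (!length(cand)) return(empty)
  row <- (cand - 1) %% nrow(img)
  col <- (cand - 1) %/% nrow(img)
  cbind(row_px = row, col_px = col)
}
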