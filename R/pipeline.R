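#' Default analysis configuration
#'
#' All stage parameters in one auditable list. The protocol constants of the
#' acquisition and filtering cascade (field of view 6.7 degrees, 2048-pixel
#' frames, 256-pixel grid squares, the 200-cell square filter, the 90%
#' mask-exclusion rule, the 2.5-degree photoreceptor exclusion band, 25
#' eccentricity bins over -10..10 degrees) carry origin `"protocol"`; every
#' threshold of the classical detector is an implementation default with
#' origin `"detector"`. [config_provenance()] tabulates the split.
#'
#' @return Nested list of parameters.
#' @export
default_config <- function() {
  list(
    fov_deg = 6.7,
    image_size = 2048L,
    grid_px = 256L,
    min_cells_per_square = 200L,
    mask_exclusion_fraction = 0.90,
    pr_exclusion_deg = 2.5,
    n_bins = 25L,
    ecc_range_deg = c(-10, 10),
    match_tol_deg = 0.41875,
    expected_density = list(RPE = 6313, PR = 10207),
    pixel_size_fallback_um = 0.949,
    quality = list(highpass_sigma_frac = 2, window_frac = 2,
                   energy_threshold = 1e-3, close_radius_frac = 0.5),
    vessel = list(smooth_sigma_px = 5, dark_fraction = 0.75,
                  min_area_px = 2000, min_elongation = 2.5, dilate_px = 0),
    mosaic = list(band_ratio_threshold = 0.015, energy_floor = 1e-4,
                  highpass_sigma_frac = 2, close_radius_frac = 0.75,
                  open_radius_frac = 0.5),
    detector = list(dog_sigma_frac = c(0.18, 0.4), minsep_frac = 0.5,
                    response_threshold_frac = 0.3)
  )
}

#' Provenance of configuration constants
#'
#' @return Data.frame mapping each top-level configuration constant to its
#'   origin: `"protocol"` (a constant of the acquisition/filtering protocol)
#'   or `"detector"` (a default of this package's classical detector).
#' @export
config_provenance <- function() {
  data.frame(
    parameter = c("fov_deg", "image_size", "grid_px", "min_cells_per_square",
                  "mask_exclusion_fraction", "pr_exclusion_deg", "n_bins",
                  "ecc_range_deg", "match_tol_deg", "expected_density",
                  "quality.*", "vessel.*", "mosaic.*", "detector.*"),
    origin = c("protocol", "protocol", "protocol", "protocol", "protocol",
               "protocol", "protocol", "protocol", "detector", "detector",
               "detector", "detector", "detector", "detector")
  )
}

#' Load a configuration from YAML, merged over the defaults
#'
#' @param path Path to a YAML file whose keys override [default_config()].
#' @return Configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_into <- function(base, over) {
    for (k in names(over)) {
      if (is.list(base[[k]]) && is.list(over[[k]])) {
        base[[k]] <- merge_into(base[[k]], over[[k]])
      } else {
        base[[k]] <- over[[k]]
      }
    }
    base
  }
  merge_into(cfg, user)
}

# raster of signed eccentricity per pixel (degrees), used for the
# photoreceptor central-band mask restriction
eccentricity_raster <- function(image) {
  n <- image$image_size
  scale <- image$fov_deg / n
  c0 <- (n - 1) / 2
  dx <- ((0:(n - 1)) - c0) * scale
  if (image$eye$side == "OS") dx <- -dx
  dy <- -(((0:(n - 1))) - c0) * scale
  x <- image$center_deg[1] + dx   # by column
  y <- image$center_deg[2] + dy   # by row
  sx <- matrix(x, n, n, byrow = TRUE)
  sy <- matrix(y, n, n)
  sgn <- ifelse(sx < 0, -1, 1)
  sgn * sqrt(sx^2 + sy^2)
}

#' Analyze one acquisition
#'
#' The per-image stage of the pipeline: build the quality, vessel, and mosaic
#' masks (unless ground-truth or precomputed masks are supplied), decide the
#' over-masking exclusion, detect cell centroids, tessellate, and attach
#' global coordinates and signed eccentricity to every cell. For
#' photoreceptor images the central exclusion band is removed from the mosaic
#' mask before detection, so cell counts and visible areas stay consistent.
#'
#' @param image An [image_record()] with pixels.
#' @param config Configuration list, see [default_config()].
#' @param masks Optional [mask_set()] to use instead of running the mask
#'   stage.
#' @return List with `masks`, `keep` (over-masking decision), `cells`
#'   (data.frame: pixel positions, degrees, eccentricity, area, perimeter,
#'   neighbors, boundary flag; empty when excluded), and
#'   `visible_mosaic_ratio`.
#' @export
analyze_image <- function(image, config = default_config(), masks = NULL) {
  stopifnot(inherits(image, "image_record"))
  s_px <- expected_spacing_px(config$expected_density[[image$modality]],
                              image$pixel_size_um)
  if (is.null(masks)) {
    quality <- build_quality_mask(image, config$quality, s_px = s_px)
    vessel <- build_vessel_mask(image, config$vessel)
    masks <- build_mosaic_mask(image, quality, vessel,
                               modality = image$modality,
                               params = config$mosaic, s_px = s_px)
  }
  if (image$modality == "PR" && config$pr_exclusion_deg > 0) {
    ecc <- eccentricity_raster(image)
    central <- abs(ecc) < config$pr_exclusion_deg
    if (any(central & masks$mosaic)) {
      masks <- mask_set(masks$quality_visible, masks$vessel,
                        masks$mosaic & !central)
    }
  }
  vratio <- tryCatch(visible_mosaic_area_ratio(masks),
                     error = function(e) NA_real_)
  keep <- exclude_overmasked_images(masks, config$mask_exclusion_fraction)
  empty_cells <- data.frame(row_px = numeric(0), col_px = numeric(0),
                            x_deg = numeric(0), y_deg = numeric(0),
                            eccentricity_deg = numeric(0),
                            area_um2 = numeric(0), perimeter_um = numeric(0),
                            n_neighbors = integer(0), boundary_flag = logical(0))
  if (!keep) {
    return(list(masks = masks, keep = FALSE, cells = empty_cells,
                visible_mosaic_ratio = vratio))
  }
  cen <- detect_centroids(image, masks, config$detector, s_px = s_px)
  if (nrow(cen) < 4) {
    return(list(masks = masks, keep = TRUE, cells = empty_cells,
                visible_mosaic_ratio = vratio))
  }
  cells <- voronoi_morphometry(cen, image$pixel_size_um,
                               image_size = image$image_size, masks = masks)
  deg <- pixel_to_global_degrees(cells$row_px, cells$col_px, image)
  cells$x_deg <- deg[, 1]
  cells$y_deg <- deg[, 2]
  cells$eccentricity_deg <- signed_eccentricity(deg[, 1], deg[, 2])
  cells <- cells[, c("row_px", "col_px", "x_deg", "y_deg", "eccentricity_deg",
                     "area_um2", "perimeter_um", "n_neighbors",
                     "boundary_flag")]
  list(masks = masks, keep = TRUE, cells = cells,
       visible_mosaic_ratio = vratio)
}

#' Run the full analysis over a set of acquisitions
#'
#' Orchestrates the end-to-end pipeline over in-memory scenes or image files:
#' per-image analysis ([analyze_image()]), the over-masking exclusion,
#' grid aggregation with the 200-cell filter ([grid_summaries()]), the
#' photoreceptor central exclusion, eccentricity profiles, per-eye
#' RPE-to-photoreceptor rectangle matching, age trends, stratified summary
#' tables, and the correlation of descriptors with eye-level covariates.
#' Filter bookkeeping (images in, kept, excluded; squares kept) is returned
#' as `filter_manifest`.
#'
#' @param images List of inputs; each element is either an [image_record()]
#'   or a list with `record` (and optionally `masks` to reuse, e.g. from the
#'   synthetic renderer — by default the pipeline recomputes its own masks).
#' @param eyes Data.frame of eye metadata (as from [generate_cohort()]), used
#'   for age trends and correlations; optional.
#' @param config Configuration list.
#' @param use_given_masks Logical; reuse masks supplied with the inputs
#'   instead of running the mask stage (default `FALSE`).
#' @param image_ids Optional character vector of image identifiers.
#' @param output_dir Optional directory; when given, CSV outputs and a
#'   markdown report are written there.
#' @return List with `cells` (per image), `summaries`, `profiles`,
#'   `ratios`, `image_table`, `summary_tables`, `age_trends`,
#'   `correlations`, `filter_manifest`, and `config`.
#' @export
run_pipeline <- function(images, eyes = NULL, config = default_config(),
                         use_given_masks = FALSE, image_ids = NULL,
                         output_dir = NULL) {
  n_img <- length(images)
  if (is.null(image_ids)) image_ids <- sprintf("img%03d", seq_len(n_img))
  per_cells <- list()
  sum_rows <- list()
  img_rows <- list()

  for (i in seq_len(n_img)) {
    inp <- images[[i]]
    rec <- if (inherits(inp, "image_record")) inp else inp$record
    masks <- if (use_given_masks && !inherits(inp, "image_record")) inp$masks
             else NULL
    res <- analyze_image(rec, config, masks = masks)
    img_rows[[i]] <- data.frame(
      image_id = image_ids[i], eye_id = rec$eye$eye_id,
      side = rec$eye$side, modality = rec$modality,
      age = rec$eye$age, gender = rec$eye$gender,
      axial_length_mm = rec$eye$axial_length,
      spherical_equivalent = rec$eye$spherical_equivalent,
      visual_acuity = rec$eye$visual_acuity,
      masked_fraction = masked_fraction(res$masks),
      visible_mosaic_ratio = res$visible_mosaic_ratio,
      kept = res$keep, n_cells = nrow(res$cells))
    if (!res$keep) next
    cells <- res$cells
    if (nrow(cells)) cells <- cbind(image_id = image_ids[i], cells)
    per_cells[[image_ids[i]]] <- cells
    if (!nrow(cells)) next
    gs <- grid_summaries(res$cells, res$masks, rec,
                         grid_px = config$grid_px,
                         min_cells = config$min_cells_per_square)
    gs <- pr_central_exclusion(gs, modality = rec$modality,
                               band = config$pr_exclusion_deg)
    if (nrow(gs)) {
      gs <- cbind(image_id = image_ids[i], eye_id = rec$eye$eye_id,
                  side = rec$eye$side, modality = rec$modality, gs)
      sum_rows[[length(sum_rows) + 1]] <- gs
    }
  }

  image_table <- do.call(rbind, img_rows)
  summaries <- if (length(sum_rows)) do.call(rbind, sum_rows) else NULL
  if (is.null(summaries)) {
    warning("no grid squares retained")
    return(list(cells = per_cells, summaries = NULL, profiles = NULL,
                ratios = NULL, image_table = image_table,
                summary_tables = NULL, age_trends = NULL,
                correlations = NULL,
                filter_manifest = pipeline_filter_manifest(image_table, NULL),
                config = config))
  }

  profiles <- list()
  summary_tables <- list()
  age_trends <- list()
  correlations <- list()
  for (mod in intersect(c("RPE", "PR"), unique(summaries$modality))) {
    sm <- summaries[summaries$modality == mod, , drop = FALSE]
    profiles[[mod]] <- eccentricity_profile(sm, n_bins = config$n_bins,
                                            range_deg = config$ecc_range_deg)
    it <- image_table[image_table$modality == mod & image_table$kept, ]
    gen <- it$gender[match(sm$eye_id, it$eye_id)]
    summary_tables[[mod]] <- do.call(rbind, lapply(
      c("local_density", "mean_neighbors", "mean_area_um2",
        "mean_perimeter_um"),
      function(d) cbind(descriptor = d,
                        stratified_summary(sm[[d]], gen))))
    eye_dens <- tapply(sm$local_density, sm$eye_id, mean)
    eye_age <- it$age[match(names(eye_dens), it$eye_id)]
    if (length(eye_dens) >= 3 && stats::sd(eye_age) > 0) {
      age_trends[[mod]] <- age_trend(as.numeric(eye_dens), eye_age)
    }
    covar <- it[match(sm$eye_id, it$eye_id),
                c("age", "axial_length_mm", "spherical_equivalent",
                  "visual_acuity")]
    cdat <- cbind(sm[, c("local_density", "mean_area_um2",
                         "mean_perimeter_um", "mean_neighbors")], covar)
    ok_cols <- vapply(cdat, function(x) sum(is.finite(x)) >= 3, logical(1))
    if (sum(ok_cols) >= 2) correlations[[mod]] <- pearson_matrix(cdat[, ok_cols])
  }

  # PR/RPE rectangle matching per eye
  ratios <- NULL
  if (all(c("RPE", "PR") %in% summaries$modality)) {
    rr <- list()
    for (eid in unique(summaries$eye_id)) {
      se <- summaries[summaries$eye_id == eid, ]
      if (!all(c("RPE", "PR") %in% se$modality)) next
      mt <- suppressWarnings(
        match_rpe_pr_rectangles(se[se$modality == "RPE", ],
                                se[se$modality == "PR", ],
                                tol_deg = config$match_tol_deg))
      if (nrow(mt)) rr[[eid]] <- cbind(eye_id = eid, mt)
    }
    if (length(rr)) ratios <- do.call(rbind, rr)
  }

  out <- list(cells = per_cells, summaries = summaries, profiles = profiles,
              ratios = ratios, image_table = image_table,
              summary_tables = summary_tables, age_trends = age_trends,
              correlations = correlations,
              filter_manifest = pipeline_filter_manifest(image_table, summaries),
              config = config)
  if (!is.null(output_dir)) write_pipeline_outputs(out, output_dir)
  out
}

# stage-by-stage before/after bookkeeping
pipeline_filter_manifest <- function(image_table, summaries) {
  if (is.null(image_table) || !nrow(image_table)) {
    return(data.frame(stage = "images_in", count = 0))
  }
  rows <- data.frame(
    stage = c("images_in", "images_kept", "images_excluded_overmasked"),
    count = c(nrow(image_table), sum(image_table$kept),
              sum(!image_table$kept)))
  if (!is.null(summaries)) {
    rows <- rbind(rows, data.frame(
      stage = c("grid_squares_retained", "eyes_with_squares"),
      count = c(nrow(summaries), length(unique(summaries$eye_id)))))
  }
  rows
}

#' Write pipeline outputs as CSV plus a markdown report
#'
#' @param results List from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_pipeline_outputs <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df) && nrow(df)) {
      utils::write.csv(df, file.path(dir, name), row.names = FALSE)
    }
  }
  if (length(results$cells)) {
    wr(do.call(rbind, results$cells), "cells.csv")
  }
  wr(results$summaries, "grid_summaries.csv")
  wr(results$image_table, "images.csv")
  wr(results$filter_manifest, "filter_manifest.csv")
  wr(results$ratios, "pr_rpe_ratios.csv")
  for (mod in names(results$profiles)) {
    wr(results$profiles[[mod]], sprintf("profile_%s.csv", mod))
  }
  for (mod in names(results$summary_tables)) {
    wr(results$summary_tables[[mod]], sprintf("summary_table_%s.csv", mod))
  }
  writeLines(build_report(results), file.path(dir, "report.md"))
  invisible(dir)
}

#' Assemble a markdown analysis report
#'
#' Renders the pipeline outputs as a self-contained markdown document:
#' filter bookkeeping, per-modality stratified summary tables, eccentricity
#' profiles, age trends, and the correlation matrix with significance stars.
#' Sections whose inputs are missing are omitted with a notice. Every number
#' shown is taken from the result tables.
#'
#' @param results List from [run_pipeline()].
#' @return Character vector of markdown lines.
#' @export
build_report <- function(results) {
  fmt_df <- function(df, digits = 2) {
    df2 <- df
    for (k in names(df2)) {
      if (is.numeric(df2[[k]])) df2[[k]] <- round(df2[[k]], digits)
    }
    hdr <- paste0("| ", paste(names(df2), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df2)), collapse = "|"), "|")
    body <- apply(df2, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    c(hdr, sep, body)
  }
  out <- c("# Retinal mosaic morphometry report", "")
  out <- c(out, "## Filtering", "", fmt_df(results$filter_manifest), "")
  if (length(results$summary_tables)) {
    for (mod in names(results$summary_tables)) {
      out <- c(out, sprintf("## %s morphometry (per grid square)", mod), "",
               fmt_df(results$summary_tables[[mod]]), "")
    }
  } else {
    out <- c(out, "## Morphometry", "", "_No retained grid squares._", "")
  }
  if (length(results$profiles)) {
    for (mod in names(results$profiles)) {
      pf <- results$profiles[[mod]]
      pf <- pf[pf$n > 0, c("ecc_mid", "n", "mean_local_density",
                           "sd_local_density")]
      if (nrow(pf)) {
        out <- c(out, sprintf("## %s density vs eccentricity", mod), "",
                 fmt_df(pf), "")
      }
    }
  }
  if (length(results$age_trends)) {
    out <- c(out, "## Age trends (per-eye mean density)", "")
    for (mod in names(results$age_trends)) {
      tr <- results$age_trends[[mod]]
      out <- c(out, sprintf(
        "- %s: slope %.2f cells/mm^2/year (95%% CI %.2f..%.2f), p = %.3g",
        mod, tr$slope, tr$slope_ci[1], tr$slope_ci[2], tr$p))
    }
    out <- c(out, "")
  }
  if (length(results$correlations)) {
    for (mod in names(results$correlations)) {
      cm <- results$correlations[[mod]]
      disp <- matrix(sprintf("%.2f%s", cm$r, ifelse(cm$flag, "*", "")),
                     nrow(cm$r), dimnames = dimnames(cm$r))
      diag(disp) <- "1"
      disp[is.na(cm$r)] <- ""
      df <- data.frame(variable = rownames(disp), disp, check.names = FALSE)
      out <- c(out, sprintf("## %s correlations (* = p < 0.001)", mod), "",
               fmt_df(df), "")
    }
  }
  out
}
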