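# run code with a local, restored RNG state so generators are pure
# functions of (config, seed)
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Synthetic cohort configuration
#'
#' Study-design parameters of the emulated acquisition campaign: cohort size
#' and demographics, per-eye biometry, and the five-zone imaging geometry
#' (fixation-centered plus four 5-degree offsets, 6.7-degree square field).
#'
#' @param n_participants Number of participants.
#' @param age_range Age span in years, default 23-80.
#' @param both_eyes_fraction Fraction of participants imaged in both eyes.
#' @param axial_length_mean,axial_length_sd Axial length distribution (mm).
#' @param zones List of image-center coordinates in degrees (x temporal-
#'   positive, y superior-positive).
#' @param fov_deg Field of view, default 6.7.
#' @param image_size Image side in pixels, default 2048.
#' @param rpe_density_offset_sd,pr_density_offset_sd Between-eye density
#'   random-effect standard deviations (cells/mm^2).
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 10,
                          age_range = c(23, 80),
                          both_eyes_fraction = 0.65,
                          axial_length_mean = 23.6,
                          axial_length_sd = 1.1,
                          zones = list(c(0, 0), c(5, 0), c(-5, 0),
                                       c(0, 5), c(0, -5)),
                          fov_deg = 6.7,
                          image_size = 2048L,
                          rpe_density_offset_sd = 300,
                          pr_density_offset_sd = 500) {
  stopifnot(length(zones) >= 1, fov_deg > 0, n_participants >= 0)
  structure(list(n_participants = n_participants, age_range = age_range,
                 both_eyes_fraction = both_eyes_fraction,
                 axial_length_mean = axial_length_mean,
                 axial_length_sd = axial_length_sd, zones = zones,
                 fov_deg = fov_deg, image_size = as.integer(image_size),
                 rpe_density_offset_sd = rpe_density_offset_sd,
                 pr_density_offset_sd = pr_density_offset_sd),
            class = "cohort_config")
}

#' Synthetic mosaic model configuration
#'
#' Parameters of the rendered cellular scene for one modality. Densities are
#' linear in absolute eccentricity (referenced at the fixation center for RPE
#' and at 2.5 degrees for photoreceptors) and in age; cells sit on a jittered
#' hexagonal lattice whose local spacing follows the hexagonal relation
#' `density = 2 / (sqrt(3) s^2)`. Dark vessel ribbons, out-of-focus patches
#' (whose extent grows linearly with age) and structureless "non-mosaic but
#' visible" patches (likewise age-linked) emulate the main acquisition
#' artifacts.
#'
#' @param modality `"RPE"` or `"PR"`.
#' @param base_density Cells/mm^2 at the reference eccentricity and age.
#' @param ecc_slope Cells/mm^2 per degree of absolute eccentricity.
#' @param ecc_ref Reference eccentricity in degrees.
#' @param age_slope Cells/mm^2 per year.
#' @param age_ref Reference age in years.
#' @param min_density Floor applied to the density field.
#' @param jitter Lattice jitter, uniform within +/- `jitter * spacing` per
#'   coordinate; in `[0, 0.5]`.
#' @param n_vessels Number of vessel ribbons.
#' @param vessel_width_px Vessel half-profile width in pixels.
#' @param vessel_depth Fractional attenuation at the vessel center.
#' @param blur_fraction_base Out-of-focus area fraction at `age_base`.
#' @param blur_fraction_per_year Added fraction per year of age.
#' @param nonmosaic_fraction_base Structureless visible-patch fraction at
#'   `age_base`.
#' @param nonmosaic_fraction_per_year Added fraction per year of age.
#' @param age_base Age at which the artifact fractions take their base value.
#' @param noise_sd Sensor noise standard deviation (intensity units).
#' @return List of class `mosaic_model`.
#' @export
mosaic_model <- function(modality = c("RPE", "PR"),
                         base_density = NULL,
                         ecc_slope = NULL,
                         ecc_ref = NULL,
                         age_slope = NULL,
                         age_ref = 50,
                         min_density = 1500,
                         jitter = 0.15,
                         n_vessels = 2,
                         vessel_width_px = 14,
                         vessel_depth = 0.75,
                         blur_fraction_base = 0.05,
                         blur_fraction_per_year = 0.005,
                         nonmosaic_fraction_base = 0.03,
                         nonmosaic_fraction_per_year = 0.004,
                         age_base = 23,
                         noise_sd = 0.05) {
  modality <- match.arg(modality)
  if (is.null(base_density)) base_density <- if (modality == "RPE") 6313 else 10207
  if (is.null(ecc_slope)) ecc_slope <- if (modality == "RPE") 0 else -600
  if (is.null(ecc_ref)) ecc_ref <- if (modality == "RPE") 0 else 2.5
  if (is.null(age_slope)) age_slope <- if (modality == "RPE") -12 else 0
  stopifnot(jitter >= 0, jitter <= 0.5, base_density > 0)
  structure(list(modality = modality, base_density = base_density,
                 ecc_slope = ecc_slope, ecc_ref = ecc_ref,
                 age_slope = age_slope, age_ref = age_ref,
                 min_density = min_density, jitter = jitter,
                 n_vessels = n_vessels, vessel_width_px = vessel_width_px,
                 vessel_depth = vessel_depth,
                 blur_fraction_base = blur_fraction_base,
                 blur_fraction_per_year = blur_fraction_per_year,
                 nonmosaic_fraction_base = nonmosaic_fraction_base,
                 nonmosaic_fraction_per_year = nonmosaic_fraction_per_year,
                 age_base = age_base, noise_sd = noise_sd),
            class = "mosaic_model")
}

#' Clean-scene variant of a mosaic model
#'
#' Convenience constructor: uniform density (no eccentricity or age effect)
#' and no vessels, blur or non-mosaic patches. Used for parameter-recovery
#' experiments where the generating density must be known exactly.
#'
#' @param modality `"RPE"` or `"PR"`.
#' @param density Uniform density in cells/mm^2.
#' @param ... Further overrides passed to [mosaic_model()].
#' @return A `mosaic_model`.
#' @export
clean_mosaic_model <- function(modality, density, ...) {
  mosaic_model(modality = modality, base_density = density, ecc_slope = 0,
               age_slope = 0, n_vessels = 0, blur_fraction_base = 0,
               blur_fraction_per_year = 0, nonmosaic_fraction_base = 0,
               nonmosaic_fraction_per_year = 0, ...)
}

# density field (cells/mm^2) at signed-eccentricity e for a given age
model_density <- function(model, ecc_deg, age) {
  d <- model$base_density +
    model$ecc_slope * (abs(ecc_deg) - model$ecc_ref) +
    model$age_slope * (age - model$age_ref)
  pmax(d, model$min_density)
}

#' Generate a synthetic cohort: eyes table and image manifest
#'
#' Draws participant demographics and per-eye biometry from the configured
#' distributions, assigns one or both eyes per participant, and lists one
#' image per zone and modality in the manifest. Per-eye axial length and
#' density random effects are drawn once and shared across all of that eye's
#' images. Reproducible: the output is a pure function of (config, seed).
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return List with data.frames `eyes` (eye_id, participant_id, side, age,
#'   gender, axial_length_mm, spherical_equivalent, visual_acuity,
#'   rpe_density_offset, pr_density_offset) and `manifest` (image_id, eye_id,
#'   modality, center_x_deg, center_y_deg, zone).
#' @export
generate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    eyes <- list()
    for (p in seq_len(config$n_participants)) {
      pid <- sprintf("P%03d", p)
      age <- round(stats::runif(1, config$age_range[1], config$age_range[2]), 1)
      gender <- sample(c("female", "male"), 1)
      sides <- if (stats::runif(1) < config$both_eyes_fraction) c("OD", "OS")
               else sample(c("OD", "OS"), 1)
      for (s in sides) {
        al <- min(max(stats::rnorm(1, config$axial_length_mean,
                                   config$axial_length_sd), 21), 27)
        eyes[[length(eyes) + 1]] <- data.frame(
          eye_id = paste0(pid, "_", s), participant_id = pid, side = s,
          age = age, gender = gender, axial_length_mm = round(al, 2),
          spherical_equivalent = round(stats::rnorm(1, 0, 1.5), 2),
          visual_acuity = round(min(max(stats::rnorm(1, 1.0, 0.15), 0.3), 1.6), 2),
          rpe_density_offset = round(stats::rnorm(1, 0, config$rpe_density_offset_sd), 1),
          pr_density_offset = round(stats::rnorm(1, 0, config$pr_density_offset_sd), 1)
        )
      }
    }
    if (!length(eyes)) {
      eyes_df <- data.frame(eye_id = character(0), participant_id = character(0),
                            side = character(0), age = numeric(0),
                            gender = character(0), axial_length_mm = numeric(0),
                            spherical_equivalent = numeric(0),
                            visual_acuity = numeric(0),
                            rpe_density_offset = numeric(0),
                            pr_density_offset = numeric(0))
      manifest <- data.frame(image_id = character(0), eye_id = character(0),
                             modality = character(0), center_x_deg = numeric(0),
                             center_y_deg = numeric(0), zone = integer(0))
      return(list(eyes = eyes_df, manifest = manifest))
    }
    eyes_df <- do.call(rbind, eyes)
    man <- list()
    for (i in seq_len(nrow(eyes_df))) {
      for (z in seq_along(config$zones)) {
        for (mod in c("RPE", "PR")) {
          man[[length(man) + 1]] <- data.frame(
            image_id = sprintf("%s_z%d_%s", eyes_df$eye_id[i], z, mod),
            eye_id = eyes_df$eye_id[i], modality = mod,
            center_x_deg = config$zones[[z]][1],
            center_y_deg = config$zones[[z]][2], zone = z)
        }
      }
    }
    list(eyes = eyes_df, manifest = do.call(rbind, man))
  })
}

# jittered hexagonal centroid field with locally varying spacing.
# spacing_px_fun(x_px) gives the local lattice constant; columns advance
# along x with pitch sqrt(3)/2 * s, points within a column are s apart with
# the usual half-spacing offset on alternate columns. Returns 0-based pixel
# coordinates (possibly outside [0, n); callers crop).
hex_field <- function(n_px, spacing_px_fun, jitter, margin) {
  x <- -margin + stats::runif(1) * spacing_px_fun(-margin)
  kcol <- 0L
  pts_r <- list(); pts_c <- list()
  phase_y <- stats::runif(1)
  while (x < n_px - 1 + margin) {
    s <- spacing_px_fun(x)
    y0 <- -margin + (phase_y + if (kcol %% 2L == 1L) 0.5 else 0) * s
    y <- seq(y0, n_px - 1 + margin, by = s)
    if (length(y)) {
      jx <- stats::runif(length(y), -jitter * s, jitter * s)
      jy <- stats::runif(length(y), -jitter * s, jitter * s)
      pts_r[[length(pts_r) + 1]] <- y + jy
      pts_c[[length(pts_c) + 1]] <- rep(x, length(y)) + jx
    }
    x <- x + sqrt(3) / 2 * s
    kcol <- kcol + 1L
  }
  cbind(row_px = unlist(pts_r), col_px = unlist(pts_c))
}

#' Jittered hexagonal centroid field at constant density
#'
#' Stand-alone generator of a synthetic centroid field covering a square
#' frame, used for topology experiments (e.g. neighbor-count statistics)
#' without rendering an image.
#'
#' @param n_px Frame side in pixels.
#' @param spacing_px Lattice constant in pixels.
#' @param jitter Uniform jitter amplitude as a fraction of spacing.
#' @param seed Integer seed.
#' @return Matrix of 0-based `row_px`, `col_px` positions inside the frame.
#' @export
hex_centroid_field <- function(n_px, spacing_px, jitter = 0.15, seed = 1) {
  with_seed(seed, {
    pts <- hex_field(n_px, function(x) spacing_px, jitter,
                     margin = 2 * spacing_px)
    keep <- pts[, 1] >= 0 & pts[, 1] <= n_px - 1 &
      pts[, 2] >= 0 & pts[, 2] <= n_px - 1
    pts[keep, , drop = FALSE]
  })
}

# place axis-aligned rectangles totalling about `fraction` of the frame;
# returns a logical raster
random_patches <- function(n_px, fraction, side_range = c(0.1, 0.25)) {
  m <- matrix(FALSE, n_px, n_px)
  if (fraction <= 0) return(m)
  target <- fraction * n_px^2
  guard <- 0
  while (sum(m) < target && guard < 100) {
    guard <- guard + 1
    w <- round(stats::runif(1, side_range[1], side_range[2]) * n_px)
    h <- round(stats::runif(1, side_range[1], side_range[2]) * n_px)
    r0 <- sample.int(n_px - h + 1, 1)
    c0 <- sample.int(n_px - w + 1, 1)
    m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- TRUE
  }
  m
}

#' Render a synthetic adaptive-optics mosaic image
#'
#' Produces one acquisition-like scene for an eye and zone: cell centroids on
#' a jittered hexagonal lattice whose local spacing follows the model's
#' density field (evaluated along the horizontal midline of the frame), an
#' intensity image (bright dots on a dark ground for photoreceptors; dim
#' centers on a bright honeycomb ground for RPE), dark vessel ribbons,
#' out-of-focus patches, structureless visible patches, and sensor noise.
#' Out-of-focus patches are blurred after the noise is added, as defocus acts
#' on everything the camera records. Ground-truth masks record every
#' artifact's footprint.
#'
#' @param eye An [eye_meta()].
#' @param center_deg Zone center (x, y) in degrees.
#' @param model A [mosaic_model()].
#' @param seed Integer seed.
#' @param image_size Frame side in pixels, default 2048.
#' @param fov_deg Field of view in degrees, default 6.7.
#' @param density_offset Additive density shift in cells/mm^2 (per-eye random
#'   effect from [generate_cohort()]).
#' @return List with `record` (an [image_record()] carrying the rendered
#'   pixels), `centroids` (data.frame of 0-based `row_px`, `col_px`, and
#'   `visible` = lies in the ground-truth mosaic), `masks` (ground-truth
#'   [mask_set()]), `density_at_center` (model density at the zone center),
#'   and `spacing_px` (lattice constant at the frame center).
#' @export
render_mosaic_image <- function(eye, center_deg, model, seed = 1,
                                image_size = 2048L, fov_deg = 6.7,
                                density_offset = 0) {
  stopifnot(inherits(eye, "eye_meta"), inherits(model, "mosaic_model"))
  n <- as.integer(image_size)
  rec0 <- image_record(eye, model$modality, pixels = NULL,
                       center_deg = center_deg, fov_deg = fov_deg,
                       image_size = n)
  ps <- rec0$pixel_size_um

  dens_at <- function(col_px) {
    deg <- pixel_to_global_degrees(rep((n - 1) / 2, length(col_px)),
                                   pmin(pmax(col_px, 0), n - 1), rec0)
    model_density(model, signed_eccentricity(deg[, 1], deg[, 2]), eye$age) +
      density_offset
  }
  sp_fun <- function(col_px) expected_spacing_px(dens_at(col_px), ps)
  s_mid <- sp_fun((n - 1) / 2)
  if (min(sp_fun(c(0, (n - 1) / 2, n - 1))) < 2) {
    stop("configured density is below pixel resolution (spacing < 2 px)")
  }

  with_seed(seed, {
    margin <- ceiling(3 * s_mid)
    pts <- hex_field(n, sp_fun, model$jitter, margin)

    # splat Gaussian blobs on a padded frame (bilinear sub-pixel placement)
    np <- n + 2 * margin
    delta <- matrix(0, np, np)
    pr <- pts[, 1] + margin; pc <- pts[, 2] + margin
    ok <- pr >= 0 & pr <= np - 2 & pc >= 0 & pc <= np - 2
    pr <- pr[ok]; pc <- pc[ok]
    r0 <- floor(pr); c0 <- floor(pc)
    fr <- pr - r0; fc <- pc - c0
    add <- function(rr, cc, w) {
      idx <- rr + 1 + (cc) * np
      agg <- tapply(w, idx, sum)
      delta[as.integer(names(agg))] <<- delta[as.integer(names(agg))] + agg
    }
    add(r0, c0, (1 - fr) * (1 - fc))
    add(r0 + 1, c0, fr * (1 - fc))
    add(r0, c0 + 1, (1 - fr) * fc)
    add(r0 + 1, c0 + 1, fr * fc)

    sigma_blob <- 0.22 * s_mid
    blob <- gauss_blur_cpp(delta, sigma_blob)
    # normalize so an isolated blob peaks at ~1
    rk <- ceiling(3.5 * sigma_blob)
    k0 <- 1 / sum(exp(-0.5 * ((-rk):rk)^2 / sigma_blob^2))
    blob <- blob / k0^2
    blob <- blob[(margin + 1):(margin + n), (margin + 1):(margin + n)]

    img <- if (model$modality == "PR") {
      0.12 + 0.6 * blob
    } else {
      0.55 - 0.38 * blob
    }

    # vessels: dark smooth ribbons with Gaussian cross-profile
    vessel_gt <- matrix(FALSE, n, n)
    if (model$n_vessels > 0) {
      xs <- 0:(n - 1)
      for (v in seq_len(model$n_vessels)) {
        y0 <- stats::runif(1, 0.1, 0.9) * n
        amp <- stats::runif(1, 0.02, 0.1) * n
        lam <- stats::runif(1, 0.5, 1.5) * n
        phi <- stats::runif(1, 0, 2 * pi)
        yc <- y0 + amp * sin(2 * pi * xs / lam + phi)
        w <- model$vessel_width_px
        for (j in seq_len(n)) {
          dy <- (0:(n - 1)) - yc[j]
          # near-flat dark core with sharp shoulders (super-Gaussian profile)
          att <- 1 - model$vessel_depth * exp(-(dy / w)^4)
          img[, j] <- img[, j] * att
          vessel_gt[abs(dy) <= 1.1 * w, j] <- TRUE
        }
      }
    }

    age_excess <- max(eye$age - model$age_base, 0)
    nonmosaic_frac <- min(model$nonmosaic_fraction_base +
                            model$nonmosaic_fraction_per_year * age_excess, 0.5)
    blur_frac <- min(model$blur_fraction_base +
                       model$blur_fraction_per_year * age_excess, 0.5)

    nonmosaic_gt <- random_patches(n, nonmosaic_frac)
    if (any(nonmosaic_gt)) {
      img[nonmosaic_gt] <- mean(img[nonmosaic_gt]) +
        stats::rnorm(sum(nonmosaic_gt), 0, 0.15)
    }

    img <- img + stats::rnorm(n * n, 0, model$noise_sd)

    blur_gt <- random_patches(n, blur_frac)
    if (any(blur_gt)) {
      blurred <- gauss_blur_cpp(img, 2.5 * s_mid)
      img[blur_gt] <- blurred[blur_gt]
    }
    img <- pmin(pmax(img, 0), 1)

    quality_gt <- !blur_gt
    mosaic_gt <- quality_gt & !vessel_gt & !nonmosaic_gt
    masks <- mask_set(quality_gt, vessel_gt, mosaic_gt)

    keep <- pts[, 1] >= 0 & pts[, 1] <= n - 1 & pts[, 2] >= 0 & pts[, 2] <= n - 1
    cen <- pts[keep, , drop = FALSE]
    vis <- mosaic_gt[cbind(pmin(pmax(round(cen[, 1]), 0), n - 1) + 1,
                           pmin(pmax(round(cen[, 2]), 0), n - 1) + 1)]
    centroids <- data.frame(row_px = cen[, 1], col_px = cen[, 2],
                            visible = vis)

    list(record = image_record(eye, model$modality, pixels = img,
                               center_deg = center_deg, fov_deg = fov_deg),
         centroids = centroids, masks = masks,
         density_at_center = dens_at((n - 1) / 2)[1],
         spacing_px = s_mid)
  })
}

#' Render a whole synthetic cohort
#'
#' Draws a cohort with [generate_cohort()] and renders every manifest entry
#' with [render_mosaic_image()], threading the per-eye density random effect
#' and deriving one sub-seed per image from the master seed. Optionally
#' persists everything to disk (images as 16-bit TIFF, ground-truth masks as
#' PNG, centroids/eyes/manifest as CSV, plus a YAML provenance record of the
#' configuration and seed).
#'
#' @param config A [cohort_config()].
#' @param models Named list with elements `RPE` and `PR`, each a
#'   [mosaic_model()]; defaults to the standard models.
#' @param seed Master seed.
#' @param image_size Frame side in pixels; defaults to the cohort config's.
#' @param output_dir Optional directory to write into.
#' @return List with `eyes`, `manifest`, and `scenes` (named list of
#'   renderer outputs, in manifest order).
#' @export
simulate_cohort <- function(config, models = list(RPE = mosaic_model("RPE"),
                                                  PR = mosaic_model("PR")),
                            seed = 1, image_size = NULL,
                            output_dir = NULL) {
  if (is.null(image_size)) image_size <- config$image_size
  coh <- generate_cohort(config, seed)
  scenes <- list()
  for (i in seq_len(nrow(coh$manifest))) {
    m <- coh$manifest[i, ]
    e <- coh$eyes[coh$eyes$eye_id == m$eye_id, ]
    eye <- eye_meta(e$eye_id, e$side, e$age, e$gender, e$axial_length_mm,
                    e$spherical_equivalent, e$visual_acuity)
    off <- if (m$modality == "RPE") e$rpe_density_offset else e$pr_density_offset
    scenes[[m$image_id]] <- render_mosaic_image(
      eye, c(m$center_x_deg, m$center_y_deg), models[[m$modality]],
      seed = (seed * 1000L + i) %% .Machine$integer.max,
      image_size = image_size, fov_deg = config$fov_deg,
      density_offset = off)
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(coh$eyes, file.path(output_dir, "eyes.csv"),
                     row.names = FALSE)
    man <- coh$manifest
    man$path <- file.path(output_dir, paste0(man$image_id, ".tif"))
    utils::write.csv(man, file.path(output_dir, "manifest.csv"),
                     row.names = FALSE)
    for (id in names(scenes)) {
      sc <- scenes[[id]]
      write_ao_image(sc$record$pixels, file.path(output_dir, paste0(id, ".tif")))
      write_ao_image(sc$masks$mosaic, file.path(output_dir,
                                                paste0(id, "_mosaic_mask.png")))
      utils::write.csv(sc$centroids,
                       file.path(output_dir, paste0(id, "_centroids.csv")),
                       row.names = FALSE)
    }
    prov <- list(seed = seed, image_size = image_size,
                 cohort = unclass(config),
                 models = lapply(models, unclass))
    yaml::write_yaml(prov, file.path(output_dir, "provenance.yaml"))
  }
  list(eyes = coh$eyes, manifest = coh$manifest, scenes = scenes)
}

#' Simulate a five-rater manual-count matrix
#'
#' Emulates independent manual annotation of image patches: each rater's
#' count is the true count minus binomial misses plus Poisson extras.
#'
#' @param true_counts Integer vector of true per-patch counts.
#' @param k Number of raters, at least 2; default 5.
#' @param miss_rate Per-cell probability of a missed detection, in `[0, 1)`.
#' @param extra_rate Expected spurious detections per true cell, in `[0, 1)`.
#' @param seed Integer seed.
#' @return Integer matrix, `length(true_counts)` rows by `k` columns.
#' @export
generate_rater_matrix <- function(true_counts, k = 5, miss_rate = 0.05,
                                  extra_rate = 0.05, seed = 1) {
  if (k < 2) stop("ICC requires at least 2 raters")
  stopifnot(miss_rate >= 0, miss_rate < 1, extra_rate >= 0, extra_rate < 1)
  n <- length(true_counts)
  with_seed(seed, {
    m <- matrix(0L, n, k)
    for (j in seq_len(k)) {
      m[, j] <- as.integer(true_counts -
                             stats::rbinom(n, true_counts, miss_rate) +
                             stats::rpois(n, extra_rate * true_counts))
    }
    colnames(m) <- paste0("rater_", seq_len(k))
    m
  })
}
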