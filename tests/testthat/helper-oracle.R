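# Brute-force Voronoi oracle, written independently of the package's
# engine: each region is built by clipping the bounding rectangle against
# the perpendicular bisector of EVERY other point (no spatial indexing, no
# early termination), tracking which point produced each surviving edge.

oracle_clip_halfplane <- function(poly, src, mx, my, dx, dy, j) {
  f <- (poly[, 1] - mx) * dx + (poly[, 2] - my) * dy
  if (all(f <= 0)) return(list(poly = poly, src = src))
  if (all(f > 0)) return(NULL)
  n <- nrow(poly)
  np <- list(); ns <- integer(0)
  for (k in seq_len(n)) {
    km <- if (k == 1) n else k - 1
    a_in <- f[km] <= 0; b_in <- f[k] <= 0
    if (a_in && b_in) {
      np[[length(np) + 1]] <- poly[k, ]; ns <- c(ns, src[k])
    } else if (a_in && !b_in) {
      t <- f[km] / (f[km] - f[k])
      np[[length(np) + 1]] <- poly[km, ] + t * (poly[k, ] - poly[km, ])
      ns <- c(ns, src[k])
    } else if (!a_in && b_in) {
      t <- f[km] / (f[km] - f[k])
      np[[length(np) + 1]] <- poly[km, ] + t * (poly[k, ] - poly[km, ])
      ns <- c(ns, j)
      np[[length(np) + 1]] <- poly[k, ]; ns <- c(ns, src[k])
    }
  }
  if (length(np) < 3) return(NULL)
  list(poly = do.call(rbind, np), src = ns)
}

oracle_voronoi <- function(x, y, lo, hi) {
  n <- length(x)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    poly <- rbind(c(lo, lo), c(hi, lo), c(hi, hi), c(lo, hi))
    src <- c(-4L, -1L, -2L, -3L)
    for (j in seq_len(n)) {
      if (j == i) next
      out <- oracle_clip_halfplane(poly, src,
                                   (x[i] + x[j]) / 2, (y[i] + y[j]) / 2,
                                   x[j] - x[i], y[j] - y[i], j)
      if (is.null(out)) { poly <- NULL; break }
      poly <- out$poly; src <- out$src
    }
    if (is.null(poly)) { res[[i]] <- NULL; next }
    m <- nrow(poly)
    area <- 0; per <- 0; nbr <- integer(0); touches <- FALSE
    for (k in seq_len(m)) {
      km <- if (k == 1) m else k - 1
      area <- area + poly[km, 1] * poly[k, 2] - poly[k, 1] * poly[km, 2]
      el <- sqrt(sum((poly[k, ] - poly[km, ])^2))
      per <- per + el
      if (el > 1e-9) {
        if (src[k] >= 0) nbr <- c(nbr, src[k]) else touches <- TRUE
      }
    }
    res[[i]] <- list(area = abs(area) / 2, perimeter = per,
                     neighbors = sort(unique(nbr)), touches_rect = touches)
  }
  res
}

# small rendered scenes, cached per test file run
make_clean_scene <- function(modality, density = NULL, size = 512L,
                             seed = 2, center = c(5, 0), age = 40,
                             axial_length = 24, ...) {
  if (is.null(density)) density <- if (modality == "RPE") 6313 else 10207
  eye <- eye_meta("TEST_OD", "OD", age, "female", axial_length)
  render_mosaic_image(eye, center, clean_mosaic_model(modality, density, ...),
                      seed = seed, image_size = size)
}

# mask_set with prescribed mosaic fraction (quality/vessel trivial)
make_fraction_masks <- function(n, mosaic_fraction) {
  q <- matrix(TRUE, n, n)
  v <- matrix(FALSE, n, n)
  m <- matrix(FALSE, n, n)
  k <- round(mosaic_fraction * n * n)
  if (k > 0) m[seq_len(k)] <- TRUE
  mask_set(q, v, m)
}

# synthetic per-cell table for aggregation fixtures: n cells uniformly
# placed inside one grid tile
make_tile_cells <- function(n, tile_i, tile_j, grid_px = 256, seed = 1,
                            area = 150, perimeter = 47, neighbors = 6L) {
  set.seed(seed)
  data.frame(
    row_px = runif(n, tile_i * grid_px, (tile_i + 1) * grid_px - 1e-6),
    col_px = runif(n, tile_j * grid_px, (tile_j + 1) * grid_px - 1e-6),
    area_um2 = rep(area, n), perimeter_um = rep(perimeter, n),
    n_neighbors = rep(neighbors, n), boundary_flag = rep(FALSE, n))
}

# morphological erosion of a logical mask by a square radius
erode_mask <- function(m, r) {
  !(aomosaic:::max_filter_cpp((!m) * 1, as.integer(r)) > 0.5)
}
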