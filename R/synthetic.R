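## Synthetic data with full ground truth: texture tiles (Beer-Lambert
## forward staining), annotated slides, and patient cohorts whose
## class-pair spatial statistics differ by outcome.

#' Texture specification for one histology class
#'
#' @param class_id Histology class id (0-16).
#' @param family One of `"noise"`, `"stripes"`, `"blobs"`, `"checker"`,
#'   `"mixture"`.
#' @param scale Spatial scale in pixels (smoothing sigma / block size).
#' @param orientation Stripe orientation in radians.
#' @param frequency Stripe frequency in cycles/pixel.
#' @param contrast Peak-to-peak amplitude of the hematoxylin pattern
#'   (optical-density units).
#' @param base_h,base_e Baseline hematoxylin / eosin concentrations
#'   (optical-density units, Beer-Lambert forward model).
#' @param noise_sd Per-pixel Gaussian concentration noise.
#' @param seed Integer seed; same spec + seed gives identical tile bytes.
#' @return List of class `texture_spec`.
#' @export
texture_spec <- function(class_id, family = "noise", scale = 4,
                         orientation = 0, frequency = 0.1, contrast = 0.3,
                         base_h = 0.5, base_e = 0.3, noise_sd = 0.02,
                         seed = 1) {
  structure(
    list(class_id = as.integer(class_id), family = family, scale = scale,
         orientation = orientation, frequency = frequency,
         contrast = contrast, base_h = base_h, base_e = base_e,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "texture_spec"
  )
}

#' Default texture specs for the 17 classes
#'
#' Pairwise-distinguishable parameter sets: classes differ in baseline
#' hematoxylin level, pattern family, scale, orientation and contrast.
#' Background is near-white (almost no stain).
#'
#' @param seed Base seed; class k uses `seed * 1000 + k`.
#' @return Named list of 17 `texture_spec`s (names "0".."16").
#' @export
default_texture_specs <- function(seed = 1) {
  fams <- c("stripes", "blobs", "checker", "noise", "mixture")
  specs <- lapply(0:15, function(k) {
    texture_spec(
      class_id = k,
      family = fams[k %% 5 + 1],
      scale = c(3, 6, 10, 16)[k %% 4 + 1],
      orientation = pi * (k %% 4) / 4,
      frequency = c(0.05, 0.1, 0.2)[k %% 3 + 1],
      contrast = 0.25 + 0.05 * (k %% 3),
      base_h = 0.10 + 0.055 * k,
      base_e = 0.45 - 0.02 * k,
      noise_sd = 0.02,
      seed = seed * 1000 + k
    )
  })
  specs[[17]] <- texture_spec(16, family = "noise", scale = 2,
                              contrast = 0.01, base_h = 0.02, base_e = 0.02,
                              noise_sd = 0.005, seed = seed * 1000 + 16)
  names(specs) <- as.character(0:16)
  specs
}

## zero-centered pattern field in roughly [-0.5, 0.5]
texture_field <- function(spec, nr, nc) {
  xs <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  ys <- matrix(seq_len(nr) - 1, nr, nc)
  f <- switch(
    spec$family,
    stripes = 0.5 * sin(2 * pi * spec$frequency *
                          (xs * cos(spec$orientation) +
                             ys * sin(spec$orientation))),
    checker = {
      s <- max(1, round(spec$scale))
      0.5 * (2 * ((floor(xs / s) + floor(ys / s)) %% 2) - 1)
    },
    blobs = {
      z <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                           spec$scale)
      z <- z / max(stats::sd(z), 1e-9)
      clamp(0.25 * z, -0.5, 0.5)
    },
    noise = {
      z <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                           spec$scale / 4)
      z <- z / max(stats::sd(z), 1e-9)
      clamp(0.25 * z, -0.5, 0.5)
    },
    mixture = {
      z <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                           spec$scale)
      z <- z / max(stats::sd(z), 1e-9)
      0.25 * sin(2 * pi * spec$frequency *
                   (xs * cos(spec$orientation) +
                      ys * sin(spec$orientation))) +
        clamp(0.125 * z, -0.25, 0.25)
    },
    stop("unknown texture family: ", spec$family)
  )
  f
}

## Beer-Lambert forward staining: concentrations -> 8-bit RGB in [0,1]
stain_rgb <- function(conc_h, conc_e) {
  s <- he_stain_matrix()
  od <- outer(as.vector(conc_h), s[1, ]) + outer(as.vector(conc_e), s[2, ])
  rgb <- round(clamp(10^(-od), 0, 1) * 255) / 255
  array(rgb, dim = c(dim(conc_h), 3))
}

## planted concentration fields for one spec
concentration_fields <- function(spec, nr, nc) {
  with_seed(spec$seed, {
    field <- texture_field(spec, nr, nc)
    noise_h <- matrix(stats::rnorm(nr * nc, sd = spec$noise_sd), nr, nc)
    noise_e <- matrix(stats::rnorm(nr * nc, sd = spec$noise_sd), nr, nc)
    list(
      h = clamp(spec$base_h + spec$contrast * field + noise_h, 0, 2),
      e = clamp(spec$base_e - 0.5 * spec$contrast * field + noise_e, 0, 2)
    )
  })
}

#' Generate one synthetic tile
#'
#' Synthesizes a stained RGB tile via the Beer-Lambert forward model from
#' planted hematoxylin/eosin concentration fields, so color deconvolution
#' recovers the planted concentrations.
#'
#' @param spec A [texture_spec()].
#' @param size Tile side in pixels (default 224).
#' @return List with `rgb` (size x size x 3, 8-bit quantized), `conc_h`,
#'   `conc_e` (planted concentration fields) and `true_label`.
#' @export
make_tile <- function(spec, size = 224) {
  cf <- concentration_fields(spec, size, size)
  list(rgb = stain_rgb(cf$h, cf$e), conc_h = cf$h, conc_e = cf$e,
       true_label = spec$class_id)
}

## even-odd scanline rasterization: which pixel centers lie inside poly
polygon_mask <- function(poly, nr, nc) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  j <- c(n, seq_len(n - 1))
  mask <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    yc <- r - 0.5
    crosses <- (py > yc) != (py[j] > yc)
    if (!any(crosses)) next
    xi <- px[crosses] + (yc - py[crosses]) /
      (py[j][crosses] - py[crosses]) * (px[j][crosses] - px[crosses])
    xi <- sort(xi)
    for (k in seq(1, length(xi) - 1, by = 2)) {
      c0 <- ceiling(xi[k] + 0.5)
      c1 <- floor(xi[k + 1] + 0.5)
      if (c1 >= c0) mask[r, max(1, c0):min(nc, c1)] <- TRUE
    }
  }
  mask
}

#' Generate a synthetic annotated slide
#'
#' Renders each layout polygon with its class texture on a white canvas,
#' records the planted per-cell label grid (by exact pixel counting of
#' polygon coverage, independent of the package's polygon-clipping path),
#' and optionally writes the image (PNG) and annotations (GeoJSON).
#'
#' @param layout List of `list(polygon = n x 2 matrix, class = id)`;
#'   overlapping polygons of different classes are an error.
#' @param specs Texture specs by class id (default
#'   [default_texture_specs()]).
#' @param canvas `c(height, width)` in pixels.
#' @param min_fraction Coverage threshold for the planted grid.
#' @param tile_size Grid stride (default 224).
#' @param slide_id Slide identifier.
#' @param image_path,annotation_path Optional output paths.
#' @return List with `image`, `regions`, `planted_grid` (integer matrix,
#'   `NA` where no class reaches `min_fraction` coverage) and
#'   `coverage` (per-cell covered-pixel counts of the winning class).
#' @export
make_slide <- function(layout, specs = default_texture_specs(),
                       canvas = c(2048, 2048), min_fraction = 0.9,
                       tile_size = 224, slide_id = "synthetic",
                       image_path = NULL, annotation_path = NULL) {
  nr <- canvas[1]; nc <- canvas[2]
  claim <- matrix(0L, nr, nc)           # 0 = unclaimed, else class id + 1
  image <- array(1, dim = c(nr, nc, 3))
  regions <- list()
  for (i in seq_along(layout)) {
    item <- layout[[i]]
    poly <- as.matrix(item$polygon)
    cls <- as.integer(item$class)
    if (any(poly[, 1] < 0) || any(poly[, 2] < 0) ||
        any(poly[, 1] > nc) || any(poly[, 2] > nr)) {
      stop("layout polygon ", i, " extends beyond the canvas")
    }
    mask <- polygon_mask(poly, nr, nc)
    conflict <- mask & claim != 0L & claim != cls + 1L
    if (any(conflict)) {
      stop("layout polygons of different classes overlap (item ", i, ")")
    }
    claim[mask] <- cls + 1L
    spec <- specs[[as.character(cls)]]
    spec$seed <- spec$seed + i          # distinct fields per region
    cf <- concentration_fields(spec, nr, nc)
    tile_rgb <- stain_rgb(cf$h, cf$e)
    for (ch in 1:3) {
      plane <- image[, , ch]
      plane[mask] <- tile_rgb[, , ch][mask]
      image[, , ch] <- plane
    }
    regions[[i]] <- annotated_region(
      region_id = sprintf("%s_r%d", slide_id, i),
      slide_id = slide_id, contour = poly, label = cls
    )
  }
  ## planted grid from exact pixel counts
  grows <- nr %/% tile_size
  gcols <- nc %/% tile_size
  planted <- matrix(NA_integer_, grows, gcols)
  coverage <- matrix(0L, grows, gcols)
  for (r in seq_len(grows)) {
    for (cc in seq_len(gcols)) {
      block <- claim[((r - 1) * tile_size + 1):(r * tile_size),
                     ((cc - 1) * tile_size + 1):(cc * tile_size)]
      counts <- tabulate(block[block > 0], nbins = 18)
      if (length(counts) == 0 || max(counts) == 0) next
      best <- which.max(counts)
      coverage[r, cc] <- counts[best]
      if (counts[best] >= min_fraction * tile_size^2) {
        planted[r, cc] <- best - 1L
      }
    }
  }
  if (!is.null(image_path)) png::writePNG(image, image_path)
  if (!is.null(annotation_path)) write_annotations(regions, annotation_path)
  list(image = image, regions = regions, planted_grid = planted,
       coverage = coverage, slide_id = slide_id)
}

## planted per-class texture summaries (6 designated summaries per class)
planted_class_textures <- function(ids = 0:16) {
  m <- t(vapply(ids, function(k) {
    c(glcm_contrast = 1 + 0.5 * k,
      glcm_correlation = 0.9 - 0.05 * k,
      glcm_energy = 0.05 + 0.01 * k,
      glcm_homogeneity = 0.8 - 0.03 * k,
      lbp_entropy = 2 + 0.1 * k,
      intensity_mean = 0.1 + 0.05 * k)
  }, numeric(6)))
  rownames(m) <- as.character(ids)
  m
}

#' Generate a synthetic patient cohort with planted spatial signal
#'
#' Each patient gets a histology label grid: every tissue class receives a
#' few small tile clusters.  For each informative class pair (A, B)
#' enriched in one outcome group, B clusters are placed at an
#' outcome-dependent distance from a random A cluster: interacting
#' distances ~ 1.2 + Gamma(2, rate 2) + (1 - effect) * 5 grid cells in the
#' enriched group versus 6.2 + Gamma(2, rate 2) cells otherwise, so at
#' `effect = 1` the pair lies well inside / outside the default 3-cell
#' edge radius, and at `effect = 0` the two groups are identically
#' distributed.  Non-informative classes are placed uniformly in both
#' groups.
#'
#' @param n_pcr,n_rd Group sizes (defaults 51 and 34).
#' @param grid_dim Label-grid dimensions in cells.
#' @param clusters_per_class Clusters planted per class.
#' @param informative_pairs List with elements `pCR` and `RD`, each a
#'   two-element class-id vector (A, B); defaults tumor-tumorTIL for pCR
#'   and microvessel-PGCC for RD.
#' @param effect Interaction effect size in `[0, 1]`.
#' @param tile_size Pixels per grid cell (default 224).
#' @param seed Integer seed.
#' @return List with `patients` (list of `list(patient_id, map, outcome)`),
#'   `outcomes` (data.frame), `class_textures`, `informative_pairs`,
#'   `effect`.
#' @export
make_cohort <- function(n_pcr = 51, n_rd = 34, grid_dim = c(48, 48),
                        clusters_per_class = 3,
                        informative_pairs = list(pCR = c(1L, 10L),
                                                 RD = c(8L, 5L)),
                        effect = 1, tile_size = 224, seed = 1) {
  stopifnot(effect >= 0, effect <= 1)
  outcomes <- c(rep("pCR", n_pcr), rep("RD", n_rd))
  ids <- tissue_class_ids()
  b_classes <- vapply(informative_pairs, `[`, integer(1), 2)
  a_classes <- vapply(informative_pairs, `[`, integer(1), 1)
  patients <- with_seed(seed, lapply(seq_along(outcomes), function(pi) {
    grid <- matrix(NA_integer_, grid_dim[1], grid_dim[2])
    seeds_of <- list()   # class id -> matrix of (row, col) seeds
    place_cluster <- function(grid, r, c, cls) {
      r <- clamp(round(r), 2, grid_dim[1] - 1)
      c <- clamp(round(c), 2, grid_dim[2] - 1)
      if (!is.na(grid[r, c])) return(list(grid = grid, ok = FALSE))
      grid[r, c] <- cls
      ## grow 0-2 adjacent cells
      extra <- sample(0:2, 1)
      if (extra > 0) {
        nbr <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
        pick <- nbr[sample.int(4, extra), , drop = FALSE]
        for (q in seq_len(nrow(pick))) {
          r2 <- r + pick[q, 1]; c2 <- c + pick[q, 2]
          if (is.na(grid[r2, c2])) grid[r2, c2] <- cls
        }
      }
      list(grid = grid, ok = TRUE, seed = c(r, c))
    }
    ## uniformly placed classes first (includes the A member of each pair)
    for (cls in setdiff(ids, b_classes)) {
      seeds <- NULL
      for (k in seq_len(clusters_per_class)) {
        for (attempt in 1:25) {
          res <- place_cluster(grid, stats::runif(1, 2, grid_dim[1] - 1),
                               stats::runif(1, 2, grid_dim[2] - 1), cls)
          if (res$ok) {
            grid <- res$grid
            seeds <- rbind(seeds, res$seed)
            break
          }
        }
      }
      seeds_of[[as.character(cls)]] <- seeds
    }
    ## B members: outcome-dependent proximity to their A anchors
    for (gi in seq_along(informative_pairs)) {
      pair <- informative_pairs[[gi]]
      enriched <- names(informative_pairs)[gi]
      cls <- pair[2]
      anchors <- seeds_of[[as.character(pair[1])]]
      seeds <- NULL
      for (k in seq_len(clusters_per_class)) {
        for (attempt in 1:25) {
          anchor <- anchors[sample.int(nrow(anchors), 1), ]
          d <- if (outcomes[pi] == enriched) {
            1.2 + stats::rgamma(1, shape = 2, rate = 2) + (1 - effect) * 5
          } else {
            6.2 + stats::rgamma(1, shape = 2, rate = 2)
          }
          ang <- stats::runif(1, 0, 2 * pi)
          res <- place_cluster(grid, anchor[1] + d * sin(ang),
                               anchor[2] + d * cos(ang), cls)
          if (res$ok) {
            grid <- res$grid
            seeds <- rbind(seeds, res$seed)
            break
          }
        }
      }
      seeds_of[[as.character(cls)]] <- seeds
    }
    map <- structure(
      list(slide_id = sprintf("P%03d", pi), grid = grid,
           tile_size = tile_size),
      class = "histology_map"
    )
    list(patient_id = sprintf("P%03d", pi), map = map,
         outcome = outcomes[pi])
  }))
  list(
    patients = patients,
    outcomes = data.frame(
      patient_id = vapply(patients, `[[`, character(1), "patient_id"),
      outcome = factor(outcomes, levels = c("pCR", "RD")),
      stringsAsFactors = FALSE
    ),
    class_textures = planted_class_textures(),
    informative_pairs = informative_pairs,
    effect = effect
  )
}

#' Patient x (pair, feature) matrix for a synthetic cohort
#'
#' @param cohort Result of [make_cohort()].
#' @param radius Edge radius in pixels (default 3 grid cells).
#' @return Numeric matrix, one row per patient, 2400 named columns.
#' @export
cohort_pair_features <- function(cohort, radius = 3 * 224) {
  rows <- lapply(cohort$patients, function(p) {
    all_pair_features(p$map, radius = radius,
                      class_textures = cohort$class_textures)
  })
  do.call(rbind, rows)
}

#' Labeled texture-tile feature dataset
#'
#' Generates `n_per_class` synthetic tiles for each of the 17 classes
#' (default specs), runs stain-color normalization and hematoxylin
#' deconvolution, and extracts the 80 raw texture features per tile.
#'
#' @param n_per_class Tiles per class.
#' @param specs Texture specs (default [default_texture_specs()]).
#' @param size Tile side in pixels.
#' @param seed Base seed (per-tile seeds are derived from it).
#' @param normalize Apply [normalize_stain()] before deconvolution.
#' @return List with `x` (tiles x 80 feature matrix) and `y` (integer
#'   class ids).
#' @export
make_texture_dataset <- function(n_per_class = 16,
                                 specs = default_texture_specs(),
                                 size = 224, seed = 1, normalize = TRUE) {
  ids <- as.integer(names(specs))
  n <- length(ids) * n_per_class
  x <- matrix(NA_real_, n, 80)
  y <- integer(n)
  row <- 0L
  for (k in ids) {
    sp <- specs[[as.character(k)]]
    for (i in seq_len(n_per_class)) {
      sp$seed <- specs[[as.character(k)]]$seed + seed + i * 131L
      tile <- make_tile(sp, size = size)
      rgb <- if (normalize) {
        suppressWarnings(normalize_stain(tile$rgb))
      } else tile$rgb
      row <- row + 1L
      x[row, ] <- extract_features(hematoxylin_channel(rgb))
      y[row] <- k
    }
  }
  colnames(x) <- feature_registry()$name
  list(x = x, y = y)
}

#' Planted-signal feature matrix (no imaging)
#'
#' Directly generates a patients x columns matrix in which
#' `n_informative` randomly positioned columns carry a between-group mean
#' shift of `effect` standard deviations; all other columns are pure
#' noise.  Used for feature-selection power studies.
#'
#' @param n_pcr,n_rd Group sizes.
#' @param n_columns Total columns.
#' @param n_informative Number of planted signal columns.
#' @param effect Mean shift in SD units.
#' @param seed Integer seed.
#' @return List with `x`, `y` and `informative` (column indices).
#' @export
make_feature_cohort <- function(n_pcr = 24, n_rd = 16, n_columns = 200,
                                n_informative = 8, effect = 3, seed = 1) {
  n <- n_pcr + n_rd
  with_seed(seed, {
    x <- matrix(stats::rnorm(n * n_columns), n, n_columns)
    informative <- sort(sample.int(n_columns, n_informative))
    x[seq_len(n_pcr), informative] <- x[seq_len(n_pcr), informative] + effect
    colnames(x) <- sprintf("col%04d", seq_len(n_columns))
    list(
      x = x,
      y = factor(c(rep("pCR", n_pcr), rep("RD", n_rd)),
                 levels = c("pCR", "RD")),
      informative = informative
    )
  })
}
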