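## Stain chemistry -----------------------------------------------------------

#' Standard H&E stain vectors (Ruifrok-Johnston)
#'
#' Rows are unit optical-density vectors for hematoxylin and eosin in RGB.
#'
#' @return A 2 x 3 numeric matrix with rownames `hematoxylin`, `eosin`.
#' @export
he_stain_matrix <- function() {
  m <- rbind(
    hematoxylin = c(0.650, 0.704, 0.286),
    eosin       = c(0.072, 0.990, 0.105)
  )
  m / sqrt(rowSums(m^2))
}

#' Default stain-normalization reference
#'
#' Target stain matrix and target 99th-percentile stain concentrations used
#' by [normalize_stain()].
#'
#' @return List with elements `stain_matrix` (2 x 3) and `max_conc`
#'   (length-2, hematoxylin then eosin, optical-density units).
#' @export
stain_reference <- function() {
  list(stain_matrix = he_stain_matrix(), max_conc = c(1.9705, 1.0308))
}

## RGB [0,1] -> optical density (base-10); OD of pure white is 0
rgb_to_od <- function(rgb) -log10(clamp(rgb, 1 / 255, 1))

od_to_rgb <- function(od) clamp(10^(-od), 0, 1)

## flatten HxWx3 array to N x 3 matrix of pixels
flatten_rgb <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  matrix(rgb, ncol = 3)
}

#' Hematoxylin channel by color deconvolution
#'
#' Unmixes the RGB optical-density image into hematoxylin and eosin
#' concentrations with the standard H&E stain vectors (least-squares
#' pseudo-inverse) and returns the hematoxylin concentration rescaled to
#' `[0, 1]` (clipped at `max_od`).  White pixels map to ~0.
#'
#' @param rgb H x W x 3 array with values in `[0, 1]`.
#' @param max_od Concentration mapped to 1.0 (optical-density units,
#'   default 1).
#' @param stains Stain matrix, see [he_stain_matrix()].
#' @return H x W matrix in `[0, 1]`.
#' @export
hematoxylin_channel <- function(rgb, max_od = 1, stains = he_stain_matrix()) {
  od <- rgb_to_od(rgb)
  odm <- flatten_rgb(od)
  ## least-squares concentrations: C = OD %*% pinv(S)
  pinv <- t(stains) %*% solve(stains %*% t(stains))
  conc_h <- odm %*% pinv[, 1]
  matrix(clamp(conc_h / max_od, 0, 1), nrow = dim(rgb)[1])
}

## Macenko stain-vector estimation on one image.
## Returns NULL when too few tissue pixels are present.
estimate_stains <- function(rgb, beta = 0.15, alpha = 1) {
  odm <- flatten_rgb(rgb_to_od(rgb))
  tissue <- odm[rowMeans(odm) > beta, , drop = FALSE]
  if (nrow(tissue) < 20) return(NULL)
  ev <- eigen(crossprod(tissue) / nrow(tissue), symmetric = TRUE)
  basis <- ev$vectors[, 1:2]               # plane of the two stains
  if (sum(basis[, 1]) < 0) basis[, 1] <- -basis[, 1]
  proj <- tissue %*% basis
  phi <- atan2(proj[, 2], proj[, 1])
  q <- stats::quantile(phi, c(alpha, 100 - alpha) / 100, names = FALSE)
  v1 <- basis %*% c(cos(q[1]), sin(q[1]))
  v2 <- basis %*% c(cos(q[2]), sin(q[2]))
  if (sum(v1) < 0) v1 <- -v1
  if (sum(v2) < 0) v2 <- -v2
  ## hematoxylin absorbs more red light than eosin does
  s <- if (v1[1] >= v2[1]) rbind(c(v1), c(v2)) else rbind(c(v2), c(v1))
  rownames(s) <- c("hematoxylin", "eosin")
  s / sqrt(rowSums(s^2))
}

#' Stain color normalization (Macenko)
#'
#' Estimates the image's own hematoxylin/eosin vectors from the singular
#' plane of tissue optical densities (pixels above a `beta = 0.15` OD
#' threshold; robust angle extremes at the 1st/99th percentile), solves for
#' per-pixel concentrations, rescales their 99th percentiles to the
#' reference concentrations, and reconstructs the image with the reference
#' stain matrix.  Near-white pixels stay near-white because their optical
#' density (hence concentration) is ~0.
#'
#' @param rgb H x W x 3 array in `[0, 1]` (8-bit semantics; the output is
#'   re-quantized to 8 bits).
#' @param reference See [stain_reference()].
#' @param beta Optical-density threshold below which a pixel is treated as
#'   background.
#' @return H x W x 3 array in `[0, 1]`.  If the tile contains essentially
#'   no tissue it is returned unchanged with attribute `white_tile = TRUE`
#'   and a warning.
#' @export
normalize_stain <- function(rgb, reference = stain_reference(), beta = 0.15) {
  stains <- estimate_stains(rgb, beta = beta)
  if (is.null(stains)) {
    warning("tile contains no tissue (all near-white); returned unchanged")
    attr(rgb, "white_tile") <- TRUE
    return(rgb)
  }
  odm <- flatten_rgb(rgb_to_od(rgb))
  conc <- odm %*% t(stains) %*% solve(stains %*% t(stains))  # N x 2
  conc[conc < 0] <- 0
  p99 <- apply(conc, 2, stats::quantile, probs = 0.99, names = FALSE)
  p99[p99 <= 0] <- 1
  conc <- sweep(conc, 2, reference$max_conc / p99, `*`)
  out_od <- conc %*% reference$stain_matrix
  out <- od_to_rgb(out_od)
  out <- round(out * 255) / 255                  # 8-bit clamp
  array(out, dim = dim(rgb))
}

## Tiling --------------------------------------------------------------------

#' Partition annotated regions into labeled tiles
#'
#' Tiles are taken from the fixed stride-`size` grid anchored at the slide
#' origin, restricted to each region's bounding box.  A tile is retained
#' when the region covers at least `min_fraction` of it
#' ([region_contains_tile()]); the retained tile carries that region's
#' class label.  A tile claimed by two regions of different classes is an
#' error (ambiguous ground truth).
#'
#' @param image H x W x 3 array in `[0, 1]`, or `NULL` to produce tiles
#'   without pixel data (coordinates and labels only).
#' @param regions List of [annotated_region()] objects.
#' @param min_fraction Coverage threshold (default 0.9).
#' @param size Tile side (default 224).
#' @param slide_id Slide identifier for tile ids.
#' @return List of tiles; each tile is a list with `tile_id`, `slide_id`,
#'   `origin` (x, y), `grid_pos` (row, col, 0-based), `true_label`, and
#'   `rgb` (NULL when `image` is NULL).  Per-class retained counts are
#'   reported via `message()`.
#' @export
tile_slide <- function(image, regions, min_fraction = 0.9, size = 224,
                       slide_id = NULL) {
  if (!is.null(image)) {
    if (dim(image)[1] < size || dim(image)[2] < size) {
      stop("image smaller than one ", size, "x", size, " tile")
    }
  }
  if (is.null(slide_id)) {
    slide_id <- if (length(regions) > 0) regions[[1]]$slide_id else "slide"
  }
  claimed <- new.env(parent = emptyenv())   # "r_c" -> list(label, region_id)
  tiles <- list()
  empty_regions <- character(0)
  for (reg in regions) {
    xs <- range(reg$contour[, 1]); ys <- range(reg$contour[, 2])
    col0 <- floor(xs[1] / size); col1 <- floor((xs[2] - 1e-9) / size)
    row0 <- floor(ys[1] / size); row1 <- floor((ys[2] - 1e-9) / size)
    n_before <- length(tiles)
    for (r in row0:row1) {
      for (cc in col0:col1) {
        x <- cc * size; y <- r * size
        if (!is.null(image) &&
            (y + size > dim(image)[1] || x + size > dim(image)[2])) next
        if (!region_contains_tile(reg, c(x, y), min_fraction, size)) next
        key <- sprintf("%d_%d", r, cc)
        prev <- claimed[[key]]
        if (!is.null(prev)) {
          if (prev$label != reg$label) {
            stop(sprintf(
              "ambiguous tile at grid (%d, %d): claimed by region '%s' (%s) and region '%s' (%s)",
              r, cc, prev$region_id, class_name_from_id(prev$label),
              reg$region_id, class_name_from_id(reg$label)))
          }
          next  # same class from two regions: keep first
        }
        claimed[[key]] <- list(label = reg$label, region_id = reg$region_id)
        px <- if (is.null(image)) NULL else
          image[(y + 1):(y + size), (x + 1):(x + size), , drop = FALSE]
        tiles[[length(tiles) + 1]] <- list(
          tile_id = sprintf("%s_t%d_%d", slide_id, r, cc),
          slide_id = slide_id,
          origin = c(x = x, y = y),
          grid_pos = c(row = r, col = cc),
          true_label = reg$label,
          rgb = px
        )
      }
    }
    if (length(tiles) == n_before) empty_regions <- c(empty_regions, reg$region_id)
  }
  if (length(empty_regions) > 0) {
    warning("region(s) yielded no retained tiles: ",
            paste(empty_regions, collapse = ", "))
  }
  labs <- vapply(tiles, function(t) t$true_label, integer(1))
  if (length(labs) > 0) {
    counts <- table(class_name_from_id(sort(unique(labs)))[
      match(labs, sort(unique(labs)))])
    message(sprintf("retained %d tiles (%s)", length(tiles),
                    paste(names(counts), counts, sep = "=", collapse = ", ")))
  } else {
    message("retained 0 tiles")
  }
  tiles
}

#' Tile manifest
#'
#' @param tiles List of tiles from [tile_slide()].
#' @return data.frame with columns `tile_id`, `slide_id`, `x`, `y`,
#'   `row`, `col`, `label`.
#' @export
tile_manifest <- function(tiles) {
  data.frame(
    tile_id = vapply(tiles, `[[`, character(1), "tile_id"),
    slide_id = vapply(tiles, `[[`, character(1), "slide_id"),
    x = vapply(tiles, function(t) t$origin[["x"]], numeric(1)),
    y = vapply(tiles, function(t) t$origin[["y"]], numeric(1)),
    row = vapply(tiles, function(t) t$grid_pos[["row"]], numeric(1)),
    col = vapply(tiles, function(t) t$grid_pos[["col"]], numeric(1)),
    label = vapply(tiles, function(t) as.integer(t$true_label), integer(1)),
    stringsAsFactors = FALSE
  )
}
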