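#' Assemble a spatial histology classification map
#'
#' Places per-tile class labels on the stride-`tile_size` grid.  Cell
#' (r, c) of the grid (1-based) corresponds to the tile with origin
#' ((c-1) * tile_size, (r-1) * tile_size) in level-0 pixels.  Cells with
#' no tile hold `NA` (the empty sentinel).
#'
#' @param manifest data.frame with columns `tile_id`, `x`, `y` (tile
#'   origins on the stride grid) and `label` (class id), e.g. from
#'   [tile_manifest()] with predicted labels substituted.
#' @param slide_id Slide identifier (default: taken from the manifest).
#' @param tile_size Grid stride in pixels (default 224).
#' @return Object of class `histology_map`: list with `slide_id`, `grid`
#'   (integer matrix, `NA` = empty) and `tile_size`.
#' @export
assemble_map <- function(manifest, slide_id = NULL, tile_size = 224) {
  stopifnot(all(c("x", "y", "label") %in% names(manifest)))
  if (nrow(manifest) == 0) stop("empty manifest")
  if (any(manifest$x %% tile_size != 0 | manifest$y %% tile_size != 0)) {
    stop("tile origins must lie on the stride-", tile_size, " grid")
  }
  if (is.null(slide_id)) {
    slide_id <- if ("slide_id" %in% names(manifest)) manifest$slide_id[1]
    else "slide"
  }
  rows <- manifest$y / tile_size + 1
  cols <- manifest$x / tile_size + 1
  key <- paste(rows, cols)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    ids <- manifest$tile_id[key == dup]
    stop("two tiles map to one grid cell: ", paste(ids, collapse = ", "))
  }
  grid <- matrix(NA_integer_, max(rows), max(cols))
  grid[cbind(rows, cols)] <- as.integer(manifest$label)
  structure(list(slide_id = slide_id, grid = grid, tile_size = tile_size),
            class = "histology_map")
}

#' @export
print.histology_map <- function(x, ...) {
  cat(sprintf("<histology_map> slide %s: %d x %d grid, %d occupied cells\n",
              x$slide_id, nrow(x$grid), ncol(x$grid), sum(!is.na(x$grid))))
  invisible(x)
}

#' Render a histology map as an RGB raster
#'
#' One `block` x `block` pixel block per grid cell, colored by the class
#' palette; empty cells render white.  Rendering is deterministic and,
#' because the palette is a bijection, invertible via [decode_map()].
#'
#' @param map A `histology_map`.
#' @param palette Class palette, see [default_palette()].
#' @param block Pixels per cell side (default 1).
#' @return H x W x 3 array in `[0, 1]`.
#' @export
render_map <- function(map, palette = default_palette(), block = 1) {
  present <- unique(stats::na.omit(as.vector(map$grid)))
  missing <- setdiff(as.character(present), rownames(palette))
  if (length(missing) > 0) {
    stop("palette has no entry for class id(s): ",
         paste(missing, collapse = ", "))
  }
  nr <- nrow(map$grid); nc <- ncol(map$grid)
  out <- array(1, dim = c(nr, nc, 3))       # empty sentinel: white
  idx <- which(!is.na(map$grid), arr.ind = TRUE)
  if (nrow(idx) > 0) {
    cols <- palette[as.character(map$grid[idx]), , drop = FALSE]
    for (ch in 1:3) out[cbind(idx, ch)] <- cols[, ch]
  }
  if (block > 1) {
    big <- array(0, dim = c(nr * block, nc * block, 3))
    for (ch in 1:3) {
      big[, , ch] <- out[rep(seq_len(nr), each = block),
                         rep(seq_len(nc), each = block), ch]
    }
    out <- big
  }
  out
}

#' Decode a rendered map back to class ids
#'
#' @param raster H x W x 3 array produced by [render_map()] with
#'   `block = 1`.
#' @param palette The palette used for rendering.
#' @return Integer matrix of class ids (`NA` where the pixel matches no
#'   palette entry, i.e. empty cells rendered white when white is not a
#'   class color; the background class itself decodes to its id).
#' @export
decode_map <- function(raster, palette = default_palette()) {
  nr <- dim(raster)[1]; nc <- dim(raster)[2]
  px <- matrix(raster, ncol = 3)
  key <- apply(round(palette * 255), 1, paste, collapse = "_")
  pxkey <- paste(round(px[, 1] * 255), round(px[, 2] * 255),
                 round(px[, 3] * 255), sep = "_")
  ids <- as.integer(names(key))[match(pxkey, key)]
  matrix(ids, nr, nc)
}
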