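#' Create an annotated region
#'
#' A labeled polygon contour on a slide: the ground-truth unit of
#' pathologist annotation.  Coordinates are 0-based level-0 pixels,
#' x to the right, y down.
#'
#' @param region_id Character identifier.
#' @param slide_id Character slide identifier.
#' @param contour Numeric n x 2 matrix of (x, y) vertices (closed polygon,
#'   final vertex need not repeat the first); at least 3 vertices and
#'   non-zero area.
#' @param label Histology class name or integer id.
#' @param holes Optional list of n x 2 matrices: interior rings subtracted
#'   from the region.
#' @return An object of class `annotated_region`.
#' @export
annotated_region <- function(region_id, slide_id, contour, label,
                             holes = list()) {
  contour <- as.matrix(contour)
  if (nrow(contour) >= 2 &&
      all(contour[1, ] == contour[nrow(contour), ])) {
    contour <- contour[-nrow(contour), , drop = FALSE]
  }
  if (nrow(contour) < 3) {
    stop("region '", region_id, "': polygon has fewer than 3 vertices")
  }
  if (abs(ring_area_signed(contour[, 1], contour[, 2])) <= 0) {
    stop("region '", region_id, "': polygon has zero area")
  }
  if (any(contour < 0)) {
    stop("region '", region_id, "': negative pixel coordinates")
  }
  label_id <- if (is.numeric(label)) {
    class_name_from_id(label)  # validates
    as.integer(label)
  } else {
    class_id_from_name(label)
  }
  structure(
    list(
      region_id = as.character(region_id),
      slide_id = as.character(slide_id),
      contour = contour,
      holes = lapply(holes, as.matrix),
      label = label_id,
      label_name = class_name_from_id(label_id)
    ),
    class = "annotated_region"
  )
}

#' Read polygonal histology annotations from a GeoJSON file
#'
#' Expects a FeatureCollection in the dialect QuPath exports: each feature
#' has Polygon geometry (first ring the boundary, further rings holes) and
#' `properties$classification$name` naming the histology class.
#'
#' @param path Path to a GeoJSON file.
#' @param slide_id Slide identifier attached to every region; defaults to
#'   the file name without extension.
#' @return A list of [annotated_region()] objects, one per feature.
#' @export
read_annotations <- function(path, slide_id = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON in ", path, ": ",
                             conditionMessage(e))
  )
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection, got type: ",
         gj$type %||% "<missing>")
  }
  if (is.null(slide_id)) {
    slide_id <- sub("\\.[^.]*$", "", basename(path))
  }
  feats <- gj$features
  lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    geom <- f$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon")) {
      stop("feature ", i, ": only Polygon geometry is supported, got ",
           geom$type %||% "<missing>")
    }
    rings <- lapply(geom$coordinates, function(ring) {
      do.call(rbind, lapply(ring, function(pt) as.numeric(pt[1:2])))
    })
    name <- f$properties$classification$name
    if (is.null(name)) name <- f$properties$classification
    if (is.null(name) || !is.character(name)) {
      stop("feature ", i, ": missing properties$classification$name")
    }
    rid <- f$id %||% f$properties$name %||% sprintf("%s_region_%d", slide_id, i)
    annotated_region(
      region_id = rid, slide_id = slide_id,
      contour = rings[[1]], label = name,
      holes = if (length(rings) > 1) rings[-1] else list()
    )
  })
}

#' Write annotations as QuPath-style GeoJSON
#'
#' Inverse of [read_annotations()]: the round trip is lossless for
#' coordinates well below 1e-6 px.
#'
#' @param regions List of [annotated_region()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(regions, path) {
  close_ring <- function(m) {
    lapply(seq_len(nrow(m) + 1), function(i) {
      j <- if (i > nrow(m)) 1L else i
      c(m[j, 1], m[j, 2])
    })
  }
  feats <- lapply(regions, function(r) {
    rings <- c(list(close_ring(r$contour)), lapply(r$holes, close_ring))
    list(
      type = "Feature",
      id = r$region_id,
      geometry = list(type = "Polygon", coordinates = rings),
      properties = list(classification = list(name = r$label_name))
    )
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## rings of a region as polyclip polygon lists
region_rings <- function(region) {
  list(
    outer = list(x = region$contour[, 1], y = region$contour[, 2]),
    holes = lapply(region$holes, function(h) list(x = h[, 1], y = h[, 2]))
  )
}

## area of region \cap axis-aligned rectangle [x0,x1) x [y0,y1);
## hole areas are subtracted
region_rect_intersection_area <- function(region, x0, y0, x1, y1) {
  rect <- list(list(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1)))
  rr <- region_rings(region)
  a <- polyset_area(polyclip::polyclip(list(rr$outer), rect, "intersection"))
  for (h in rr$holes) {
    a <- a - polyset_area(polyclip::polyclip(list(h), rect, "intersection"))
  }
  max(a, 0)
}

#' Does a region cover at least a given fraction of a tile?
#'
#' The tile is the half-open box `[x, x + size) x [y, y + size)`.  Returns
#' `TRUE` iff area(polygon intersect box) / area(box) >= `min_fraction`
#' (inclusive at equality, matching a "at least 90%" retention rule).
#' Hole areas are subtracted from the covered area.
#'
#' @param region An [annotated_region()].
#' @param tile_box Numeric `c(x, y)` tile origin in level-0 pixels, or
#'   `c(x, y, size)`.
#' @param min_fraction Required coverage fraction in `[0, 1]`.
#' @param size Tile side length in pixels (default 224).
#' @return Logical scalar.
#' @export
region_contains_tile <- function(region, tile_box, min_fraction = 0.9,
                                 size = 224) {
  stopifnot(inherits(region, "annotated_region"),
            min_fraction >= 0, min_fraction <= 1)
  if (length(tile_box) >= 3) size <- tile_box[3]
  x <- tile_box[1]; y <- tile_box[2]
  a <- region_rect_intersection_area(region, x, y, x + size, y + size)
  frac <- a / (size * size)
  ## tolerate clipping round-off at exact equality
  frac >= min_fraction - 1e-9
}

#' Read a patient outcome table
#'
#' @param path CSV file with header `patient_id,outcome`; outcome values
#'   must be `pCR` or `RD`.
#' @param cohort Cohort tag, `"development"` or `"validation"`.
#' @return A data.frame with columns `patient_id`, `outcome` (factor with
#'   levels pCR, RD) and attribute `cohort`; per-outcome counts are
#'   reported via `message()`.
#' @export
read_outcomes <- function(path, cohort = c("development", "validation")) {
  cohort <- match.arg(cohort)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "outcome") %in% names(tab))) {
    stop("outcome CSV must have header patient_id,outcome")
  }
  tab$patient_id <- as.character(tab$patient_id)
  if (anyDuplicated(tab$patient_id)) {
    stop("duplicate patient_id(s): ",
         paste(unique(tab$patient_id[duplicated(tab$patient_id)]),
               collapse = ", "))
  }
  bad <- setdiff(unique(tab$outcome), c("pCR", "RD"))
  if (length(bad) > 0) {
    stop("outcome values outside {pCR, RD}: ", paste(bad, collapse = ", "))
  }
  tab$outcome <- factor(tab$outcome, levels = c("pCR", "RD"))
  message(sprintf("%s cohort: %d patients (%d pCR, %d RD)", cohort,
                  nrow(tab), sum(tab$outcome == "pCR"),
                  sum(tab$outcome == "RD")))
  attr(tab, "cohort") <- cohort
  tab
}

#' Write a patient outcome table
#' @param outcomes data.frame with `patient_id` and `outcome`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  utils::write.csv(outcomes[, c("patient_id", "outcome")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
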