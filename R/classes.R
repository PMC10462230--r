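#' Histology class registry
#'
#' The 16 annotated tissue classes plus background, with the integer coding
#' used throughout the package (0 = stroma ... 15 = mucinous change,
#' 16 = background) and a display color per class.  The id/color map is a
#' bijection so rendered maps can be decoded losslessly.
#'
#' @return A data.frame with columns `id` (integer 0-16), `name` (character)
#'   and `color` (hex string).
#' @export
#' @examples
#' histology_classes()
histology_classes <- function() {
  data.frame(
    id = 0:16,
    name = c(
      "stroma", "tumor", "tertiaryTIL", "stromaTIL", "normal tissue",
      "PGCC", "blood vessels", "necrosis", "microvessel", "benign tumor",
      "tumorTIL", "in situ carcinoma", "hemorrhage", "adipocytes",
      "apocrine change", "mucinous change", "background"
    ),
    color = c(
      "#2ca02c", "#d62728", "#9467bd", "#8c564b", "#e377c2",
      "#ff7f0e", "#1f77b4", "#7f7f7f", "#bcbd22", "#17becf",
      "#aec7e8", "#ffbb78", "#98df8a", "#ff9896", "#c5b0d5",
      "#c49c94", "#e6e6e6"
    ),
    stringsAsFactors = FALSE
  )
}

#' Default rendering palette
#'
#' @return A 17 x 3 numeric matrix of RGB values in `[0, 1]`, one row per
#'   class id (rownames "0".."16").  Rows are pairwise distinct.
#' @export
default_palette <- function() {
  cls <- histology_classes()
  pal <- t(grDevices::col2rgb(cls$color)) / 255
  rownames(pal) <- as.character(cls$id)
  colnames(pal) <- c("r", "g", "b")
  pal
}

#' Tissue class ids (background excluded)
#' @return Integer vector 0:15.
#' @export
tissue_class_ids <- function() 0:15

#' Background class id
#' @return Integer 16.
#' @export
background_class_id <- function() 16L

## map class name -> id, with validation
class_id_from_name <- function(name) {
  cls <- histology_classes()
  idx <- match(name, cls$name)
  if (anyNA(idx)) {
    bad <- unique(name[is.na(idx)])
    stop(
      "unknown histology class name(s): ", paste(bad, collapse = ", "),
      "; valid names are: ", paste(cls$name, collapse = ", ")
    )
  }
  cls$id[idx]
}

class_name_from_id <- function(id) {
  cls <- histology_classes()
  idx <- match(id, cls$id)
  if (anyNA(idx)) stop("unknown histology class id(s): ",
                       paste(unique(id[is.na(idx)]), collapse = ", "))
  cls$name[idx]
}
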