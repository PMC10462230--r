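#' Connected tile clusters of one histology class
#'
#' Clusters are the connected components (8-adjacency, so diagonal
#' contact connects) of same-class cells in a histology map.  The cluster
#' centroid is the arithmetic mean of member tile centers in level-0
#' pixels.
#'
#' @param map A `histology_map`.
#' @param cls Class id.
#' @return List of clusters; each is a list with `cluster_id`, `class`,
#'   `cells` (n x 2 matrix of (row, col), 1-based), `centroid` (x, y
#'   pixels).  Empty list when the class is absent.
#' @export
find_clusters <- function(map, cls) {
  grid <- map$grid
  ts <- map$tile_size
  mask <- !is.na(grid) & grid == cls
  if (!any(mask)) return(list())
  nr <- nrow(grid); nc <- ncol(grid)
  comp <- matrix(0L, nr, nc)
  nb <- expand.grid(dr = -1:1, dc = -1:1)
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  next_id <- 0L
  cells_of <- list()
  for (start in which(mask & comp == 0L)) {
    if (comp[start] != 0L) next
    next_id <- next_id + 1L
    stack <- start
    comp[start] <- next_id
    members <- integer(0)
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, cur)
      r <- ((cur - 1L) %% nr) + 1L
      cc <- ((cur - 1L) %/% nr) + 1L
      for (j in seq_len(nrow(nb))) {
        r2 <- r + nb$dr[j]; c2 <- cc + nb$dc[j]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        lin <- (c2 - 1L) * nr + r2
        if (mask[lin] && comp[lin] == 0L) {
          comp[lin] <- next_id
          stack <- c(stack, lin)
        }
      }
    }
    cells_of[[next_id]] <- members
  }
  lapply(seq_len(next_id), function(i) {
    lin <- cells_of[[i]]
    r <- ((lin - 1L) %% nr) + 1L
    cc <- ((lin - 1L) %/% nr) + 1L
    list(
      cluster_id = sprintf("%s_c%d_k%d", map$slide_id, cls, i),
      class = cls,
      cells = cbind(row = r, col = cc),
      centroid = c(x = mean((cc - 1) * ts + ts / 2),
                   y = mean((r - 1) * ts + ts / 2))
    )
  })
}

#' Attach mean texture vectors to clusters
#'
#' Averages tile-level texture features over each cluster's member tiles.
#'
#' @param clusters From [find_clusters()].
#' @param features Tiles x features matrix.
#' @param manifest data.frame with `row`, `col` (0-based grid positions)
#'   aligned with the rows of `features`.
#' @return `clusters` with a `mean_texture` element added to each.
#' @export
attach_textures <- function(clusters, features, manifest) {
  key <- paste(manifest$row + 1, manifest$col + 1)
  lapply(clusters, function(cl) {
    idx <- match(paste(cl$cells[, "row"], cl$cells[, "col"]), key)
    idx <- idx[!is.na(idx)]
    cl$mean_texture <- if (length(idx) > 0) {
      colMeans(features[idx, , drop = FALSE])
    } else NULL
    cl
  })
}

#' Build the TME graph for one unordered class pair
#'
#' Nodes are the tile clusters of the two classes; an (undirected,
#' unweighted, simple) edge joins two nodes whose centroids lie within
#' `radius` pixels (random geometric construct).
#'
#' @param clusters_a,clusters_b Cluster lists from [find_clusters()].
#' @param radius Edge radius in pixels (default 672 = 3 tile widths).
#' @return Object of class `tme_graph`: list with `nodes` (data.frame:
#'   `class`, `x`, `y`), `edges` (m x 2 integer matrix, i < j),
#'   `textures` (list of per-node mean-texture vectors or NULL), and
#'   `radius`.
#' @export
build_pair_graph <- function(clusters_a, clusters_b, radius = 672) {
  stopifnot(radius > 0)
  all_cl <- c(clusters_a, clusters_b)
  n <- length(all_cl)
  nodes <- data.frame(
    class = vapply(all_cl, function(cl) as.integer(cl$class), integer(1L)),
    x = vapply(all_cl, function(cl) cl$centroid[["x"]], numeric(1)),
    y = vapply(all_cl, function(cl) cl$centroid[["y"]], numeric(1))
  )
  edges <- matrix(integer(0), ncol = 2)
  if (n >= 2) {
    d <- as.matrix(stats::dist(nodes[, c("x", "y")]))
    adj <- which(upper.tri(d) & d <= radius, arr.ind = TRUE)
    if (nrow(adj) > 0) edges <- unname(adj[, c(1, 2), drop = FALSE])
  }
  structure(
    list(nodes = nodes, edges = edges,
         textures = lapply(all_cl, function(cl) cl$mean_texture),
         radius = radius),
    class = "tme_graph"
  )
}

#' Names and construct tags of the 20 graph features
#'
#' @return data.frame with columns `name` and `construct`
#'   (`texture_average`, `local_node`, `global_connectivity`).
#' @export
graph_feature_names <- function() {
  data.frame(
    name = c(
      "ta_glcm_contrast", "ta_glcm_correlation", "ta_glcm_energy",
      "ta_glcm_homogeneity", "ta_lbp_entropy", "ta_intensity_mean",
      "ln_node_count", "ln_edge_count", "ln_mean_degree",
      "ln_degree_variance", "ln_clustering_coeff", "ln_cross_edge_fraction",
      "ln_algebraic_connectivity",
      "gc_component_count", "gc_largest_component_fraction",
      "gc_mst_total_length", "gc_mst_mean_edge", "gc_mst_edge_variance",
      "gc_mst_diameter", "gc_mean_nn_distance"
    ),
    construct = c(rep("texture_average", 6), rep("local_node", 7),
                  rep("global_connectivity", 7)),
    stringsAsFactors = FALSE
  )
}

## six designated texture summaries from a full tile-feature vector
texture_summary <- function(v) {
  lbp <- v[grep("^lbp_", names(v))]
  c(
    glcm_contrast = unname(v["glcm_contrast"]),
    glcm_correlation = unname(v["glcm_correlation"]),
    glcm_energy = unname(v["glcm_energy"]),
    glcm_homogeneity = unname(v["glcm_homogeneity"]),
    lbp_entropy = entropy2(lbp / max(sum(lbp), 1e-12)),
    intensity_mean = unname(v["hist_mean"])
  )
}

#' The 20 TME graph features
#'
#' Texture-average block (6): mean over connected (degree >= 1) nodes of
#' the six designated texture summaries.  Local-node block (7): node
#' count, edge count, mean degree, degree variance, global clustering
#' coefficient, cross-class edge fraction, and the algebraic connectivity
#' (second-smallest Laplacian eigenvalue) of the largest component.
#' Global-connectivity block (7): component count, largest-component
#' fraction, Euclidean MST total / mean / variance of edge lengths, MST
#' diameter (in edges), and mean nearest-neighbor centroid distance.
#' Degenerate defaults: an empty graph returns all zeros; a single-node
#' graph returns zeros except node count 1.
#'
#' @param g A `tme_graph`.
#' @return Named numeric vector of length 20 (see
#'   [graph_feature_names()]), all finite.
#' @export
graph_features <- function(g) {
  nm <- graph_feature_names()$name
  out <- stats::setNames(numeric(20), nm)
  n <- nrow(g$nodes)
  if (n == 0) return(out)
  out["ln_node_count"] <- n
  if (n == 1) return(out)

  m <- nrow(g$edges)
  deg <- tabulate(c(g$edges[, 1], g$edges[, 2]), nbins = n)
  out["ln_edge_count"] <- m
  out["ln_mean_degree"] <- mean(deg)
  out["ln_degree_variance"] <- stats::var(deg) * (n - 1) / n  # population

  ig <- igraph::make_empty_graph(n, directed = FALSE)
  if (m > 0) ig <- igraph::add_edges(ig, t(g$edges))
  tr <- igraph::transitivity(ig, type = "global")
  out["ln_clustering_coeff"] <- if (is.nan(tr)) 0 else tr
  if (m > 0) {
    cross <- g$nodes$class[g$edges[, 1]] != g$nodes$class[g$edges[, 2]]
    out["ln_cross_edge_fraction"] <- mean(cross)
  }

  comp <- igraph::components(ig)
  out["gc_component_count"] <- comp$no
  out["gc_largest_component_fraction"] <- max(comp$csize) / n

  ## algebraic connectivity of the largest component
  big <- which(comp$membership == which.max(comp$csize))
  if (length(big) >= 2) {
    sub <- igraph::induced_subgraph(ig, big)
    L <- as.matrix(igraph::laplacian_matrix(sub))
    ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
    out["ln_algebraic_connectivity"] <- max(ev[2], 0)
  }

  ## Euclidean-weighted minimum spanning forest of the geometric graph
  ## (one tree per component; edge count = sum of |V_c| - 1)
  dmat <- as.matrix(stats::dist(g$nodes[, c("x", "y")]))
  if (m > 0) {
    igraph::E(ig)$weight <- dmat[g$edges]
    mst <- igraph::mst(ig)
    w <- igraph::E(mst)$weight
    out["gc_mst_total_length"] <- sum(w)
    out["gc_mst_mean_edge"] <- mean(w)
    out["gc_mst_edge_variance"] <- if (length(w) > 1) stats::var(w) else 0
    out["gc_mst_diameter"] <- igraph::diameter(mst, weights = NA)
  }
  nnd <- apply(dmat + diag(Inf, n), 1, min)
  out["gc_mean_nn_distance"] <- mean(nnd)

  ## texture averages over interacting (degree >= 1) nodes
  connected <- which(deg >= 1)
  if (length(connected) > 0 && !is.null(g$textures) &&
      !all(vapply(g$textures, is.null, logical(1)))) {
    tex <- g$textures[connected]
    tex <- tex[!vapply(tex, is.null, logical(1))]
    if (length(tex) > 0) {
      avg <- Reduce(`+`, tex) / length(tex)
      if (length(avg) == 6) {
        out[1:6] <- avg
      } else {
        out[1:6] <- texture_summary(avg)
      }
    }
  }
  out
}

#' All unordered pairs of tissue classes
#'
#' @param ids Class ids (default the 16 tissue classes).
#' @return Two-column integer matrix, one row per unordered pair
#'   (`C(16, 2) = 120` rows for the default).
#' @export
class_pairs <- function(ids = tissue_class_ids()) {
  t(utils::combn(sort(as.integer(ids)), 2))
}

#' Patient-level (pair, feature) matrix
#'
#' Builds the TME graph for every unordered pair of tissue classes and
#' concatenates the 20 graph features of each: 120 x 20 = 2400 named
#' columns per patient for the full class set.  Column order is fixed
#' (pairs by ascending ids, features in roster order).
#'
#' @param map A `histology_map` for one patient.
#' @param radius Edge radius in pixels.
#' @param class_textures Optional named list or matrix mapping class id to
#'   a 6-element texture-summary vector used for every cluster of that
#'   class (rownames/names are class ids).  When `NULL`, texture-average
#'   features are zero unless clusters carry `mean_texture`.
#' @param ids Tissue class ids (default 0:15).
#' @param clusters Optional precomputed list of cluster lists indexed by
#'   class id as character (bypasses [find_clusters()]).
#' @return Named numeric vector of length `nrow(class_pairs(ids)) * 20`.
#' @export
all_pair_features <- function(map, radius = 672, class_textures = NULL,
                              ids = tissue_class_ids(), clusters = NULL) {
  if (is.null(clusters)) {
    clusters <- lapply(ids, function(cl) find_clusters(map, cl))
    names(clusters) <- as.character(ids)
  }
  if (!is.null(class_textures)) {
    for (cl in names(clusters)) {
      tex <- if (is.matrix(class_textures)) class_textures[cl, ]
      else class_textures[[cl]]
      clusters[[cl]] <- lapply(clusters[[cl]], function(x) {
        x$mean_texture <- tex
        x
      })
    }
  }
  pairs <- class_pairs(ids)
  fn <- graph_feature_names()$name
  out <- numeric(nrow(pairs) * 20)
  nms <- character(nrow(pairs) * 20)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    gr <- build_pair_graph(clusters[[as.character(a)]],
                           clusters[[as.character(b)]], radius = radius)
    idx <- ((i - 1) * 20 + 1):(i * 20)
    out[idx] <- graph_features(gr)
    nms[idx] <- sprintf("c%02d_c%02d__%s", a, b, fn)
  }
  stats::setNames(out, nms)
}

#' Class pairs referenced by selected feature columns
#'
#' @param colnames Character column names of the pair-feature matrix
#'   (format `cAA_cBB__feature`).
#' @return Unique two-column integer matrix of class pairs.
#' @export
selected_pair_ids <- function(colnames) {
  m <- regmatches(colnames, regexec("^c([0-9]+)_c([0-9]+)__", colnames))
  pairs <- unique(t(vapply(m, function(x) as.integer(x[2:3]), integer(2))))
  pairs
}
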