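map_from_grid <- function(grid, tile_size = 224) {
  structure(list(slide_id = "s", grid = grid, tile_size = tile_size),
            class = "histology_map")
}

test_that("tile clusters are 8-connected components with pixel centroids", {
  g <- matrix(NA_integer_, 4, 4)
  g[2, 3] <- 1L
  cl <- find_clusters(map_from_grid(g), 1)
  expect_length(cl, 1)
  ## tile center of cell (2, 3): x = 2*224 + 112, y = 1*224 + 112
  expect_equal(unname(cl[[1]]$centroid), c(2 * 224 + 112, 224 + 112))
  ## diagonal contact joins clusters under 8-adjacency
  g2 <- matrix(NA_integer_, 3, 3)
  g2[1, 1] <- 1L; g2[2, 2] <- 1L
  expect_length(find_clusters(map_from_grid(g2), 1), 1)
  ## absent class: empty list, no error
  expect_length(find_clusters(map_from_grid(g2), 7), 0)
})

test_that("cluster counts match an independent flood fill on random grids", {
  set.seed(17)
  for (rep in 1:5) {
    g <- matrix(sample(c(NA, 0:3), 400, replace = TRUE,
                       prob = c(0.4, rep(0.15, 4))), 20, 20)
    for (cls in 0:3) {
      expect_length(find_clusters(map_from_grid(g), cls),
                    oracle_cluster_count(g, cls))
    }
  }
})

test_that("geometric edges follow the Euclidean radius rule exactly", {
  a <- toy_node(0, 0, 1); b <- toy_node(100, 0, 2)
  expect_equal(nrow(build_pair_graph(list(a), list(b), radius = 150)$edges), 1)
  expect_equal(nrow(build_pair_graph(list(a), list(b), radius = 50)$edges), 0)
  ## 10 random nodes against the all-pairs oracle
  set.seed(23)
  xy <- cbind(runif(10, 0, 1000), runif(10, 0, 1000))
  nodes <- lapply(1:10, function(i) toy_node(xy[i, 1], xy[i, 2], i %% 2))
  g <- build_pair_graph(nodes[1:5], nodes[6:10], radius = 400)
  d <- as.matrix(dist(xy))
  want <- which(upper.tri(d) & d <= 400, arr.ind = TRUE)
  got <- g$edges[order(g$edges[, 1], g$edges[, 2]), , drop = FALSE]
  want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
  expect_equal(unname(got), unname(want))
})

test_that("graph features have closed forms on canonical graphs", {
  ## empty graph: all zeros
  expect_true(all(graph_features(build_pair_graph(list(), list(), 10)) == 0))
  ## single node: zeros except node count
  f1 <- graph_features(build_pair_graph(list(toy_node(5, 5)), list(), 10))
  expect_equal(unname(f1["ln_node_count"]), 1)
  expect_equal(sum(f1 != 0), 1)
  ## path of 3 unit-spaced nodes: P3 spectrum {0, 1, 3}
  p3 <- build_pair_graph(list(toy_node(0, 0), toy_node(1, 0),
                              toy_node(2, 0)), list(), radius = 1)
  f3 <- graph_features(p3)
  expect_equal(unname(f3["ln_algebraic_connectivity"]), 1, tolerance = 1e-10)
  expect_equal(unname(f3["gc_mst_total_length"]), 2)
  expect_equal(unname(f3["gc_mst_diameter"]), 2)
  expect_equal(unname(f3["ln_edge_count"]), 2)
  expect_equal(unname(f3["gc_component_count"]), 1)
  ## explicit Laplacian spectrum check
  L <- rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1))
  expect_equal(sort(eigen(L, symmetric = TRUE)$values), c(0, 1, 3),
               tolerance = 1e-10)
})

test_that("MST length matches exhaustive spanning-tree enumeration", {
  set.seed(31)
  for (n in c(4, 5, 6)) {
    xy <- cbind(runif(n, 0, 10), runif(n, 0, 10))
    nodes <- lapply(seq_len(n), function(i) toy_node(xy[i, 1], xy[i, 2]))
    radius <- 8
    g <- build_pair_graph(nodes, list(), radius = radius)
    f <- graph_features(g)
    expect_equal(unname(f["gc_mst_total_length"]),
                 oracle_mst_length(xy, radius), tolerance = 1e-9)
  }
})

test_that("features are translation invariant and scale as expected", {
  set.seed(37)
  xy <- cbind(runif(6, 0, 500), runif(6, 0, 500))
  mk <- function(xy, r) {
    graph_features(build_pair_graph(
      lapply(seq_len(nrow(xy)), function(i) toy_node(xy[i, 1], xy[i, 2])),
      list(), radius = r))
  }
  f <- mk(xy, 300)
  ## translation by a common offset changes nothing
  expect_equal(mk(sweep(xy, 2, c(1234, 770), `+`), 300), f,
               tolerance = 1e-9)
  ## uniform 2x scaling with 2x radius: degrees invariant, lengths double
  f2 <- mk(xy * 2, 600)
  deg_feats <- c("ln_node_count", "ln_edge_count", "ln_mean_degree",
                 "ln_degree_variance", "ln_clustering_coeff",
                 "gc_component_count", "gc_largest_component_fraction",
                 "gc_mst_diameter")
  expect_equal(f2[deg_feats], f[deg_feats], tolerance = 1e-9)
  expect_equal(unname(f2["gc_mst_total_length"]),
               2 * unname(f["gc_mst_total_length"]), tolerance = 1e-9)
  expect_equal(unname(f2["gc_mean_nn_distance"]),
               2 * unname(f["gc_mean_nn_distance"]), tolerance = 1e-9)
})

test_that("the pair roster enumerates C(n, 2) unordered pairs symmetrically", {
  expect_equal(nrow(class_pairs()), 120)
  expect_equal(nrow(class_pairs(c(2, 5, 9))), 3)
  ## features do not depend on the order the two classes are given
  set.seed(41)
  a_nodes <- lapply(1:4, function(i) toy_node(runif(1, 0, 2000),
                                              runif(1, 0, 2000), 1))
  b_nodes <- lapply(1:3, function(i) toy_node(runif(1, 0, 2000),
                                              runif(1, 0, 2000), 10))
  fab <- graph_features(build_pair_graph(a_nodes, b_nodes, 900))
  fba <- graph_features(build_pair_graph(b_nodes, a_nodes, 900))
  expect_equal(fab, fba, tolerance = 1e-12)
})

test_that("the patient pair-feature vector has fixed 2400-column layout", {
  g <- matrix(NA_integer_, 8, 8)
  g[1, 1] <- 1L; g[1, 2] <- 1L; g[3, 3] <- 10L; g[6, 6] <- 5L
  v <- all_pair_features(map_from_grid(g), radius = 672)
  expect_length(v, 120 * 20)
  expect_true(all(is.finite(v)))
  nm <- names(v)
  expect_equal(nm[1], "c00_c01__ta_glcm_contrast")
  expect_equal(sum(grepl("^c01_c10__", nm)), 20)
  ## adjacent classes 1 and 10 interact; classes 1 and 5 are far apart
  expect_gt(v["c01_c10__ln_edge_count"], 0)
  expect_equal(unname(v["c01_c05__ln_edge_count"]), 0)
})
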