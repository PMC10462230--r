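## Independent brute-force oracles used to cross-check the package's
## vectorized implementations.  Deliberately written as plain loops.

## quantize exactly like the implementation under test
oracle_quantize <- function(img, L) pmin(floor(pmin(pmax(img, 0), 1) * L) + 1, L)

## co-occurrence features for one offset by explicit pair counting
oracle_glcm_one <- function(img, L, dr, dc) {
  q <- oracle_quantize(img, L)
  counts <- matrix(0, L, L)
  for (r in seq_len(nrow(q))) {
    for (c in seq_len(ncol(q))) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        counts[q[r, c], q[r2, c2]] <- counts[q[r, c], q[r2, c2]] + 1
      }
    }
  }
  counts <- counts + t(counts)
  p <- counts / sum(counts)
  mu_i <- 0; mu_j <- 0
  for (i in 1:L) for (j in 1:L) { mu_i <- mu_i + i * p[i, j]; mu_j <- mu_j + j * p[i, j] }
  v_i <- 0; v_j <- 0; cov_ij <- 0
  contrast <- 0; energy <- 0; homog <- 0; ent <- 0
  for (i in 1:L) {
    for (j in 1:L) {
      pij <- p[i, j]
      v_i <- v_i + (i - mu_i)^2 * pij
      v_j <- v_j + (j - mu_j)^2 * pij
      cov_ij <- cov_ij + (i - mu_i) * (j - mu_j) * pij
      contrast <- contrast + (i - j)^2 * pij
      energy <- energy + pij^2
      homog <- homog + pij / (1 + abs(i - j))
      if (pij > 0) ent <- ent - pij * log2(pij)
    }
  }
  corr <- if (v_i > 0 && v_j > 0) cov_ij / sqrt(v_i * v_j) else 0
  c(contrast = contrast, correlation = corr, energy = energy,
    homogeneity = homog, entropy = ent)
}

## offset-averaged GLCM features (same four offsets as the implementation)
oracle_glcm <- function(img, L = 32) {
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  per <- lapply(offs, function(o) oracle_glcm_one(img, L, o[1], o[2]))
  Reduce(`+`, per) / 4
}

## rotation-invariant uniform LBP histogram by per-pixel looping
oracle_lbp <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  shifts <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
                 c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  h <- numeric(10)
  for (r in 2:(nr - 1)) {
    for (c in 2:(nc - 1)) {
      bits <- vapply(shifts, function(s) img[r + s[1], c + s[2]] >= img[r, c],
                     logical(1))
      trans <- sum(bits != bits[c(2:8, 1)])
      bin <- if (trans <= 2) sum(bits) else 9
      h[bin + 1] <- h[bin + 1] + 1
    }
  }
  h / sum(h)
}

## exhaustive minimum spanning forest length of a geometric graph:
## enumerate all edge subsets of the right size per component
oracle_mst_length <- function(xy, radius) {
  n <- nrow(xy)
  d <- as.matrix(dist(xy))
  edges <- which(upper.tri(d) & d <= radius, arr.ind = TRUE)
  if (nrow(edges) == 0) return(0)
  ## component membership by repeated expansion
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  total <- 0
  for (cid in unique(comp)) {
    nodes <- which(comp == cid)
    if (length(nodes) < 2) next
    in_comp <- edges[, 1] %in% nodes & edges[, 2] %in% nodes
    ce <- edges[in_comp, , drop = FALSE]
    k <- length(nodes) - 1
    best <- Inf
    for (subset in utils::combn(nrow(ce), k, simplify = FALSE)) {
      sub <- ce[subset, , drop = FALSE]
      ## spanning tree iff k edges connect all nodes
      cc <- seq_along(nodes); names(cc) <- nodes
      for (e in seq_len(nrow(sub))) {
        a <- as.character(sub[e, 1]); b <- as.character(sub[e, 2])
        m <- min(cc[a], cc[b])
        cc[cc == cc[a] | cc == cc[b]] <- m
      }
      if (length(unique(cc)) == 1) {
        best <- min(best, sum(d[sub]))
      }
    }
    total <- total + best
  }
  total
}

## connected components of same-class cells by explicit flood fill
oracle_cluster_count <- function(grid, cls) {
  nr <- nrow(grid); nc <- ncol(grid)
  seen <- matrix(FALSE, nr, nc)
  count <- 0
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (seen[r0, c0] || is.na(grid[r0, c0]) || grid[r0, c0] != cls) next
      count <- count + 1
      queue <- list(c(r0, c0))
      seen[r0, c0] <- TRUE
      while (length(queue) > 0) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (dr in -1:1) {
          for (dc in -1:1) {
            r <- cur[1] + dr; c <- cur[2] + dc
            if (r < 1 || r > nr || c < 1 || c > nc) next
            if (!seen[r, c] && !is.na(grid[r, c]) && grid[r, c] == cls) {
              seen[r, c] <- TRUE
              queue[[length(queue) + 1]] <- c(r, c)
            }
          }
        }
      }
    }
  }
  count
}

## quick cluster-like node for graph construction in tests
toy_node <- function(x, y, class = 1L) {
  list(cluster_id = sprintf("n_%g_%g", x, y), class = as.integer(class),
       cells = cbind(row = 1L, col = 1L), centroid = c(x = x, y = y))
}
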