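## Six texture families computed on the hematoxylin channel.
## Registry order is fixed: GLCM offset-averaged (5), GLCM per-offset (16),
## Gabor (24), LBP (10), Tamura (3), lower-order histogram (6),
## intensity percentiles (10), gradient histogram (6) -- 80 features.

## quantize [0,1] image to integer levels 1..L
quantize_levels <- function(img, L) {
  pmin(floor(clamp(img, 0, 1) * L) + 1L, L)
}

## the four standard distance-1 offsets as (drow, dcol):
## 0, 45, 90, 135 degrees in image (y-down) convention
glcm_offsets <- function() {
  list(deg0 = c(0L, 1L), deg45 = c(-1L, 1L),
       deg90 = c(-1L, 0L), deg135 = c(-1L, -1L))
}

## symmetric normalized co-occurrence matrix for one offset
glcm_matrix <- function(q, L, offset) {
  nr <- nrow(q); nc <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  r0 <- max(1, 1 - dr):min(nr, nr - dr)
  c0 <- max(1, 1 - dc):min(nc, nc - dc)
  a <- q[r0, c0, drop = FALSE]
  b <- q[r0 + dr, c0 + dc, drop = FALSE]
  counts <- tabulate((a - 1L) * L + b, nbins = L * L)
  m <- matrix(counts, L, L, byrow = TRUE)
  m <- m + t(m)                       # symmetric
  m / sum(m)
}

glcm_stats <- function(p, L) {
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  sd_i <- sqrt(sum((i - mu_i)^2 * p)); sd_j <- sqrt(sum((j - mu_j)^2 * p))
  corr <- if (sd_i > 0 && sd_j > 0) {
    sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j)
  } else 0                            # constant image: correlation := 0
  c(
    contrast = sum((i - j)^2 * p),
    correlation = corr,
    energy = sum(p^2),
    homogeneity = sum(p / (1 + abs(i - j))),
    entropy = entropy2(as.vector(p))
  )
}

#' Gray-level co-occurrence features
#'
#' Computes the symmetric normalized GLCM at distance 1 for the four
#' standard offsets (0, 45, 90, 135 degrees) on an image quantized to
#' `levels` gray levels, and averages contrast, correlation, energy,
#' homogeneity and entropy over offsets.
#'
#' @param img Numeric matrix with values in `[0, 1]`.
#' @param levels Number of gray levels (default 32).
#' @param per_offset If `TRUE`, additionally return the per-offset
#'   contrast/correlation/energy/homogeneity (16 extra features).
#' @return Named numeric vector (5 features, or 21 with `per_offset`).
#' @export
glcm_features <- function(img, levels = 32, per_offset = FALSE) {
  q <- quantize_levels(img, levels)
  offs <- glcm_offsets()
  per <- lapply(offs, function(o) glcm_stats(glcm_matrix(q, levels, o), levels))
  avg <- Reduce(`+`, per) / length(per)
  names(avg) <- paste0("glcm_", names(avg))
  if (!per_offset) return(avg)
  extra <- unlist(lapply(names(offs), function(nm) {
    v <- per[[nm]][c("contrast", "correlation", "energy", "homogeneity")]
    names(v) <- paste0("glcm_", nm, "_", names(v))
    v
  }))
  c(avg, extra)
}

## Gabor -----------------------------------------------------------------

## complex Gabor kernel; zero-mean even part so constant images give 0
gabor_kernel <- function(frequency, theta, sigma = 0.56 / frequency,
                         max_half = Inf) {
  half <- max(3L, ceiling(2.5 * sigma))
  half <- min(half, max_half)
  ax <- seq(-half, half)
  x <- matrix(ax, length(ax), length(ax), byrow = TRUE)   # col -> x
  y <- matrix(ax, length(ax), length(ax))                 # row -> y
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
  even <- env * cos(2 * pi * frequency * xr)
  odd <- env * sin(2 * pi * frequency * xr)
  even <- even - sum(even) / sum(env) * env   # remove DC response
  matrix(complex(real = even, imaginary = odd), nrow = length(ax))
}

#' Gabor filter-bank features
#'
#' Applies a bank of 4 orientations (0, 45, 90, 135 degrees) x 3 spatial
#' frequencies (0.1, 0.2, 0.4 cycles/px) and returns the mean and variance
#' of each response magnitude: 24 features.  The even kernel is DC-free, so
#' a constant image yields zero response.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param frequencies Bank frequencies (cycles/pixel).
#' @param orientations Bank orientations (radians).
#' @return Named numeric vector of 24 features
#'   (`gabor_f<freq>_o<deg>_{mean,var}`).
#' @export
gabor_features <- function(img, frequencies = c(0.1, 0.2, 0.4),
                           orientations = pi * (0:3) / 4) {
  out <- numeric(0)
  max_half <- floor((min(dim(img)) - 1) / 2)
  for (f in frequencies) {
    for (k in seq_along(orientations)) {
      th <- orientations[k]
      kern <- gabor_kernel(f, th, max_half = max_half)
      mag <- Mod(fft_convolve(img, kern))
      nm <- sprintf("gabor_f%s_o%d", format(f), round(th * 180 / pi))
      out[paste0(nm, "_mean")] <- mean(mag)
      out[paste0(nm, "_var")] <- stats::var(as.vector(mag))
    }
  }
  out
}

## LBP -------------------------------------------------------------------

#' Rotation-invariant uniform local binary patterns (P=8, R=1)
#'
#' Thresholds each interior pixel's 8 neighbors at the center value,
#' classifies the ring code as uniform (at most 2 circular transitions,
#' binned by the number of set bits: 0..8) or non-uniform (bin 10), and
#' returns the normalized 10-bin histogram (sums to 1).
#'
#' @param img Numeric matrix in `[0, 1]`, at least 3 x 3.
#' @return Named numeric vector `lbp_u0`..`lbp_u8`, `lbp_nonuniform`.
#' @export
lbp_features <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  stopifnot(nr >= 3, nc >= 3)
  ctr <- img[2:(nr - 1), 2:(nc - 1)]
  ## neighbors in circular order starting east, counter-clockwise in (x,y)
  shifts <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
                 c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  bits <- lapply(shifts, function(s) {
    img[2:(nr - 1) + s[1], 2:(nc - 1) + s[2]] >= ctr
  })
  trans <- matrix(0L, nr - 2, nc - 2)
  ones <- matrix(0L, nr - 2, nc - 2)
  for (p in 1:8) {
    nxt <- if (p == 8) 1 else p + 1
    trans <- trans + (bits[[p]] != bits[[nxt]])
    ones <- ones + bits[[p]]
  }
  bin <- ifelse(trans <= 2, ones, 9L)
  h <- tabulate(as.vector(bin) + 1L, nbins = 10)
  h <- h / sum(h)
  names(h) <- c(paste0("lbp_u", 0:8), "lbp_nonuniform")
  h
}

## Tamura ----------------------------------------------------------------

## local means over 2*half windows via integral image (edge-replicated)
box_mean <- function(img, half) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(rep(1, half), seq_len(nr), rep(nr, half))
  ci <- c(rep(1, half), seq_len(nc), rep(nc, half))
  pad <- img[ri, ci]
  cs <- matrix(0, nrow(pad) + 1, ncol(pad) + 1)
  cs[-1, -1] <- t(apply(apply(pad, 2, cumsum), 1, cumsum))
  w <- 2 * half
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ## window for pixel (r, c): padded rows r..r+w-1, cols c..c+w-1
  s <- cs[cbind(as.vector(rr + w), as.vector(cc + w))] -
    cs[cbind(as.vector(rr), as.vector(cc + w))] -
    cs[cbind(as.vector(rr + w), as.vector(cc))] +
    cs[cbind(as.vector(rr), as.vector(cc))]
  matrix(s, nr, nc) / (w * w)
}

tamura_coarseness <- function(img, kmax = 5) {
  nr <- nrow(img); nc <- ncol(img)
  kmax <- min(kmax, max(1, floor(log2(min(nr, nc) / 2))))
  best_e <- matrix(-Inf, nr, nc)
  sbest <- matrix(1, nr, nc)
  for (k in seq_len(kmax)) {
    half <- 2^(k - 1)
    A <- box_mean(img, half)
    eh <- matrix(0, nr, nc); ev <- matrix(0, nr, nc)
    ok_c <- (half + 1):(nc - half); ok_r <- (half + 1):(nr - half)
    if (length(ok_c) > 0) {
      eh[, ok_c] <- abs(A[, ok_c + half] - A[, ok_c - half])
    }
    if (length(ok_r) > 0) {
      ev[ok_r, ] <- abs(A[ok_r + half, ] - A[ok_r - half, ])
    }
    e <- pmax(eh, ev)
    upd <- e > best_e + 1e-12
    best_e[upd] <- e[upd]
    sbest[upd] <- 2^k
  }
  mean(sbest)
}

prewitt_gradients <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3 || nc < 3) return(list(gx = matrix(0, 1, 1), gy = matrix(0, 1, 1)))
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  gx <- (img[ri - 1, ci + 1] + img[ri, ci + 1] + img[ri + 1, ci + 1] -
         img[ri - 1, ci - 1] - img[ri, ci - 1] - img[ri + 1, ci - 1]) / 3
  gy <- (img[ri + 1, ci - 1] + img[ri + 1, ci] + img[ri + 1, ci + 1] -
         img[ri - 1, ci - 1] - img[ri - 1, ci] - img[ri - 1, ci + 1]) / 3
  list(gx = gx, gy = gy)
}

#' Tamura perceptual texture features
#'
#' Coarseness (mean best window size from the classic Sbest construction),
#' contrast (sd / kurtosis^(1/4), 0 for flat images), and directionality
#' (concentration -- sum of squared bin masses -- of the 16-bin
#' gradient-orientation histogram over pixels with appreciable gradient;
#' 0 when no such pixels exist).
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param grad_threshold Minimum mean absolute Prewitt response for a pixel
#'   to vote in the orientation histogram.
#' @return Named numeric vector `tamura_coarseness`, `tamura_contrast`,
#'   `tamura_directionality`.
#' @export
tamura_features <- function(img, grad_threshold = 0.01) {
  v <- as.vector(img)
  sdv <- stats::sd(v)
  contrast <- if (is.na(sdv) || sdv == 0) 0 else {
    m4 <- mean((v - mean(v))^4)
    sdv / (m4 / sdv^4)^0.25
  }
  g <- prewitt_gradients(img)
  mag <- (abs(g$gx) + abs(g$gy)) / 2
  keep <- mag > grad_threshold
  directionality <- if (!any(keep)) 0 else {
    theta <- atan2(g$gy[keep], g$gx[keep]) %% pi
    bins <- pmin(floor(theta / pi * 16) + 1L, 16L)
    h <- tabulate(bins, nbins = 16)
    h <- h / sum(h)
    sum(h^2)
  }
  c(
    tamura_coarseness = tamura_coarseness(img),
    tamura_contrast = contrast,
    tamura_directionality = directionality
  )
}

## Histogram families ----------------------------------------------------

moment_stats <- function(v, prefix, bins = 32, range01 = TRUE) {
  mu <- mean(v)
  va <- mean((v - mu)^2)           # population variance
  if (va > 0) {
    sk <- mean((v - mu)^3) / va^1.5
    ku <- mean((v - mu)^4) / va^2
  } else {
    sk <- 0; ku <- 0                # flat input: moments defined as 0
  }
  rng <- if (range01) c(0, 1) else range(v)
  if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1
  b <- pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * bins) + 1L, bins)
  p <- tabulate(b, nbins = bins) / length(v)
  out <- c(mu, va, sk, ku, sum(p^2), entropy2(p))
  names(out) <- paste0(prefix, c("mean", "variance", "skewness", "kurtosis",
                                 "energy", "entropy"))
  out
}

#' Intensity and gradient histogram features
#'
#' Lower-order block: mean, variance, skewness, kurtosis of the intensity
#' distribution plus energy and entropy of its 32-bin histogram (6
#' features) and ten intensity percentiles.  Higher-order block: the same
#' six statistics of the Prewitt gradient-magnitude distribution.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @return Named numeric vector of 22 features.
#' @export
histogram_features <- function(img) {
  v <- as.vector(img)
  lower <- moment_stats(v, "hist_", range01 = TRUE)
  probs <- c(0.01, 0.05, 0.10, 0.20, 0.25, 0.50, 0.75, 0.90, 0.95, 0.99)
  pct <- stats::quantile(v, probs, names = FALSE)
  names(pct) <- paste0("hist_p", sub("\\.", "_", format(probs * 100)))
  names(pct) <- gsub(" ", "", names(pct))
  g <- prewitt_gradients(img)
  gmag <- sqrt(as.vector(g$gx)^2 + as.vector(g$gy)^2)
  higher <- moment_stats(gmag, "grad_", range01 = FALSE)
  c(lower, pct, higher)
}

## Registry ---------------------------------------------------------------

#' Texture feature registry
#'
#' Fixed names, family tags and order of the 80 raw tile features.
#'
#' @return data.frame with columns `name` and `family`.
#' @export
feature_registry <- function() {
  probe <- matrix(((1:64) %% 7) / 7, 8, 8)  # only the names are used
  nm <- names(extract_features_impl(probe))
  family <- c(
    rep("GLCM", 5 + 16),
    rep("Gabor", 24),
    rep("LBP", 10),
    rep("Tamura", 3),
    rep("lower_histogram", 6 + 10),
    rep("higher_histogram", 6)
  )
  data.frame(name = nm, family = family, stringsAsFactors = FALSE)
}

extract_features_impl <- function(img, levels = 32) {
  c(
    glcm_features(img, levels = levels, per_offset = TRUE),
    gabor_features(img),
    lbp_features(img),
    tamura_features(img),
    histogram_features(img)
  )
}

#' Extract the 80 raw texture features for one tile
#'
#' @param img Numeric matrix in `[0, 1]` (normally the hematoxylin channel
#'   of a 224 x 224 tile).
#' @param levels GLCM quantization levels.
#' @return Named numeric vector of length 80, in registry order.
#' @export
extract_features <- function(img, levels = 32) {
  v <- extract_features_impl(img, levels = levels)
  stopifnot(length(v) == 80)
  v
}

#' Feature filtering: drop zero, NA, and repeated columns
#'
#' Applied to a training-tile feature matrix only.  A feature is dropped
#' when it is identically zero on the training data, contains any NA, or
#' exactly duplicates an earlier (registry-order) retained feature.
#'
#' @param mat Numeric tiles x features matrix (training tiles only).
#' @return Logical retained mask of length `ncol(mat)`; the retained count
#'   is reported via `message()`.
#' @export
filter_features <- function(mat) {
  stopifnot(is.matrix(mat))
  p <- ncol(mat)
  keep <- rep(TRUE, p)
  for (j in seq_len(p)) {
    col <- mat[, j]
    if (anyNA(col) || all(col == 0)) {
      keep[j] <- FALSE
      next
    }
    if (j > 1) {
      for (i in which(keep[seq_len(j - 1)])) {
        if (identical(mat[, i], col)) {
          keep[j] <- FALSE
          break
        }
      }
    }
  }
  if (!any(keep)) stop("feature filtering retained 0 features")
  message(sprintf("retained %d of %d features", sum(keep), p))
  keep
}
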