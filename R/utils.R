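## internal helpers shared across modules

## evaluate `expr` under a temporary RNG state seeded with `seed`;
## restores the caller's .Random.seed afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## signed (shoelace) area of one polygon ring; positive if counter-clockwise
ring_area_signed <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

## total area of a polyclip result (list of rings; holes carry opposite
## orientation so the signed sum is the enclosed area)
polyset_area <- function(rings) {
  if (length(rings) == 0) return(0)
  abs(sum(vapply(rings, function(r) ring_area_signed(r$x, r$y), numeric(1))))
}

## Shannon entropy (base 2) of a probability vector; 0 * log(0) := 0
entropy2 <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  -sum(p * log2(p))
}

## clamp to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## 2-D circular convolution via FFT; kernel given as a small matrix
## (possibly complex), implicitly centered at its middle element
fft_convolve <- function(img, kernel) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(kernel); kc <- ncol(kernel)
  if (kr > nr || kc > nc) stop("kernel larger than image")
  pad <- matrix(0 + 0i, nr, nc)
  cr <- (kr + 1) %/% 2; cc <- (kc + 1) %/% 2
  rows <- ((seq_len(kr) - cr) %% nr) + 1
  cols <- ((seq_len(kc) - cc) %% nc) + 1
  pad[rows, cols] <- kernel
  fft(fft(img) * fft(pad), inverse = TRUE) / (nr * nc)
}

## isotropic Gaussian smoothing with circular boundary
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  half <- min(half, floor((min(dim(img)) - 1) / 2))
  ax <- seq(-half, half)
  g <- exp(-ax^2 / (2 * sigma^2))
  k <- outer(g, g)
  k <- k / sum(k)
  Re(fft_convolve(img, k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
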