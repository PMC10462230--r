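test_that("GLCM features have closed-form values on degenerate images", {
  flat <- matrix(0.5, 8, 8)
  g <- glcm_features(flat)
  expect_equal(unname(g["glcm_contrast"]), 0)
  expect_equal(unname(g["glcm_energy"]), 1)
  expect_equal(unname(g["glcm_homogeneity"]), 1)
  expect_equal(unname(g["glcm_entropy"]), 0)
  expect_equal(unname(g["glcm_correlation"]), 0)  # defined fallback
  ## checkerboard of extreme levels: every horizontal pair differs by L-1
  L <- 32
  cb <- outer(1:8, 1:8, function(r, c) ((r + c) %% 2))
  gp <- glcm_features(cb, levels = L, per_offset = TRUE)
  expect_equal(unname(gp["glcm_deg0_contrast"]), (L - 1)^2)
  expect_equal(unname(gp["glcm_deg90_contrast"]), (L - 1)^2)
  ## diagonal neighbors are equal on a checkerboard
  expect_equal(unname(gp["glcm_deg45_contrast"]), 0)
})

test_that("GLCM matches the brute-force pair-counting oracle", {
  set.seed(11)
  for (rep in 1:5) {
    img <- matrix(sample(0:7, 64, replace = TRUE) / 8, 8, 8)
    mine <- glcm_features(img, levels = 8)
    oracle <- oracle_glcm(img, L = 8)
    expect_equal(unname(mine), unname(oracle), tolerance = 1e-12)
  }
})

test_that("LBP histogram is normalized and matches a hand oracle", {
  flat <- matrix(0.4, 6, 6)
  h <- lbp_features(flat)
  expect_equal(unname(h["lbp_u8"]), 1)  # all neighbors >= center
  set.seed(3)
  img <- matrix(runif(25), 5, 5)
  expect_equal(sum(lbp_features(img)), 1, tolerance = 1e-12)
  expect_equal(unname(lbp_features(img)), oracle_lbp(img), tolerance = 1e-12)
})

test_that("Gabor bank responds maximally to a matching grating", {
  x <- matrix(seq_len(64) - 1, 64, 64, byrow = TRUE)
  grating <- 0.5 + 0.4 * sin(2 * pi * 0.2 * x)  # frequency 0.2, angle 0
  g <- gabor_features(grating)
  means <- g[grep("_mean$", names(g))]
  expect_equal(names(which.max(means)), "gabor_f0.2_o0_mean")
  ## constant image: zero response everywhere
  g0 <- gabor_features(matrix(0.7, 64, 64))
  expect_true(all(abs(g0[grep("_var$", names(g0))]) < 1e-20))
  ## white noise carries no preferred orientation: mean responses
  ## (averaged over draws at a fixed seed) agree across orientations
  set.seed(21)
  gn <- Reduce(`+`, lapply(1:6, function(i) {
    gabor_features(matrix(runif(128 * 128), 128, 128))
  })) / 6
  for (f in c("0.1", "0.2", "0.4")) {
    m <- gn[sprintf("gabor_f%s_o%d_mean", f, c(0, 45, 90, 135))]
    expect_lt((max(m) - min(m)) / mean(m), 0.1)
  }
})

test_that("Tamura features order stimuli as perception suggests", {
  flat <- matrix(0.3, 32, 32)
  tf <- tamura_features(flat)
  expect_true(is.finite(tf["tamura_coarseness"]))
  expect_equal(unname(tf["tamura_contrast"]), 0)
  expect_equal(unname(tf["tamura_directionality"]), 0)
  ## stripes are more directional than white noise
  x <- matrix(seq_len(64) - 1, 64, 64, byrow = TRUE)
  stripes <- 0.5 + 0.4 * sin(2 * pi * 0.1 * x)
  set.seed(9)
  noise <- matrix(runif(64 * 64), 64, 64)
  expect_gt(tamura_features(stripes)["tamura_directionality"],
            tamura_features(noise)["tamura_directionality"])
  ## low-frequency blobs are coarser than fine noise
  set.seed(9)
  blobs <- tmegraph:::gaussian_smooth(matrix(rnorm(64 * 64), 64, 64), 8)
  blobs <- (blobs - min(blobs)) / diff(range(blobs))
  expect_gt(tamura_features(blobs)["tamura_coarseness"],
            tamura_features(noise)["tamura_coarseness"])
})

test_that("histogram features obey closed forms and bounds", {
  flat <- matrix(0.3, 16, 16)
  h <- histogram_features(flat)
  expect_equal(unname(h["hist_variance"]), 0)
  expect_equal(unname(h["hist_skewness"]), 0)
  expect_equal(unname(h["hist_kurtosis"]), 0)
  expect_equal(unname(h["hist_energy"]), 1)
  expect_equal(unname(h["hist_entropy"]), 0)
  ## two-level image: closed-form mean and variance
  two <- matrix(rep(c(0, 1), each = 128), 16, 16)
  h2 <- histogram_features(two)
  expect_equal(unname(h2["hist_mean"]), 0.5)
  expect_equal(unname(h2["hist_variance"]), 0.25)
  ## entropy never exceeds log2(bins)
  set.seed(2)
  h3 <- histogram_features(matrix(runif(256), 16, 16))
  expect_lte(h3[["hist_entropy"]], log2(32))
})

test_that("the full 80-feature vector is finite, stable and symmetric", {
  set.seed(4)
  img <- matrix(runif(64 * 64), 64, 64)
  v <- extract_features(img)
  expect_length(v, 80)
  expect_true(all(is.finite(v)))
  expect_identical(v, extract_features(img))  # deterministic
  expect_identical(feature_registry()$name, names(v))
  ## LBP and histogram families are flip invariant
  fams <- feature_registry()
  inv <- fams$name[fams$family %in% c("LBP", "lower_histogram",
                                      "higher_histogram")]
  vh <- extract_features(img[, rev(seq_len(64))])
  vv <- extract_features(img[rev(seq_len(64)), ])
  expect_equal(v[inv], vh[inv], tolerance = 1e-10)
  expect_equal(v[inv], vv[inv], tolerance = 1e-10)
  ## offset-averaged GLCM features survive 90-degree rotation
  glcm_avg <- c("glcm_contrast", "glcm_correlation", "glcm_energy",
                "glcm_homogeneity", "glcm_entropy")
  vr <- extract_features(t(img)[64:1, ])
  expect_equal(v[glcm_avg], vr[glcm_avg], tolerance = 1e-10)
})

test_that("feature filtering drops zero, NA and duplicate columns", {
  set.seed(6)
  mat <- matrix(rnorm(40 * 6), 40, 6)
  mat[, 2] <- 0                      # identically zero
  mat[, 4] <- mat[, 1]               # duplicate of an earlier column
  mat[3, 5] <- NA                    # contains NA
  keep <- suppressMessages(filter_features(mat))
  expect_equal(keep, c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  ## engineered 25 degenerate columns among 80 leave exactly 55
  base <- matrix(rnorm(30 * 55), 30, 55)
  degenerate <- cbind(
    matrix(0, 30, 10),                      # 10 zero columns
    base[, rep(1:10, length.out = 10)],     # 10 duplicates
    matrix(NA_real_, 30, 5)                 # 5 NA columns
  )
  ## originals precede their duplicates, honoring registry-order ties
  full <- cbind(base, degenerate)
  keep2 <- suppressMessages(filter_features(full))
  expect_equal(sum(keep2), 55)
  expect_error(suppressMessages(filter_features(matrix(0, 5, 3))),
               "retained 0")
})
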