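test_that("ReliefF weights follow the hit/miss update exactly", {
  ## constant column: zero diffs, zero weight
  x <- cbind(sig = c(0, 0, 1, 1), flat = rep(0.5, 4))
  y <- c("pCR", "pCR", "RD", "RD")
  rw <- suppressWarnings(relieff_rank(x, y, k_neighbors = 1))
  ## perfect separator: hit diffs 0, miss diffs 1 -> weight 1
  expect_equal(unname(rw$weights["sig"]), 1)
  expect_equal(unname(rw$weights["flat"]), 0)
  expect_equal(rw$ranking[1], 1)
  ## weights are bounded by [-1, 1] on random data
  set.seed(19)
  xr <- matrix(runif(30 * 12), 30, 12)
  yr <- rep(c("pCR", "RD"), 15)
  wr <- relieff_rank(xr, yr, k_neighbors = 5)$weights
  expect_true(all(wr >= -1 & wr <= 1))
  ## oversized neighborhoods clamp with a warning
  expect_warning(relieff_rank(x, y, k_neighbors = 10), "clamped")
  expect_error(relieff_rank(x[1:2, ], c("pCR", "RD")), "at least 2")
})

test_that("top-k selection ranks by weight with stable tie-breaks", {
  expect_equal(select_top(c(3, 1, 2), 2), c(1, 3))
  expect_equal(select_top(rep(0.5, 12), 8), 1:8)
  expect_error(select_top(c(1, 2), 5), "exceeds")
})

test_that("LOO prediction is exact on separable cohorts and order invariant", {
  set.seed(44)
  x <- rbind(matrix(rnorm(20, 0, 0.3), 10, 2),
             matrix(rnorm(20, 4, 0.3), 10, 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("pCR", "RD"), each = 10)
  pred <- loo_predict(x, y, model = "rbfSVM", k_top = 2, k_neighbors = 3)
  expect_equal(as.character(pred$predicted), y)
  expect_equal(pred$p_pCR + pred$p_RD, rep(1, 20), tolerance = 1e-9)
  ## permuting patient order permutes predictions identically (1NN is
  ## fully deterministic)
  pred1nn <- loo_predict(x, y, model = "1NN", k_top = 2, k_neighbors = 3)
  perm <- sample(20)
  pred2 <- loo_predict(x[perm, ], y[perm], model = "1NN", k_top = 2,
                       k_neighbors = 3)
  expect_equal(pred2$p_pCR, pred1nn$p_pCR[perm])
  expect_error(loo_predict(x[1:2, ], y[1:2]), "at least 3")
})

test_that("LOO feature selection never sees the held-out patient", {
  fc <- make_feature_cohort(8, 7, n_columns = 30, n_informative = 3,
                            effect = 3, seed = 5)
  pred <- loo_predict(fc$x, fc$y, model = "1NN", k_top = 3, k_neighbors = 3)
  sel <- attr(pred, "selected")
  ## perturbing the held-out patient's features leaves that fold's
  ## selection (fit inputs) unchanged
  x2 <- fc$x
  x2[4, ] <- x2[4, ] + 100
  pred2 <- loo_predict(x2, fc$y, model = "1NN", k_top = 3, k_neighbors = 3)
  expect_identical(attr(pred2, "selected")[[4]], sel[[4]])
})

test_that("binary metrics reproduce hand arithmetic and ROC properties", {
  ## perfect predictions
  y <- factor(rep(c("pCR", "RD"), each = 5), levels = c("pCR", "RD"))
  ev <- evaluate_binary(y, y, scores = c(rep(0.9, 5), rep(0.1, 5)))
  expect_equal(unname(ev$metrics), rep(1, 5))
  expect_equal(ev$auc, 1)
  ## single class in truth is an error
  expect_error(evaluate_binary(y[1:5], factor(rep("pCR", 5),
                                              levels = c("pCR", "RD"))),
               "both outcome classes")
  ## AUC agrees with pROC on random scores
  set.seed(55)
  truth <- factor(sample(c("pCR", "RD"), 60, replace = TRUE),
                  levels = c("pCR", "RD"))
  while (length(unique(truth)) < 2) truth <- sample(truth)
  sc <- runif(60)
  mine <- evaluate_binary(factor(ifelse(sc >= 0.5, "pCR", "RD"),
                                 levels = c("pCR", "RD")),
                          truth, scores = sc)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = truth, predictor = sc,
                                        levels = c("RD", "pCR"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(mine, ref, tolerance = 1e-9)
})

test_that("random scores give chance-level AUC on balanced labels", {
  set.seed(61)
  aucs <- replicate(100, {
    truth <- factor(rep(c("pCR", "RD"), each = 40), levels = c("pCR", "RD"))
    sc <- runif(80)
    evaluate_binary(factor(ifelse(sc >= 0.5, "pCR", "RD"),
                           levels = c("pCR", "RD")),
                    truth, scores = sc)$auc
  })
  expect_true(all(abs(aucs - 0.5) < 0.25))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("reported accuracy equals the recomputation from emitted counts", {
  fc <- make_feature_cohort(10, 8, n_columns = 40, n_informative = 4,
                            effect = 2, seed = 9)
  pred <- loo_predict(fc$x, fc$y, model = "linSVM", k_top = 4,
                      k_neighbors = 3)
  ev <- evaluate_binary(pred)
  cn <- ev$counts
  expect_equal(unname(ev$metrics["accuracy"]),
               unname((cn["TP"] + cn["TN"]) / sum(cn)))
})

test_that("attention overlays highlight exactly the selected pairs' cells", {
  g <- matrix(NA_integer_, 4, 4)
  g[1, 1] <- 1L; g[1, 2] <- 10L; g[4, 4] <- 7L
  m <- structure(list(slide_id = "s", grid = g, tile_size = 224),
                 class = "histology_map")
  base <- render_map(m)
  ## selected tumor-tumorTIL pair: exactly those two cells change
  ov <- attention_map(m, "c01_c10__ln_edge_count")
  changed <- which(apply(abs(ov - base) > 1e-12, c(1, 2), any),
                   arr.ind = TRUE)
  expect_equal(nrow(changed), 2)
  expect_setequal(paste(changed[, 1], changed[, 2]), c("1 1", "1 2"))
  ## pairs absent from the map leave the render untouched
  expect_identical(attention_map(m, rbind(c(2, 3))), base)
})
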