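#' ReliefF feature importance weights
#'
#' Classic multi-class ReliefF with every instance used as a reference
#' (m = n) and Manhattan diff on range-normalized features.  For each
#' instance, the k nearest same-class neighbors ("hits") subtract their
#' mean per-feature difference from the weight, and for each other class
#' the k nearest neighbors of that class ("misses") add their mean
#' difference weighted by the class prior P(C) / (1 - P(class(i))).
#' Weights lie in `[-1, 1]`; a feature constant across patients scores 0.
#'
#' @param x Numeric patients x features matrix.
#' @param y Class labels (2 or more classes, at least 2 instances each).
#' @param k_neighbors Neighbors per class (default 10); clamped with a
#'   warning when a class is too small.
#' @return List with `weights` (named numeric) and `ranking` (column
#'   indices sorted by decreasing weight, ties broken by column order).
#' @export
relieff_rank <- function(x, y, k_neighbors = 10) {
  x <- as.matrix(x)
  y <- factor(y)
  n <- nrow(x)
  p <- ncol(x)
  stopifnot(n == length(y))
  if (any(table(y) < 2)) stop("each class needs at least 2 instances")
  ## range-normalize to [0, 1]; constant columns become all-zero
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  xn <- sweep(sweep(x, 2, rng[1, ], `-`), 2, span, `/`)
  kmax <- min(table(y)) - 1
  if (k_neighbors > kmax) {
    warning("k_neighbors clamped from ", k_neighbors, " to ", kmax)
    k_neighbors <- kmax
  }
  d <- as.matrix(stats::dist(xn, method = "manhattan"))
  prior <- table(y) / n
  w <- numeric(p)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    ci <- y[i]
    ## hits
    hit_idx <- which(y == ci & seq_len(n) != i)
    kh <- min(k_neighbors, length(hit_idx))
    hits <- hit_idx[order(di[hit_idx])[seq_len(kh)]]
    hit_diff <- colMeans(abs(xn[hits, , drop = FALSE] -
                             xn[rep(i, kh), , drop = FALSE]))
    w <- w - hit_diff / n
    ## misses, per other class
    for (cm in levels(y)[levels(y) != ci]) {
      miss_idx <- which(y == cm)
      km <- min(k_neighbors, length(miss_idx))
      miss <- miss_idx[order(di[miss_idx])[seq_len(km)]]
      miss_diff <- colMeans(abs(xn[miss, , drop = FALSE] -
                                xn[rep(i, km), , drop = FALSE]))
      scale <- as.numeric(prior[cm]) / (1 - as.numeric(prior[ci]))
      w <- w + scale * miss_diff / n
    }
  }
  names(w) <- colnames(x)
  list(weights = w, ranking = order(-w, seq_len(p)))
}

#' Select the top-k ranked feature columns
#'
#' @param weights Result of [relieff_rank()] (or a bare numeric vector).
#' @param k Number of columns to keep (default 8).
#' @return Integer vector of the k highest-weight column indices, ties
#'   broken by column order.
#' @export
select_top <- function(weights, k = 8) {
  w <- if (is.list(weights)) weights$weights else weights
  if (k > length(w)) stop("k (", k, ") exceeds the number of columns")
  order(-w, seq_along(w))[seq_len(k)]
}

## binary probability model used inside LOO folds
fit_binary <- function(x, y, model, seed = 1) {
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("training set contains a single class")
  scaler <- fit_scaler(x)
  xs <- apply_scaler(x, scaler)
  fit <- switch(
    model,
    "1NN" = list(x = xs, y = y),
    "linSVM" = e1071::svm(xs, y, kernel = "linear", probability = TRUE,
                          scale = FALSE),
    "rbfSVM" = {
      gamma <- 1 / (ncol(xs) * max(mean(apply(xs, 2, stats::var)), 1e-12))
      e1071::svm(xs, y, kernel = "radial", cost = 10, gamma = gamma,
                 probability = TRUE, scale = FALSE)
    },
    "ensembleTree" = rusboost_fit(xs, y, seed = seed),
    stop("unknown model: ", model)
  )
  list(model = model, fit = fit, scaler = scaler, levels = levels(y))
}

predict_binary <- function(object, x) {
  xs <- apply_scaler(x, object$scaler)
  lv <- object$levels
  switch(
    object$model,
    "1NN" = {
      d2 <- outer(rowSums(xs^2), rowSums(object$fit$x^2), `+`) -
        2 * xs %*% t(object$fit$x)
      nn <- apply(d2, 1, which.min)
      p <- matrix(0, nrow(xs), length(lv), dimnames = list(NULL, lv))
      p[cbind(seq_len(nrow(xs)), match(object$fit$y[nn], lv))] <- 1
      p
    },
    "ensembleTree" = rusboost_prob(object$fit, xs)[, lv, drop = FALSE],
    {
      pr <- predict(object$fit, xs, probability = TRUE)
      attr(pr, "probabilities")[, lv, drop = FALSE]
    }
  )
}

#' Leave-one-out patient-level response prediction
#'
#' For each held-out patient, the remaining n - 1 patients drive the whole
#' training protocol: ReliefF ranking, top-k column selection, feature
#' standardization and model fitting.  The held-out patient is then scored
#' with the fold's model; the predicted class is the one with the larger
#' probability.  With `global_selection = TRUE`, ReliefF runs once on all
#' patients instead (the leakier variant, off by default).
#'
#' @param x Patients x feature-columns matrix.
#' @param y Outcomes, factor with levels `pCR`, `RD`.
#' @param model `"rbfSVM"` (default), `"1NN"`, `"linSVM"` or
#'   `"ensembleTree"`.
#' @param k_top Number of columns kept per fold (default 8).
#' @param k_neighbors ReliefF neighbors (default 10).
#' @param patient_id Optional identifiers.
#' @param global_selection Run ReliefF on the full cohort once.
#' @param seed Seed for stochastic learners.
#' @return data.frame with `patient_id`, `p_pCR`, `p_RD`, `predicted`,
#'   `truth`; attribute `selected` holds each fold's chosen columns.
#' @export
loo_predict <- function(x, y, model = "rbfSVM", k_top = 8, k_neighbors = 10,
                        patient_id = NULL, global_selection = FALSE,
                        seed = 1) {
  x <- as.matrix(x)
  y <- factor(y, levels = c("pCR", "RD"))
  n <- nrow(x)
  if (n < 3) stop("need at least 3 patients for LOO-CV")
  if (is.null(patient_id)) patient_id <- sprintf("P%03d", seq_len(n))
  global_sel <- if (global_selection) {
    select_top(suppressWarnings(relieff_rank(x, y, k_neighbors)), k_top)
  } else NULL
  p_pcr <- numeric(n)
  selected <- vector("list", n)
  for (i in seq_len(n)) {
    tr_x <- x[-i, , drop = FALSE]
    tr_y <- droplevels(y[-i])
    if (nlevels(tr_y) < 2) {
      stop("training set single-class after leaving out patient ",
           patient_id[i])
    }
    sel <- if (global_selection) global_sel else {
      select_top(suppressWarnings(relieff_rank(tr_x, tr_y, k_neighbors)),
                 k_top)
    }
    selected[[i]] <- sel
    fold_fit <- fit_binary(tr_x[, sel, drop = FALSE], tr_y, model,
                           seed = seed)
    pr <- predict_binary(fold_fit, x[i, sel, drop = FALSE])
    p_pcr[i] <- if ("pCR" %in% colnames(pr)) pr[1, "pCR"] else
      1 - pr[1, "RD"]
  }
  out <- data.frame(
    patient_id = patient_id,
    p_pCR = p_pcr,
    p_RD = 1 - p_pcr,
    predicted = factor(ifelse(p_pcr >= 0.5, "pCR", "RD"),
                       levels = c("pCR", "RD")),
    truth = y,
    stringsAsFactors = FALSE
  )
  attr(out, "selected") <- selected
  out
}

#' Binary evaluation: confusion counts, metrics, ROC and AUC
#'
#' pCR is the positive class.  Metrics are proportions in `[0, 1]`:
#' Accuracy = (TP + TN) / n, Sensitivity (recall) = TP / (TP + FN),
#' Specificity = TN / (TN + FP), Precision = TP / (TP + FP),
#' F1 = harmonic mean of precision and recall.  The ROC sweeps thresholds
#' over the unique predicted pCR probabilities plus {0, 1}; AUC by the
#' trapezoid rule.
#'
#' @param predictions data.frame from [loo_predict()], or a factor of
#'   predicted classes (then supply `truth` and optionally `scores`).
#' @param truth True outcomes (when `predictions` is not a data.frame).
#' @param scores Predicted pCR probabilities for the ROC (optional).
#' @return List with `counts` (TP, FP, TN, FN), `metrics` (accuracy,
#'   sensitivity, specificity, precision, f1), `roc` (data.frame fpr,
#'   tpr) and `auc` (NA when no scores are available).
#' @export
evaluate_binary <- function(predictions, truth = NULL, scores = NULL) {
  if (is.data.frame(predictions)) {
    truth <- predictions$truth
    scores <- predictions$p_pCR
    predictions <- predictions$predicted
  }
  truth <- factor(truth, levels = c("pCR", "RD"))
  predictions <- factor(predictions, levels = c("pCR", "RD"))
  if (any(table(truth) == 0)) {
    stop("both outcome classes must be present in the truth labels")
  }
  tp <- sum(predictions == "pCR" & truth == "pCR")
  fp <- sum(predictions == "pCR" & truth == "RD")
  tn <- sum(predictions == "RD" & truth == "RD")
  fn <- sum(predictions == "RD" & truth == "pCR")
  n <- tp + fp + tn + fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- tp / (tp + fn)
  f1 <- if (!is.na(precision) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  roc <- NULL
  auc <- NA_real_
  if (!is.null(scores)) {
    thr <- sort(unique(c(0, scores, 1)), decreasing = TRUE)
    pts <- t(vapply(thr, function(t) {
      pred_pos <- scores >= t
      c(fpr = sum(pred_pos & truth == "RD") / sum(truth == "RD"),
        tpr = sum(pred_pos & truth == "pCR") / sum(truth == "pCR"))
    }, numeric(2)))
    pts <- rbind(c(0, 0), pts, c(1, 1))
    pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
    auc <- sum(diff(pts[, 1]) * (utils::head(pts[, 2], -1) +
                                   utils::tail(pts[, 2], -1)) / 2)
    roc <- data.frame(fpr = pts[, 1], tpr = pts[, 2])
  }
  list(
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
    metrics = c(accuracy = (tp + tn) / n,
                sensitivity = recall,
                specificity = tn / (tn + fp),
                precision = precision,
                f1 = f1),
    roc = roc,
    auc = auc
  )
}

#' Attention overlay for the selected class pairs
#'
#' Highlights the grid cells of every cluster that contributes a node to
#' any selected pair's TME graph (i.e. all cells whose class belongs to a
#' selected pair).  Cells outside those classes render as in
#' [render_map()]; a map containing none of the selected classes yields
#' exactly the base render.
#'
#' @param map A `histology_map`.
#' @param selected_cols Character names of the selected (pair, feature)
#'   columns (format `cAA_cBB__feature`), or a two-column matrix of class
#'   pairs.
#' @param palette Rendering palette.
#' @param highlight RGB triple blended into highlighted cells.
#' @param alpha Blend weight of the highlight color.
#' @return H x W x 3 array in `[0, 1]`.
#' @export
attention_map <- function(map, selected_cols, palette = default_palette(),
                          highlight = c(1, 0.85, 0), alpha = 0.5) {
  pairs <- if (is.character(selected_cols)) selected_pair_ids(selected_cols)
  else as.matrix(selected_cols)
  base <- render_map(map, palette)
  cls <- unique(as.vector(pairs))
  sel <- which(!is.na(map$grid) & map$grid %in% cls, arr.ind = TRUE)
  if (nrow(sel) > 0) {
    for (ch in 1:3) {
      base[cbind(sel, ch)] <- (1 - alpha) * base[cbind(sel, ch)] +
        alpha * highlight[ch]
    }
  }
  base
}
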