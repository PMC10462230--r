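#' Stratified k-fold plan
#'
#' Shuffles tiles within each class and deals them to folds round-robin,
#' so per-class counts per fold differ by at most one.  Classes with fewer
#' tiles than folds trigger a warning (some folds will miss them).
#'
#' @param labels Vector of class labels (one per tile).
#' @param k Number of folds (default 8).
#' @param seed Integer seed; the same seed yields the same plan.
#' @return Integer vector of fold indices in `1..k`, with attribute
#'   `k`.
#' @export
stratified_kfold <- function(labels, k = 8, seed = 1) {
  n <- length(labels)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k (", k, ") exceeds the number of tiles (", n, ")")
  counts <- table(labels)
  if (any(counts < k)) {
    warning("class(es) with fewer tiles than folds: ",
            paste(names(counts)[counts < k], collapse = ", "),
            "; some folds will not contain them")
  }
  fold <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (cls in names(counts)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- (offset + length(idx)) %% k  # balance fold sizes overall
    }
  })
  attr(fold, "k") <- k
  fold
}

## z-score scaler fitted on training data; zero-variance columns pass through
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  list(mean = mu, sd = sdv)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$mean, `-`), 2, scaler$sd, `/`)
}

## RUSBoost: SAMME boosting of small decision trees, each round trained on
## a class-balanced random undersample drawn by current boosting weights
rusboost_fit <- function(x, y, rounds = 30, maxdepth = 5, seed = 1) {
  y <- factor(y)
  K <- nlevels(y)
  n <- nrow(x)
  w <- rep(1 / n, n)
  df <- data.frame(.y = y, x, check.names = FALSE)
  learners <- list()
  alphas <- numeric(0)
  with_seed(seed, {
    for (t in seq_len(rounds)) {
      ## random undersampling: per class, sample min-class-count rows with
      ## probability proportional to the boosting weights
      m <- min(table(y))
      take <- unlist(lapply(levels(y), function(l) {
        idx <- which(y == l)
        if (length(idx) <= m) idx
        else sample(idx, m, prob = w[idx] / sum(w[idx]))
      }))
      fit <- rpart::rpart(
        .y ~ ., data = df[take, , drop = FALSE], method = "class",
        control = rpart::rpart.control(maxdepth = maxdepth, cp = 0,
                                       minsplit = 4, xval = 0)
      )
      pred <- factor(predict(fit, df, type = "class"), levels = levels(y))
      err <- sum(w * (pred != y)) / sum(w)
      if (err >= 1 - 1 / K) next           # worse than chance: discard
      err <- max(err, 1e-10)
      alpha <- log((1 - err) / err) + log(K - 1)
      w <- w * exp(alpha * (pred != y))
      w <- w / sum(w)
      learners[[length(learners) + 1]] <- fit
      alphas[length(alphas) + 1] <- alpha
      if (err < 1e-8) break
    }
  })
  if (length(learners) == 0) stop("RUSBoost: no usable weak learner")
  structure(list(learners = learners, alphas = alphas, levels = levels(y)),
            class = "rusboost")
}

rusboost_prob <- function(object, x) {
  df <- data.frame(x, check.names = FALSE)
  votes <- matrix(0, nrow(x), length(object$levels),
                  dimnames = list(NULL, object$levels))
  for (i in seq_along(object$learners)) {
    pred <- predict(object$learners[[i]], df, type = "class")
    votes[cbind(seq_len(nrow(x)), match(pred, object$levels))] <-
      votes[cbind(seq_len(nrow(x)), match(pred, object$levels))] +
      object$alphas[i]
  }
  votes / rowSums(votes)
}

#' Train a tile-level histology classifier
#'
#' Features are z-scored with training statistics.  Four model families
#' are supported: 1-nearest-neighbor, linear SVM, radial-basis SVM
#' (cost 10, gamma = 1 / (d * mean feature variance), probabilities via
#' pairwise-coupled Platt scaling), and boosted trees with random
#' undersampling (RUSBoost).  SVMs use inverse-frequency class weights.
#'
#' @param features Numeric tiles x features matrix (training tiles).
#' @param labels Class labels (coerced to factor).
#' @param model One of `"1NN"`, `"linSVM"`, `"rbfSVM"`, `"ensembleTree"`.
#' @param seed Seed for the stochastic RUSBoost sampler.
#' @param ... Passed to the underlying fitter.
#' @return An object of class `tile_model`.
#' @export
train_tile_classifier <- function(features,
                                  labels,
                                  model = c("rbfSVM", "1NN", "linSVM",
                                            "ensembleTree"),
                                  seed = 1, ...) {
  model <- match.arg(model)
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2) {
    stop("training fold contains a single class")
  }
  labels <- droplevels(labels)
  features <- as.matrix(features)
  scaler <- fit_scaler(features)
  xs <- apply_scaler(features, scaler)
  inv_freq <- {
    tab <- table(labels)
    w <- as.numeric(sum(tab) / (length(tab) * tab))
    names(w) <- names(tab)
    w
  }
  fit <- switch(
    model,
    "1NN" = list(x = xs, y = labels),
    "linSVM" = e1071::svm(xs, labels, kernel = "linear", probability = TRUE,
                          class.weights = inv_freq, scale = FALSE, ...),
    "rbfSVM" = {
      gamma <- 1 / (ncol(xs) * max(mean(apply(xs, 2, stats::var)), 1e-12))
      e1071::svm(xs, labels, kernel = "radial", cost = 10, gamma = gamma,
                 probability = TRUE, class.weights = inv_freq,
                 scale = FALSE, ...)
    },
    "ensembleTree" = rusboost_fit(xs, labels, seed = seed, ...)
  )
  structure(list(model = model, fit = fit, scaler = scaler,
                 levels = levels(labels)),
            class = "tile_model")
}

## raw class probabilities over all trained classes
predict_class_probs <- function(object, features) {
  features <- as.matrix(features)
  xs <- apply_scaler(features, object$scaler)
  lv <- object$levels
  probs <- switch(
    object$model,
    "1NN" = {
      ## one-hot profile of the single nearest training tile
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
  probs
}

#' Per-tile probability profiles
#'
#' Predicts each tile's class (argmax over every trained class, ties to
#' the lowest class id) and its probability profile over the 16 tissue
#' classes.  When the model was trained with background as a 17th class,
#' the background probability is dropped and the tissue profile
#' renormalized to sum to 1.
#'
#' @param object A `tile_model`.
#' @param features Tiles x features matrix (same columns as training).
#' @param tile_ids Optional tile identifiers.
#' @return List with `predicted` (integer class ids) and `probs` (tiles x
#'   tissue-classes matrix, rows summing to 1; all-background rows are
#'   uniform).
#' @export
predict_profiles <- function(object, features, tile_ids = NULL) {
  probs <- predict_class_probs(object, features)
  ids <- as.integer(colnames(probs))
  ord <- order(ids)
  probs <- probs[, ord, drop = FALSE]
  ids <- ids[ord]
  predicted <- ids[max.col(probs, ties.method = "first")]
  tissue <- ids != background_class_id()
  tp <- probs[, tissue, drop = FALSE]
  rs <- rowSums(tp)
  uniform <- rs <= 0
  tp[uniform, ] <- 1 / ncol(tp)
  rs[uniform] <- 1
  tp <- tp / rs
  list(tile_id = tile_ids, predicted = predicted, probs = tp)
}

#' Stratified k-fold cross-validation of the tile classifier
#'
#' Runs the full leakage-free protocol: feature filtering, z-scoring and
#' model fitting use each round's training folds only.
#'
#' @param features Tiles x raw-features matrix.
#' @param labels Class labels.
#' @param k Folds (default 8).
#' @param model Model name, see [train_tile_classifier()].
#' @param seed Seed for the fold plan (and RUSBoost).
#' @return List with `fold` (the plan), `predicted`, `probs`,
#'   `fold_accuracy` and `mean_accuracy`.
#' @export
cross_validate_tiles <- function(features, labels, k = 8,
                                 model = "rbfSVM", seed = 1) {
  features <- as.matrix(features)
  labels <- factor(labels)
  fold <- stratified_kfold(labels, k = k, seed = seed)
  predicted <- integer(length(labels))
  probs <- NULL
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    keep <- suppressMessages(filter_features(features[tr, , drop = FALSE]))
    fit <- train_tile_classifier(features[tr, keep, drop = FALSE],
                                 labels[tr], model = model, seed = seed)
    pp <- predict_profiles(fit, features[!tr, keep, drop = FALSE])
    predicted[!tr] <- pp$predicted
    if (is.null(probs)) {
      probs <- matrix(NA_real_, length(labels), ncol(pp$probs),
                      dimnames = list(NULL, colnames(pp$probs)))
    }
    probs[!tr, ] <- pp$probs
    acc[f] <- mean(pp$predicted == as.integer(as.character(labels[!tr])))
  }
  list(fold = fold, predicted = predicted, probs = probs,
       fold_accuracy = acc, mean_accuracy = mean(acc))
}

#' Tile-level evaluation
#'
#' @param predicted Predicted class ids.
#' @param truth True class ids.
#' @param classes Class ids defining the confusion-matrix axes (default:
#'   classes present in `truth` or `predicted`).
#' @return List with `confusion` (truth x predicted), `accuracy`, and
#'   `per_class` data.frame (recall, precision, F1; `NA` for classes
#'   absent from `truth`).
#' @export
evaluate_tiles <- function(predicted, truth, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  cm <- table(truth = tf, predicted = pf)
  acc <- sum(diag(cm)) / sum(cm)
  per <- lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    if (tp + fn == 0) return(c(recall = NA, precision = NA, f1 = NA))
    recall <- tp / (tp + fn)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA
    f1 <- if (!is.na(precision) && (precision + recall) > 0) {
      2 * precision * recall / (precision + recall)
    } else NA
    c(recall = recall, precision = precision, f1 = f1)
  })
  per <- do.call(rbind, per)
  list(confusion = cm, accuracy = acc,
       per_class = data.frame(class = classes, per))
}
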