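# Tenfold cross-validation harness (with nested train/validation split and
# model selection) and the classical baselines: RBF-kernel SVM (SMO), KNN
# and L2-regularised logistic regression, each with a small grid search.

#' Cross-validation fold assignment
#'
#' Random partition into `k` disjoint folds covering all samples.  With
#' `groups` (e.g. subject ids), whole groups are assigned to folds so no
#' group straddles a fold boundary (leakage-free subject-level CV).
#'
#' @param n number of samples.
#' @param k number of folds.
#' @param seed RNG seed.
#' @param groups optional group id per sample.
#' @return integer vector of fold ids in `1..k`.
#' @export
cv_folds <- function(n, k = 10L, seed = 1L, groups = NULL) {
  if (k > n) stop_input("k exceeds the dataset size")
  with_seed(seed, {
    if (is.null(groups)) {
      sample(rep_len(seq_len(k), n))
    } else {
      g <- unique(groups)
      if (k > length(g)) stop_input("k exceeds the number of groups")
      gf <- sample(rep_len(seq_len(k), length(g)))
      gf[match(groups, g)]
    }
  })
}

#' Tenfold cross-validation of the hybrid network
#'
#' For each fold the held-out tenth is the test set; the remaining samples
#' are split 8:1 into train and validation, the model is trained with model
#' selection on validation accuracy, and test metrics are computed from the
#' selected weights.
#'
#' @param x images array `(H, W, C, frames, N)` or list of `image_sequence`s.
#' @param y integer labels 0/1.
#' @param model_factory function(seed) returning a fresh `eeg_model`.
#' @param cfg a [train_config()].
#' @param k folds (default 10).
#' @param seed seed driving fold assignment, initialisation and training.
#' @param groups optional subject ids for subject-level folds.
#' @return list with `folds` (per-fold `fold_result`) and `summary`
#'   (mean/sd of test accuracy, mean validation accuracy).
#' @export
crossvalidate <- function(x, y, model_factory, cfg = train_config(), k = 10L,
                          seed = 1L, groups = NULL) {
  if (is.list(x) && !is.array(x)) x <- sequences_to_array(x)
  y <- as.integer(y)
  n <- dim(x)[5]
  stopifnot(length(y) == n)
  fold_id <- cv_folds(n, k, derive_seed(seed, "folds"), groups)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold_id == f)
    rest <- which(fold_id != f)
    # nested 8:1 train/validation split of the remaining 9 folds
    val_take <- max(1L, round(length(rest) / 9))
    val_idx <- with_seed(derive_seed(seed, "val", f),
                         sample(rest, val_take))
    train_idx <- setdiff(rest, val_idx)
    model <- model_factory(derive_seed(seed, "init", f))
    cfg_f <- cfg; cfg_f$seed <- derive_seed(seed, "train", f)
    fit <- train_model(model,
                       x[, , , , train_idx, drop = FALSE], y[train_idx], cfg_f,
                       x[, , , , val_idx, drop = FALSE], y[val_idx])
    pred <- predict(fit, x[, , , , test_idx, drop = FALSE], type = "class")
    prob <- predict(fit, x[, , , , test_idx, drop = FALSE], type = "prob")
    test_acc <- mean(pred == y[test_idx])
    test_loss <- -mean(log(pmax(prob[cbind(seq_along(test_idx), y[test_idx] + 1L)], 1e-12)))
    h <- fit$history
    folds[[f]] <- structure(list(
      fold_index = f,
      train_acc = tail(h$train_acc, 1), train_loss = tail(h$train_loss, 1),
      val_acc = if (length(h$val_acc)) max(h$val_acc) else NA_real_,
      test_acc = test_acc, test_loss = test_loss,
      confusion = table(factor(y[test_idx], levels = 0:1),
                        factor(pred, levels = 0:1)),
      n_test = length(test_idx), best_epoch = fit$best_epoch),
      class = "fold_result")
  }
  acc <- vapply(folds, `[[`, 0, "test_acc")
  val <- vapply(folds, `[[`, 0, "val_acc")
  list(folds = folds,
       summary = list(mean_test_acc = mean(acc), sd_test_acc = sd(acc),
                      mean_val_acc = mean(val), fold_acc = acc))
}

# ---- baselines --------------------------------------------------------------

# Gaussian-kernel matrix
rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

# Binary C-SVC trained by a simplified SMO (Platt-style working pair
# selection with random second choice), adequate for desk-scale problems.
svm_fit <- function(x, y, C = 1, gamma = 1 / ncol(x), max_passes = 8,
                    tol = 1e-3, seed = 1L) {
  yy <- ifelse(y == 1, 1, -1)
  n <- nrow(x)
  K <- rbf_kernel(x, x, gamma)
  alpha <- numeric(n); b <- 0
  with_seed(seed, {
    passes <- 0
    while (passes < max_passes) {
      changed <- 0L
      for (i in seq_len(n)) {
        Ei <- sum(alpha * yy * K[, i]) + b - yy[i]
        if ((yy[i] * Ei < -tol && alpha[i] < C) ||
            (yy[i] * Ei > tol && alpha[i] > 0)) {
          j <- sample(setdiff(seq_len(n), i), 1)
          Ej <- sum(alpha * yy * K[, j]) + b - yy[j]
          ai_old <- alpha[i]; aj_old <- alpha[j]
          if (yy[i] != yy[j]) {
            L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
          } else {
            L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
          }
          if (L >= H) next
          eta <- 2 * K[i, j] - K[i, i] - K[j, j]
          if (eta >= 0) next
          aj <- aj_old - yy[j] * (Ei - Ej) / eta
          aj <- min(H, max(L, aj))
          if (abs(aj - aj_old) < 1e-5) next
          ai <- ai_old + yy[i] * yy[j] * (aj_old - aj)
          alpha[i] <- ai; alpha[j] <- aj
          b1 <- b - Ei - yy[i] * (ai - ai_old) * K[i, i] -
            yy[j] * (aj - aj_old) * K[i, j]
          b2 <- b - Ej - yy[i] * (ai - ai_old) * K[i, j] -
            yy[j] * (aj - aj_old) * K[j, j]
          b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else (b1 + b2) / 2
          changed <- changed + 1L
        }
      }
      passes <- if (changed == 0L) passes + 1 else 0
    }
  })
  list(x = x, yy = yy, alpha = alpha, b = b, gamma = gamma)
}

svm_predict <- function(fit, xnew) {
  K <- rbf_kernel(xnew, fit$x, fit$gamma)
  as.integer(drop(K %*% (fit$alpha * fit$yy)) + fit$b > 0)
}

knn_predict <- function(xtr, ytr, xte, k) {
  d2 <- outer(rowSums(xte^2), rowSums(xtr^2), "+") - 2 * tcrossprod(xte, xtr)
  apply(d2, 1, function(row) {
    nb <- ytr[order(row)[seq_len(k)]]
    as.integer(mean(nb) >= 0.5)
  })
}

logreg_fit_predict <- function(xtr, ytr, xte, C) {
  # glmnet ridge; lambda chosen as 1/(n*C) to mirror the usual C convention
  lam <- 1 / (nrow(xtr) * C)
  # suppress glmnet's small-class-count notices on desk-scale folds
  fit <- suppressWarnings(
    glmnet::glmnet(xtr, factor(ytr, levels = 0:1), family = "binomial",
                   alpha = 0, lambda = lam, standardize = FALSE))
  as.integer(drop(predict(fit, xte, type = "class", s = lam)))
}

#' Classical baselines with tenfold cross-validation
#'
#' Flattened trial feature vectors are standardised per feature on each
#' training split.  Hyperparameters are grid-searched by inner 3-fold CV on
#' the training split: SVM over `(C, gamma)`, KNN over `k`, logistic
#' regression over `C` in the log range `[1e-2, 1e3]`.
#'
#' @param features N x p numeric matrix (one flattened vector per trial).
#' @param labels integer 0/1 labels.
#' @param method `"svm"`, `"knn"` or `"logreg"`.
#' @param k CV folds (default 10).
#' @param seed RNG seed.
#' @param groups optional subject ids for subject-level folds.
#' @return list with per-fold accuracies, their mean, and the chosen
#'   hyperparameters per fold.
#' @export
baseline_fit <- function(features, labels, method = c("svm", "knn", "logreg"),
                         k = 10L, seed = 1L, groups = NULL) {
  if (!is.character(method) || !(method[1] %in% c("svm", "knn", "logreg")))
    stop_input(sprintf("unknown baseline method '%s'", as.character(method)[1]))
  method <- match.arg(method)
  features <- as.matrix(features)
  labels <- as.integer(labels)
  n <- nrow(features)
  if (length(unique(labels)) < 2) stop_input("need both classes present")
  fold_id <- cv_folds(n, k, derive_seed(seed, "bfolds"), groups)
  accs <- numeric(k); chosen <- vector("list", k)
  for (f in seq_len(k)) {
    te <- which(fold_id == f); tr <- which(fold_id != f)
    mu <- colMeans(features[tr, , drop = FALSE])
    sg <- apply(features[tr, , drop = FALSE], 2, sd); sg[sg == 0] <- 1
    xtr <- scale(features[tr, , drop = FALSE], mu, sg)
    xte <- scale(features[te, , drop = FALSE], mu, sg)
    ytr <- labels[tr]
    pick <- tune_baseline(xtr, ytr, method, derive_seed(seed, "tune", f))
    chosen[[f]] <- pick
    pred <- switch(method,
      svm = svm_predict(svm_fit(xtr, ytr, C = pick$C, gamma = pick$gamma,
                                seed = derive_seed(seed, "svm", f)), xte),
      knn = knn_predict(xtr, ytr, xte, pick$k),
      logreg = logreg_fit_predict(xtr, ytr, xte, pick$C))
    accs[f] <- mean(pred == labels[te])
  }
  list(method = method, fold_acc = accs, mean_acc = mean(accs), chosen = chosen)
}

# inner 3-fold grid search on the training split
tune_baseline <- function(xtr, ytr, method, seed) {
  grids <- switch(method,
    svm = expand.grid(C = c(1, 10, 100), gamma = c(0.1, 1, 10) / ncol(xtr)),
    knn = expand.grid(k = c(1, 3, 5, 9)),
    logreg = expand.grid(C = 10^seq(-2, 3, by = 1)))
  if (nrow(grids) == 1) return(as.list(grids[1, , drop = FALSE]))
  inner <- cv_folds(length(ytr), 3L, seed)
  score <- numeric(nrow(grids))
  for (gi in seq_len(nrow(grids))) {
    g <- grids[gi, , drop = FALSE]
    acc <- numeric(3)
    for (f in 1:3) {
      te <- which(inner == f); tr <- which(inner != f)
      if (length(unique(ytr[tr])) < 2) { acc[f] <- NA; next }
      pred <- switch(method,
        svm = svm_predict(svm_fit(xtr[tr, , drop = FALSE], ytr[tr], C = g$C,
                                  gamma = g$gamma, max_passes = 3,
                                  seed = derive_seed(seed, gi, f)),
                          xtr[te, , drop = FALSE]),
        knn = knn_predict(xtr[tr, , drop = FALSE], ytr[tr],
                          xtr[te, , drop = FALSE], g$k),
        logreg = logreg_fit_predict(xtr[tr, , drop = FALSE], ytr[tr],
                                    xtr[te, , drop = FALSE], g$C))
      acc[f] <- mean(pred == ytr[te])
    }
    score[gi] <- mean(acc, na.rm = TRUE)
  }
  as.list(grids[which.max(score), , drop = FALSE])
}
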