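# Architecture algebra, parameter counting, LSTM step, training behaviour,
# CV partitioning, baselines.

test_that("layer-size algebra matches the conv/pool recursion for A-D", {
  for (nm in c("A", "B", "C", "D")) {
    cfg <- cnn_config(nm)
    st <- cnn_shape_table(cfg)
    orc <- shape_oracle(cfg$conv_counts, cfg$conv_channels)
    expect_equal(attr(st, "flatten"), unname(orc["flatten"]), label = nm)
    expect_equal(st$side[nrow(st)], unname(orc["side"]), label = nm)
  }
  expect_equal(attr(cnn_shape_table(cnn_config("C")), "flatten"), 2048)
  expect_equal(attr(cnn_shape_table(cnn_config("A")), "flatten"), 8192)
  expect_error(cnn_config("E"), "unknown")
  # a 10x10 input cannot pool three times to integer sizes
  expect_error(cnn_shape_table(cnn_config("C"), image_size = 10L),
               "non-integer")
})

test_that("parameter counts equal the closed-form layer sums", {
  for (nm in c("A", "B", "C", "D")) {
    cfg <- cnn_config(nm)
    m <- build_model(cfg, seed = 1)
    expect_equal(count_parameters(m),
                 param_count_oracle(cfg$conv_counts, cfg$conv_channels),
                 label = nm)
  }
  # spot values: first conv layer and the conv stack of C
  m <- build_model(cnn_config("C"), seed = 1)
  expect_equal(length(m$weights$conv_w[[1]]) + length(m$weights$conv_b[[1]]), 896)
  conv_total <- sum(vapply(seq_along(m$weights$conv_w), function(i)
    length(m$weights$conv_w[[i]]) + length(m$weights$conv_b[[i]]), 0))
  expect_equal(conv_total, 139424)
  lstm_total <- sum(vapply(c("lstm_wf", "lstm_wi", "lstm_wc", "lstm_wo",
                             "lstm_bf", "lstm_bi", "lstm_bc", "lstm_bo"),
                           function(nm) length(m$weights[[nm]]), 0))
  expect_equal(lstm_total, 4 * (512 * 128 + 128^2 + 128))
})

test_that("the network LSTM step reproduces the gate equations", {
  set.seed(21)
  H <- 5; In <- 7
  w <- list()
  for (nm in c("lstm_wf", "lstm_wi", "lstm_wc", "lstm_wo"))
    w[[nm]] <- matrix(runif(H * (H + In), -0.3, 0.3), H)
  for (nm in c("lstm_bf", "lstm_bi", "lstm_bc", "lstm_bo"))
    w[[nm]] <- runif(H, -0.1, 0.1)
  x <- runif(In, -1, 1); h <- runif(H, -0.5, 0.5); c <- runif(H, -0.5, 0.5)
  got <- lstm_step(w, x, h, c)
  ref <- lstm_oracle(w, x, h, c)
  expect_equal(as.numeric(got$h), ref$h, tolerance = 1e-6)
  expect_equal(as.numeric(got$c), ref$c, tolerance = 1e-6)
  # a second chained step stays in agreement
  got2 <- lstm_step(w, x, got$h, got$c)
  ref2 <- lstm_oracle(w, x, ref$h, ref$c)
  expect_equal(as.numeric(got2$h), ref2$h, tolerance = 1e-6)
})

test_that("softmax rows normalise and forward pass has the contracted shape", {
  set.seed(2)
  X <- array(runif(32 * 32 * 3 * 6 * 4), dim = c(32, 32, 3, 6, 4))
  m <- build_model(cnn_config("A"), seed = 3)
  p <- predict(m, X, type = "prob")
  expect_equal(dim(p), c(4L, 2L))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
})

test_that("analytic gradients match finite differences (double-precision tail)", {
  set.seed(3)
  n <- 3
  X <- array(runif(8 * 8 * 3 * 2 * n), dim = c(8, 8, 3, 2, n))
  y <- c(0L, 1L, 1L)
  m <- build_model(cnn_config("A"), lstm_hidden = 6, n_frames = 2,
                   image_size = 8, seed = 5)
  g <- eegtopoclass:::nn_grad_cpp(m$weights, X, y, m$cnn$conv_counts,
                                  m$cnn$conv_channels, 2L, 8L)
  loss_of <- function(w) {
    mm <- m; mm$weights <- w
    p <- predict(mm, X, type = "prob")
    -mean(log(p[cbind(1:n, y + 1)]))
  }
  eps <- 5e-3
  set.seed(11)
  for (field in c("fc_w", "lstm_wf", "out_w")) {
    for (i in 1:4) {
      idx <- sample(length(m$weights[[field]]), 1)
      wp <- m$weights; wm <- m$weights
      wp[[field]][idx] <- wp[[field]][idx] + eps
      wm[[field]][idx] <- wm[[field]][idx] - eps
      gn <- (loss_of(wp) - loss_of(wm)) / (2 * eps)
      ga <- g[[field]][idx]
      expect_lt(abs(gn - ga) / max(abs(gn), abs(ga), 1e-3), 0.02,
                label = sprintf("%s[%d]", field, idx))
    }
  }
})

test_that("training contracts: zero epochs, determinism, single class, memorisation", {
  set.seed(4)
  n <- 12
  X <- array(0, dim = c(16, 16, 3, 2, n))
  y <- rep(0:1, each = n / 2)
  for (i in 1:n)
    X[, , , , i] <- (if (y[i] == 1) 0.75 else 0.25) +
      array(rnorm(16 * 16 * 3 * 2, sd = 0.02), c(16, 16, 3, 2))
  m <- build_model(cnn_config("A"), n_frames = 2, image_size = 16, seed = 5)
  m0 <- train_model(m, X, y, train_config(epochs = 0))
  expect_identical(m0$weights, m$weights)
  expect_length(m0$history$train_loss, 0)
  expect_error(train_model(m, X, rep(1L, n), train_config(epochs = 1)),
               "both classes")
  cfg <- train_config(epochs = 3, batch_size = 4, patience = NULL, seed = 9)
  f1 <- train_model(m, X, y, cfg)
  f2 <- train_model(m, X, y, cfg)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  # trivially separable class-constant images are memorised
  cfg2 <- train_config(epochs = 40, batch_size = 4, dropout = 0,
                       patience = NULL, seed = 10)
  fit <- train_model(m, X, y, cfg2)
  expect_equal(tail(fit$history$train_acc, 1), 1.0)
  expect_equal(predict(fit, X, type = "class"), y)
})

test_that("cv_folds partitions trials and respects groups", {
  f <- cv_folds(100, 10, seed = 3)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) == 10))
  expect_error(cv_folds(5, 10), "exceeds")
  groups <- rep(sprintf("s%02d", 1:20), each = 5)
  fg <- cv_folds(100, 10, seed = 4, groups = groups)
  for (g in unique(groups))
    expect_length(unique(fg[groups == g]), 1)
  # property over sizes: disjoint and exhaustive
  for (n in c(11, 37, 100)) {
    f <- cv_folds(n, 5, seed = n)
    expect_length(f, n)
    expect_equal(sort(unique(f)), 1:5)
  }
})

test_that("baselines separate Gaussian blobs and are at chance on permuted labels", {
  set.seed(12)
  n <- 60
  x <- rbind(matrix(rnorm(n / 2 * 8, 0), n / 2),
             matrix(rnorm(n / 2 * 8, 3), n / 2))
  y <- rep(0:1, each = n / 2)
  for (m in c("svm", "knn", "logreg")) {
    r <- baseline_fit(x, y, m, k = 5, seed = 1)
    expect_gte(r$mean_acc, 0.95)
  }
  yperm <- with_seed(5, sample(y))
  accs <- vapply(c("knn", "logreg"), function(m)
    baseline_fit(x, yperm, m, k = 5, seed = 2)$mean_acc, 0)
  expect_true(all(abs(accs - 0.5) < 0.2))
  expect_error(baseline_fit(x, y, "forest"), "unknown")
  # 1-NN on its own training set is perfect
  expect_equal(eegtopoclass:::knn_predict(x, y, x, 1), y)
})

test_that("classification accuracy is non-decreasing in the complexity effect (on average)", {
  acc_at <- function(effect, seed) {
    cfg <- synth_config(6, trials_per_subject = 3, complexity_effect = effect,
                        theta_power_effect = 1, seed = seed)
    feats <- extract_cohort_features(generate_cohort(cfg),
                                     pipeline_config(feature = "fft",
                                                     max_trials = 3, seed = seed))
    bm <- eegtopoclass:::frames_to_baseline_matrix(feats$frames)
    baseline_fit(bm, feats$labels, "logreg", k = 5, seed = seed)$mean_acc
  }
  effects <- c(0, 0.3, 0.8)
  means <- vapply(effects, function(e)
    mean(vapply(1:3, function(s) acc_at(e, 500 + s), 0)), 0)
  expect_lt(abs(means[1] - 0.5), 0.2)        # null: chance
  expect_gt(means[3], means[1] + 0.2)        # strong effect clearly above null
  expect_gte(means[3], means[2] - 0.05)      # monotone up to simulation noise
})

test_that("fuzzy-entropy features classify at least as well as FFT features (soft ordering)", {
  cfg <- synth_config(6, trials_per_subject = 3, complexity_effect = 0.5,
                      seed = 77)
  cohort <- generate_cohort(cfg)
  acc_for <- function(feature) {
    feats <- extract_cohort_features(cohort,
                                     pipeline_config(feature = feature,
                                                     max_trials = 3, seed = 77))
    bm <- eegtopoclass:::frames_to_baseline_matrix(feats$frames)
    baseline_fit(bm, feats$labels, "logreg", k = 5, seed = 78)$mean_acc
  }
  fz <- acc_for("fuzzyen"); ft <- acc_for("fft")
  # reported comparison mirroring the benchmark table's ordering; soft bound
  expect_gte(fz, ft - 0.1)
})
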