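# Pipeline orchestration: prep -> features -> images -> cross-validated
# classification (hybrid DNN and/or classical baselines) -> group statistics,
# reproducible from (config, seed).

#' Pipeline configuration
#'
#' Defaults mirror the method's stated values: theta/alpha/beta bands,
#' 1400 ms trials (max 55), 400/200 ms sliding windows, fuzzy entropy with
#' r = 0.25 SD and m = 2, 32 x 32 mesh, CNN config C with LSTM-128, Adam
#' (1e-3, 0.9/0.999), batch 32, dropout 0.5, tenfold CV.
#'
#' @param feature `"fuzzyen"` or `"fft"`.
#' @param cnn_name CNN configuration name (A-D).
#' @param trial_length,max_trials trial segmentation parameters.
#' @param window,step sliding-window parameters (seconds).
#' @param bands list of [band_definition()]s.
#' @param fuzzyen a [fuzzyen_params()].
#' @param train a [train_config()].
#' @param k CV folds.
#' @param cv_level `"trial"` (default; mirrors random trial-level splitting)
#'   or `"subject"` (leakage-free grouping).
#' @param grid_size topographic mesh side.
#' @param lstm_hidden LSTM hidden size.
#' @param drop_labels channels removed during prep.
#' @param montage an `eeg_montage` (default the 60-channel template).
#' @param seed master seed.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(feature = c("fuzzyen", "fft"),
                            cnn_name = "C",
                            trial_length = 1.4, max_trials = 55,
                            window = 0.4, step = 0.2,
                            bands = default_bands(),
                            fuzzyen = fuzzyen_params(),
                            train = train_config(),
                            k = 10L, cv_level = c("trial", "subject"),
                            grid_size = 32L, lstm_hidden = 128L,
                            drop_labels = ocular_labels(),
                            montage = NULL, seed = 1L) {
  feature <- match.arg(feature)
  cv_level <- match.arg(cv_level)
  cnn <- cnn_config(cnn_name)   # validates the name before any compute
  if (is.null(montage)) montage <- template_montage()
  structure(list(feature = feature, cnn = cnn, trial_length = trial_length,
                 max_trials = max_trials, window = window, step = step,
                 bands = bands, fuzzyen = fuzzyen, train = train, k = as.integer(k),
                 cv_level = cv_level, grid_size = as.integer(grid_size),
                 lstm_hidden = as.integer(lstm_hidden),
                 drop_labels = drop_labels, montage = montage,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from JSON
#'
#' Any subset of the [pipeline_config()] fields may be given; bands as
#' `{name, f_lo, f_hi}` objects, the montage as a montage file path.
#'
#' @param path JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("config file not found: %s", path))
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  args <- list()
  for (nm in c("feature", "cnn_name", "trial_length", "max_trials", "window",
               "step", "k", "cv_level", "grid_size", "lstm_hidden", "seed"))
    if (!is.null(j[[nm]])) args[[nm]] <- j[[nm]]
  if (!is.null(j$bands))
    args$bands <- lapply(j$bands, function(b) band_definition(b$name, b$f_lo, b$f_hi))
  if (!is.null(j$fuzzyen))
    args$fuzzyen <- do.call(fuzzyen_params, j$fuzzyen)
  if (!is.null(j$train))
    args$train <- do.call(train_config, j$train)
  if (!is.null(j$montage_file))
    args$montage <- read_montage(j$montage_file)
  if (!is.null(j$drop_labels)) args$drop_labels <- unlist(j$drop_labels)
  do.call(pipeline_config, args)
}

#' Stage 1-2: prep and per-trial features for a cohort
#'
#' Prunes channels, segments trials, and extracts per-window feature frames
#' per trial.
#'
#' @param recordings list of `recording`s.
#' @param cfg a [pipeline_config()].
#' @param progress print per-stage counts.
#' @return list with `frames` (per trial: list of `feature_frame`s),
#'   `labels`, `subjects`, `channel_labels`.
#' @export
extract_cohort_features <- function(recordings, cfg, progress = FALSE) {
  frames <- list(); labels <- integer(0); subjects <- character(0)
  channel_labels <- NULL
  for (rec in recordings) {
    pruned <- if (length(intersect(cfg$drop_labels, rec$channel_labels)))
      remove_channels(rec, intersect(cfg$drop_labels, rec$channel_labels)) else rec
    if (is.null(channel_labels)) channel_labels <- pruned$channel_labels
    trials <- segment_trials(pruned, cfg$trial_length, cfg$max_trials)
    for (tr in trials) {
      frames[[length(frames) + 1L]] <-
        trial_features(tr, cfg$bands, cfg$feature, cfg$fuzzyen,
                       cfg$window, cfg$step)
      labels <- c(labels, rec$label)
      subjects <- c(subjects, rec$subject_id)
    }
    if (progress)
      message(sprintf("features: %s -> %d trials", rec$subject_id, length(trials)))
  }
  list(frames = frames, labels = labels, subjects = subjects,
       channel_labels = channel_labels)
}

#' Raw (un-normalised) per-trial band grids
#'
#' Renders every feature frame through the cached topographic operator.
#'
#' @param frames list (per trial) of lists of `feature_frame`s.
#' @param montage an `eeg_montage` (projected on the fly if needed).
#' @param grid_size mesh side.
#' @return array `(pixels, bands, windows, trials)`.
#' @export
frames_to_raw_grids <- function(frames, montage, grid_size = 32L) {
  stopifnot(inherits(montage, "eeg_montage"))
  if (is.null(montage$pos2d)) montage <- aep_project(montage)
  op <- topo_operator(montage$pos2d, grid_size)
  ntr <- length(frames)
  nwin <- length(frames[[1]])
  nb <- ncol(frames[[1]][[1]]$values)
  raw <- array(0, dim = c(grid_size^2, nb, nwin, ntr))
  for (i in seq_len(ntr)) {
    for (w in seq_len(nwin)) {
      raw[, , w, i] <- op$W %*% frames[[i]][[w]]$values
    }
  }
  raw
}

# normalise a subset of raw grids with per-band (lo, hi), optionally apply
# the per-(pixel, band) Normalize transform (mu, sdv fitted on the training
# split), and emit the (H, W, C, frames, N) array the network consumes
raw_to_x <- function(raw, idx, lo, hi, grid_size, mu = NULL, sdv = NULL) {
  nb <- dim(raw)[2]; nwin <- dim(raw)[3]
  X <- array(0, dim = c(grid_size, grid_size, nb, nwin, length(idx)))
  for (b in seq_len(nb)) {
    denom <- hi[b] - lo[b]
    v <- raw[, b, , idx, drop = FALSE]
    v <- if (denom <= 0) v * 0 else pmin(1, pmax(0, (v - lo[b]) / denom))
    if (!is.null(mu)) {
      s <- sdv[, b]
      s[s < 1e-6] <- 1                       # constant (background) pixels
      v <- (v - mu[, b]) / s
    }
    X[, , b, , ] <- v
  }
  X
}

# per-(pixel, band) mean and SD of the [0,1]-mapped training grids
fit_pixel_norm <- function(raw, train_idx, lo, hi) {
  nb <- dim(raw)[2]
  mu <- matrix(0, dim(raw)[1], nb); sdv <- matrix(0, dim(raw)[1], nb)
  for (b in seq_len(nb)) {
    denom <- hi[b] - lo[b]
    v <- raw[, b, , train_idx, drop = FALSE]
    v <- if (denom <= 0) v * 0 else pmin(1, pmax(0, (v - lo[b]) / denom))
    dim(v) <- c(dim(raw)[1], length(v) / dim(raw)[1])
    mu[, b] <- rowMeans(v)
    sdv[, b] <- sqrt(rowMeans((v - mu[, b])^2))
  }
  list(mu = mu, sdv = sdv)
}

#' Cross-validated hybrid-DNN evaluation from raw band grids
#'
#' Tenfold CV where, inside each fold, the per-band min-max normaliser and a
#' per-(pixel, band) standardisation (the classifier's Normalize input
#' transform) are fitted on the training split only (validation/test values
#' clip to `[0, 1]` before standardising), the model is selected on the
#' nested validation split, and the test fold is scored with the selected
#' weights.
#'
#' @param raw array from [frames_to_raw_grids()].
#' @param labels 0/1 labels per trial.
#' @param cfg a [pipeline_config()].
#' @param groups optional subject ids (used when `cfg$cv_level == "subject"`).
#' @return as [crossvalidate()]: `folds` + `summary`.
#' @export
dnn_crossvalidate <- function(raw, labels, cfg, groups = NULL) {
  n <- dim(raw)[4]
  gs <- cfg$grid_size
  y <- as.integer(labels)
  use_groups <- if (cfg$cv_level == "subject") groups else NULL
  fold_id <- cv_folds(n, cfg$k, derive_seed(cfg$seed, "folds"), use_groups)
  folds <- vector("list", cfg$k)
  for (f in seq_len(cfg$k)) {
    test_idx <- which(fold_id == f)
    rest <- which(fold_id != f)
    val_take <- max(1L, round(length(rest) / 9))
    val_idx <- with_seed(derive_seed(cfg$seed, "val", f), sample(rest, val_take))
    train_idx <- setdiff(rest, val_idx)
    lo <- numeric(dim(raw)[2]); hi <- numeric(dim(raw)[2])
    for (b in seq_along(lo)) {
      v <- raw[, b, , train_idx]
      lo[b] <- min(v); hi[b] <- max(v)
    }
    pn <- fit_pixel_norm(raw, train_idx, lo, hi)
    xtr <- raw_to_x(raw, train_idx, lo, hi, gs, pn$mu, pn$sdv)
    xva <- raw_to_x(raw, val_idx, lo, hi, gs, pn$mu, pn$sdv)
    xte <- raw_to_x(raw, test_idx, lo, hi, gs, pn$mu, pn$sdv)
    model <- build_model(cfg$cnn, cfg$lstm_hidden, dim(raw)[3], gs,
                         seed = derive_seed(cfg$seed, "init", f))
    cfg_f <- cfg$train; cfg_f$seed <- derive_seed(cfg$seed, "train", f)
    fit <- train_model(model, xtr, y[train_idx], cfg_f, xva, y[val_idx])
    pred <- predict(fit, xte, type = "class")
    test_acc <- mean(pred == y[test_idx])
    h <- fit$history
    folds[[f]] <- structure(list(
      fold_index = f,
      train_acc = tail(h$train_acc, 1), train_loss = tail(h$train_loss, 1),
      val_acc = if (length(h$val_acc)) max(h$val_acc) else NA_real_,
      test_acc = test_acc,
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

# flattened per-trial feature vectors for the classical baselines
frames_to_baseline_matrix <- function(frames) {
  t(vapply(frames, function(fr) {
    unlist(lapply(fr, function(x) as.numeric(x$values)), use.names = FALSE)
  }, numeric(length(frames[[1]]) * length(frames[[1]][[1]]$values))))
}

# per-subject channel-mean feature matrices for the group stats stage
subject_channel_means <- function(frames, labels, subjects) {
  us <- unique(subjects)
  nch <- nrow(frames[[1]][[1]]$values)
  m <- matrix(0, length(us), nch)
  lab <- integer(length(us))
  for (i in seq_along(us)) {
    idx <- which(subjects == us[i])
    acc <- 0
    for (j in idx) for (fr in frames[[j]]) acc <- acc + rowMeans(fr$values)
    m[i, ] <- acc / (length(idx) * length(frames[[idx[1]]]))
    lab[i] <- labels[idx[1]]
  }
  list(matrix = m, labels = lab, subjects = us)
}

#' Run the full pipeline
#'
#' prep -> features -> images -> cross-validated classification (hybrid DNN
#' and optionally the classical baselines) -> channel-wise group statistics.
#' Fully reproducible from `(cfg, recordings)`.
#'
#' @param cfg a [pipeline_config()].
#' @param recordings list of `recording`s (e.g. [generate_cohort()] or
#'   [read_cohort()]).
#' @param run character subset of `c("dnn", "baselines", "stats")`.
#' @param out_dir optional directory for JSON metrics and the comparison
#'   table.
#' @param progress logical.
#' @return results bundle: features stage counts, `dnn`, `baselines`,
#'   `stats`, and `comparison` table.
#' @export
run_pipeline <- function(cfg, recordings, run = c("dnn", "stats"),
                         out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_input(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e))))
  }
  feats <- stage("features", extract_cohort_features(recordings, cfg, progress))
  res <- list(config = list(feature = cfg$feature, cnn = cfg$cnn$name,
                            k = cfg$k, seed = cfg$seed),
              n_trials = length(feats$frames),
              n_subjects = length(unique(feats$subjects)))
  montage <- aep_project(cfg$montage)
  if ("dnn" %in% run) {
    raw <- stage("images", frames_to_raw_grids(feats$frames, montage, cfg$grid_size))
    res$dnn <- stage("crossvalidate",
                     dnn_crossvalidate(raw, feats$labels, cfg, feats$subjects))
  }
  if ("baselines" %in% run) {
    bm <- frames_to_baseline_matrix(feats$frames)
    res$baselines <- lapply(c("svm", "knn", "logreg"), function(m)
      stage(paste0("baseline_", m),
            baseline_fit(bm, feats$labels, m, k = cfg$k,
                         seed = derive_seed(cfg$seed, "baseline", m),
                         groups = if (cfg$cv_level == "subject") feats$subjects)))
    names(res$baselines) <- c("svm", "knn", "logreg")
  }
  if ("stats" %in% run) {
    scm <- subject_channel_means(feats$frames, feats$labels, feats$subjects)
    ga <- scm$matrix[scm$labels == 1, , drop = FALSE]
    gb <- scm$matrix[scm$labels == 0, , drop = FALSE]
    res$stats <- if (nrow(ga) >= 2 && nrow(gb) >= 2)
      stage("stats", t_map(ga, gb, channel_labels = feats$channel_labels))
    else NULL
  }
  res$comparison <- comparison_table(res)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    metrics <- list(config = res$config, n_trials = res$n_trials,
                    dnn_mean_test_acc = res$dnn$summary$mean_test_acc,
                    dnn_fold_acc = res$dnn$summary$fold_acc,
                    baselines = lapply(res$baselines, function(b)
                      list(mean_acc = b$mean_acc, fold_acc = b$fold_acc)))
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    if (!is.null(res$comparison))
      data.table::fwrite(res$comparison, file.path(out_dir, "comparison.tsv"),
                         sep = "\t")
  }
  res
}

#' Method x feature comparison table
#'
#' A benchmark table in the layout method / model / test accuracy, built
#' from one or more pipeline result bundles.
#'
#' @param ... pipeline result bundles from [run_pipeline()].
#' @return data.frame, or NULL if no accuracies are present.
#' @export
comparison_table <- function(...) {
  rows <- list()
  for (res in list(...)) {
    if (is.null(res)) next
    feat <- res$config$feature
    if (!is.null(res$dnn))
      rows[[length(rows) + 1L]] <- data.frame(
        method = "hybrid_dnn", model = res$config$cnn, feature = feat,
        test_accuracy = res$dnn$summary$mean_test_acc)
    for (m in names(res$baselines))
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, model = "-", feature = feat,
        test_accuracy = res$baselines[[m]]$mean_acc)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
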