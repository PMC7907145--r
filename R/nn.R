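# R-side API of the hybrid CNN + LSTM classifier.

#' CNN configuration (VGG-style, configs A-D)
#'
#' Conv plans per configuration (stacks of 3x3/stride 1/pad 1 convolutions,
#' each stack followed by 2x2/stride 2 max pooling, then FC-512):
#' A: 2x32; B: 2x32 + 2x64; C: 2x32 + 2x64 + 1x128; D: 4x32 + 2x64 + 1x128.
#'
#' @param name one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return a `cnn_config` with `conv_counts`, `conv_channels`, `fc_nodes`.
#' @export
cnn_config <- function(name = c("A", "B", "C", "D")) {
  if (!is.character(name) || !(name[1] %in% c("A", "B", "C", "D")))
    stop_input(sprintf("unknown CNN configuration '%s' (use A, B, C or D)",
                       as.character(name)[1]))
  name <- match.arg(name)
  plan <- switch(name,
    A = list(counts = c(2L), channels = c(32L)),
    B = list(counts = c(2L, 2L), channels = c(32L, 64L)),
    C = list(counts = c(2L, 2L, 1L), channels = c(32L, 64L, 128L)),
    D = list(counts = c(4L, 2L, 1L), channels = c(32L, 64L, 128L)))
  structure(list(name = name, conv_counts = plan$counts,
                 conv_channels = plan$channels, kernel = 3L, stride = 1L,
                 padding = 1L, pool = 2L, fc_nodes = 512L),
            class = "cnn_config")
}

#' Layer-size algebra of a configuration
#'
#' Applies the convolution size rule `y = (n + 2p - f)/s + 1` and the pooling
#' rule `y = (n - f)/s + 1` through the conv plan, erroring (naming the
#' layer) if any intermediate size is non-integral.
#'
#' @param cnn a [cnn_config()].
#' @param image_size input side length (default 32).
#' @return data.frame of layer names, output side and channels, with the
#'   flatten size as attribute `flatten`.
#' @export
cnn_shape_table <- function(cnn, image_size = 32L) {
  side <- image_size; ch <- 3L
  rows <- list(list(layer = "input", side = side, channels = ch))
  for (s in seq_along(cnn$conv_counts)) {
    for (r in seq_len(cnn$conv_counts[s])) {
      y <- (side + 2 * cnn$padding - cnn$kernel) / cnn$stride + 1
      if (y != round(y))
        stop_input(sprintf("non-integer size after conv stack %d layer %d", s, r))
      side <- as.integer(y); ch <- cnn$conv_channels[s]
      rows[[length(rows) + 1L]] <-
        list(layer = sprintf("conv%d_%d", s, r), side = side, channels = ch)
    }
    y <- (side - cnn$pool) / 2 + 1
    if (y != round(y))
      stop_input(sprintf("non-integer size after pool %d", s))
    side <- as.integer(y)
    rows[[length(rows) + 1L]] <-
      list(layer = sprintf("pool%d", s), side = side, channels = ch)
  }
  out <- do.call(rbind.data.frame, rows)
  attr(out, "flatten") <- side * side * ch
  out
}

#' Build the hybrid CNN + LSTM model
#'
#' Per-frame shared-weight CNN embedding (conv stacks + pools + FC-512 with
#' ReLU), a single-layer LSTM over the frame embeddings, and a 2-unit
#' softmax head.  Weights are He-initialised (convs/FC) or uniform in
#' `[-1/sqrt(h), 1/sqrt(h)]` (LSTM/head), deterministically from `seed`.
#'
#' @param cnn a [cnn_config()].
#' @param lstm_hidden LSTM hidden size (default 128).
#' @param n_frames frames per trial (default 6).
#' @param image_size image side (default 32).
#' @param seed RNG seed for initialisation.
#' @return an `eeg_model`.
#' @export
build_model <- function(cnn, lstm_hidden = 128L, n_frames = 6L,
                        image_size = 32L, seed = 1L) {
  stopifnot(inherits(cnn, "cnn_config"))
  shp <- cnn_shape_table(cnn, image_size)
  flat <- attr(shp, "flatten")
  with_seed(seed, {
    conv_w <- list(); conv_b <- list()
    cin <- 3L
    for (s in seq_along(cnn$conv_counts)) {
      for (r in seq_len(cnn$conv_counts[s])) {
        cout <- cnn$conv_channels[s]
        fan_in <- 9L * cin
        conv_w[[length(conv_w) + 1L]] <-
          matrix(rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in)
        conv_b[[length(conv_b) + 1L]] <- numeric(cout)
        cin <- cout
      }
    }
    fc_w <- matrix(rnorm(cnn$fc_nodes * flat, sd = sqrt(2 / flat)),
                   cnn$fc_nodes, flat)
    fc_b <- numeric(cnn$fc_nodes)
    k <- 1 / sqrt(lstm_hidden)
    lw <- function() matrix(runif(lstm_hidden * (lstm_hidden + cnn$fc_nodes),
                                  -k, k), lstm_hidden, lstm_hidden + cnn$fc_nodes)
    lb <- function() runif(lstm_hidden, -k, k)
    weights <- list(conv_w = conv_w, conv_b = conv_b, fc_w = fc_w, fc_b = fc_b,
                    lstm_wf = lw(), lstm_wi = lw(), lstm_wc = lw(), lstm_wo = lw(),
                    lstm_bf = lb(), lstm_bi = lb(), lstm_bc = lb(), lstm_bo = lb(),
                    out_w = matrix(runif(2 * lstm_hidden, -k, k), 2, lstm_hidden),
                    out_b = runif(2, -k, k))
    structure(list(cnn = cnn, lstm_hidden = as.integer(lstm_hidden),
                   n_frames = as.integer(n_frames),
                   image_size = as.integer(image_size),
                   shape_table = shp, weights = weights),
              class = "eeg_model")
  })
}

#' @export
print.eeg_model <- function(x, ...) {
  cat(sprintf("<eeg_model> config %s, %d frames of %dx%dx3, LSTM %d, %s parameters\n",
              x$cnn$name, x$n_frames, x$image_size, x$image_size,
              x$lstm_hidden, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model an `eeg_model`.
#' @return total number of trainable scalars.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "eeg_model"))
  length(unlist(model$weights, use.names = FALSE))
}

#' Training configuration
#'
#' Adam with learning rate 1e-3 and moment decays 0.9/0.999, batch size 32,
#' dropout 0.5 on the FC layers.  `epochs` defaults to the desk-scale 30
#' (200 at paper scale); `patience` enables early stopping on a validation
#' plateau (`NULL` disables).
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param dropout dropout probability on FC layers.
#' @param patience early-stop patience in epochs (`NULL` = none).
#' @param seed RNG seed (shuffling, dropout).
#' @return a `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 32L, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, dropout = 0.5,
                         patience = 3L, seed = 1L) {
  stopifnot(epochs >= 0, batch_size > 0, lr > 0, beta1 > 0, beta2 > 0,
            dropout >= 0, dropout < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, beta1 = beta1, beta2 = beta2, dropout = dropout,
                 patience = if (is.null(patience)) -1L else as.integer(patience),
                 seed = as.integer(seed)), class = "train_config")
}

# stack a list of image_sequence objects into the (H, W, C, frames, N) array
# consumed by the compiled network
sequences_to_array <- function(sequences) {
  n <- length(sequences)
  f1 <- sequences[[1]]$frames
  d <- dim(f1[[1]])
  T <- length(f1)
  X <- array(0, dim = c(d[1], d[2], d[3], T, n))
  for (i in seq_len(n)) {
    fr <- sequences[[i]]$frames
    for (t in seq_len(T)) X[, , , t, i] <- unclass(fr[[t]])
  }
  X
}

#' Train the hybrid network
#'
#' Runs Adam on softmax cross-entropy.  With a validation set, the weights
#' returned are those of the epoch with the highest validation accuracy
#' (model selection), and training stops early once the validation accuracy
#' has not improved for `patience` epochs.  Deterministic given the seed
#' (single-threaded).
#'
#' @param model an `eeg_model` from [build_model()].
#' @param x training images: `(H, W, C, frames, N)` array (see
#'   [sequences_to_array()]) or list of `image_sequence`s.
#' @param y integer labels (0/1), length N.
#' @param cfg a [train_config()].
#' @param x_val,y_val optional validation split (enables model selection and
#'   early stopping).
#' @return the model with trained weights and a `history` element (per-epoch
#'   train/validation loss and accuracy).
#' @export
train_model <- function(model, x, y, cfg = train_config(),
                        x_val = NULL, y_val = NULL) {
  stopifnot(inherits(model, "eeg_model"), inherits(cfg, "train_config"))
  if (is.list(x) && !is.array(x)) x <- sequences_to_array(x)
  if (length(dim(x)) != 5L)
    stop_input("x must be a (H, W, C, frames, N) array or list of sequences")
  y <- as.integer(y)
  if (length(unique(y)) < 2 && cfg$epochs > 0)
    stop_input("training requires both classes present")
  if (!all(y %in% 0:1)) stop_input("labels must be 0/1")
  if (cfg$epochs == 0L) {
    model$history <- list(train_loss = numeric(0), train_acc = numeric(0),
                          val_loss = numeric(0), val_acc = numeric(0))
    return(model)
  }
  if (is.list(x_val) && !is.array(x_val)) x_val <- sequences_to_array(x_val)
  res <- nn_train_cpp(model$weights, x, y,
                      model$cnn$conv_counts, model$cnn$conv_channels,
                      cfg$epochs, cfg$batch_size, cfg$lr, cfg$beta1, cfg$beta2,
                      cfg$dropout, cfg$seed, x_val,
                      if (is.null(y_val)) NULL else as.integer(y_val),
                      cfg$patience, model$n_frames, model$image_size)
  model$weights <- res$weights
  model$history <- res$history
  model$best_epoch <- res$best_epoch
  model
}

#' Class probabilities / predictions of a trained model
#'
#' @param object an `eeg_model`.
#' @param x images array or list of `image_sequence`s.
#' @param type `"prob"` (N x 2 matrix) or `"class"` (0/1 vector).
#' @param ... unused.
#' @export
predict.eeg_model <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.list(x) && !is.array(x)) x <- sequences_to_array(x)
  if (length(dim(x)) != 5L)
    stop_input("x must be a (H, W, C, frames, N) array or list of sequences")
  p <- nn_predict_cpp(object$weights, x, object$cnn$conv_counts,
                      object$cnn$conv_channels, object$n_frames,
                      object$image_size)
  colnames(p) <- c("0", "1")
  if (type == "prob") p else as.integer(p[, 2] > p[, 1])
}

#' One LSTM step (exposed for verification)
#'
#' Applies the gate equations exactly as the network does (double
#' precision): forget/input/candidate/output gates on the concatenation
#' `[h, x]`, cell update `c' = c*f + g*i`, output `h' = tanh(c')*o`.
#'
#' @param weights list with `lstm_wf/wi/wc/wo` and `lstm_bf/bi/bc/bo`.
#' @param x input vector; `h`,`c` previous hidden/cell state.
#' @return list with new `h` and `c`.
#' @export
lstm_step <- function(weights, x, h, c) {
  lstm_step_cpp(weights$lstm_wf, weights$lstm_wi, weights$lstm_wc,
                weights$lstm_wo, weights$lstm_bf, weights$lstm_bi,
                weights$lstm_bc, weights$lstm_bo, x, h, c)
}
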