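#' Specification of one convolutional branch
#'
#' Each branch applies a 1D convolution (valid padding, ReLU), non-overlapping
#' max pooling, and dropout to the shared raw-signal input. The three branches
#' differ in kernel length, giving the network three temporal scales of
#' feature extraction.
#'
#' @param n_filters number of convolution filters (default 16).
#' @param kernel_len kernel length in samples.
#' @param pool_len max-pooling length in samples (default 4).
#' @param dropout dropout probability in \[0, 1) (default 0.2).
#' @return an object of class `branch_spec`.
#' @export
branch_spec <- function(n_filters = 16, kernel_len = 15, pool_len = 4,
                        dropout = 0.2) {
  if (kernel_len < 1 || pool_len < 1)
    input_error("branch_spec", "kernel_len and pool_len must be >= 1")
  if (dropout < 0 || dropout >= 1)
    input_error("branch_spec", "dropout must be in [0, 1)")
  structure(list(n_filters = as.integer(n_filters),
                 kernel_len = as.integer(kernel_len),
                 pool_len = as.integer(pool_len), dropout = dropout),
            class = "branch_spec")
}

#' Model configuration for the three-branch 1D CNN
#'
#' Topology: exactly three parallel (convolution -> ReLU -> max-pool ->
#' dropout) branches over the shared input window, flattened and
#' concatenated, then a fully connected stack (defaults 20, 16, 16, 64
#' neurons, each ReLU + dropout 0.2), then a softmax output layer with one
#' neuron per class. Published hyperparameters are the dense sizes, the
#' dropout rate and the class count; the branch kernel lengths are not
#' published and default to 7, 15 and 31 samples (three temporal scales).
#'
#' The dense stack uses a leaky rectifier (slope `leaky_alpha` below zero).
#' With the ~12,000 all-positive pooled features feeding the narrow first
#' dense layer, plain ReLU units die irrecoverably within a few Adam steps
#' (the optimizer's fixed-size per-weight steps translate into large
#' correlated shifts of the pre-activations); the leak keeps the gradient
#' path open so units recover. Set `leaky_alpha = 0` for plain ReLU.
#'
#' @param branches list of exactly 3 [branch_spec()]s.
#' @param dense_sizes fully connected layer sizes (default c(20, 16, 16, 64)).
#' @param dense_dropout dropout after each dense layer (default 0.2).
#' @param leaky_alpha negative-side slope of the dense activations
#'   (default 0.1).
#' @param n_classes output classes (default 4).
#' @param input_shape integer length-2: (window_len, n_channels), default
#'   c(1028, 2).
#' @return an object of class `model_config`.
#' @export
model_config <- function(branches = list(branch_spec(kernel_len = 7),
                                         branch_spec(kernel_len = 15),
                                         branch_spec(kernel_len = 31)),
                         dense_sizes = c(20, 16, 16, 64),
                         dense_dropout = 0.2,
                         leaky_alpha = 0.1,
                         n_classes = 4,
                         input_shape = c(1028, 2)) {
  if (length(branches) != 3)
    input_error("model_config", "exactly 3 branches are required, got %d",
                length(branches))
  stopifnot(all(vapply(branches, inherits, logical(1), "branch_spec")))
  if (!length(dense_sizes)) input_error("model_config", "dense_sizes must be nonempty")
  for (b in branches)
    if (b$kernel_len > input_shape[1])
      input_error("model_config", "branch kernel (%d) longer than input (%d)",
                  b$kernel_len, input_shape[1])
  if (leaky_alpha < 0 || leaky_alpha >= 1)
    input_error("model_config", "leaky_alpha must be in [0, 1)")
  structure(list(branches = branches,
                 dense_sizes = as.integer(dense_sizes),
                 dense_dropout = dense_dropout,
                 leaky_alpha = leaky_alpha,
                 n_classes = as.integer(n_classes),
                 input_shape = as.integer(input_shape)),
            class = "model_config")
}

# Flattened feature length contributed by one branch.
branch_feat_len <- function(b, input_len) {
  out_len <- input_len - b$kernel_len + 1L
  (out_len %/% b$pool_len) * b$n_filters
}

#' Build an (untrained) three-branch CNN
#'
#' Initializes all weights (He initialization for ReLU layers, Glorot for the
#' softmax output) under `seed`. The returned handle supports [predict()],
#' [n_parameters()] and [train_cnn()].
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization (default 1).
#' @return an object of class `cnn_model`.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  wl <- config$input_shape[1]
  nch <- config$input_shape[2]
  params <- with_seed(seed, {
    br <- lapply(config$branches, function(b) {
      fan_in <- b$kernel_len * nch
      list(W = array(rnorm(b$kernel_len * nch * b$n_filters,
                           sd = sqrt(2 / fan_in)),
                     c(b$kernel_len, nch, b$n_filters)),
           b = rep(0, b$n_filters))
    })
    sizes <- c(sum(vapply(config$branches, branch_feat_len, numeric(1), wl)),
               config$dense_sizes, config$n_classes)
    nd <- length(sizes) - 1L
    dn <- vector("list", nd)
    for (i in seq_len(nd)) {
      fan_in <- sizes[i]
      sdv <- if (i == nd) sqrt(2 / (sizes[i] + sizes[i + 1])) else sqrt(2 / fan_in)
      dn[[i]] <- list(W = matrix(rnorm(sizes[i] * sizes[i + 1], sd = sdv),
                                 sizes[i], sizes[i + 1]),
                      b = rep(0, sizes[i + 1]))
    }
    list(branches = br, dense = dn)
  })
  structure(list(config = config, params = params, trained = FALSE,
                 class_order = NULL, history = NULL),
            class = "cnn_model")
}

#' Count trainable parameters
#'
#' Sums the lengths of every weight and bias array actually held by the
#' model (the tests check this against an independent closed-form count).
#'
#' @param model a `cnn_model`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  flat <- c(unlist(model$params$branches), unlist(model$params$dense))
  length(flat)
}

#' @export
print.cnn_model <- function(x, ...) {
  ks <- vapply(x$config$branches, `[[`, integer(1), "kernel_len")
  cat(sprintf("<cnn_model> input %s, branch kernels %s, dense %s -> %d classes, %d parameters%s\n",
              paste(x$config$input_shape, collapse = "x"),
              paste(ks, collapse = "/"),
              paste(x$config$dense_sizes, collapse = "-"),
              x$config$n_classes, n_parameters(x),
              if (x$trained) " (trained)" else ""))
  invisible(x)
}

#' Training configuration
#'
#' Adam on categorical cross-entropy, matching the published training setup;
#' epochs, batch size and learning rate are not published and default to
#' desk-scale values.
#'
#' @param epochs training epochs (default 20).
#' @param batch_size minibatch size (default 128).
#' @param learning_rate Adam step size (default 3e-3).
#' @param seed integer seed driving weight re-initialization, shuffling and
#'   dropout (default 1). Reproducibility is statistical across BLAS builds,
#'   bit-exact on one machine.
#' @param early_stopping logical; stop when validation loss has not improved
#'   for `patience` epochs (default FALSE).
#' @param patience early-stopping patience in epochs (default 5).
#' @param verbose print per-epoch progress (default FALSE).
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 20, batch_size = 128, learning_rate = 3e-3,
                         seed = 1L, early_stopping = FALSE, patience = 5,
                         verbose = FALSE) {
  if (epochs < 1) input_error("train_config", "epochs must be >= 1")
  if (batch_size < 1) input_error("train_config", "batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 early_stopping = early_stopping,
                 patience = as.integer(patience), verbose = verbose),
            class = "train_config")
}

# --- internal forward/backward machinery -----------------------------------

# windows (n, len, ch) -> cube (len, ch, n) for the C++ kernels
wm_to_cube <- function(windows, idx = NULL) {
  if (!is.null(idx)) windows <- windows[idx, , , drop = FALSE]
  aperm(windows, c(2, 3, 1))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass. x: cube (len, ch, m). When `train` is TRUE dropout masks are
# drawn from the current RNG stream and kept for the backward pass.
cnn_forward <- function(model, x, train = FALSE) {
  cfg <- model$config
  p <- model$params
  m <- dim(x)[3]
  feats <- vector("list", 3)
  cache <- list(branches = vector("list", 3))
  for (i in 1:3) {
    b <- cfg$branches[[i]]
    bf <- cpp_branch_forward(x, p$branches[[i]]$W, p$branches[[i]]$b,
                             b$pool_len, train)
    feat <- bf$feat
    drop <- NULL
    if (train && b$dropout > 0) {
      drop <- (matrix(runif(length(feat)), nrow(feat)) >= b$dropout) /
        (1 - b$dropout)
      feat <- feat * drop
    }
    feats[[i]] <- feat
    cache$branches[[i]] <- list(feat_raw = bf$feat, state = bf$state,
                                drop = drop)
  }
  h <- do.call(cbind, feats)
  cache$feat_sizes <- vapply(feats, ncol, numeric(1))
  nd <- length(p$dense)
  cache$dense <- vector("list", nd)
  for (i in seq_len(nd)) {
    z <- sweep(h %*% p$dense[[i]]$W, 2, p$dense[[i]]$b, `+`)
    if (i < nd) {
      al <- if (is.null(cfg$leaky_alpha)) 0 else cfg$leaky_alpha
      a <- z * ((z > 0) + al * (z <= 0))
      drop <- NULL
      if (train && cfg$dense_dropout > 0) {
        drop <- (matrix(runif(length(a)), nrow(a)) >= cfg$dense_dropout) /
          (1 - cfg$dense_dropout)
        a <- a * drop
      }
      cache$dense[[i]] <- list(h_in = h, z = z, drop = drop)
      h <- a
    } else {
      cache$dense[[i]] <- list(h_in = h, z = z)
      h <- z
    }
  }
  list(probs = softmax_rows(h), cache = cache)
}

# Backward pass; returns gradients with the same structure as params.
cnn_backward <- function(model, x, fw, y_onehot) {
  cfg <- model$config
  p <- model$params
  m <- nrow(y_onehot)
  grads <- list(branches = vector("list", 3), dense = vector("list", length(p$dense)))
  dz <- (fw$probs - y_onehot) / m
  for (i in rev(seq_along(p$dense))) {
    cc <- fw$cache$dense[[i]]
    grads$dense[[i]] <- list(W = crossprod(cc$h_in, dz), b = colSums(dz))
    dh <- dz %*% t(p$dense[[i]]$W)
    if (i > 1) {
      prev <- fw$cache$dense[[i - 1]]
      if (!is.null(prev$drop)) dh <- dh * prev$drop
      al <- if (is.null(cfg$leaky_alpha)) 0 else cfg$leaky_alpha
      dz <- dh * ((prev$z > 0) + al * (prev$z <= 0))
    }
  }
  # dh is now the gradient wrt the concatenated branch features
  offs <- c(0, cumsum(fw$cache$feat_sizes))
  for (i in 1:3) {
    b <- cfg$branches[[i]]
    cc <- fw$cache$branches[[i]]
    dfeat <- dh[, (offs[i] + 1L):offs[i + 1L], drop = FALSE]
    if (!is.null(cc$drop)) dfeat <- dfeat * cc$drop
    dfeat <- dfeat * (cc$feat_raw > 0)   # ReLU derivative at the pooled max
    g <- cpp_branch_backward(cc$state, dfeat, b$kernel_len, cfg$input_shape[2])
    grads$branches[[i]] <- list(W = g$dW, b = as.numeric(g$db))
  }
  grads
}

# Flatten/unflatten helpers for the Adam state.
params_flatten <- function(p) {
  out <- list()
  for (i in 1:3) { out[[length(out) + 1]] <- p$branches[[i]]$W
                   out[[length(out) + 1]] <- p$branches[[i]]$b }
  for (i in seq_along(p$dense)) { out[[length(out) + 1]] <- p$dense[[i]]$W
                                  out[[length(out) + 1]] <- p$dense[[i]]$b }
  out
}
params_set <- function(p, flat) {
  j <- 1
  for (i in 1:3) { p$branches[[i]]$W <- flat[[j]]; j <- j + 1
                   p$branches[[i]]$b <- flat[[j]]; j <- j + 1 }
  for (i in seq_along(p$dense)) { p$dense[[i]]$W <- flat[[j]]; j <- j + 1
                                  p$dense[[i]]$b <- flat[[j]]; j <- j + 1 }
  p
}

labels_to_onehot <- function(labels, class_order) {
  y <- matrix(0, length(labels), length(class_order))
  y[cbind(seq_along(labels), match(labels, class_order))] <- 1
  y
}

# Loss/accuracy of a model on a window matrix, batched.
evaluate_model <- function(model, wm, batch_size = 256) {
  n <- length(wm$labels)
  if (n == 0) return(list(loss = NA_real_, acc = NA_real_))
  y <- match(wm$labels, model$class_order)
  loss <- 0; correct <- 0
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, n)
    fw <- cnn_forward(model, wm_to_cube(wm$windows, idx), train = FALSE)
    pr <- pmax(fw$probs, 1e-12)
    loss <- loss + sum(-log(pr[cbind(seq_along(idx), y[idx])]))
    correct <- correct + sum(max.col(fw$probs) == y[idx])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Train the three-branch CNN
#'
#' Minibatch Adam on categorical cross-entropy. One integer seed
#' (`tc$seed`) drives weight re-initialization, epoch shuffling and dropout
#' masks. History metrics (train and validation) are computed after each
#' epoch with dropout off, so [predict()] on the training set reproduces the
#' final recorded training accuracy.
#'
#' @param model a `cnn_model` from [build_model()].
#' @param split a `data_split` from [split_windows()] (or a bare
#'   `window_matrix`, trained without validation).
#' @param tc a [train_config()].
#' @return the trained `cnn_model` with `history` (data.frame: epoch,
#'   train_loss, val_loss, train_acc, val_acc) and `class_order` fixed.
#' @export
train_cnn <- function(model, split, tc = train_config()) {
  stopifnot(inherits(model, "cnn_model"))
  if (inherits(split, "window_matrix"))
    split <- list(train = split, test = NULL)
  train_wm <- split$train
  n <- length(train_wm$labels)
  if (n == 0) input_error("train", "empty training set")
  class_order <- train_wm$class_order
  if (length(class_order) != model$config$n_classes)
    input_error("train", "split has %d classes but model expects %d",
                length(class_order), model$config$n_classes)
  model <- with_seed(tc$seed, {
    model <- build_model(model$config, seed = sample.int(2^31 - 2, 1))
    model$class_order <- class_order
    y_all <- labels_to_onehot(train_wm$labels, class_order)
    flat <- params_flatten(model$params)
    mstate <- lapply(flat, function(w) w * 0)
    vstate <- mstate
    tstep <- 0
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    hist <- data.frame()
    best_val <- Inf; wait <- 0
    for (epoch in seq_len(tc$epochs)) {
      ord <- sample.int(n)
      for (s in seq(1, n, by = tc$batch_size)) {
        idx <- ord[s:min(s + tc$batch_size - 1, n)]
        x <- wm_to_cube(train_wm$windows, idx)
        yb <- y_all[idx, , drop = FALSE]
        fw <- cnn_forward(model, x, train = TRUE)
        grads <- cnn_backward(model, x, fw, yb)
        gflat <- params_flatten(grads)
        flat <- params_flatten(model$params)
        tstep <- tstep + 1
        for (j in seq_along(flat)) {
          mstate[[j]] <- beta1 * mstate[[j]] + (1 - beta1) * gflat[[j]]
          vstate[[j]] <- beta2 * vstate[[j]] + (1 - beta2) * gflat[[j]]^2
          mhat <- mstate[[j]] / (1 - beta1^tstep)
          vhat <- vstate[[j]] / (1 - beta2^tstep)
          flat[[j]] <- flat[[j]] - tc$learning_rate * mhat / (sqrt(vhat) + eps)
        }
        model$params <- params_set(model$params, flat)
      }
      # post-epoch metrics with dropout off, so predict() on the training
      # set reproduces the recorded history
      tr <- evaluate_model(model, train_wm)
      val <- if (!is.null(split$test) && length(split$test$labels))
        evaluate_model(model, split$test) else list(loss = NA_real_, acc = NA_real_)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr$loss,
                                     val_loss = val$loss,
                                     train_acc = tr$acc,
                                     val_acc = val$acc))
      if (tc$verbose)
        message(sprintf("epoch %d: loss %.4f acc %.3f val_loss %s val_acc %s",
                        epoch, tr$loss, tr$acc,
                        format(val$loss, digits = 4), format(val$acc, digits = 3)))
      if (tc$early_stopping && !is.na(val$loss)) {
        if (val$loss < best_val - 1e-6) { best_val <- val$loss; wait <- 0 }
        else { wait <- wait + 1; if (wait >= tc$patience) break }
      }
    }
    model$history <- hist
    model$trained <- TRUE
    model
  })
  model
}

#' Predict classes for a window matrix
#'
#' Forward pass with dropout off; labels are argmax probabilities under the
#' model's `class_order`.
#'
#' @param object a `cnn_model`.
#' @param wm a `window_matrix` whose window shape matches the model's
#'   `input_shape`.
#' @param batch_size forward batch size (default 256).
#' @param ... unused.
#' @return list with `labels` (character) and `probs` (n x n_classes matrix,
#'   rows summing to 1).
#' @export
predict.cnn_model <- function(object, wm, batch_size = 256, ...) {
  d <- dim(wm$windows)
  if (d[1] == 0)
    return(list(labels = character(0),
                probs = matrix(0, 0, object$config$n_classes)))
  if (any(d[2:3] != object$config$input_shape))
    input_error("predict", "window shape (%d, %d) does not match model input (%d, %d)",
                d[2], d[3], object$config$input_shape[1], object$config$input_shape[2])
  class_order <- object$class_order
  if (is.null(class_order)) class_order <- paste0("class", seq_len(object$config$n_classes))
  probs <- matrix(0, d[1], object$config$n_classes)
  for (s in seq(1, d[1], by = batch_size)) {
    idx <- s:min(s + batch_size - 1, d[1])
    probs[idx, ] <- cnn_forward(object, wm_to_cube(wm$windows, idx))$probs
  }
  colnames(probs) <- class_order
  list(labels = class_order[max.col(probs)], probs = probs)
}

#' FFT band-power baseline classifier
#'
#' The handcrafted-feature comparison point for the CNN: per window and
#' channel, log mean Welch band power in each requested band, fed to a ridge
#' multinomial logistic regression. Returns the same metrics-report type as
#' the CNN path, so the two are directly comparable.
#'
#' @param split a `data_split`.
#' @param bands list of c(low, high) Hz pairs; defaults to 4-Hz-wide bins
#'   spanning 8--40 Hz.
#' @param lambda ridge penalty (default 1e-3).
#' @return a `metrics_report` (see [cm_metrics()]), with the confusion
#'   matrix attached as attribute `confusion`.
#' @export
bandpower_baseline <- function(split, bands = NULL, lambda = 1e-3) {
  stopifnot(inherits(split, "data_split"))
  fs <- split$train$fs
  if (is.null(bands))
    bands <- lapply(seq(8, 36, by = 4), function(lo) c(lo, lo + 4))
  if (!length(bands)) input_error("bandpower_baseline", "empty band list")
  for (b in bands)
    if (b[1] <= 0 || b[2] >= fs / 2)
      input_error("bandpower_baseline", "band (%g, %g) outside (0, fs/2)", b[1], b[2])
  featurize <- function(wm) {
    d <- dim(wm$windows)
    wl <- d[2]
    freqs <- (seq_len(wl) - 1) * fs / wl
    keep <- freqs <= fs / 2
    sel <- lapply(bands, function(b) which(keep & freqs >= b[1] & freqs <= b[2]))
    out <- matrix(0, d[1], length(bands) * d[3])
    for (ch in seq_len(d[3])) {
      m <- wm$windows[, , ch, drop = TRUE]
      if (d[1] == 1L) m <- matrix(m, 1L)
      sp <- abs(stats::mvfft(t(m)))^2 / wl
      for (j in seq_along(bands))
        out[, (ch - 1) * length(bands) + j] <- log(colMeans(sp[sel[[j]], , drop = FALSE]) + 1e-12)
    }
    out
  }
  xtr <- featurize(split$train)
  xte <- featurize(split$test)
  fit <- glmnet::glmnet(xtr, factor(split$train$labels, levels = split$train$class_order),
                        family = "multinomial", alpha = 0, lambda = lambda,
                        standardize = TRUE)
  pred <- as.character(predict(fit, xte, type = "class", s = lambda))
  cm <- confusion(split$test$labels, pred, split$train$class_order)
  rep <- cm_metrics(cm)
  attr(rep, "confusion") <- cm
  rep
}
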