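#' Classifier architectures and training
#'
#' Two architectures share one input format, the channels x 33 x 8
#' spectro-tensor, so they compose into a single detection-then-typing
#' pipeline:
#'
#' * the binary detector: three 3x3 convolutions of 16, 32 and 64 feature
#'   maps (padding 1) over the frequency-by-time plane with the electrodes
#'   as input channels, each followed by ReLU, 2x2 max pooling and batch
#'   normalization, then dense layers of 256 and 2 units (softmax);
#' * the multigroup (8-type) classifier: two modules of a convolutional
#'   LSTM over the 8 timesteps (16 then 32 filters, 3x3, same padding),
#'   each followed by batch normalization, per-step 2x2 max pooling and
#'   dropout; the second module returns its final state, which flattens
#'   into dense layers of 256 and 8 units.
#'
#' Training minimizes class-weighted cross-entropy with Adam.
#'
#' @name models
NULL

#' Build the untrained binary seizure-detection CNN
#'
#' @param input_shape integer vector `(channels, freq_bins, timesteps)`;
#'   the frequency-by-time plane must survive three 2x2 poolings
#' @param class_labels two class names, positive (seizure) class second
#' @param conv_channels three conv layer widths
#' @param dense_units width of the penultimate dense layer
#' @param seed seed for weight initialization
#' @return an untrained `seizr_model`
#' @export
build_binary_cnn <- function(input_shape = c(21L, 33L, 8L),
                             class_labels = c("bckg", "seiz"),
                             conv_channels = c(16L, 32L, 64L),
                             dense_units = 256L, seed = 1L) {
  stopifnot(length(input_shape) == 3L, length(class_labels) == 2L)
  C <- input_shape[1L]; H <- input_shape[2L]; W <- input_shape[3L]
  if (H %/% 8L < 1L || W %/% 8L < 1L)
    stop("input plane ", H, "x", W, " collapses to zero under three poolings")
  with_seed(seed, {
    layers <- list()
    dims <- c(C, H, W)
    for (k in conv_channels) {
      cv <- .layer_conv(dims[1L], dims[2L], dims[3L], k)
      rl <- .layer_relu(cv$out_dim)
      pl <- .layer_pool(k, dims[2L], dims[3L])
      bn <- .layer_bn(k, prod(pl$out_dim[2:3]))
      layers <- c(layers, list(cv, rl, pl, bn))
      dims <- pl$out_dim
    }
    flat <- prod(dims)
    layers <- c(layers,
                list(.layer_dense(flat, dense_units, "relu"),
                     .layer_dense(dense_units, length(class_labels), "linear")))
    structure(list(kind = "binary_cnn", layers = layers,
                   input_shape = input_shape, class_labels = class_labels,
                   flatten_width = flat),
              class = "seizr_model")
  })
}

#' Build the untrained multigroup ConvLSTM classifier
#'
#' The 8 timesteps form the sequence axis; each step is a single-feature
#' map of electrodes x frequencies.
#'
#' @param input_shape `(channels, freq_bins, timesteps)`
#' @param class_labels the seizure type labels (default all eight)
#' @param convlstm_filters filters of the two ConvLSTM modules
#' @param dropout dropout probability after each module
#' @param dense_units penultimate dense width
#' @param seed seed for weight initialization
#' @return an untrained `seizr_model`
#' @export
build_multigroup_model <- function(input_shape = c(21L, 33L, 8L),
                                   class_labels = SEIZURE_LABELS,
                                   convlstm_filters = c(16L, 32L),
                                   dropout = 0.3, dense_units = 256L,
                                   seed = 1L) {
  stopifnot(length(input_shape) == 3L, length(class_labels) >= 2L)
  C <- input_shape[1L]; FQ <- input_shape[2L]
  with_seed(seed, {
    k1 <- convlstm_filters[1L]; k2 <- convlstm_filters[2L]
    cl1 <- .layer_convlstm(1L, C, FQ, k1, return_sequence = TRUE)
    bn1 <- .layer_bn(k1, C * FQ)
    pl1 <- .layer_pool(k1, C, FQ)
    dims1 <- pl1$out_dim
    do1 <- .layer_dropout(dropout)
    cl2 <- .layer_convlstm(k1, dims1[2L], dims1[3L], k2,
                           return_sequence = FALSE)
    bn2 <- .layer_bn(k2, dims1[2L] * dims1[3L])
    pl2 <- .layer_pool(k2, dims1[2L], dims1[3L])
    do2 <- .layer_dropout(dropout)
    flat <- prod(pl2$out_dim)
    d1 <- .layer_dense(flat, dense_units, "relu")
    d2 <- .layer_dense(dense_units, length(class_labels), "linear")
    structure(list(kind = "multigroup_convlstm",
                   layers = list(cl1, bn1, pl1, do1, cl2, bn2, pl2, do2,
                                 d1, d2),
                   input_shape = input_shape, class_labels = class_labels,
                   flatten_width = flat),
              class = "seizr_model")
  })
}

#' @export
print.seizr_model <- function(x, ...) {
  cat(sprintf("<seizr_model:%s> input %s -> %d classes (%s)\n", x$kind,
              paste(x$input_shape, collapse = "x"),
              length(x$class_labels), paste(x$class_labels, collapse = ",")))
  invisible(x)
}

# forward to pre-softmax logits; x is [C, F, T, N]. `training` governs
# batch-norm statistics and dropout; `cache` retains what backward needs
# (activation maximization backpropagates through an eval-mode forward).
# Raw magnitude tensors are standardized per element with the training-set
# statistics stored on the model; `standardized` marks inputs already in
# those units (the space activation maximization works in).
.model_forward <- function(model, x, training = FALSE, cache = training,
                           standardized = FALSE) {
  stopifnot(all(dim(x)[1:3] == model$input_shape))
  N <- dim(x)[4L]
  if (!standardized && !is.null(model$input_stats)) {
    st <- model$input_stats
    x <- (x - c(st$mu)) / c(st$sd)
  }
  if (model$kind == "binary_cnn") {
    h <- matrix(x, ncol = N)
    for (l in model$layers) {
      h <- switch(l$type,
        conv = .conv_fwd(l, h, cache),
        relu = { if (cache) l$cache <- h > 0; pmax(h, 0) },
        pool = .pool_fwd(l, h, cache),
        bn = .bn_fwd(l, h, training),
        dense = .dense_fwd(l, h, training))
    }
    h
  } else {
    CF <- prod(model$input_shape[1:2]); T_ <- model$input_shape[3L]
    x_seq <- array(aperm(array(x, c(CF, T_, N)), c(1L, 3L, 2L)),
                   c(CF, N, T_))
    l <- model$layers
    h <- .convlstm_fwd(l[[1L]], x_seq, cache)            # [K*HW, N, T]
    h <- matrix(h, ncol = N * T_)
    h <- .bn_fwd(l[[2L]], h, training)
    h <- .pool_fwd(l[[3L]], h, cache)
    h <- .dropout_fwd(l[[4L]], h, training)
    h <- array(h, c(nrow(h), N, T_))
    h <- .convlstm_fwd(l[[5L]], h, cache)                # [K2*HW2, N]
    h <- .bn_fwd(l[[6L]], h, training)
    h <- .pool_fwd(l[[7L]], h, cache)
    h <- .dropout_fwd(l[[8L]], h, training)
    h <- .dense_fwd(l[[9L]], h, training)
    .dense_fwd(l[[10L]], h, training)
  }
}

# backward from dlogits [n_out, N]; returns input gradient [C, F, T, N]
# when need_input_grad
.model_backward <- function(model, dlogits, need_input_grad = FALSE) {
  if (model$kind == "binary_cnn") {
    d <- dlogits
    for (l in rev(model$layers)) {
      d <- switch(l$type,
        conv = .conv_bwd(l, d),
        relu = d * l$cache,
        pool = .pool_bwd(l, d),
        bn = .bn_bwd(l, d),
        dense = .dense_bwd(l, d))
    }
    if (need_input_grad) {
      N <- ncol(d)
      array(d, c(model$input_shape, N))
    } else invisible(NULL)
  } else {
    l <- model$layers
    T_ <- model$input_shape[3L]
    d <- .dense_bwd(l[[10L]], dlogits)
    d <- .dense_bwd(l[[9L]], d)
    d <- .dropout_bwd(l[[8L]], d)
    d <- .pool_bwd(l[[7L]], d)
    d <- .bn_bwd(l[[6L]], d)
    N <- ncol(d)
    d <- .convlstm_bwd(l[[5L]], d, need_input_grad = TRUE)  # [C1*HW1p, N, T]
    d <- matrix(d, ncol = N * T_)
    d <- .dropout_bwd(l[[4L]], d)
    d <- .pool_bwd(l[[3L]], d)
    d <- .bn_bwd(l[[2L]], d)
    d <- array(d, c(nrow(d), N, T_))
    d <- .convlstm_bwd(l[[1L]], d, need_input_grad = need_input_grad)
    if (need_input_grad) {
      CF <- prod(model$input_shape[1:2])
      array(aperm(d, c(1L, 3L, 2L)), c(model$input_shape, N))
    } else invisible(NULL)
  }
}

.softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), `/`)
}

#' Predict class probabilities
#'
#' @param model a trained `seizr_model`
#' @param x input array `channels x freq x time x n` (a single 3-D tensor
#'   is promoted to a batch of one); shapes must match `model$input_shape`
#' @param batch_size forward-pass batch size
#' @return `n x n_classes` matrix of probabilities; rows sum to 1
#' @export
predict_proba <- function(model, x, batch_size = 64L) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (!all(dim(x)[1:3] == model$input_shape))
    stop("input shape ", paste(dim(x)[1:3], collapse = "x"),
         " does not match model input ",
         paste(model$input_shape, collapse = "x"))
  N <- dim(x)[4L]
  out <- matrix(0, N, length(model$class_labels),
                dimnames = list(NULL, model$class_labels))
  for (b in split(seq_len(N), ceiling(seq_len(N) / batch_size))) {
    logits <- .model_forward(model, x[, , , b, drop = FALSE],
                             training = FALSE)
    out[b, ] <- t(.softmax_cols(logits))
  }
  out
}

#' Predicted class labels (argmax of [predict_proba])
#' @inheritParams predict_proba
#' @export
predict_labels <- function(model, x, batch_size = 64L) {
  p <- predict_proba(model, x, batch_size)
  model$class_labels[max.col(p, ties.method = "first")]
}

#' Pre-softmax logit and input gradient of one output unit
#'
#' The gradient-access contract used by activation maximization: returns
#' the target class's pre-softmax activation summed over the batch and its
#' gradient with respect to the input tensor. For a trained `seizr_model`
#' the input is interpreted in the model's standardized units (per-element
#' z-scores of the training tensors), so ascent directions are measured in
#' data standard deviations rather than raw microvolt-scale magnitudes.
#'
#' @param model a `seizr_model` (methods for other classes may be defined)
#' @param x input array `channels x freq x time x n`
#' @param class_index 1-based output unit index
#' @return `list(value =, grad =)` with `grad` shaped like `x`
#' @export
logit_and_gradient <- function(model, x, class_index) {
  UseMethod("logit_and_gradient")
}

#' @export
logit_and_gradient.seizr_model <- function(model, x, class_index) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  K <- length(model$class_labels)
  if (class_index < 1L || class_index > K)
    stop("class_index ", class_index, " out of range 1..", K)
  logits <- .model_forward(model, x, training = FALSE, cache = TRUE,
                           standardized = TRUE)
  dlogits <- matrix(0, K, dim(x)[4L])
  dlogits[class_index, ] <- 1
  grad <- .model_backward(model, dlogits, need_input_grad = TRUE)
  list(value = sum(logits[class_index, ]), grad = grad)
}

#' Convert a standardized prototype back to raw magnitude units
#'
#' Maps an activation-maximization pattern (standardized units) to the
#' raw tensor scale via the model's stored training statistics, clipped at
#' zero since inputs are magnitude spectra. Models without stored
#' statistics return the pattern unchanged.
#'
#' @param model a trained `seizr_model`
#' @param pattern array in the model's input shape (e.g. `$pattern` of an
#'   `am_pattern`)
#' @return array in raw magnitude units
#' @export
destandardize_pattern <- function(model, pattern) {
  if (is.null(model$input_stats)) return(pattern)
  st <- model$input_stats
  pmax(array(c(st$mu) + c(pattern) * c(st$sd), dim = dim(pattern)), 0)
}

#' Training settings
#'
#' @param epochs training epochs
#' @param batch_size minibatch size
#' @param learning_rate Adam learning rate
#' @param class_weights named per-class loss weights (`NULL` = uniform);
#'   see [class_weights]
#' @param seed seed controlling shuffling and dropout
#' @export
training_config <- function(epochs = 20L, batch_size = 32L,
                            learning_rate = 1e-3, class_weights = NULL,
                            seed = 1L) {
  stopifnot(epochs >= 1L)
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       learning_rate = learning_rate, class_weights = class_weights,
       seed = as.integer(seed))
}

# rank-based AUC of scores for the positive class (binary only)
.auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.eval_set <- function(model, x, y_idx, w) {
  p <- predict_proba(model, x)
  n <- nrow(p)
  eps <- 1e-12
  wv <- w[y_idx]
  loss <- -sum(wv * log(p[cbind(seq_len(n), y_idx)] + eps)) / sum(wv)
  pred <- max.col(p, ties.method = "first")
  list(loss = loss, acc = mean(pred == y_idx), p = p, pred = pred)
}

#' Train a model with Adam on class-weighted cross-entropy
#'
#' @param model an untrained (or previously trained) `seizr_model`
#' @param train `list(x =, labels =)`: input array and character labels
#' @param val optional validation set of the same form
#' @param tcfg a [training_config]
#' @return the trained model, with a `history` tibble attached (one row
#'   per epoch: losses, accuracy, and recall/precision/AUC for binary or
#'   macro recall/precision for multigroup, on the validation set when
#'   given)
#' @export
train_model <- function(model, train, val = NULL, tcfg = training_config()) {
  labels <- train$labels
  if (length(labels) == 0L) stop("empty training set")
  unknown <- setdiff(unique(labels), model$class_labels)
  if (length(unknown) > 0L)
    stop("training labels outside model classes: ",
         paste(unknown, collapse = ", "))
  K <- length(model$class_labels)
  y <- match(labels, model$class_labels)
  w <- rep(1, K); names(w) <- model$class_labels
  if (!is.null(tcfg$class_weights))
    w[names(tcfg$class_weights)] <- tcfg$class_weights
  N <- dim(train$x)[4L]
  if (is.null(model$input_stats)) {
    mu <- apply(train$x, 1:3, mean)
    sd_ <- apply(train$x, 1:3, stats::sd)
    sd_ <- pmax(sd_, 0.01 * mean(sd_))   # floor near-empty bins
    model$input_stats <- list(mu = mu, sd = sd_)
  }
  y_val <- if (!is.null(val)) match(val$labels, model$class_labels)
  history <- vector("list", tcfg$epochs)
  with_seed(tcfg$seed, {
    adam <- .adam_init(model$layers)
    step <- 0L
    for (epoch in seq_len(tcfg$epochs)) {
      perm <- sample.int(N)
      batch_losses <- c(); batch_hits <- 0L
      for (b in split(perm, ceiling(seq_along(perm) / tcfg$batch_size))) {
        xb <- train$x[, , , b, drop = FALSE]
        yb <- y[b]
        logits <- .model_forward(model, xb, training = TRUE)
        p <- .softmax_cols(logits)
        wb <- w[yb]
        onehot <- matrix(0, K, length(b))
        onehot[cbind(yb, seq_along(b))] <- 1
        eps <- 1e-12
        batch_losses <- c(batch_losses,
          -sum(wb * log(p[cbind(yb, seq_along(b))] + eps)) / sum(wb))
        batch_hits <- batch_hits +
          sum(max.col(t(p), ties.method = "first") == yb)
        dlogits <- sweep(p - onehot, 2L, wb / sum(wb), `*`)
        .model_backward(model, dlogits)
        step <- step + 1L
        adam <- .adam_step(model$layers, adam, tcfg$learning_rate, step)
      }
      # train loss/accuracy come from the minibatch passes (pre-update);
      # the named validation metrics need a full evaluation pass
      row <- tibble::tibble(epoch = epoch,
                            train_loss = mean(batch_losses),
                            train_acc = batch_hits / N,
                            val_loss = NA_real_, val_acc = NA_real_,
                            recall = NA_real_, precision = NA_real_,
                            auc = NA_real_)
      if (!is.null(val)) {
        ev <- .eval_set(model, val$x, y_val, w)
        row$val_loss <- ev$loss; row$val_acc <- ev$acc
        if (K == 2L) {
          pos <- 2L  # positive (seizure) class is the second label
          tp <- sum(ev$pred == pos & y_val == pos)
          row$recall <- if (sum(y_val == pos) > 0) tp / sum(y_val == pos)
            else NA_real_
          row$precision <- if (sum(ev$pred == pos) > 0)
            tp / sum(ev$pred == pos) else NA_real_
          row$auc <- .auc_rank(ev$p[, pos], y_val == pos)
        } else {
          rec <- vapply(seq_len(K), function(k) {
            nk <- sum(y_val == k)
            if (nk == 0) NA_real_ else sum(ev$pred == k & y_val == k) / nk
          }, numeric(1))
          prc <- vapply(seq_len(K), function(k) {
            nk <- sum(ev$pred == k)
            if (nk == 0) NA_real_ else sum(ev$pred == k & y_val == k) / nk
          }, numeric(1))
          row$recall <- mean(rec, na.rm = TRUE)
          row$precision <- mean(prc, na.rm = TRUE)
        }
      }
      history[[epoch]] <- row
    }
  })
  model$history <- do.call(rbind, history)
  model$trained <- TRUE
  model
}

#' Route windows through the detection-then-typing pipeline
#'
#' The binary model screens every window; only windows it flags as seizure
#' reach the multigroup model, which assigns the type. Background windows
#' keep the label `bckg`.
#'
#' @param binary_model trained binary `seizr_model`
#' @param multigroup_model trained multigroup `seizr_model`
#' @param x input array `channels x freq x time x n`
#' @return character labels: `bckg` or a seizure type per window
#' @export
classify_pipeline <- function(binary_model, multigroup_model, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  det <- predict_labels(binary_model, x)
  out <- rep("bckg", dim(x)[4L])
  hit <- which(det == binary_model$class_labels[2L])
  if (length(hit) > 0L)
    out[hit] <- predict_labels(multigroup_model,
                               x[, , , hit, drop = FALSE])
  out
}

#' Collapse annotation labels to the binary detection task
#'
#' @param labels character labels from [ANNOTATION_LABELS]
#' @return `"bckg"` or `"seiz"` per element
#' @export
binarize_labels <- function(labels) {
  ifelse(labels == "bckg", "bckg", "seiz")
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a single RDS file holding the architecture descriptor
#' and all parameters (including batch-norm running statistics), so a
#' loaded model reproduces predictions exactly.
#'
#' @param model a `seizr_model`
#' @param path checkpoint path
#' @export
save_model <- function(model, path) {
  arch <- list(kind = model$kind, input_shape = model$input_shape,
               class_labels = model$class_labels,
               input_stats = model$input_stats)
  state <- lapply(model$layers, function(l) {
    s <- list(params = l$params)
    if (l$type == "bn") {
      s$run_mean <- l$run_mean; s$run_var <- l$run_var
    }
    s
  })
  saveRDS(list(arch = arch, state = state, history = model$history), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  model <- if (ck$arch$kind == "binary_cnn")
    build_binary_cnn(ck$arch$input_shape, ck$arch$class_labels)
  else
    build_multigroup_model(ck$arch$input_shape, ck$arch$class_labels)
  for (i in seq_along(model$layers)) {
    model$layers[[i]]$params <- ck$state[[i]]$params
    if (model$layers[[i]]$type == "bn") {
      model$layers[[i]]$run_mean <- ck$state[[i]]$run_mean
      model$layers[[i]]$run_var <- ck$state[[i]]$run_var
    }
  }
  model$input_stats <- ck$arch$input_stats
  model$history <- ck$history
  model$trained <- TRUE
  model
}
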