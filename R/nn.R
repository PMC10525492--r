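#' @title Minimal neural-network engine
#' @description Forward/backward passes for the two architectures the
#'   package trains: 2-D convolution (3x3, stride 1, padding 1) via
#'   im2col + BLAS matrix products, 2x2 max pooling, batch normalization,
#'   dropout, dense layers, and a convolutional LSTM with backpropagation
#'   through time. Tensors are held as flattened column vectors in
#'   (channel-fastest, then rows, then columns) order; a batch is a matrix
#'   with one column per sample. Layers are environments so caches, batch
#'   statistics and Adam moments persist across calls.
#' @name nn-engine
#' @keywords internal
NULL

.sigmoid <- function(x) 1 / (1 + exp(-x))

# geometry descriptor for 3x3 / stride-1 / padding-1 convolution
.conv_geom <- function(C, H, W) {
  list(C = C, H = H, W = W, HW = H * W)
}

.he_init <- function(nrow_, ncol_, fan_in) {
  matrix(stats::rnorm(nrow_ * ncol_, sd = sqrt(2 / fan_in)), nrow_, ncol_)
}

# ---- layer constructors (environments) -------------------------------------

.layer_conv <- function(C, H, W, K) {
  l <- new.env(parent = emptyenv())
  l$type <- "conv"
  l$geom <- .conv_geom(C, H, W)
  l$K <- K
  l$params <- list(W = .he_init(K, C * 9L, C * 9L), b = numeric(K))
  l$out_dim <- c(K, H, W)
  l
}

.conv_fwd <- function(l, x, cache = TRUE) {
  if (cache) l$cache <- list(x = x)
  g <- l$geom
  cpp_conv3x3_fwd(x, l$params$W, l$params$b, g$C, g$H, g$W)
}

.conv_bwd <- function(l, dout) {
  g <- l$geom
  r <- cpp_conv3x3_bwd(l$cache$x, dout, l$params$W, g$C, g$H, g$W, TRUE)
  l$grads <- list(W = r$dW, b = r$db)
  r$dX
}

.layer_relu <- function(dim) {
  l <- new.env(parent = emptyenv())
  l$type <- "relu"; l$params <- list(); l$out_dim <- dim
  l
}

.layer_pool <- function(K, H, W) {
  H2 <- H %/% 2L; W2 <- W %/% 2L
  if (H2 < 1L || W2 < 1L)
    stop("spatial dimensions ", H, "x", W, " collapse under 2x2 pooling")
  flat <- function(k, h, w) k + K * (h - 1L) + K * H * (w - 1L)
  og <- expand.grid(k = seq_len(K), h = seq_len(H2), w = seq_len(W2))
  MPI <- cbind(flat(og$k, 2L * og$h - 1L, 2L * og$w - 1L),
               flat(og$k, 2L * og$h,      2L * og$w - 1L),
               flat(og$k, 2L * og$h - 1L, 2L * og$w),
               flat(og$k, 2L * og$h,      2L * og$w))
  l <- new.env(parent = emptyenv())
  l$type <- "pool"; l$params <- list()
  l$MPI <- MPI; l$in_len <- K * H * W
  l$out_dim <- c(K, H2, W2)
  l
}

.pool_fwd <- function(l, x, training) {
  N <- ncol(x)
  P <- nrow(l$MPI)
  G <- matrix(0, P * N, 4L)
  for (j in 1:4) G[, j] <- as.vector(x[l$MPI[, j], , drop = FALSE])
  choice <- max.col(G, ties.method = "first")
  out_vec <- G[cbind(seq_len(P * N), choice)]
  if (training) {
    pos <- rep(seq_len(P), times = N)
    n_of <- rep(seq_len(N), each = P)
    l$cache <- list(lin = l$MPI[cbind(pos, choice)] + (n_of - 1L) * l$in_len,
                    N = N)
  }
  matrix(out_vec, P, N)
}

.pool_bwd <- function(l, dout) {
  dx <- matrix(0, l$in_len, l$cache$N)
  dx[l$cache$lin] <- as.vector(dout)
  dx
}

.layer_bn <- function(K, spatial_len, momentum = 0.1, eps = 1e-5) {
  l <- new.env(parent = emptyenv())
  l$type <- "bn"
  l$params <- list(gamma = rep(1, K), beta = numeric(K))
  l$ch <- rep(seq_len(K), times = spatial_len)
  l$K <- K
  l$run_mean <- numeric(K); l$run_var <- rep(1, K)
  l$momentum <- momentum; l$eps <- eps
  l$out_dim <- c(K, spatial_len)
  l
}

.bn_fwd <- function(l, x, training) {
  if (training) {
    M <- length(x) / l$K
    # per-channel moments over (spatial x batch)
    s1 <- rowSums(rowsum(x, l$ch)) / M
    xc <- x - s1[l$ch]
    v <- rowSums(rowsum(xc^2, l$ch)) / M
    l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * s1
    l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * v
    inv <- 1 / sqrt(v + l$eps)
    xhat <- xc * inv[l$ch]
    l$cache <- list(xhat = xhat, inv = inv, M = M, training = TRUE)
    l$params$gamma[l$ch] * xhat + l$params$beta[l$ch]
  } else {
    inv <- 1 / sqrt(l$run_var + l$eps)
    xhat <- (x - l$run_mean[l$ch]) * inv[l$ch]
    l$cache <- list(inv = inv, training = FALSE)
    l$params$gamma[l$ch] * xhat + l$params$beta[l$ch]
  }
}

.bn_bwd <- function(l, dout) {
  if (!isTRUE(l$cache$training)) {
    # inference-mode statistics are constants
    return(dout * (l$params$gamma * l$cache$inv)[l$ch])
  }
  xhat <- l$cache$xhat; M <- l$cache$M
  dgamma <- rowSums(rowsum(dout * xhat, l$ch))
  dbeta <- rowSums(rowsum(dout, l$ch))
  l$grads <- list(gamma = dgamma, beta = dbeta)
  g_inv <- l$params$gamma[l$ch] * l$cache$inv[l$ch]
  g_inv * (dout - (dbeta / M)[l$ch] - xhat * (dgamma / M)[l$ch])
}

.layer_dropout <- function(p) {
  l <- new.env(parent = emptyenv())
  l$type <- "dropout"; l$params <- list(); l$p <- p
  l
}

.dropout_fwd <- function(l, x, training) {
  if (!training || l$p <= 0) return(x)
  mask <- matrix(stats::runif(length(x)) >= l$p, nrow(x), ncol(x)) / (1 - l$p)
  l$cache <- list(mask = mask)
  x * mask
}

.dropout_bwd <- function(l, dout) {
  if (is.null(l$cache)) return(dout)
  out <- dout * l$cache$mask
  l$cache <- NULL
  out
}

.layer_dense <- function(D, U, act = c("relu", "linear")) {
  l <- new.env(parent = emptyenv())
  l$type <- "dense"; l$act <- match.arg(act)
  l$params <- list(W = .he_init(U, D, D), b = numeric(U))
  l$out_dim <- U
  l
}

.dense_fwd <- function(l, x, training) {
  z <- l$params$W %*% x + l$params$b
  if (l$act == "relu") {
    l$cache <- list(x = x, mask = z > 0)
    pmax(z, 0)
  } else {
    l$cache <- list(x = x)
    z
  }
}

.dense_bwd <- function(l, dout) {
  if (l$act == "relu") dout <- dout * l$cache$mask
  l$grads <- list(W = dout %*% t(l$cache$x), b = rowSums(dout))
  t(l$params$W) %*% dout
}

# ---- ConvLSTM --------------------------------------------------------------

.layer_convlstm <- function(Cin, H, W, K, return_sequence) {
  l <- new.env(parent = emptyenv())
  l$type <- "convlstm"
  l$geom_x <- .conv_geom(Cin, H, W)
  l$geom_h <- .conv_geom(K, H, W)
  l$K <- K; l$Cin <- Cin; l$H <- H; l$W <- W
  l$return_sequence <- return_sequence
  fan <- (Cin + K) * 9L
  l$params <- list(Wx = .he_init(4L * K, Cin * 9L, fan),
                   Wh = .he_init(4L * K, K * 9L, fan),
                   b = numeric(4L * K))
  l$gate_rows <- lapply(0:3, function(g) {
    ch <- g * K + seq_len(K)
    as.vector(outer(ch, (seq_len(H * W) - 1L) * 4L * K, `+`))
  })
  b <- numeric(4L * K); b[K + seq_len(K)] <- 1   # gates ordered i, f, g, o
  l$params$b <- b
  l$out_dim <- c(K, H, W)
  l
}

# x_seq: array [Cin*H*W, N, T]; returns [K*HW, N, T] or [K*HW, N]
.convlstm_fwd <- function(l, x_seq, cache = TRUE) {
  dims <- dim(x_seq)
  N <- dims[2L]; T_ <- dims[3L]
  HW <- l$geom_x$HW; K <- l$K
  h <- matrix(0, K * HW, N); c_ <- matrix(0, K * HW, N)
  steps <- vector("list", T_)
  out_seq <- if (l$return_sequence) array(0, c(K * HW, N, T_)) else NULL
  gx <- l$geom_x; gh <- l$geom_h
  for (t in seq_len(T_)) {
    x_t <- matrix(x_seq[, , t], ncol = N)
    h_prev <- h
    z <- cpp_conv3x3_fwd(x_t, l$params$Wx, l$params$b, gx$C, gx$H, gx$W) +
      cpp_conv3x3_fwd(h_prev, l$params$Wh, numeric(4L * K), gh$C, gh$H, gh$W)
    gi <- .sigmoid(z[l$gate_rows[[1L]], , drop = FALSE])
    gf <- .sigmoid(z[l$gate_rows[[2L]], , drop = FALSE])
    gg <- tanh(z[l$gate_rows[[3L]], , drop = FALSE])
    go <- .sigmoid(z[l$gate_rows[[4L]], , drop = FALSE])
    c_prev <- c_
    c_ <- gf * c_prev + gi * gg
    tc <- tanh(c_)
    h <- go * tc
    if (l$return_sequence) out_seq[, , t] <- h
    if (cache)
      steps[[t]] <- list(x_t = x_t, h_prev = h_prev, gi = gi, gf = gf,
                         gg = gg, go = go, c_prev = c_prev, tc = tc)
  }
  if (cache) l$cache <- list(steps = steps, N = N, T_ = T_)
  if (l$return_sequence) out_seq else h
}

# dout: [K*HW, N, T] if return_sequence else [K*HW, N]
# returns gradient w.r.t. the input sequence [Cin*HW, N, T];
# skipped when need_input_grad is FALSE (first layer of a model)
.convlstm_bwd <- function(l, dout, need_input_grad = TRUE) {
  N <- l$cache$N; T_ <- l$cache$T_
  HW <- l$geom_x$HW; K <- l$K
  dWx <- matrix(0, 4L * K, l$Cin * 9L)
  dWh <- matrix(0, 4L * K, K * 9L)
  db <- numeric(4L * K)
  dh_next <- matrix(0, K * HW, N)
  dc_next <- matrix(0, K * HW, N)
  dx_seq <- array(0, c(l$Cin * HW, N, T_))
  for (t in rev(seq_len(T_))) {
    st <- l$cache$steps[[t]]
    dh <- dh_next + if (l$return_sequence) matrix(dout[, , t], ncol = N)
      else if (t == T_) dout else matrix(0, K * HW, N)
    dc <- dc_next + dh * st$go * (1 - st$tc^2)
    dgo <- dh * st$tc
    dgi <- dc * st$gg
    dgg <- dc * st$gi
    dgf <- dc * st$c_prev
    dc_next <- dc * st$gf
    dz <- matrix(0, 4L * K * HW, N)
    dz[l$gate_rows[[1L]], ] <- dgi * st$gi * (1 - st$gi)
    dz[l$gate_rows[[2L]], ] <- dgf * st$gf * (1 - st$gf)
    dz[l$gate_rows[[3L]], ] <- dgg * (1 - st$gg^2)
    dz[l$gate_rows[[4L]], ] <- dgo * st$go * (1 - st$go)
    gx <- l$geom_x; gh <- l$geom_h
    bx <- cpp_conv3x3_bwd(st$x_t, dz, l$params$Wx, gx$C, gx$H, gx$W,
                          need_input_grad)
    bh <- cpp_conv3x3_bwd(st$h_prev, dz, l$params$Wh, gh$C, gh$H, gh$W, TRUE)
    dWx <- dWx + bx$dW
    dWh <- dWh + bh$dW
    db <- db + bx$db
    if (need_input_grad) dx_seq[, , t] <- bx$dX
    dh_next <- bh$dX
  }
  l$grads <- list(Wx = dWx, Wh = dWh, b = db)
  dx_seq
}

# ---- Adam ------------------------------------------------------------------

.adam_init <- function(layers) {
  lapply(layers, function(l)
    lapply(l$params, function(p) list(m = p * 0, v = p * 0)))
}

.adam_step <- function(layers, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (length(l$params) == 0L || is.null(l$grads)) next
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  state
}
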