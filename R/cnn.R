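#' CNN architecture and training configuration
#'
#' Describes one of the three published network configurations on a
#' square grayscale input.  Configuration 3 (the supported default) is a
#' stack of four blocks, each `3x3` convolution (padding 1, stride 1, with
#' 16/32/64/128 filters), batch normalisation, ReLU and `2x2`/stride-2
#' max-pooling, followed by one fully-connected layer and softmax.  On a
#' 28x28 input the four pooling layers emit spatial sides 14, 7, 3 and 1.
#' Configurations 1 and 2 are buildable variants (2x2 filters with
#' padding 3, and a three-block network, respectively).
#'
#' @param n_classes number of output classes (may be `NULL` and resolved
#'   at fit time from the data).
#' @param table3_config which published configuration to build (1, 2 or 3).
#' @param input_side input image side in pixels.
#' @param input_channels input channels (1 for grayscale).
#' @param epochs training epochs.
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum coefficient.
#' @param batch_size mini-batch size.
#' @param steps_per_epoch optional cap on optimiser steps per epoch
#'   (`NULL` = every batch).
#' @param seed integer seed controlling weight initialisation and batch
#'   shuffling.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(n_classes = NULL, table3_config = 3L,
                       input_side = 28L, input_channels = 1L,
                       epochs = 30L, learning_rate = 0.01, momentum = 0.9,
                       batch_size = 32L, steps_per_epoch = NULL, seed = 1L) {
  table3_config <- as.integer(table3_config)
  stopifnot(table3_config %in% 1:3, input_side >= 1, epochs >= 1,
            learning_rate > 0, momentum >= 0, momentum < 1, batch_size >= 1)
  blocks <- switch(table3_config,
    # config 1: 2x2 filters, padding 3; pooling after the first 3 blocks
    list(list(k = 2L, n = 16L,  pad = 3L, pool = TRUE),
         list(k = 2L, n = 32L,  pad = 3L, pool = TRUE),
         list(k = 2L, n = 64L,  pad = 3L, pool = TRUE),
         list(k = 2L, n = 128L, pad = 3L, pool = FALSE)),
    # config 2: three 3x3 blocks, pooling after the first two
    list(list(k = 3L, n = 16L, pad = 1L, pool = TRUE),
         list(k = 3L, n = 32L, pad = 1L, pool = TRUE),
         list(k = 3L, n = 64L, pad = 1L, pool = FALSE)),
    # config 3 (default): four 3x3 blocks, each pooled
    list(list(k = 3L, n = 16L,  pad = 1L, pool = TRUE),
         list(k = 3L, n = 32L,  pad = 1L, pool = TRUE),
         list(k = 3L, n = 64L,  pad = 1L, pool = TRUE),
         list(k = 3L, n = 128L, pad = 1L, pool = TRUE))
  )
  structure(list(blocks = blocks, table3_config = table3_config,
                 n_classes = n_classes,
                 input_side = as.integer(input_side),
                 input_channels = as.integer(input_channels),
                 training = list(epochs = as.integer(epochs),
                                 learning_rate = learning_rate,
                                 momentum = momentum,
                                 batch_size = as.integer(batch_size),
                                 steps_per_epoch = steps_per_epoch,
                                 seed = as.integer(seed))),
            class = "cnn_config")
}

#' Per-layer architecture table
#'
#' Walks a [cnn_config()] through the size and parameter-count formulas
#' ([conv_output_size()], [pool_output_size()], [conv_param_count()]) and
#' returns the per-layer table: layer type, spatial output side, channel
#' count and learnable parameter count.
#'
#' @param config a [cnn_config()]; `n_classes` may be `NULL` (the
#'   fully-connected row is then omitted).
#' @return A data.frame with columns `layer`, `type`, `out_side`,
#'   `channels`, `params`.
#' @export
cnn_architecture <- function(config) {
  stopifnot(inherits(config, "cnn_config"))
  side <- config$input_side
  ch <- config$input_channels
  rows <- list(list(layer = "input", type = "input", out_side = side,
                    channels = ch, params = 0L))
  bi <- 0L
  for (b in config$blocks) {
    bi <- bi + 1L
    side <- conv_output_size(side, b$k, b$pad, 1L)
    rows[[length(rows) + 1L]] <- list(
      layer = paste0("conv", bi), type = "conv", out_side = side,
      channels = b$n, params = conv_param_count(b$k, b$k, ch, b$n))
    ch <- b$n
    rows[[length(rows) + 1L]] <- list(
      layer = paste0("batchnorm", bi), type = "batchnorm", out_side = side,
      channels = ch, params = 2L * ch)
    rows[[length(rows) + 1L]] <- list(
      layer = paste0("relu", bi), type = "relu", out_side = side,
      channels = ch, params = 0L)
    if (isTRUE(b$pool)) {
      side <- pool_output_size(side, 2L, 0L, 2L)
      rows[[length(rows) + 1L]] <- list(
        layer = paste0("pool", bi), type = "pool", out_side = side,
        channels = ch, params = 0L)
    }
  }
  if (!is.null(config$n_classes)) {
    d <- side * side * ch
    rows[[length(rows) + 1L]] <- list(
      layer = "fc", type = "fc", out_side = 1L,
      channels = as.integer(config$n_classes),
      params = as.integer((d + 1L) * config$n_classes))
    rows[[length(rows) + 1L]] <- list(
      layer = "softmax", type = "softmax", out_side = 1L,
      channels = as.integer(config$n_classes), params = 0L)
  }
  do.call(rbind, lapply(rows, as.data.frame))
}

#' @export
print.cnn_config <- function(x, ...) {
  cat("<cnn_config> configuration ", x$table3_config, ", input ",
      x$input_side, "x", x$input_side, "x", x$input_channels, "\n", sep = "")
  print(cnn_architecture(x))
  invisible(x)
}

#' Batch normalisation forward pass
#'
#' Normalises each channel (column) of a batch to zero mean and unit
#' variance, `xhat = (x - mu) / sqrt(var + epsilon)`, then applies the
#' learnable affine map `y = gamma * xhat + beta`.  In `"train"` mode the
#' mini-batch statistics are used; in `"infer"` mode the stored
#' full-training-set statistics (`trained_mean`, `trained_var`) must be
#' supplied.
#'
#' @param x numeric matrix, rows = batch observations, columns = channels.
#' @param gamma,beta per-channel scale and offset.
#' @param epsilon small stabiliser added to the variance.
#' @param mode `"train"` or `"infer"`.
#' @param trained_mean,trained_var stored per-channel statistics
#'   (required in `"infer"` mode).
#' @return Matrix of the same shape as `x`.
#' @export
batchnorm_forward <- function(x, gamma = rep(1, ncol(x)),
                              beta = rep(0, ncol(x)), epsilon = 1e-5,
                              mode = c("train", "infer"),
                              trained_mean = NULL, trained_var = NULL) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (mode == "train") {
    if (nrow(x) < 2L) stop("train-mode batch normalisation needs >= 2 rows")
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
  } else {
    if (is.null(trained_mean) || is.null(trained_var)) {
      stop("infer-mode batch normalisation requires trained statistics")
    }
    mu <- trained_mean; v <- trained_var
  }
  m <- nrow(x)
  xhat <- (x - rep(mu, each = m)) / rep(sqrt(v + epsilon), each = m)
  xhat * rep(gamma, each = m) + rep(beta, each = m)
}

# ---- internal network machinery ------------------------------------------
#
# Activations travel as flat matrices of shape (pixels * batch) x channels
# with rows ordered pixel-fastest, image-second.  In that layout the
# convolution's im2col gather is one vector subscript, batch norm is pure
# column arithmetic, and the output of `G %*% W` is already the next
# layer's input — no array transposes anywhere on the hot path.

# truncated-normal init (+-2 sd), sd scaled by fan-in
init_weights <- function(n, fan_in) {
  sd <- sqrt(2 / fan_in)
  u <- stats::runif(n, stats::pnorm(-2), stats::pnorm(2))
  stats::qnorm(u) * sd
}

# Per-output-pixel gather map of a convolution in unpadded input pixel
# coordinates; 0 marks a padded (zero) tap.  Columns ordered kr-fastest,
# matching the filter-weight row order (kr, kc, channel).
make_conv_pix <- function(h, w, k, pad, stride) {
  oh <- conv_output_size(h, k, pad, stride)
  ow <- conv_output_size(w, k, pad, stride)
  r0 <- rep((seq_len(oh) - 1L) * stride - pad, times = ow)
  c0 <- rep((seq_len(ow) - 1L) * stride - pad, each = oh)
  pix <- matrix(0L, oh * ow, k * k)
  col <- 0L
  for (kc in seq_len(k)) for (kr in seq_len(k)) {
    col <- col + 1L
    rr <- r0 + kr; cc <- c0 + kc
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    pix[, col] <- ifelse(ok, (cc - 1L) * h + rr, 0L)
  }
  pix
}

make_pool_pos <- function(h, w, k, s) {
  oh <- pool_output_size(h, k, 0L, s)
  ow <- pool_output_size(w, k, 0L, s)
  pr <- rep((seq_len(oh) - 1L) * s, times = ow)
  pc <- rep((seq_len(ow) - 1L) * s, each = oh)
  pos <- matrix(0L, oh * ow, k * k)
  col <- 0L
  for (kc in seq_len(k)) for (kr in seq_len(k)) {
    col <- col + 1L
    pos[, col] <- (pc + kc - 1L) * h + (pr + kr)
  }
  pos
}

# Expand a per-pixel gather map to a whole batch of N images stacked in
# the flat layout; zeros (padding taps) map to the appended zero row.
expand_rows <- function(pix, hw, N, zero_row = NULL) {
  op <- nrow(pix); kk <- ncol(pix)
  offs <- rep.int((seq_len(N) - 1L) * hw, rep.int(op, N))
  out <- matrix(0L, op * N, kk)
  for (j in seq_len(kk)) {
    v <- rep.int(pix[, j], N) + offs
    if (!is.null(zero_row)) {
      pad_tap <- rep.int(pix[, j] == 0L, N)
      if (any(pad_tap)) v[pad_tap] <- zero_row
    }
    out[, j] <- v
  }
  out
}

# gather/scatter index tables are cached per (layer, batch size)
layer_cache <- function(env, i, N, build) {
  key <- paste0(i, "_", N)
  val <- env[[key]]
  if (is.null(val)) {
    val <- build()
    env[[key]] <- val
  }
  val
}

# Builds the layer list for a config; draws initial weights from the
# current RNG stream (callers wrap in with_seed).
build_layers <- function(config) {
  stopifnot(!is.null(config$n_classes), config$n_classes >= 2)
  h <- config$input_side; w <- config$input_side; ch <- config$input_channels
  layers <- list()
  for (b in config$blocks) {
    oh <- conv_output_size(h, b$k, b$pad, 1L)
    ow <- conv_output_size(w, b$k, b$pad, 1L)
    kkc <- b$k * b$k * ch
    layers[[length(layers) + 1L]] <- list(
      type = "conv", k = b$k, pad = b$pad, stride = 1L,
      in_shape = c(h, w, ch), out_shape = c(oh, ow, b$n),
      W = matrix(init_weights(kkc * b$n, kkc), kkc, b$n),
      b = numeric(b$n),
      pix = make_conv_pix(h, w, b$k, b$pad, 1L))
    h <- oh; w <- ow; ch <- b$n
    layers[[length(layers) + 1L]] <- list(
      type = "bn", gamma = rep(1, ch), beta = rep(0, ch), eps = 1e-5,
      trained_mean = NULL, trained_var = NULL)
    layers[[length(layers) + 1L]] <- list(type = "relu")
    if (isTRUE(b$pool)) {
      oh <- pool_output_size(h, 2L, 0L, 2L)
      ow <- pool_output_size(w, 2L, 0L, 2L)
      layers[[length(layers) + 1L]] <- list(
        type = "pool", k = 2L, s = 2L, in_shape = c(h, w, ch),
        out_shape = c(oh, ow, ch), pos = make_pool_pos(h, w, 2L, 2L))
      h <- oh; w <- ow
    }
  }
  d <- h * w * ch
  layers[[length(layers) + 1L]] <- list(
    type = "fc", in_dim = d, in_shape = c(h, w, ch),
    W = matrix(init_weights(d * config$n_classes, d), config$n_classes, d),
    b = numeric(config$n_classes))
  layers
}

conv_fw <- function(ly, X, N, idx) {
  Xa <- rbind(X, 0)
  G <- Xa[as.vector(idx$gidx), , drop = FALSE]
  dim(G) <- c(nrow(idx$gidx), ncol(idx$gidx) * ncol(X))
  A <- G %*% ly$W
  A <- A + rep(ly$b, each = nrow(A))
  list(out = A, G = G)
}

conv_bw <- function(ly, cache, dM, N, idx) {
  dW <- crossprod(cache$G, dM)
  db <- colSums(dM)
  cin <- ly$in_shape[3]
  dG <- tcrossprod(dM, ly$W)
  dim(dG) <- c(length(idx$gidx), cin)
  acc <- rowsum(dG, group = idx$gvec, reorder = TRUE)
  hw <- ly$in_shape[1] * ly$in_shape[2]
  dX <- matrix(0, hw * N + 1L, cin)
  dX[idx$ui, ] <- acc
  list(dX = dX[-(hw * N + 1L), , drop = FALSE], dW = dW, db = db)
}

# y = a x + b with per-channel a = gamma/sd and b = beta - a mu; the raw
# input is kept for the backward pass instead of materialising xhat
bn_fw <- function(ly, X, mode) {
  if (mode == "infer") {
    if (is.null(ly$trained_mean)) {
      stop("batch-norm inference requested before trained statistics exist")
    }
    mu <- ly$trained_mean; v <- ly$trained_var
  } else {
    mu <- colMeans(X)
    v <- colMeans(X * X) - mu * mu
  }
  m <- nrow(X)
  invstd <- 1 / sqrt(v + ly$eps)
  a <- ly$gamma * invstd
  out <- X * rep(a, each = m) + rep(ly$beta - a * mu, each = m)
  list(out = out, X = X, invstd = invstd, m = m, mu = mu, v = v)
}

bn_bw <- function(ly, cache, dY) {
  m <- cache$m
  mu <- cache$mu; invstd <- cache$invstd
  dbeta <- colSums(dY)
  dgamma <- invstd * (colSums(dY * cache$X) - mu * dbeta)
  a <- ly$gamma * invstd
  cb <- a * invstd * dgamma / m
  dX <- dY * rep(a, each = m) - cache$X * rep(cb, each = m) +
    rep(cb * mu - a * dbeta / m, each = m)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

pool_fw <- function(ly, X, N, idx) {
  prow <- idx$prow
  out <- X[prow[, 1L], , drop = FALSE]
  amax <- matrix(1L, nrow(out), ncol(out))
  for (j in 2:ncol(prow)) {
    Aj <- X[prow[, j], , drop = FALSE]
    upd <- Aj > out
    if (any(upd)) {
      amax[upd] <- j
      out[upd] <- Aj[upd]
    }
  }
  list(out = out, amax = amax)
}

pool_bw <- function(ly, cache, dOut, N, idx) {
  # stride >= window in all shipped configs, so chosen cells are unique
  hw <- ly$in_shape[1] * ly$in_shape[2]
  cch <- ncol(dOut)
  m <- nrow(dOut)
  row_i <- rep.int(seq_len(m), cch)
  chosen <- idx$prow[cbind(row_i, as.vector(cache$amax))]
  lin <- chosen + (rep.int(seq_len(cch) - 1L, rep.int(m, cch))) * (hw * N)
  dX <- matrix(0, hw * N, cch)
  dX[lin] <- as.vector(dOut)
  dX
}

fc_fw <- function(ly, X, N) {
  hw <- ly$in_shape[1] * ly$in_shape[2]; cin <- ly$in_shape[3]
  Fm <- matrix(aperm(array(X, c(hw, N, cin)), c(1, 3, 2)), ly$in_dim, N)
  list(out = ly$W %*% Fm + ly$b, F = Fm)
}

fc_bw <- function(ly, cache, dA, N) {
  hw <- ly$in_shape[1] * ly$in_shape[2]; cin <- ly$in_shape[3]
  dF <- crossprod(ly$W, dA)
  dX <- matrix(aperm(array(dF, c(hw, cin, N)), c(1, 3, 2)), hw * N, cin)
  list(dX = dX, dW = tcrossprod(dA, cache$F), db = rowSums(dA))
}

# X: flat layout matrix (hw*N) x channels; returns fc activations
# (n_classes x N) plus caches / collected batch-norm statistics
net_forward <- function(layers, X, N, mode = "infer", keep_cache = FALSE,
                        idx_env = new.env(parent = emptyenv())) {
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  collected <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      hw <- ly$in_shape[1] * ly$in_shape[2]
      idx <- layer_cache(idx_env, i, N, function() {
        gidx <- expand_rows(ly$pix, hw, N, zero_row = hw * N + 1L)
        gvec <- as.vector(gidx)
        list(gidx = gidx, gvec = gvec, ui = sort.int(unique(gvec)))
      })
      r <- conv_fw(ly, X, N, idx)
      X <- r$out
      if (keep_cache) caches[[i]] <- list(G = r$G, idx = idx)
    } else if (ly$type == "bn") {
      r <- bn_fw(ly, X, if (mode == "infer") "infer" else "train")
      X <- r$out
      if (keep_cache) caches[[i]] <- r
      if (mode == "collect") collected[[i]] <- list(mu = r$mu, v = r$v)
    } else if (ly$type == "relu") {
      mask <- X > 0
      if (keep_cache) caches[[i]] <- list(mask = mask)
      X <- X * mask
    } else if (ly$type == "pool") {
      hw <- ly$in_shape[1] * ly$in_shape[2]
      idx <- layer_cache(idx_env, i, N, function() {
        list(prow = expand_rows(ly$pos, hw, N))
      })
      r <- pool_fw(ly, X, N, idx)
      if (keep_cache) caches[[i]] <- list(amax = r$amax, idx = idx)
      X <- r$out
    } else if (ly$type == "fc") {
      r <- fc_fw(ly, X, N)
      if (keep_cache) caches[[i]] <- list(F = r$F)
      X <- r$out
    }
  }
  list(act = X, caches = caches, collected = collected)
}

softmax_cols <- function(A) {
  A <- A - rep(apply(A, 2, max), each = nrow(A))
  E <- exp(A)
  E / rep(colSums(E), each = nrow(A))
}

net_backward <- function(layers, caches, dA, N) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (ly$type == "fc") {
      r <- fc_bw(ly, caches[[i]], dA, N)
      grads[[i]] <- list(dW = r$dW, db = r$db)
      dA <- r$dX
    } else if (ly$type == "pool") {
      dA <- pool_bw(ly, caches[[i]], dA, N, caches[[i]]$idx)
    } else if (ly$type == "relu") {
      dA <- dA * caches[[i]]$mask
    } else if (ly$type == "bn") {
      r <- bn_bw(ly, caches[[i]], dA)
      grads[[i]] <- list(dgamma = r$dgamma, dbeta = r$dbeta)
      dA <- r$dX
    } else if (ly$type == "conv") {
      r <- conv_bw(ly, caches[[i]], dA, N, caches[[i]]$idx)
      grads[[i]] <- list(dW = r$dW, db = r$db)
      dA <- r$dX
    }
  }
  grads
}

# 4-d input tensor (h, w, c, N) -> flat layout (hw*N) x c
to_layout <- function(X4) {
  d <- dim(X4)
  if (d[3] == 1L) {
    matrix(X4, d[1] * d[2] * d[4], 1L)
  } else {
    matrix(aperm(X4, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  }
}

# ---- fitting --------------------------------------------------------------

#' Fit the convolutional network
#'
#' Trains the configured CNN on a labeled dataset by stochastic gradient
#' descent with momentum on the softmax cross-entropy loss.  Mini-batch
#' statistics drive the batch-normalisation layers during training; after
#' the last epoch each layer's statistics are recomputed over the full
#' training set and stored for inference.
#'
#' @param ds a [labeled_dataset()] whose images match the configured
#'   input size, or a numeric array `h x w x 1 x N` (then `y` is
#'   required).
#' @param config a [cnn_config()]; `n_classes` is resolved from the data
#'   when `NULL`.
#' @param labels which dataset labels to classify: `"genus"` or
#'   `"suborder"` (ignored when `y` is given).
#' @param y optional explicit label vector.
#' @param verbose print per-epoch loss/accuracy.
#' @return An object of class `myxo_cnn` with the trained layers, the
#'   class list, the configuration and a per-epoch `training_log`
#'   (data.frame with `epoch`, `loss`, `accuracy`).
#' @seealso [predict.myxo_cnn()], [extract_features()], [ecnn()]
#' @export
cnn_fit <- function(ds, config = cnn_config(),
                    labels = c("genus", "suborder"), y = NULL,
                    verbose = FALSE) {
  labels <- match.arg(labels)
  if (inherits(ds, "myxo_dataset")) {
    X <- dataset_tensor(ds)
    if (is.null(y)) y <- ds[[labels]]
  } else {
    X <- ds
    if (is.null(y)) stop("y is required when ds is a plain array")
  }
  stopifnot(length(dim(X)) == 4L, dim(X)[4] == length(y))
  if (dim(X)[1] != config$input_side || dim(X)[2] != config$input_side) {
    stop("images are ", dim(X)[1], "x", dim(X)[2],
         " but the configuration expects ", config$input_side, "x",
         config$input_side)
  }
  classes <- sort(unique(as.character(y)))
  if (is.null(config$n_classes)) {
    config$n_classes <- length(classes)
  } else if (config$n_classes != length(classes)) {
    stop("config declares ", config$n_classes, " classes but the labels ",
         "contain ", length(classes))
  }
  yi <- match(as.character(y), classes)
  N <- dim(X)[4]
  hw <- dim(X)[1] * dim(X)[2]
  cin <- dim(X)[3]
  tr <- config$training
  Y <- matrix(0, length(classes), N)
  Y[cbind(yi, seq_len(N))] <- 1
  # flat layout of the full set, images addressable by column blocks
  Xcols <- matrix(to_layout(X), hw, N * cin)  # (hw) x (N*cin) column view
  pick <- function(bi) {
    nb <- length(bi)
    cols <- as.vector(outer(bi, (seq_len(cin) - 1L) * N, "+"))
    matrix(Xcols[, cols], hw * nb, cin)
  }
  idx_env <- new.env(parent = emptyenv())

  with_seed(tr$seed, {
    layers <- build_layers(config)
    vel <- lapply(layers, function(ly) {
      switch(ly$type,
             conv = list(W = ly$W * 0, b = ly$b * 0),
             bn = list(gamma = ly$gamma * 0, beta = ly$beta * 0),
             fc = list(W = ly$W * 0, b = ly$b * 0),
             NULL)
    })
    log_loss <- numeric(tr$epochs); log_acc <- numeric(tr$epochs)
    for (ep in seq_len(tr$epochs)) {
      ord <- sample.int(N)
      starts <- seq(1L, N, by = tr$batch_size)
      if (!is.null(tr$steps_per_epoch)) {
        starts <- starts[seq_len(min(length(starts), tr$steps_per_epoch))]
      }
      ep_loss <- 0; ep_correct <- 0L; ep_n <- 0L
      for (s in starts) {
        bi <- ord[s:min(s + tr$batch_size - 1L, N)]
        if (length(bi) < 2L) next  # batch norm needs >= 2 samples
        nb <- length(bi)
        Xb <- pick(bi)
        Yb <- Y[, bi, drop = FALSE]
        fw <- net_forward(layers, Xb, nb, mode = "train", keep_cache = TRUE,
                          idx_env = idx_env)
        P <- softmax_cols(fw$act)
        ep_loss <- ep_loss - sum(log(pmax(P[Yb > 0], 1e-12)))
        pred <- max.col(t(P), ties.method = "first")
        ep_correct <- ep_correct + sum(pred == yi[bi])
        ep_n <- ep_n + nb
        grads <- net_backward(layers, fw$caches, (P - Yb) / nb, nb)
        for (i in seq_along(layers)) {
          g <- grads[[i]]
          if (is.null(g)) next
          for (nm in names(vel[[i]])) {
            gn <- switch(nm, W = g$dW, b = g$db,
                         gamma = g$dgamma, beta = g$dbeta)
            vel[[i]][[nm]] <- tr$momentum * vel[[i]][[nm]] -
              tr$learning_rate * gn
            layers[[i]][[nm]] <- layers[[i]][[nm]] + vel[[i]][[nm]]
          }
        }
      }
      log_loss[ep] <- ep_loss / max(ep_n, 1L)
      log_acc[ep] <- ep_correct / max(ep_n, 1L)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f",
                        ep, log_loss[ep], log_acc[ep]))
      }
    }
    # finalise batch-norm statistics over the full training set
    fin <- net_forward(layers, pick(seq_len(N)), N, mode = "collect",
                       idx_env = idx_env)
    for (i in seq_along(layers)) {
      if (!is.null(fin$collected[[i]])) {
        layers[[i]]$trained_mean <- fin$collected[[i]]$mu
        layers[[i]]$trained_var <- fin$collected[[i]]$v
      }
    }
    structure(list(layers = layers, config = config, classes = classes,
                   label_type = if (inherits(ds, "myxo_dataset")) labels
                                else "custom",
                   training_log = data.frame(epoch = seq_len(tr$epochs),
                                             loss = log_loss,
                                             accuracy = log_acc)),
              class = "myxo_cnn")
  })
}

#' @export
print.myxo_cnn <- function(x, ...) {
  tl <- x$training_log
  cat("<myxo_cnn> configuration ", x$config$table3_config, ", ",
      length(x$classes), " classes; final training loss ",
      sprintf("%.4f", tl$loss[nrow(tl)]), ", accuracy ",
      sprintf("%.3f", tl$accuracy[nrow(tl)]), "\n", sep = "")
  invisible(x)
}

#' @export
summary.myxo_cnn <- function(object, ...) {
  cat("Trained CNN (configuration ", object$config$table3_config, ")\n",
      sep = "")
  print(cnn_architecture(object$config))
  cat("\nClasses: ", paste(object$classes, collapse = ", "), "\n", sep = "")
  invisible(object)
}

as_input_tensor <- function(model, newdata) {
  if (inherits(newdata, "myxo_dataset")) {
    X <- dataset_tensor(newdata)
  } else if (is.matrix(newdata)) {
    X <- array(newdata / 255, c(dim(newdata), 1L, 1L))
  } else X <- newdata
  s <- model$config$input_side
  if (dim(X)[1] != s || dim(X)[2] != s) {
    stop("images are ", dim(X)[1], "x", dim(X)[2], " but the model expects ",
         s, "x", s)
  }
  X
}

infer_batches <- function(model, X, chunk = 256L) {
  N <- dim(X)[4]
  out <- matrix(0, length(model$classes), N)
  idx_env <- new.env(parent = emptyenv())
  for (s in seq(1L, N, by = chunk)) {
    i <- s:min(s + chunk - 1L, N)
    Xi <- X[, , , i, drop = FALSE]
    out[, i] <- net_forward(model$layers, to_layout(Xi), length(i),
                            mode = "infer", idx_env = idx_env)$act
  }
  out
}

#' Predict from a trained CNN
#'
#' @param object a fitted [cnn_fit()] model.
#' @param newdata a `myxo_dataset`, a single image matrix (intensities in
#'   `[0, 255]`), or an input tensor `h x w x 1 x N` already scaled to
#'   `[0, 1]`.
#' @param type `"class"` (predicted labels), `"prob"` (softmax class
#'   probabilities, `N x n_classes`), or `"features"` (pre-softmax
#'   fully-connected activations, `N x n_classes`).
#' @param ... ignored.
#' @return Character vector or numeric matrix according to `type`.
#' @export
predict.myxo_cnn <- function(object, newdata,
                             type = c("class", "prob", "features"), ...) {
  type <- match.arg(type)
  X <- as_input_tensor(object, newdata)
  A <- infer_batches(object, X)
  if (type == "features") {
    out <- t(A); colnames(out) <- object$classes
    return(out)
  }
  P <- softmax_cols(A)
  if (type == "prob") {
    out <- t(P); colnames(out) <- object$classes
    return(out)
  }
  object$classes[max.col(t(P), ties.method = "first")]
}

#' Extract fully-connected-layer features
#'
#' Returns the pre-softmax fully-connected activations used as the
#' feature representation for hybrid classifier heads; one row per image,
#' one column per class (so a 25-class model yields 1 x 25 features).
#'
#' @param model a fitted [cnn_fit()] model.
#' @param images as `newdata` in [predict.myxo_cnn()].
#' @return Numeric matrix, `N x n_classes`.
#' @export
extract_features <- function(model, images) {
  stopifnot(inherits(model, "myxo_cnn"))
  predict(model, images, type = "features")
}

#' Softmax class probabilities for a single image
#'
#' @param model a fitted [cnn_fit()] model.
#' @param image a grayscale image matrix (intensities in `[0, 255]`).
#' @return Named probability vector over the model's classes (sums to 1).
#' @export
predict_softmax <- function(model, image) {
  p <- predict(model, image, type = "prob")
  stats::setNames(as.numeric(p[1L, ]), model$classes)
}

#' Plot the training history of a fitted CNN
#'
#' Loss and training accuracy per epoch, on a shared epoch axis.
#'
#' @param x a fitted [cnn_fit()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.myxo_cnn <- function(x, ...) {
  tl <- x$training_log
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(tl$epoch, tl$loss, type = "l", lwd = 2,
                 xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::par(new = TRUE)
  graphics::plot(tl$epoch, tl$accuracy, type = "l", lty = 2, col = "grey40",
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4)
  graphics::mtext("training accuracy", side = 4, line = 2.5)
  invisible(x)
}
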