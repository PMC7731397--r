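# Small from-scratch convolutional network for binary grayscale
# classification: repeated (3x3 stride-1 conv, same padding -> ReLU -> 2x2
# max-pool) blocks, then a fully connected layer and softmax over the two
# classes. Implemented with im2col matrix multiplication and trained with
# Adam on the cross-entropy loss; single-threaded and deterministic given
# the config seed.

#' Convolutional network configuration
#'
#' Every convolution uses 3x3 filters with stride 1 and same padding; each
#' block halves the spatial size with a 2x2 max-pool. The head is one fully
#' connected layer with a 2-way softmax.
#'
#' @param input_size square input side length (default 224; reduced sizes
#'   train in seconds on a CPU).
#' @param channels per-block output channel counts (default 16, 32, 64).
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param rng_seed initialization/shuffling seed.
#' @return List of class `convnet_config`.
#' @export
convnet_config <- function(input_size = 224L, channels = c(16L, 32L, 64L),
                           epochs = 20L, batch_size = 16L,
                           learning_rate = 1e-3, rng_seed = 1L) {
  if (any(channels < 1)) stop_param("channel counts must be >= 1")
  structure(list(input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 filter_size = 3L, stride = 1L,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, rng_seed = as.integer(rng_seed)),
            class = "convnet_config")
}

#' Feature-map sizes through the network
#'
#' Same-padded 3x3 stride-1 convolutions preserve the spatial size; each 2x2
#' max-pool halves it (floor). Returns the side length after each block.
#'
#' @param config a [convnet_config()].
#' @return Integer vector, one entry per block.
#' @export
convnet_map_sizes <- function(config) {
  s <- config$input_size
  out <- integer(length(config$channels))
  for (i in seq_along(config$channels)) {
    s <- s %/% 2L
    out[i] <- s
  }
  out
}

# --- layer primitives (x: H x W x C array) ---

im2col <- function(x, H, W, C) {
  # same padding: pad 1 on each side, output (H*W) x (9C)
  xp <- array(0, c(H + 2, W + 2, C))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  cols <- matrix(0, H * W, 9 * C)
  k <- 0
  for (c in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
    k <- k + 1
    cols[, k] <- as.vector(xp[(1 + di):(H + di), (1 + dj):(W + dj), c])
  }
  cols
}

conv_forward <- function(x, Wf, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  cols <- im2col(x, H, W, C)
  out <- cols %*% Wf + matrix(b, H * W, length(b), byrow = TRUE)
  list(out = array(out, c(H, W, ncol(Wf))), cols = cols)
}

conv_backward <- function(grad_out, cache, Wf, H, W, C) {
  G <- matrix(grad_out, H * W, ncol(Wf))
  dW <- t(cache$cols) %*% G
  db <- colSums(G)
  dcols <- G %*% t(Wf)
  # col2im (scatter-add back through padding)
  dxp <- array(0, c(H + 2, W + 2, C))
  k <- 0
  for (c in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
    k <- k + 1
    dxp[(1 + di):(H + di), (1 + dj):(W + dj), c] <-
      dxp[(1 + di):(H + di), (1 + dj):(W + dj), c] + matrix(dcols[, k], H, W)
  }
  list(dx = dxp[2:(H + 1), 2:(W + 1), , drop = FALSE], dW = dW, db = db)
}

maxpool_forward <- function(x) {
  d <- dim(x); H2 <- d[1] %/% 2; W2 <- d[2] %/% 2; C <- d[3]
  xt <- x[seq_len(2 * H2), seq_len(2 * W2), , drop = FALSE]
  a <- xt[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2), , drop = FALSE]
  b <- xt[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2), , drop = FALSE]
  cc <- xt[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2), , drop = FALSE]
  dd <- xt[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2), , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  list(out = out, argmax = list(a = out == a, b = out == b & out != a,
                                cc = out == cc & out != a & out != b,
                                dd = out == dd & out != a & out != b & out != cc),
       in_dim = d)
}

maxpool_backward <- function(grad_out, cache) {
  d <- cache$in_dim; H2 <- dim(grad_out)[1]; W2 <- dim(grad_out)[2]
  dx <- array(0, d)
  put <- function(sel, ri, ci) {
    g <- grad_out * sel
    dx[ri, ci, ] <<- dx[ri, ci, , drop = FALSE] + g
  }
  put(cache$argmax$a, seq(1, 2 * H2, 2), seq(1, 2 * W2, 2))
  put(cache$argmax$b, seq(2, 2 * H2, 2), seq(1, 2 * W2, 2))
  put(cache$argmax$cc, seq(1, 2 * H2, 2), seq(2, 2 * W2, 2))
  put(cache$argmax$dd, seq(2, 2 * H2, 2), seq(2, 2 * W2, 2))
  dx
}

init_convnet <- function(config) {
  with_local_seed(config$rng_seed, {
    params <- list(conv = list(), fc = NULL)
    cin <- 1L
    for (i in seq_along(config$channels)) {
      cout <- config$channels[i]
      fan_in <- 9 * cin
      params$conv[[i]] <- list(
        W = matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout),
        b = numeric(cout))
      cin <- cout
    }
    s <- convnet_map_sizes(config)
    nfeat <- s[length(s)]^2 * cin
    params$fc <- list(W = matrix(stats::rnorm(nfeat * 2, sd = sqrt(2 / nfeat)), nfeat, 2),
                      b = numeric(2))
    params
  })
}

convnet_forward <- function(params, x, config, keep_cache = FALSE) {
  caches <- list()
  h <- x
  for (i in seq_along(params$conv)) {
    d <- dim(h)
    cf <- conv_forward(h, params$conv[[i]]$W, params$conv[[i]]$b)
    relu_mask <- cf$out > 0
    hr <- cf$out * relu_mask
    mp <- maxpool_forward(hr)
    if (keep_cache)
      caches[[i]] <- list(conv = cf, relu = relu_mask, pool = mp, in_dim = d)
    h <- mp$out
  }
  feat <- as.vector(h)
  logits <- drop(feat %*% params$fc$W) + params$fc$b
  z <- logits - max(logits)
  probs <- exp(z) / sum(exp(z))
  list(probs = probs, logits = logits, feat = feat, feat_dim = dim(h),
       caches = caches)
}

convnet_backward <- function(params, fwd, y_onehot, config) {
  dlogits <- fwd$probs - y_onehot
  grads <- list(conv = vector("list", length(params$conv)),
                fc = list(W = outer(fwd$feat, dlogits), b = dlogits))
  dfeat <- array(params$fc$W %*% dlogits, fwd$feat_dim)
  g <- dfeat
  for (i in rev(seq_along(params$conv))) {
    cc <- fwd$caches[[i]]
    g <- maxpool_backward(g, cc$pool)
    g <- g * cc$relu
    bk <- conv_backward(g, cc$conv, params$conv[[i]]$W,
                        cc$in_dim[1], cc$in_dim[2], cc$in_dim[3])
    grads$conv[[i]] <- list(W = bk$dW, b = bk$db)
    g <- bk$dx
  }
  grads
}

#' Train the small ConvNet
#'
#' @param x_train numeric array `N x H x W` of grayscale images (values in
#'   \[0, 1\]), or a list of [radiograph()] objects.
#' @param y_train binary labels.
#' @param config a [convnet_config()]; `input_size` must match the images.
#' @param x_val,y_val optional validation partition; per-epoch validation
#'   accuracy is recorded in the history.
#' @param verbose print per-epoch progress.
#' @return List of class `convnet_model`: `params`, `config`, `classes`,
#'   `history` (data.frame epoch/train_loss/val_accuracy).
#' @export
train_convnet <- function(x_train, y_train, config = convnet_config(),
                          x_val = NULL, y_val = NULL, verbose = FALSE) {
  x_train <- as_image_array(x_train, config$input_size)
  y <- as.character(y_train)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop_param("labels must be binary")
  yi <- match(y, classes)
  n <- dim(x_train)[1]
  params <- init_convnet(config)
  # flatten params to a list of matrices for Adam bookkeeping
  flat <- function(p) c(lapply(p$conv, `[[`, "W"), lapply(p$conv, `[[`, "b"),
                        list(p$fc$W, p$fc$b))
  mstate <- lapply(flat(params), function(x) x * 0)
  vstate <- lapply(flat(params), function(x) x * 0)
  unflat_apply <- function(params, upd) {
    k <- 0; nc <- length(params$conv)
    for (i in seq_len(nc)) params$conv[[i]]$W <- params$conv[[i]]$W + upd[[i]]
    for (i in seq_len(nc)) params$conv[[i]]$b <- params$conv[[i]]$b + upd[[nc + i]]
    params$fc$W <- params$fc$W + upd[[2 * nc + 1]]
    params$fc$b <- params$fc$b + upd[[2 * nc + 2]]
    params
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t <- 0
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_accuracy = numeric(0))
  order_seed <- derive_seed(config$rng_seed, 777L)
  for (ep in seq_len(config$epochs)) {
    idx <- with_local_seed(derive_seed(order_seed, ep), sample(n))
    losses <- numeric(0)
    for (start in seq(1, n, by = config$batch_size)) {
      batch <- idx[start:min(start + config$batch_size - 1, n)]
      gacc <- NULL
      bl <- 0
      for (s in batch) {
        x <- array(x_train[s, , ], dim = c(dim(x_train)[2], dim(x_train)[3], 1))
        fwd <- convnet_forward(params, x, config, keep_cache = TRUE)
        onehot <- c(0, 0); onehot[yi[s]] <- 1
        bl <- bl - log(max(fwd$probs[yi[s]], 1e-12))
        g <- convnet_backward(params, fwd, onehot, config)
        gf <- c(lapply(g$conv, `[[`, "W"), lapply(g$conv, `[[`, "b"),
                list(g$fc$W, g$fc$b))
        gacc <- if (is.null(gacc)) gf else Map(`+`, gacc, gf)
      }
      gacc <- lapply(gacc, `/`, length(batch))
      losses <- c(losses, bl / length(batch))
      t <- t + 1
      upd <- vector("list", length(gacc))
      for (i in seq_along(gacc)) {
        mstate[[i]] <- b1 * mstate[[i]] + (1 - b1) * gacc[[i]]
        vstate[[i]] <- b2 * vstate[[i]] + (1 - b2) * gacc[[i]]^2
        mh <- mstate[[i]] / (1 - b1^t)
        vh <- vstate[[i]] / (1 - b2^t)
        upd[[i]] <- -config$learning_rate * mh / (sqrt(vh) + eps)
      }
      params <- unflat_apply(params, upd)
    }
    va <- NA_real_
    if (!is.null(x_val)) {
      model_tmp <- structure(list(params = params, config = config,
                                  classes = classes), class = "convnet_model")
      va <- evaluate_convnet(model_tmp, x_val, y_val)$accuracy
    }
    history <- rbind(history, data.frame(epoch = ep, train_loss = mean(losses),
                                         val_accuracy = va))
    if (verbose)
      cat(sprintf("epoch %d  loss %.4f  val %.1f%%\n", ep, mean(losses), va))
  }
  structure(list(params = params, config = config, classes = classes,
                 history = history), class = "convnet_model")
}

#' Predict class probabilities with a trained ConvNet
#'
#' @param object a `convnet_model`.
#' @param newdata image array `N x H x W` or list of radiographs.
#' @param ... unused.
#' @return data.frame with `class` and per-class softmax probabilities (rows
#'   sum to 1).
#' @export
predict.convnet_model <- function(object, newdata, ...) {
  xs <- as_image_array(newdata, object$config$input_size)
  n <- dim(xs)[1]
  probs <- matrix(0, n, 2, dimnames = list(NULL, object$classes))
  for (s in seq_len(n)) {
    x <- array(xs[s, , ], dim = c(dim(xs)[2], dim(xs)[3], 1))
    probs[s, ] <- convnet_forward(object$params, x, object$config)$probs
  }
  data.frame(class = object$classes[max.col(probs, ties.method = "first")],
             probs, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Evaluate a trained ConvNet on a test partition
#'
#' @param model a `convnet_model`.
#' @param x_test image array or list of radiographs (non-empty).
#' @param y_test labels.
#' @return List with `accuracy` (percent) and `predictions` (data.frame with
#'   truth, prediction and probabilities, one row per test image).
#' @export
evaluate_convnet <- function(model, x_test, y_test) {
  xs <- as_image_array(x_test, model$config$input_size)
  if (dim(xs)[1] == 0) stop_param("test set is empty")
  if (length(y_test) != dim(xs)[1]) stop_param("labels do not match test size")
  pred <- predict(model, xs)
  pred$truth <- as.character(y_test)
  list(accuracy = 100 * mean(pred$class == pred$truth), predictions = pred)
}

# coerce list of radiographs / matrix / array to N x H x W, resizing to the
# configured input size when needed
as_image_array <- function(x, input_size) {
  if (is.list(x) && length(x) > 0 && inherits(x[[1]], "radiograph"))
    x <- lapply(x, as_pixels)
  if (is.list(x)) {
    x <- lapply(x, function(m) {
      if (nrow(m) != input_size)
        m <- as.matrix(EBImage::resize(EBImage::Image(m), w = input_size, h = input_size))
      m
    })
    arr <- array(0, c(length(x), input_size, input_size))
    for (i in seq_along(x)) arr[i, , ] <- x[[i]]
    return(arr)
  }
  if (is.matrix(x)) x <- array(x, c(1, dim(x)))
  if (length(dim(x)) != 3) stop_param("expected N x H x W image array")
  if (dim(x)[2] != input_size) {
    arr <- array(0, c(dim(x)[1], input_size, input_size))
    for (i in seq_len(dim(x)[1]))
      arr[i, , ] <- as.matrix(EBImage::resize(EBImage::Image(x[i, , ]),
                                              w = input_size, h = input_size))
    x <- arr
  }
  x
}

#' Replicate a grayscale image to three channels (pseudo-colour utility)
#'
#' Utility for architectures that expect RGB input; the small ConvNet itself
#' consumes single-channel images.
#'
#' @param image matrix or [radiograph()].
#' @return `H x W x 3` array with identical channels.
#' @export
pseudo_color <- function(image) {
  px <- as_pixels(image)
  array(rep(px, 3), c(dim(px), 3))
}
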