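# A small 1D convolutional network for tabular feature vectors, written
# in base R: four same-padded Conv1D stages with ReLU, max pooling after
# stages 2 and 4, three dense stages (ReLU + dropout on the first two,
# sigmoid head), binary cross-entropy loss, full-batch Adam. The feature
# vector is treated as a length-k single-channel sequence.

cnn_default_hyperparams <- function() {
  list(conv_channels = c(16, 16, 32, 32), kernel = 3,
       dense_units = c(32, 16), dropout = 0.5,
       lr = 1e-3, epochs = 200, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

# conv1d forward with same padding via im2col; X: [n, L, Cin]
conv1d_forward <- function(X, W, b) {
  d <- dim(X); n <- d[1]; L <- d[2]; Cin <- d[3]
  k <- dim(W)[1] %/% Cin
  Xp <- array(0, c(n, L + k - 1, Cin))
  Xp[, (1:L) + (k - 1) %/% 2, ] <- X
  M <- matrix(0, n * L, k * Cin)
  for (o in seq_len(k))
    M[, ((o - 1) * Cin + 1):(o * Cin)] <-
      matrix(Xp[, (1:L) + o - 1, , drop = FALSE], n * L, Cin)
  out <- M %*% W + matrix(b, n * L, length(b), byrow = TRUE)
  list(out = array(out, c(n, L, length(b))), M = M)
}

conv1d_backward <- function(dOut, cache_M, W, X_dim) {
  n <- X_dim[1]; L <- X_dim[2]; Cin <- X_dim[3]
  k <- dim(W)[1] %/% Cin
  Cout <- ncol(W)
  dO <- matrix(dOut, n * L, Cout)
  dW <- t(cache_M) %*% dO
  db <- colSums(dO)
  dM <- dO %*% t(W)
  dXp <- array(0, c(n, L + k - 1, Cin))
  for (o in seq_len(k)) {
    blk <- array(dM[, ((o - 1) * Cin + 1):(o * Cin)], c(n, L, Cin))
    dXp[, (1:L) + o - 1, ] <- dXp[, (1:L) + o - 1, , drop = FALSE] + blk
  }
  list(dX = dXp[, (1:L) + (k - 1) %/% 2, , drop = FALSE], dW = dW, db = db)
}

# width-2 stride-2 max pooling, ceil mode (odd tail passes through)
maxpool2_forward <- function(X) {
  d <- dim(X); n <- d[1]; L <- d[2]; C <- d[3]
  Lo <- ceiling(L / 2)
  idx_a <- 2 * (1:Lo) - 1
  idx_b <- pmin(2 * (1:Lo), L)
  a <- X[, idx_a, , drop = FALSE]
  b <- X[, idx_b, , drop = FALSE]
  take_a <- a >= b | array(rep(idx_a == idx_b, each = n), c(n, Lo, C))
  list(out = ifelse(take_a, a, b), take_a = take_a, L_in = L)
}

maxpool2_backward <- function(dOut, cache) {
  d <- dim(dOut); Lo <- d[2]
  n <- d[1]; C <- d[3]
  dX <- array(0, c(n, cache$L_in, C))
  idx_a <- 2 * (1:Lo) - 1
  idx_b <- pmin(2 * (1:Lo), cache$L_in)
  ga <- dOut * cache$take_a
  gb <- dOut * !cache$take_a
  for (t in seq_len(Lo)) {
    dX[, idx_a[t], ] <- dX[, idx_a[t], ] + ga[, t, ]
    dX[, idx_b[t], ] <- dX[, idx_b[t], ] + gb[, t, ]
  }
  dX
}

glorot <- function(n_in, n_out, nrow_, ncol_) {
  matrix(stats::runif(nrow_ * ncol_, -1, 1) * sqrt(6 / (n_in + n_out)),
         nrow_, ncol_)
}

cnn_init <- function(k_features, hp) {
  ch <- c(1, hp$conv_channels)
  params <- list()
  for (l in seq_along(hp$conv_channels)) {
    fan_in <- hp$kernel * ch[l]
    params[[paste0("Wc", l)]] <- glorot(fan_in, ch[l + 1],
                                        hp$kernel * ch[l], ch[l + 1])
    params[[paste0("bc", l)]] <- numeric(ch[l + 1])
  }
  L_flat <- ceiling(ceiling(k_features / 2) / 2) * hp$conv_channels[4]
  sizes <- c(L_flat, hp$dense_units, 1)
  for (l in seq_len(length(sizes) - 1)) {
    params[[paste0("Wd", l)]] <- glorot(sizes[l], sizes[l + 1],
                                        sizes[l], sizes[l + 1])
    params[[paste0("bd", l)]] <- numeric(sizes[l + 1])
  }
  params
}

cnn_forward <- function(params, X, hp, dropout_masks = NULL) {
  n <- dim(X)[1]
  caches <- list()
  A <- X
  for (l in 1:4) {
    in_dim <- dim(A)
    cv <- conv1d_forward(A, params[[paste0("Wc", l)]],
                         params[[paste0("bc", l)]])
    Z <- cv$out
    R <- Z > 0
    A <- Z * R
    caches[[paste0("conv", l)]] <- list(M = cv$M, R = R, X_dim = in_dim)
    if (l %in% c(2, 4)) {
      mp <- maxpool2_forward(A)
      A <- mp$out
      caches[[paste0("pool", l)]] <- mp
    }
  }
  flat_dim <- prod(dim(A)[2:3])
  A <- matrix(A, n, flat_dim)
  n_dense <- length(hp$dense_units) + 1
  for (l in seq_len(n_dense)) {
    Zin <- A
    Z <- A %*% params[[paste0("Wd", l)]] +
      matrix(params[[paste0("bd", l)]], n,
             length(params[[paste0("bd", l)]]), byrow = TRUE)
    if (l < n_dense) {
      R <- Z > 0
      A <- Z * R
      if (!is.null(dropout_masks)) {
        A <- A * dropout_masks[[l]]
      }
      caches[[paste0("dense", l)]] <- list(A_in = Zin, R = R)
    } else {
      caches[[paste0("dense", l)]] <- list(A_in = Zin)
      A <- Z  # logits
    }
  }
  list(logits = as.numeric(A), caches = caches)
}

cnn_backward <- function(params, X, y, fw, hp, dropout_masks) {
  n <- dim(X)[1]
  p <- 1 / (1 + exp(-fw$logits))
  grads <- list()
  n_dense <- length(hp$dense_units) + 1
  dA <- matrix((p - y) / n, n, 1)
  for (l in rev(seq_len(n_dense))) {
    cache <- fw$caches[[paste0("dense", l)]]
    grads[[paste0("Wd", l)]] <- t(cache$A_in) %*% dA
    grads[[paste0("bd", l)]] <- colSums(dA)
    dA <- dA %*% t(params[[paste0("Wd", l)]])
    if (l > 1) {
      prev <- fw$caches[[paste0("dense", l - 1)]]
      dA <- dA * dropout_masks[[l - 1]] * prev$R
    }
  }
  # reshape into the post-pool4 tensor
  d4 <- dim(fw$caches$pool4$take_a)
  dT <- array(dA, c(n, d4[2], d4[3]))
  for (l in 4:1) {
    if (l %in% c(2, 4))
      dT <- maxpool2_backward(dT, fw$caches[[paste0("pool", l)]])
    cache <- fw$caches[[paste0("conv", l)]]
    dT <- dT * cache$R
    bw <- conv1d_backward(dT, cache$M, params[[paste0("Wc", l)]],
                          cache$X_dim)
    grads[[paste0("Wc", l)]] <- bw$dW
    grads[[paste0("bc", l)]] <- bw$db
    dT <- bw$dX
  }
  grads
}

#' Train the 1D-CNN probability-of-malignancy classifier
#'
#' Fits a small one-dimensional convolutional network on standardized
#' feature vectors: four Conv1D stages (ReLU), max pooling after stages
#' two and four, three dense stages with ReLU and 0.5 dropout on the
#' first two and a sigmoid head giving the probability of malignancy
#' (POM). Training is full-batch Adam on binary cross-entropy and fully
#' deterministic given the seed.
#'
#' @param table standardized feature data.frame with a `label` column;
#'   rows with `split == "test"` are ignored during fitting.
#' @param selected_features character vector of feature columns to use.
#' @param hyperparams overrides of [cnn_default_hyperparams()]:
#'   `conv_channels`, `kernel`, `dense_units`, `dropout`, `lr`,
#'   `epochs`.
#' @param seed integer seed controlling initialization and dropout.
#' @return A `pom_cnn` model (weights, architecture, loss history,
#'   feature names, seed).
#' @export
train_cnn <- function(table, selected_features = feature_columns(table),
                      hyperparams = list(), seed = 1L) {
  hp <- utils::modifyList(cnn_default_hyperparams(), hyperparams)
  train <- if ("split" %in% names(table)) table$split == "train"
           else rep(TRUE, nrow(table))
  df <- table[train, , drop = FALSE]
  if (length(unique(df$label)) < 2)
    stop("train_cnn: training data must contain both classes")
  if (length(selected_features) < 1)
    stop("train_cnn: at least one feature required")
  y <- as.numeric(df$label == "malignant")
  Xm <- as.matrix(df[, selected_features, drop = FALSE])
  n <- nrow(Xm); k <- ncol(Xm)
  X <- array(Xm, c(n, k, 1))
  set.seed(seed)
  params <- cnn_init(k, hp)
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  keep <- 1 - hp$dropout
  loss_hist <- numeric(hp$epochs)
  for (epoch in seq_len(hp$epochs)) {
    masks <- lapply(hp$dense_units, function(u)
      matrix(stats::rbinom(n * u, 1, keep) / keep, n, u))
    fw <- cnn_forward(params, X, hp, masks)
    p_hat <- 1 / (1 + exp(-fw$logits))
    loss_hist[epoch] <- -mean(y * log(pmax(p_hat, 1e-12)) +
                                (1 - y) * log(pmax(1 - p_hat, 1e-12)))
    grads <- cnn_backward(params, X, y, fw, hp, masks)
    for (nm in names(params)) {
      g <- grads[[nm]]
      m[[nm]] <- hp$beta1 * m[[nm]] + (1 - hp$beta1) * g
      v[[nm]] <- hp$beta2 * v[[nm]] + (1 - hp$beta2) * g^2
      mh <- m[[nm]] / (1 - hp$beta1^epoch)
      vh <- v[[nm]] / (1 - hp$beta2^epoch)
      params[[nm]] <- params[[nm]] - hp$lr * mh / (sqrt(vh) + hp$eps)
    }
  }
  structure(list(params = params, hyperparams = hp,
                 features = selected_features, seed = seed,
                 loss = loss_hist, n_train = n),
            class = "pom_cnn")
}

#' Predict probability of malignancy
#'
#' @param object a `pom_cnn` model.
#' @param newdata data.frame containing the model's feature columns
#'   (standardized with the training scaler).
#' @param ... unused.
#' @return Numeric POM vector in `[0, 1]`, one per row; batch-order
#'   invariant and deterministic (dropout disabled).
#' @export
predict.pom_cnn <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss))
    stop(sprintf("predict: feature-set mismatch, missing %s",
                 paste(miss, collapse = ", ")))
  Xm <- as.matrix(newdata[, object$features, drop = FALSE])
  X <- array(Xm, c(nrow(Xm), ncol(Xm), 1))
  fw <- cnn_forward(object$params, X, object$hyperparams, NULL)
  1 / (1 + exp(-fw$logits))
}

#' @rdname predict.pom_cnn
#' @param model a `pom_cnn`.
#' @param table data.frame of standardized features.
#' @export
predict_pom <- function(model, table) predict(model, table)

#' @export
print.pom_cnn <- function(x, ...) {
  hp <- x$hyperparams
  cat(sprintf("1D-CNN POM classifier: %d features, conv %s (k=%d), dense %s, dropout %.1f\n",
              length(x$features),
              paste(hp$conv_channels, collapse = "-"), hp$kernel,
              paste(c(hp$dense_units, 1), collapse = "-"), hp$dropout))
  cat(sprintf("  trained %d epochs on %d masses; final loss %.4f\n",
              hp$epochs, x$n_train, x$loss[length(x$loss)]))
  invisible(x)
}

#' @export
summary.pom_cnn <- function(object, ...) {
  print(object)
  cat(sprintf("  loss: start %.4f, min %.4f, end %.4f\n",
              object$loss[1], min(object$loss),
              object$loss[length(object$loss)]))
  invisible(object)
}
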