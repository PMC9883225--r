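## Small convolutional network over PNCC images, used purely as a deep
## feature extractor: 3 conv(3x3, same) + maxpool(2x2) blocks, dropout,
## a 64-unit fully connected feature layer with ReLU, and a 3-class softmax
## head that is discarded after training. Trained with Adam and categorical
## cross-entropy. Implemented with im2col + BLAS matrix products; single
## threaded and fully deterministic given the seed.

#' CNN architecture and training specification
#'
#' @param input_dim `c(height, width)` of the input image
#'   (`n_frames_out x n_channels` of the PNCC image); both must be divisible
#'   by `2^3` and `2` respectively per pooling stage (64 x 40 works).
#' @param filters Numbers of filters in the three conv blocks.
#' @param fc_units Width of the fully connected feature layer (64).
#' @param n_classes Number of classes (3).
#' @param dropout_rate Dropout probability before the feature layer.
#' @param lr,beta1,beta2 Adam hyperparameters (0.001, 0.9, 0.999).
#' @param epochs,batch_size Training schedule.
#' @param seed RNG seed controlling init, shuffling and dropout.
#' @return A list of class `cnn_spec`.
#' @export
cnn_spec <- function(input_dim = c(64L, 40L), filters = c(16L, 32L, 64L),
                     fc_units = 64L, n_classes = 3L, dropout_rate = 0.5,
                     lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                     epochs = 30L, batch_size = 32L, seed = 1L) {
  stopifnot(length(filters) == 3L, fc_units == 64L || fc_units > 0L)
  if (any(input_dim %% 8L != 0L))
    stop("cnn_spec: input_dim must be divisible by 8 (three 2x2 poolings)")
  structure(as.list(environment()), class = "cnn_spec")
}

## ---- array helpers --------------------------------------------------------

## x: (H, W, C, B) -> im2col matrix (H*W*B, 9*C) for 3x3 "same" convolution.
im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  xp <- array(0, c(H + 2L, W + 2L, C, B))
  xp[2:(H + 1L), 2:(W + 1L), , ] <- x
  out <- matrix(0, H * W * B, 9L * C)
  o <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    o <- o + 1L
    patch <- xp[dy + (1:H), dx + (1:W), , , drop = FALSE]
    patch <- aperm(patch, c(1L, 2L, 4L, 3L))        # (H, W, B, C)
    dim(patch) <- c(H * W * B, C)
    out[, ((o - 1L) * C + 1L):(o * C)] <- patch
  }
  out
}

## inverse scatter-add of im2col3 for gradients: dcol (H*W*B, 9*C) -> (H,W,C,B)
col2im3 <- function(dcol, H, W, C, B) {
  dxp <- array(0, c(H + 2L, W + 2L, C, B))
  o <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    o <- o + 1L
    patch <- dcol[, ((o - 1L) * C + 1L):(o * C), drop = FALSE]
    dim(patch) <- c(H, W, B, C)
    patch <- aperm(patch, c(1L, 2L, 4L, 3L))        # (H, W, C, B)
    dxp[dy + (1:H), dx + (1:W), , ] <-
      dxp[dy + (1:H), dx + (1:W), , , drop = FALSE] + patch
  }
  dxp[2:(H + 1L), 2:(W + 1L), , , drop = FALSE]
}

conv_fw <- function(x, Wt, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; B <- d[4]
  Xc <- im2col3(x)
  out <- Xc %*% Wt
  out <- sweep(out, 2L, b, "+")
  Fo <- ncol(Wt)
  dim(out) <- c(H, W, B, Fo)
  list(out = aperm(out, c(1L, 2L, 4L, 3L)), Xc = Xc)
}

conv_bw <- function(dout, cache_Xc, Wt, xdim) {
  d <- xdim; H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  Fo <- ncol(Wt)
  dmat <- aperm(dout, c(1L, 2L, 4L, 3L))            # (H, W, B, F)
  dim(dmat) <- c(H * W * B, Fo)
  dW <- crossprod(cache_Xc, dmat)
  db <- colSums(dmat)
  dXc <- dmat %*% t(Wt)
  list(dx = col2im3(dXc, H, W, C, B), dW = dW, db = db)
}

pool_fw <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  x1 <- x; dim(x1) <- c(2L, H %/% 2L, W * C * B)
  a <- x1[1L, , ]; b <- x1[2L, , ]
  m1 <- a >= b
  y1 <- ifelse(m1, a, b)                            # (H/2, W*C*B)
  dim(y1) <- c((H %/% 2L) * 1L, W, C * B)
  y1m <- y1; dim(y1m) <- c(H %/% 2L, 2L, (W %/% 2L) * C * B)
  a2 <- y1m[, 1L, ]; b2 <- y1m[, 2L, ]
  m2 <- a2 >= b2
  y <- ifelse(m2, a2, b2)
  dim(y) <- c(H %/% 2L, W %/% 2L, C, B)
  list(out = y, m1 = m1, m2 = m2, dims = d)
}

pool_bw <- function(dy, cache) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  dy2 <- dy; dim(dy2) <- c(H %/% 2L, (W %/% 2L) * C * B)
  d1a <- dy2 * cache$m2
  d1b <- dy2 * (!cache$m2)
  d1 <- array(0, c(H %/% 2L, 2L, (W %/% 2L) * C * B))
  d1[, 1L, ] <- d1a; d1[, 2L, ] <- d1b
  dim(d1) <- c(H %/% 2L, W * C * B)
  d0a <- d1 * cache$m1
  d0b <- d1 * (!cache$m1)
  dx <- array(0, c(2L, H %/% 2L, W * C * B))
  dx[1L, , ] <- d0a; dx[2L, , ] <- d0b
  dim(dx) <- c(H, W, C, B)
  dx
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

init_params <- function(spec) {
  he <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))
  H <- spec$input_dim[1L]; Wd <- spec$input_dim[2L]
  f <- spec$filters
  cin <- c(1L, f[1L], f[2L])
  p <- list()
  for (i in 1:3) {
    p[[paste0("Wc", i)]] <- matrix(he(9L * cin[i], 9L * cin[i] * f[i]), 9L * cin[i], f[i])
    p[[paste0("bc", i)]] <- numeric(f[i])
  }
  flat <- (H %/% 8L) * (Wd %/% 8L) * f[3L]
  p$Wf <- matrix(he(flat, flat * spec$fc_units), flat, spec$fc_units)
  p$bf <- numeric(spec$fc_units)
  p$Wo <- matrix(he(spec$fc_units, spec$fc_units * spec$n_classes),
                 spec$fc_units, spec$n_classes)
  p$bo <- numeric(spec$n_classes)
  p
}

## Forward pass; x (H, W, 1, B). Returns caches when train = TRUE.
cnn_forward <- function(p, x, spec, train = FALSE, drop_mask = NULL) {
  c1 <- conv_fw(x, p$Wc1, p$bc1); a1 <- pmax(c1$out, 0)
  p1 <- pool_fw(a1)
  c2 <- conv_fw(p1$out, p$Wc2, p$bc2); a2 <- pmax(c2$out, 0)
  p2 <- pool_fw(a2)
  c3 <- conv_fw(p2$out, p$Wc3, p$bc3); a3 <- pmax(c3$out, 0)
  p3 <- pool_fw(a3)
  d <- dim(p3$out); B <- d[4]
  flat <- matrix(aperm(p3$out, c(1L, 2L, 3L, 4L)), ncol = B)  # (flat, B)
  flat <- t(flat)                                             # (B, flat)
  if (train) {
    if (is.null(drop_mask))
      drop_mask <- matrix(stats::runif(length(flat)) >= spec$dropout_rate,
                          nrow(flat), ncol(flat)) / (1 - spec$dropout_rate)
    flat_d <- flat * drop_mask
  } else {
    drop_mask <- NULL
    flat_d <- flat
  }
  zf <- sweep(flat_d %*% p$Wf, 2L, p$bf, "+")
  hf <- pmax(zf, 0)                                           # 64-dim features
  zo <- sweep(hf %*% p$Wo, 2L, p$bo, "+")
  list(probs = softmax_rows(zo), features = hf,
       cache = if (train) list(x = x, c1 = c1, a1 = a1, p1 = p1, c2 = c2,
                               a2 = a2, p2 = p2, c3 = c3, a3 = a3, p3 = p3,
                               flat = flat, drop_mask = drop_mask,
                               flat_d = flat_d, zf = zf, hf = hf) else NULL)
}

cnn_backward <- function(p, fw, y_onehot, spec) {
  ca <- fw$cache
  B <- nrow(y_onehot)
  dzo <- (fw$probs - y_onehot) / B
  g <- list()
  g$Wo <- crossprod(ca$hf, dzo); g$bo <- colSums(dzo)
  dhf <- dzo %*% t(p$Wo)
  dzf <- dhf * (ca$zf > 0)
  g$Wf <- crossprod(ca$flat_d, dzf); g$bf <- colSums(dzf)
  dflat <- (dzf %*% t(p$Wf)) * ca$drop_mask                   # (B, flat)
  d3 <- dim(ca$p3$out)
  dflat <- t(dflat); dim(dflat) <- d3
  dp3 <- pool_bw(dflat, ca$p3)
  dc3 <- dp3 * (ca$c3$out > 0)
  b3 <- conv_bw(dc3, ca$c3$Xc, p$Wc3, dim(ca$p2$out))
  g$Wc3 <- b3$dW; g$bc3 <- b3$db
  dp2 <- pool_bw(b3$dx, ca$p2)
  dc2 <- dp2 * (ca$c2$out > 0)
  b2 <- conv_bw(dc2, ca$c2$Xc, p$Wc2, dim(ca$p1$out))
  g$Wc2 <- b2$dW; g$bc2 <- b2$db
  dp1 <- pool_bw(b2$dx, ca$p1)
  dc1 <- dp1 * (ca$c1$out > 0)
  b1 <- conv_bw(dc1, ca$c1$Xc, p$Wc1, dim(ca$x))
  g$Wc1 <- b1$dW; g$bc1 <- b1$db
  g
}

#' Train the CNN feature extractor
#'
#' Trains the network on labelled PNCC images with Adam and categorical
#' cross-entropy, recording the mean training loss per epoch. The class head
#' exists only to shape the feature layer; it is kept in the returned object
#' but ignored by [extract_deep_features()].
#'
#' @param images List of `pncc_image` matrices (all the same shape).
#' @param labels Class labels (character or factor with the levels of
#'   [pah_classes()]), one per image.
#' @param spec A [cnn_spec()].
#' @return An object of class `cnn_extractor` with elements `params`,
#'   `spec`, and `loss_history`.
#' @export
train_feature_extractor <- function(images, labels, spec = cnn_spec()) {
  stopifnot(length(images) >= 2L, length(images) == length(labels))
  labels <- factor(as.character(labels), levels = pah_classes())
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L)
    stop("train_feature_extractor: need at least two classes")
  shp <- dim(images[[1L]])
  if (!all(vapply(images, function(im) all(dim(im) == shp), logical(1))))
    stop("train_feature_extractor: images differ in shape")
  if (!all(shp == spec$input_dim))
    stop("train_feature_extractor: image shape ", paste(shp, collapse = "x"),
         " != spec input_dim ", paste(spec$input_dim, collapse = "x"))

  n <- length(images)
  H <- shp[1L]; Wd <- shp[2L]
  X <- array(0, c(H, Wd, 1L, n))
  for (i in seq_len(n)) X[, , 1L, i] <- images[[i]]
  y <- as.integer(labels)
  spec$n_classes <- nlevels(labels)
  Y <- matrix(0, n, spec$n_classes); Y[cbind(seq_len(n), y)] <- 1

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(spec$seed)
  p <- init_params(spec)
  adam_m <- lapply(p, function(w) w * 0)
  adam_v <- lapply(p, function(w) w * 0)
  t_step <- 0L
  loss_hist <- numeric(spec$epochs)

  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (b0 in seq(1L, n, by = spec$batch_size)) {
      idx <- ord[b0:min(n, b0 + spec$batch_size - 1L)]
      xb <- X[, , , idx, drop = FALSE]
      yb <- Y[idx, , drop = FALSE]
      fw <- cnn_forward(p, xb, spec, train = TRUE)
      eps_p <- 1e-12
      losses <- c(losses, -mean(log(rowSums(fw$probs * yb) + eps_p)))
      g <- cnn_backward(p, fw, yb, spec)
      t_step <- t_step + 1L
      for (k in names(p)) {
        adam_m[[k]] <- spec$beta1 * adam_m[[k]] + (1 - spec$beta1) * g[[k]]
        adam_v[[k]] <- spec$beta2 * adam_v[[k]] + (1 - spec$beta2) * g[[k]]^2
        mhat <- adam_m[[k]] / (1 - spec$beta1^t_step)
        vhat <- adam_v[[k]] / (1 - spec$beta2^t_step)
        p[[k]] <- p[[k]] - spec$lr * mhat / (sqrt(vhat) + 1e-8)
      }
    }
    loss_hist[ep] <- mean(losses)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  structure(list(params = p, spec = spec, loss_history = loss_hist,
                 classes = levels(labels)),
            class = "cnn_extractor")
}

#' @export
print.cnn_extractor <- function(x, ...) {
  cat(sprintf("<cnn_extractor> input %s, %d epochs, final loss %.4f\n",
              paste(x$spec$input_dim, collapse = "x"),
              length(x$loss_history), x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Extract 64-dimensional deep features
#'
#' Forward pass with dropout disabled; returns the ReLU activations of the
#' fully connected feature layer (never class probabilities). Deterministic.
#'
#' @param images A single `pncc_image` matrix or a list of them.
#' @param extractor A trained `cnn_extractor`.
#' @return Numeric matrix (`n_images x 64`) with columns `deep_1..deep_64`.
#' @export
extract_deep_features <- function(images, extractor) {
  stopifnot(inherits(extractor, "cnn_extractor"))
  if (is.matrix(images)) images <- list(images)
  spec <- extractor$spec
  shp <- spec$input_dim
  n <- length(images)
  out <- matrix(0, n, spec$fc_units)
  bs <- 64L
  for (b0 in seq(1L, n, by = bs)) {
    idx <- b0:min(n, b0 + bs - 1L)
    X <- array(0, c(shp[1L], shp[2L], 1L, length(idx)))
    for (j in seq_along(idx)) {
      im <- images[[idx[j]]]
      if (!all(dim(im) == shp))
        stop("extract_deep_features: image shape mismatch")
      X[, , 1L, j] <- im
    }
    fw <- cnn_forward(extractor$params, X, spec, train = FALSE)
    out[idx, ] <- fw$features
  }
  colnames(out) <- paste0("deep_", seq_len(spec$fc_units))
  out
}

## Class probabilities from the training head (used only for diagnostics
## such as the shuffled-label control; the pipeline never classifies with it).
cnn_predict_probs <- function(images, extractor) {
  if (is.matrix(images)) images <- list(images)
  spec <- extractor$spec
  shp <- spec$input_dim
  n <- length(images)
  out <- matrix(0, n, spec$n_classes)
  bs <- 64L
  for (b0 in seq(1L, n, by = bs)) {
    idx <- b0:min(n, b0 + bs - 1L)
    X <- array(0, c(shp[1L], shp[2L], 1L, length(idx)))
    for (j in seq_along(idx)) X[, , 1L, j] <- images[[idx[j]]]
    out[idx, ] <- cnn_forward(extractor$params, X, spec, train = FALSE)$probs
  }
  out
}
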