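# Small convolutional image classifier, implemented directly in base R
# (im2col convolution + backprop + Adam) because no deep-learning framework
# is assumed at run time. The fixed architecture: three valid 3x3 conv
# layers of 32/64/128 filters with ReLU, 2x2/stride-2 max-pooling after the
# first two, flatten, dense 128 and 64 with ReLU, and a softmax output layer
# (192 units by default). Trained with Adam on sparse categorical
# cross-entropy.

# linear-index table mapping each 3x3xC patch to columns of an im2col matrix
build_im2col_idx <- function(H, W, C, k = 3L) {
  Hp <- H - k + 1L; Wp <- W - k + 1L
  rO <- rep(seq_len(Hp), Wp)
  cO <- rep(seq_len(Wp), each = Hp)
  idx <- matrix(0L, Hp * Wp, k * k * C)
  j <- 0L
  for (ch in seq_len(C)) for (dc in 0:(k - 1L)) for (dr in 0:(k - 1L)) {
    j <- j + 1L
    idx[, j] <- (rO + dr) + (cO + dc - 1L) * H + (ch - 1L) * H * W
  }
  list(idx = idx, H = Hp, W = Wp)
}

# 2x2 stride-2 pooling index groups (4 input positions per output cell)
build_pool_idx <- function(H, W) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  rO <- rep(seq_len(Ho), Wo)
  cO <- rep(seq_len(Wo), each = Ho)
  p <- matrix(0L, Ho * Wo, 4L)
  p[, 1] <- (2L * rO - 1L) + (2L * cO - 2L) * H
  p[, 2] <- (2L * rO)      + (2L * cO - 2L) * H
  p[, 3] <- (2L * rO - 1L) + (2L * cO - 1L) * H
  p[, 4] <- (2L * rO)      + (2L * cO - 1L) * H
  list(idx = p, H = Ho, W = Wo)
}

#' Build the distracted-driving CNN
#'
#' @param input_size `c(H, W, channels)`; H and W at least 16 so both
#'   pooling stages are feasible (default `c(64, 64, 3)`)
#' @param conv_filters filters of the three 3x3 conv layers (default
#'   `c(32, 64, 128)`)
#' @param dense_units widths of the two hidden dense layers (default
#'   `c(128, 64)`)
#' @param output_units softmax width; default 192, configurable
#' @param seed RNG seed for He-normal weight initialisation
#' @return a `cnn_model` with parameters, layer caches and a summary table
#' @export
build_cnn <- function(input_size = c(64L, 64L, 3L),
                      conv_filters = c(32L, 64L, 128L),
                      dense_units = c(128L, 64L),
                      output_units = 192L, seed = 1L) {
  if (input_size[1] < 16L || input_size[2] < 16L) {
    stop("input must be at least 16x16 for two 2x pooling stages", call. = FALSE)
  }
  if (output_units < 2L) stop("output_units must be >= 2", call. = FALSE)
  set.seed(as.integer(seed))
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  H <- input_size[1]; W <- input_size[2]; C <- input_size[3]
  caches <- list(); params <- list(); shapes <- list()
  # conv1 -> pool1 -> conv2 -> pool2 -> conv3
  c1 <- build_im2col_idx(H, W, C)
  params$W1 <- he(9L * C, conv_filters[1]); params$b1 <- numeric(conv_filters[1])
  p1 <- build_pool_idx(c1$H, c1$W)
  c2 <- build_im2col_idx(p1$H, p1$W, conv_filters[1])
  params$W2 <- he(9L * conv_filters[1], conv_filters[2]); params$b2 <- numeric(conv_filters[2])
  p2 <- build_pool_idx(c2$H, c2$W)
  c3 <- build_im2col_idx(p2$H, p2$W, conv_filters[2])
  params$W3 <- he(9L * conv_filters[2], conv_filters[3]); params$b3 <- numeric(conv_filters[3])
  flat <- c3$H * c3$W * conv_filters[3]
  params$Wd1 <- he(flat, dense_units[1]); params$bd1 <- numeric(dense_units[1])
  params$Wd2 <- he(dense_units[1], dense_units[2]); params$bd2 <- numeric(dense_units[2])
  params$Wo <- he(dense_units[2], output_units); params$bo <- numeric(output_units)
  structure(list(
    input_size = input_size, conv_filters = conv_filters,
    dense_units = dense_units, output_units = as.integer(output_units),
    params = params,
    caches = list(c1 = c1, p1 = p1, c2 = c2, p2 = p2, c3 = c3, flat = flat)),
    class = "cnn_model")
}

#' Architecture summary
#'
#' One row per layer in construction order with output shapes and parameter
#' counts; stable across runs for a fixed specification.
#'
#' @param model a `cnn_model`
#' @return data.frame with columns `layer`, `type`, `output_shape`,
#'   `n_params`
#' @export
cnn_summary <- function(model) {
  cc <- model$caches; cf <- model$conv_filters; du <- model$dense_units
  np <- function(w, b) length(w) + length(b)
  p <- model$params
  shp <- function(h, w, f) sprintf("%dx%dx%d", h, w, f)
  data.frame(
    layer = c("conv1", "pool1", "conv2", "pool2", "conv3", "flatten",
              "dense1", "dense2", "output"),
    type = c("conv3x3+relu", "maxpool2x2", "conv3x3+relu", "maxpool2x2",
             "conv3x3+relu", "flatten", "dense+relu", "dense+relu",
             "dense+softmax"),
    output_shape = c(shp(cc$c1$H, cc$c1$W, cf[1]), shp(cc$p1$H, cc$p1$W, cf[1]),
                     shp(cc$c2$H, cc$c2$W, cf[2]), shp(cc$p2$H, cc$p2$W, cf[2]),
                     shp(cc$c3$H, cc$c3$W, cf[3]), as.character(cc$flat),
                     as.character(du[1]), as.character(du[2]),
                     as.character(model$output_units)),
    n_params = c(np(p$W1, p$b1), 0L, np(p$W2, p$b2), 0L, np(p$W3, p$b3), 0L,
                 np(p$Wd1, p$bd1), np(p$Wd2, p$bd2), np(p$Wo, p$bo)))
}

#' Output-layer width of a built CNN
#' @param model a `cnn_model`
#' @return integer number of softmax units
#' @export
cnn_output_width <- function(model) {
  s <- cnn_summary(model)
  as.integer(s$output_shape[s$layer == "output"])
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

cnn_forward <- function(model, x, keep = FALSE) {
  p <- model$params; cc <- model$caches
  conv <- function(xvec, ci, W, b) {
    Xcol <- matrix(xvec[ci$idx], nrow(ci$idx), ncol(ci$idx))
    Z <- Xcol %*% W
    Z <- Z + rep(b, each = nrow(Z))
    list(Xcol = Xcol, Z = Z, A = pmax(Z, 0))
  }
  pool <- function(A, pi) {
    out <- A[pi$idx[, 1], , drop = FALSE]
    arg <- matrix(1L, nrow(out), ncol(out))
    for (k in 2:4) {
      Ak <- A[pi$idx[, k], , drop = FALSE]
      upd <- Ak > out
      out[upd] <- Ak[upd]
      arg[upd] <- k
    }
    list(A = out, arg = arg, n_in = nrow(A))
  }
  l1 <- conv(as.numeric(x), cc$c1, p$W1, p$b1)
  q1 <- pool(l1$A, cc$p1)
  l2 <- conv(as.numeric(q1$A), cc$c2, p$W2, p$b2)
  q2 <- pool(l2$A, cc$p2)
  l3 <- conv(as.numeric(q2$A), cc$c3, p$W3, p$b3)
  v <- as.numeric(l3$A)
  z1 <- as.numeric(v %*% p$Wd1) + p$bd1; a1 <- pmax(z1, 0)
  z2 <- as.numeric(a1 %*% p$Wd2) + p$bd2; a2 <- pmax(z2, 0)
  zo <- as.numeric(a2 %*% p$Wo) + p$bo
  prob <- softmax(zo)
  out <- list(prob = prob)
  if (keep) out <- c(out, list(l1 = l1, q1 = q1, l2 = l2, q2 = q2, l3 = l3,
                               v = v, z1 = z1, a1 = a1, z2 = z2, a2 = a2))
  out
}

cnn_backward <- function(model, fw, label0) {
  p <- model$params; cc <- model$caches
  g <- list()
  dzo <- fw$prob
  dzo[label0 + 1L] <- dzo[label0 + 1L] - 1
  g$Wo <- outer(fw$a2, dzo); g$bo <- dzo
  da2 <- as.numeric(p$Wo %*% dzo)
  dz2 <- da2 * (fw$z2 > 0)
  g$Wd2 <- outer(fw$a1, dz2); g$bd2 <- dz2
  da1 <- as.numeric(p$Wd2 %*% dz2)
  dz1 <- da1 * (fw$z1 > 0)
  g$Wd1 <- outer(fw$v, dz1); g$bd1 <- dz1
  dv <- as.numeric(p$Wd1 %*% dz1)
  conv_back <- function(layer, ci, W, dA, need_dx) {
    dZ <- dA * (layer$Z > 0)
    gW <- crossprod(layer$Xcol, dZ)
    gb <- colSums(dZ)
    dx <- NULL
    if (need_dx) {
      dXcol <- dZ %*% t(W)
      dx <- numeric(max(ci$idx))
      for (j in seq_len(ncol(ci$idx))) {
        dx[ci$idx[, j]] <- dx[ci$idx[, j]] + dXcol[, j]
      }
    }
    list(gW = gW, gb = gb, dx = dx)
  }
  pool_back <- function(q, pi, dOut) {
    dA <- matrix(0, q$n_in, ncol(dOut))
    for (k in 1:4) {
      mask <- q$arg == k
      if (any(mask)) {
        sub <- dA[pi$idx[, k], , drop = FALSE]
        sub[mask] <- sub[mask] + dOut[mask]
        dA[pi$idx[, k], ] <- sub
      }
    }
    dA
  }
  dA3 <- matrix(dv, nrow(fw$l3$A), ncol(fw$l3$A))
  b3 <- conv_back(fw$l3, cc$c3, p$W3, dA3, need_dx = TRUE)
  g$W3 <- b3$gW; g$b3 <- b3$gb
  dA2p <- matrix(b3$dx, nrow(fw$q2$A), ncol(fw$q2$A))
  dA2 <- pool_back(fw$q2, cc$p2, dA2p)
  b2 <- conv_back(fw$l2, cc$c2, p$W2, dA2, need_dx = TRUE)
  g$W2 <- b2$gW; g$b2 <- b2$gb
  dA1p <- matrix(b2$dx, nrow(fw$q1$A), ncol(fw$q1$A))
  dA1 <- pool_back(fw$q1, cc$p1, dA1p)
  b1 <- conv_back(fw$l1, cc$c1, p$W1, dA1, need_dx = FALSE)
  g$W1 <- b1$gW; g$b1 <- b1$gb
  g
}

#' Train the CNN on labelled images
#'
#' Adam on sparse categorical cross-entropy (labels are 0-based integers
#' below `output_units`); mini-batches shuffled deterministically from the
#' seed. Training stops early once training accuracy reaches `stop_at_acc`.
#'
#' @param model a `cnn_model` from [build_cnn()]
#' @param images list of H x W x C arrays matching the model's input size
#' @param labels integer class labels (0-based), at least 2 distinct
#' @param epochs maximum epochs (default 20)
#' @param lr Adam learning rate (default 1e-3)
#' @param batch_size mini-batch size (default 8)
#' @param seed shuffling seed
#' @param stop_at_acc early-stop training-accuracy target (default 0.999)
#' @return the trained model, with a `history` data.frame (`epoch`, `loss`,
#'   `accuracy`) attached
#' @export
train_cnn <- function(model, images, labels, epochs = 20L, lr = 1e-3,
                      batch_size = 8L, seed = 1L, stop_at_acc = 0.999) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(labels < 0L) || any(labels >= model$output_units)) {
    stop("labels must be 0-based integers below output_units", call. = FALSE)
  }
  sz <- model$input_size
  ok <- vapply(images, function(im) identical(dim(im), as.integer(sz)) ||
                 identical(dim(im), as.numeric(sz)), logical(1))
  if (!all(ok)) stop("image size mismatch with model input_size", call. = FALSE)
  n <- length(images)
  adam_m <- lapply(model$params, function(w) w * 0)
  adam_v <- lapply(model$params, function(w) w * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0), accuracy = numeric(0))
  for (ep in seq_len(epochs)) {
    set.seed(as.integer(seed) + ep)
    ord <- sample(n)
    losses <- numeric(n); correct <- logical(n)
    for (bs in seq(1L, n, by = batch_size)) {
      batch <- ord[bs:min(bs + batch_size - 1L, n)]
      acc_g <- NULL
      for (i in batch) {
        fw <- cnn_forward(model, images[[i]], keep = TRUE)
        losses[i] <- -log(max(fw$prob[labels[i] + 1L], 1e-12))
        correct[i] <- (which.max(fw$prob) - 1L) == labels[i]
        g <- cnn_backward(model, fw, labels[i])
        if (is.null(acc_g)) acc_g <- g
        else acc_g <- Map(`+`, acc_g, g)
      }
      step <- step + 1L
      for (nm in names(model$params)) {
        grad <- acc_g[[nm]] / length(batch)
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * grad
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * grad^2
        mhat <- adam_m[[nm]] / (1 - beta1^step)
        vhat <- adam_v[[nm]] / (1 - beta2^step)
        model$params[[nm]] <- model$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = mean(losses),
                                   accuracy = mean(correct)))
    if (mean(correct) >= stop_at_acc) break
  }
  model$history <- hist
  model
}

#' Classify images with a (trained) CNN
#'
#' @param model a `cnn_model`
#' @param images list of arrays matching the model input size
#' @return list with `labels` (0-based argmax classes) and `prob`
#'   (n x output_units matrix; each row sums to 1)
#' @export
predict_cnn <- function(model, images) {
  sz <- model$input_size
  probs <- matrix(0, length(images), model$output_units)
  for (i in seq_along(images)) {
    im <- images[[i]]
    if (!identical(as.integer(dim(im)), as.integer(sz))) {
      stop("image size mismatch with model input_size", call. = FALSE)
    }
    probs[i, ] <- cnn_forward(model, im)$prob
  }
  list(labels = max.col(probs) - 1L, prob = probs)
}
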