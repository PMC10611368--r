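# Gradient-boosted decision trees for binary classification, the default
# back-end of the classifier harness. Second-order (Newton) leaf values and
# split gains in the xgboost style, best-first leaf growth, log-loss
# objective. Fully deterministic: no row or column subsampling.

# grow one regression tree on gradients g, hessians h
# nodes table columns: feature, threshold, left, right, value, is_leaf
gbdt_grow_tree <- function(X, g, h, max_leaves = 31L, min_child = 5L,
                           lambda = 1, gamma = 0) {
  nodes <- list()
  new_node <- function(rows) {
    nodes[[length(nodes) + 1L]] <<- list(
      rows = rows, feature = NA_integer_, threshold = NA_real_,
      left = NA_integer_, right = NA_integer_,
      value = -sum(g[rows]) / (sum(h[rows]) + lambda), is_leaf = TRUE)
    length(nodes)
  }
  best_split <- function(rows) {
    G <- sum(g[rows]); H <- sum(h[rows])
    base <- G^2 / (H + lambda)
    best <- list(gain = 0)
    for (j in seq_len(ncol(X))) {
      xo <- order(X[rows, j])
      r <- rows[xo]
      xs <- X[r, j]
      gc <- cumsum(g[r]); hc <- cumsum(h[r])
      k <- seq_len(length(r) - 1L)
      valid <- k >= min_child & (length(r) - k) >= min_child &
               xs[k] < xs[k + 1L]
      if (!any(valid)) next
      gl <- gc[k]; hl <- hc[k]
      gain <- gl^2 / (hl + lambda) + (G - gl)^2 / (H - hl + lambda) - base - gamma
      gain[!valid] <- -Inf
      kb <- which.max(gain)
      if (gain[kb] > best$gain) {
        best <- list(gain = gain[kb], feature = j,
                     threshold = (xs[kb] + xs[kb + 1L]) / 2,
                     left_rows = r[seq_len(kb)], right_rows = r[(kb + 1L):length(r)])
      }
    }
    best
  }
  root <- new_node(seq_len(nrow(X)))
  frontier <- list(list(id = root, split = best_split(nodes[[root]]$rows)))
  n_leaves <- 1L
  gains <- numeric(ncol(X))
  while (n_leaves < max_leaves) {
    gvals <- vapply(frontier, function(f) f$split$gain, numeric(1))
    if (length(gvals) == 0L || max(gvals) <= 0) break
    bi <- which.max(gvals)
    f <- frontier[[bi]]; frontier[[bi]] <- NULL
    sp <- f$split
    l <- new_node(sp$left_rows); r <- new_node(sp$right_rows)
    nodes[[f$id]]$is_leaf <- FALSE
    nodes[[f$id]]$feature <- sp$feature
    nodes[[f$id]]$threshold <- sp$threshold
    nodes[[f$id]]$left <- l; nodes[[f$id]]$right <- r
    gains[sp$feature] <- gains[sp$feature] + sp$gain
    n_leaves <- n_leaves + 1L
    frontier <- c(frontier, list(list(id = l, split = best_split(sp$left_rows)),
                                 list(id = r, split = best_split(sp$right_rows))))
  }
  nodes <- lapply(nodes, function(nd) { nd$rows <- NULL; nd })
  list(nodes = nodes, gains = gains)
}

gbdt_tree_predict <- function(tree, X) {
  out <- numeric(nrow(X))
  walk <- function(id, rows) {
    nd <- tree$nodes[[id]]
    if (nd$is_leaf) {
      out[rows] <<- nd$value
      return(invisible())
    }
    go_left <- X[rows, nd$feature] <= nd$threshold
    if (any(go_left)) walk(nd$left, rows[go_left])
    if (any(!go_left)) walk(nd$right, rows[!go_left])
  }
  walk(1L, seq_len(nrow(X)))
  out
}

#' Fit a gradient-boosted tree binary classifier
#'
#' @param X numeric feature matrix
#' @param y 0/1 response vector
#' @param n_trees boosting rounds (default 100)
#' @param learning_rate shrinkage (default 0.1)
#' @param max_leaves leaves per tree (default 31)
#' @param min_child minimum rows per leaf (default 5)
#' @param lambda L2 regularisation on leaf values (default 1)
#' @return a `gbdt_model`
#' @export
gbdt_fit <- function(X, y, n_trees = 100L, learning_rate = 0.1,
                     max_leaves = 31L, min_child = 5L, lambda = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
  f0 <- log(p0 / (1 - p0))
  f <- rep(f0, nrow(X))
  trees <- vector("list", n_trees)
  gains <- numeric(ncol(X))
  for (t in seq_len(n_trees)) {
    p <- 1 / (1 + exp(-f))
    g <- p - y
    h <- pmax(p * (1 - p), 1e-12)
    tr <- gbdt_grow_tree(X, g, h, max_leaves, min_child, lambda)
    trees[[t]] <- tr
    gains <- gains + tr$gains
    f <- f + learning_rate * gbdt_tree_predict(tr, X)
  }
  structure(list(trees = trees, f0 = f0, learning_rate = learning_rate,
                 feature_gains = gains), class = "gbdt_model")
}

#' Predict class-1 probabilities from a gbdt model
#' @param model a `gbdt_model`
#' @param X feature matrix with the training column layout
#' @return probability vector
#' @export
gbdt_predict_prob <- function(model, X) {
  X <- as.matrix(X)
  f <- rep(model$f0, nrow(X))
  for (tr in model$trees) f <- f + model$learning_rate * gbdt_tree_predict(tr, X)
  1 / (1 + exp(-f))
}
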