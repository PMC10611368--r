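# Per-modality fatigue classifier harness: one train/predict/evaluate
# contract over three interchangeable back-ends (gradient-boosted trees,
# linear SVM, logistic regression) with a stratified 80/20 split protocol.

#' Training configuration
#'
#' @param backend `"gbdt"` (default), `"svm"` or `"logistic"`
#' @param test_fraction held-out fraction in (0, 1); default 0.2 (the 80/20
#'   protocol)
#' @param seed integer split/back-end seed
#' @param ... back-end hyperparameters (gbdt: `n_trees` 100, `max_leaves`
#'   31, `learning_rate` 0.1, `min_child`; svm: `lambda`, `iters`)
#' @return a `train_config`
#' @export
train_config <- function(backend = c("gbdt", "svm", "logistic"),
                         test_fraction = 0.2, seed = 1L, ...) {
  backend <- match.arg(backend)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(list(backend = backend, test_fraction = test_fraction,
                 seed = as.integer(seed), hyper = list(...)),
            class = "train_config")
}

#' Stratified train/test split
#'
#' Shuffles within each class (deterministically from the seed) and holds
#' out `test_fraction` of every class, so class balance is preserved within
#' one row in both parts.
#'
#' @param table a labelled `feature_table` with at least 2 classes
#' @param cfg a [train_config()]
#' @return list with `train` and `test` feature tables
#' @export
split_table <- function(table, cfg = train_config()) {
  if (!"label" %in% names(table)) stop("table must be labelled", call. = FALSE)
  classes <- unique(table$label)
  if (length(classes) < 2L) stop("need at least 2 classes to split", call. = FALSE)
  set.seed(cfg$seed)
  test_idx <- integer(0)
  for (cl in sort(classes)) {
    rows <- which(table$label == cl)
    n_test <- round(length(rows) * cfg$test_fraction)
    test_idx <- c(test_idx, sample(rows)[seq_len(n_test)])
  }
  list(train = table[-test_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE])
}

encode_labels <- function(labels) {
  lv <- sort(unique(labels))
  if (length(lv) != 2L) stop("back-ends are binary: expected 2 classes", call. = FALSE)
  list(levels = lv, y = as.numeric(labels == lv[2L]))
}

# deterministic full-batch linear SVM (squared hinge + L2), standardised X
svm_fit <- function(X, y01, lambda = 1e-3, iters = 500L) {
  y <- ifelse(y01 == 1, 1, -1)
  mu <- colMeans(X); sg <- apply(X, 2L, stats::sd); sg[sg == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sg, "/")
  w <- numeric(ncol(X)); b <- 0
  lr <- 0.1
  for (it in seq_len(iters)) {
    marg <- y * (Xs %*% w + b)
    act <- as.numeric(marg < 1)
    gw <- -2 * crossprod(Xs, y * act * pmax(1 - marg, 0)) / nrow(Xs) + 2 * lambda * w
    gb <- -2 * sum(y * act * pmax(1 - marg, 0)) / nrow(Xs)
    w <- w - lr * gw; b <- b - lr * gb
  }
  list(w = as.numeric(w), b = b, mu = mu, sg = sg)
}

svm_decision <- function(fit, X) {
  Xs <- sweep(sweep(as.matrix(X), 2L, fit$mu), 2L, fit$sg, "/")
  as.numeric(Xs %*% fit$w + fit$b)
}

#' Train a fatigue classifier
#'
#' @param table a labelled `feature_table` (binary labels)
#' @param cfg a [train_config()]
#' @return a `fatigue_model` carrying the back-end fit, feature schema and
#'   label levels
#' @export
train_classifier <- function(table, cfg = train_config()) {
  fn <- feature_names(table)
  X <- as.matrix(as.data.frame(table)[fn])
  enc <- encode_labels(table$label)
  set.seed(cfg$seed)
  hp <- cfg$hyper
  fit <- switch(cfg$backend,
    gbdt = gbdt_fit(X, enc$y,
                    n_trees = hp$n_trees %||% 100L,
                    learning_rate = hp$learning_rate %||% 0.1,
                    max_leaves = hp$max_leaves %||% 31L,
                    min_child = hp$min_child %||% 5L),
    svm = svm_fit(X, enc$y, lambda = hp$lambda %||% 1e-3,
                  iters = hp$iters %||% 500L),
    logistic = {
      df <- data.frame(X, .y = enc$y, check.names = FALSE)
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial(),
                                  control = list(maxit = 50)))
    })
  structure(list(backend = cfg$backend, fit = fit, feature_names = fn,
                 levels = enc$levels, config = cfg, version = "drowsyfuse-1"),
            class = "fatigue_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict labels from a fatigue classifier
#'
#' @param model a `fatigue_model`
#' @param table a `feature_table` with the training schema
#' @return vector of predicted labels (original label values)
#' @export
predict_classifier <- function(model, table) {
  fn <- feature_names(table)
  if (!identical(sort(fn), sort(model$feature_names))) {
    stop("feature schema mismatch with the training table", call. = FALSE)
  }
  X <- as.matrix(as.data.frame(table)[model$feature_names])
  p <- switch(model$backend,
    gbdt = gbdt_predict_prob(model$fit, X),
    svm = 1 / (1 + exp(-svm_decision(model$fit, X))),
    logistic = {
      df <- as.data.frame(X)
      as.numeric(stats::predict(model$fit, newdata = df, type = "response"))
    })
  model$levels[ifelse(p >= 0.5, 2L, 1L)]
}

#' Evaluate predictions against ground truth
#'
#' @param truth,predicted aligned label vectors
#' @return an `eval_report`: list with `accuracy`, `confusion` (table,
#'   truth in rows), per-class `precision` and `recall`, `n_test`
#' @export
evaluate_classification <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  lv <- sort(unique(c(truth, predicted)))
  conf <- table(factor(truth, levels = lv), factor(predicted, levels = lv))
  acc <- sum(diag(conf)) / length(truth)
  precision <- diag(conf) / pmax(colSums(conf), 1)
  recall <- diag(conf) / pmax(rowSums(conf), 1)
  structure(list(accuracy = acc, confusion = conf,
                 precision = precision, recall = recall,
                 n_test = length(truth)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.4f on %d rows\n", x$accuracy, x$n_test))
  print(x$confusion)
  invisible(x)
}

#' Split, train and evaluate in one call
#'
#' Applies the stratified 80/20 protocol, fits the configured back-end on
#' the training part and reports held-out performance.
#'
#' @param table a labelled `feature_table`
#' @param cfg a [train_config()]
#' @return list with `model`, `report` (an `eval_report` augmented with
#'   `n_train`), and the `split`
#' @export
run_experiment <- function(table, cfg = train_config()) {
  sp <- split_table(table, cfg)
  model <- train_classifier(sp$train, cfg)
  pred <- predict_classifier(model, sp$test)
  rep <- evaluate_classification(sp$test$label, pred)
  rep$n_train <- nrow(sp$train)
  list(model = model, report = rep, split = sp)
}

#' Normalised gbdt feature importances
#'
#' Total split gain per feature, normalised to sum to 1.
#'
#' @param model a gbdt `fatigue_model`
#' @return named numeric vector over the training features
#' @export
feature_importance <- function(model) {
  if (model$backend != "gbdt") stop("importances available for gbdt only", call. = FALSE)
  g <- model$fit$feature_gains
  names(g) <- model$feature_names
  if (sum(g) > 0) g / sum(g) else g
}
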