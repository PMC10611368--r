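# a small separable two-class table, cheap to rebuild per test
toy_table <- function(n_per = 50, sep = 2, seed = 1) {
  set.seed(seed)
  x1 <- matrix(rnorm(n_per * 4), n_per, 4)
  x2 <- matrix(rnorm(n_per * 4, mean = sep), n_per, 4)
  feature_table(rbind(x1, x2), feature_names = paste0("f", 1:4),
                labels = rep(c("alert", "fatigued"), each = n_per))
}

test_that("split_table is stratified, sized and deterministic", {
  ft <- toy_table()
  cfg <- train_config(seed = 7)
  sp <- split_table(ft, cfg)
  expect_equal(nrow(sp$train), 80L)
  expect_equal(nrow(sp$test), 20L)
  expect_true(all(abs(table(sp$test$label) - 10) <= 1))
  expect_true(all(abs(table(sp$train$label) - 40) <= 1))
  sp2 <- split_table(ft, cfg)
  expect_identical(sp, sp2)

  single <- feature_table(matrix(rnorm(20), 10, 2), labels = rep("alert", 10))
  expect_error(split_table(single, cfg), "2 classes")
})

test_that("all back-ends share the train/predict contract and are deterministic", {
  ft <- toy_table()
  for (be in c("gbdt", "svm", "logistic")) {
    cfg <- train_config(be, seed = 3)
    ex <- run_experiment(ft, cfg)
    expect_gte(ex$report$accuracy, 0.9)
    expect_equal(ex$report$n_train, 80L)
    expect_equal(ex$report$n_test, 20L)
    ex2 <- run_experiment(ft, cfg)
    expect_identical(ex$report$accuracy, ex2$report$accuracy)
    expect_identical(ex$report$confusion, ex2$report$confusion)
  }
})

test_that("evaluate_classification computes accuracy and confusion coherently", {
  truth <- c("a", "a", "b", "b", "b")
  pred <- c("a", "b", "b", "b", "a")
  r <- evaluate_classification(truth, pred)
  expect_equal(r$accuracy, 3 / 5)
  expect_equal(sum(r$confusion), 5)
  expect_equal(r$accuracy, sum(diag(r$confusion)) / r$n_test)
  expect_error(predict_classifier(
    train_classifier(toy_table(), train_config()),
    feature_table(matrix(1, 2, 2), feature_names = c("zz", "f1"))), "schema")
})

test_that("a deep-grown gbdt fits train at least as well as test", {
  ft <- toy_table(n_per = 40, sep = 0.8, seed = 5)
  cfg <- train_config("gbdt", seed = 5, max_leaves = 63L, min_child = 1L)
  sp <- split_table(ft, cfg)
  model <- train_classifier(sp$train, cfg)
  acc_train <- evaluate_classification(
    sp$train$label, predict_classifier(model, sp$train))$accuracy
  acc_test <- evaluate_classification(
    sp$test$label, predict_classifier(model, sp$test))$accuracy
  expect_gte(acc_train, acc_test)
})

test_that("gbdt feature importances normalise and rank the signal features", {
  ft <- toy_table(seed = 2)
  # dilute with two pure-noise features
  set.seed(99)
  df <- as.data.frame(ft)
  df$noise1 <- rnorm(nrow(df)); df$noise2 <- rnorm(nrow(df))
  lab <- df$label; df$label <- NULL
  ft2 <- feature_table(df, labels = lab)
  model <- train_classifier(ft2, train_config("gbdt", seed = 2))
  imp <- feature_importance(model)
  expect_equal(sum(imp), 1, tolerance = 1e-12)
  expect_gt(sum(imp[paste0("f", 1:4)]), sum(imp[c("noise1", "noise2")]))
  expect_error(feature_importance(train_classifier(ft, train_config("logistic"))),
               "gbdt")
})
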