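toy_features <- function(n = 60, sep = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n * 2, mean = 0), n, 2),
    matrix(rnorm(n * 2, mean = sep / 2), n, 2)
  )
  list(x = x, y = c(rep("NoErrP", n), rep("ErrP", n)))
}

test_that("a separable toy problem is fit without training errors", {
  toy <- toy_features(sep = 8)
  model <- fit_errp_model(toy$x, toy$y, cost = 1)
  expect_equal(predict(model, toy$x), toy$y)
})

test_that("duplicating a separable dataset leaves the boundary unchanged", {
  toy <- toy_features(sep = 8)
  m1 <- fit_errp_model(toy$x, toy$y, cost = 1)
  m2 <- fit_errp_model(rbind(toy$x, toy$x), c(toy$y, toy$y), cost = 1)
  d1 <- c(m1$weights / sqrt(sum(m1$weights^2)),
          m1$bias / sqrt(sum(m1$weights^2)))
  d2 <- c(m2$weights / sqrt(sum(m2$weights^2)),
          m2$bias / sqrt(sum(m2$weights^2)))
  expect_equal(d1, d2, tolerance = 1e-4)
})

test_that("up-weighting the error class raises its training-set recall", {
  toy <- toy_features(n = 150, sep = 1.5, seed = 3)
  weighted <- fit_errp_model(toy$x, toy$y, cost = 1,
                             class_weights = c(NoErrP = 1, ErrP = 2))
  flat <- fit_errp_model(toy$x, toy$y, cost = 1,
                         class_weights = c(NoErrP = 1, ErrP = 1))
  tpr <- function(m) mean(predict(m, toy$x)[toy$y == "ErrP"] == "ErrP")
  expect_gte(tpr(weighted), tpr(flat))
  expect_gt(tpr(weighted), tpr(flat) - 1e-9)  # strictly informative case
})

test_that("single-class input is rejected", {
  toy <- toy_features()
  expect_error(fit_errp_model(toy$x, rep("ErrP", nrow(toy$x))), "both classes")
})

test_that("metric formulas and degenerate flags are correct", {
  m <- compute_metrics(tp = 9, fn = 1, tn = 95, fp = 5)
  expect_equal(m$tpr, 0.9)
  expect_equal(m$tnr, 0.95)
  expect_equal(m$bacc, 0.925)
  expect_equal(m$precision, 9 / 14)
  expect_equal(m$f1, 2 * (9 / 14) * 0.9 / (9 / 14 + 0.9))

  perfect <- compute_metrics(tp = 10, fn = 0, tn = 50, fp = 0)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$bacc, 1)

  degenerate <- compute_metrics(tp = 0, fn = 5, tn = 50, fp = 0)
  expect_true(is.na(degenerate$precision))
  expect_true(is.na(degenerate$f1))
  expect_true(all(c("precision", "f1") %in% attr(degenerate, "undefined")))
  expect_false(identical(degenerate$precision, 0))
})

test_that("stratified folds partition the data with both classes everywhere", {
  labels <- c(rep("ErrP", 23), rep("NoErrP", 57))
  fold <- stratified_folds(labels, 5, seed = 2)
  expect_equal(sort(unique(fold)), 1:5)
  expect_length(fold, 80)
  for (k in 1:5) {
    expect_true(all(c("ErrP", "NoErrP") %in% labels[fold == k]))
  }
  expect_error(stratified_folds(c("a", rep("b", 20)), 3), "fewer than")
})

test_that("nested CV reports per-fold costs from the grid and coherent pooling", {
  corp <- build_corpus(n_sets = 2, seed = 11)
  plan <- cv_plan(outer_folds = 4, inner_folds = 3, seed = 5)
  cv <- nested_cv(corp$epochs, plan)
  expect_equal(nrow(cv$per_fold), 4)
  expect_true(all(cv$per_fold$cost %in% plan$c_grid))
  expect_equal(sum(cv$per_fold$tp + cv$per_fold$fn + cv$per_fold$tn + cv$per_fold$fp),
               dim(corp$epochs$data)[1])
  expect_equal(cv$pooled$tp, sum(cv$per_fold$tp))
  expect_equal(glance(cv)$bacc, cv$pooled$bacc)
  expect_equal(nrow(tidy(cv)), 4)
})

test_that("permuted labels drop performance to chance", {
  corp <- build_corpus(n_sets = 2, seed = 11)
  ep <- corp$epochs
  set.seed(8)
  ep$info$label <- sample(ep$info$label)
  cv <- nested_cv(ep, cv_plan(outer_folds = 4, inner_folds = 3, seed = 5))
  expect_gt(cv$pooled$bacc, 0.25)
  expect_lt(cv$pooled$bacc, 0.75)
})

test_that("perfectly separable features give perfect pooled metrics", {
  set.seed(4)
  n <- 40
  labels <- rep(c("ErrP", "NoErrP"), each = n)
  x <- rbind(matrix(rnorm(n * 3, 10), n, 3), matrix(rnorm(n * 3, -10), n, 3))
  fold <- stratified_folds(labels, 4, seed = 1)
  pooled <- c(tp = 0, fn = 0, tn = 0, fp = 0)
  for (k in 1:4) {
    model <- fit_errp_model(x[fold != k, ], labels[fold != k], cost = 1)
    cc <- errpipe:::confusion_counts(labels[fold == k], predict(model, x[fold == k, ]))
    pooled <- pooled + unlist(cc)
  }
  m <- compute_metrics(pooled["tp"], pooled["fn"], pooled["tn"], pooled["fp"])
  expect_equal(m$bacc, 1)
  expect_equal(m$f1, 1)
})
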