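#' Cross-validation plan
#'
#' Nested stratified cross-validation: 10 stratified outer folds estimate
#' generalization, and within each outer-training set a 5-fold stratified
#' inner loop selects the SVM cost from a log-spaced grid by highest pooled
#' inner balanced accuracy (ties broken towards the smallest cost, i.e. the
#' strongest regularization).
#'
#' @param outer_folds,inner_folds Fold counts (defaults 10 and 5).
#' @param c_grid Cost grid (default `10^(-6:0)`).
#' @param class_weights Named SVM class weights.
#' @param n_components xDAWN components fitted inside each training fold.
#' @param seed Seed for the fold shuffling.
#' @return A validated plan list.
#' @export
cv_plan <- function(outer_folds = 10, inner_folds = 5,
                    c_grid = 10^(-6:0),
                    class_weights = c(NoErrP = 1, ErrP = 2),
                    n_components = 7, seed = 1L) {
  stopifnot(outer_folds >= 2, inner_folds >= 2, all(c_grid > 0))
  list(outer_folds = as.integer(outer_folds),
       inner_folds = as.integer(inner_folds),
       c_grid = sort(c_grid), class_weights = class_weights,
       n_components = as.integer(n_components), seed = as.integer(seed))
}

#' Stratified fold assignment
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer fold id per observation; every fold contains both classes.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      if (length(idx) < k) {
        abort(sprintf("class '%s' has %d members, fewer than %d folds.",
                      cl, length(idx), k))
      }
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# inner loop: select C by pooled inner balanced accuracy
.select_cost <- function(epochs, plan, seed) {
  labels <- epochs$info$label
  fold <- stratified_folds(labels, plan$inner_folds, seed)
  counts <- matrix(0, nrow = length(plan$c_grid), ncol = 4,
                   dimnames = list(NULL, c("tp", "fn", "tn", "fp")))
  for (j in seq_len(plan$inner_folds)) {
    tr <- subset_epochs(epochs, fold != j)
    te <- subset_epochs(epochs, fold == j)
    ext <- fit_feature_extractor(tr, plan$n_components, permitted_folds = j)
    xtr <- transform_features(ext, tr, fold = j)
    xte <- transform_features(ext, te, fold = j)
    for (ci in seq_along(plan$c_grid)) {
      model <- fit_errp_model(xtr, tr$info$label, plan$c_grid[ci], plan$class_weights)
      cc <- confusion_counts(te$info$label, predict(model, xte))
      counts[ci, ] <- counts[ci, ] + unlist(cc)
    }
  }
  bacc <- (counts[, "tp"] / (counts[, "tp"] + counts[, "fn"]) +
           counts[, "tn"] / (counts[, "tn"] + counts[, "fp"])) / 2
  plan$c_grid[which.max(bacc)]  # which.max takes the first (smallest C) tie
}

#' Nested stratified cross-validation of the full pipeline
#'
#' For each outer fold, the entire feature extractor (xDAWN filters, Frechet
#' reference point, normalization statistics) and the classifier are fitted
#' on the outer-training portion only; the inner 5-fold loop — itself
#' refitting the extractor per inner fold — selects the SVM cost. Metrics are
#' computed per outer fold and pooled over the outer-test confusion counts.
#'
#' Setting `concat_first = TRUE` reproduces the variant in which the feature
#' extractor is fitted once on all concatenated data before cross-validation;
#' this leaks feature-extraction information across folds and exists only for
#' comparison.
#'
#' @param epochs Preprocessed `errp_epochs` (feature window, both classes).
#' @param plan A [cv_plan()].
#' @param concat_first Fit the feature extractor on all data first (leaky
#'   variant, default `FALSE`).
#' @return An `errp_cv` object: `per_fold` tibble (fold, chosen cost,
#'   confusion, metrics), `pooled` one-row metrics tibble, `plan`.
#' @export
nested_cv <- function(epochs, plan = cv_plan(), concat_first = FALSE) {
  labels <- epochs$info$label
  if (min(table(labels)) < plan$outer_folds) {
    abort("every class needs at least as many epochs as outer folds.")
  }
  fold <- stratified_folds(labels, plan$outer_folds,
                           derive_seed(plan$seed, "outer_folds"))
  global_ext <- if (concat_first) {
    fit_feature_extractor(epochs, plan$n_components, permitted_folds = NULL,
                          strict = FALSE)
  }
  per_fold <- vector("list", plan$outer_folds)
  pooled <- c(tp = 0, fn = 0, tn = 0, fp = 0)
  for (o in seq_len(plan$outer_folds)) {
    tr <- subset_epochs(epochs, fold != o)
    te <- subset_epochs(epochs, fold == o)
    cost <- .select_cost(tr, plan, derive_seed(plan$seed, "inner_folds", o))
    if (concat_first) {
      xtr <- transform_features(global_ext, tr)
      xte <- transform_features(global_ext, te)
    } else {
      ext <- fit_feature_extractor(tr, plan$n_components, permitted_folds = o)
      xtr <- transform_features(ext, tr, fold = o)
      xte <- transform_features(ext, te, fold = o)
    }
    model <- fit_errp_model(xtr, tr$info$label, cost, plan$class_weights)
    cc <- confusion_counts(te$info$label, predict(model, xte))
    pooled <- pooled + unlist(cc)
    per_fold[[o]] <- dplyr::bind_cols(
      tibble(fold = o, cost = cost),
      compute_metrics(cc$tp, cc$fn, cc$tn, cc$fp)
    )
  }
  structure(
    list(
      per_fold = dplyr::bind_rows(per_fold),
      pooled = compute_metrics(pooled["tp"], pooled["fn"],
                               pooled["tn"], pooled["fp"]),
      plan = plan, concat_first = concat_first
    ),
    class = "errp_cv"
  )
}

#' @export
print.errp_cv <- function(x, ...) {
  p <- x$pooled
  cat(sprintf(
    "<errp_cv> %d-fold nested CV, pooled bACC %.3f (TPR %.3f, TNR %.3f) over %d epochs\n",
    x$plan$outer_folds, p$bacc, p$tpr, p$tnr, p$tp + p$fn + p$tn + p$fp
  ))
  invisible(x)
}

#' Fit a transfer pipeline on one scenario's data
#'
#' Fits the feature extractor on all training epochs, selects the SVM cost by
#' the inner stratified 5-fold loop, and fits the final classifier on the
#' full training set. The frozen extractor and model are then applied to
#' recordings from another scenario with [transfer_evaluate()].
#'
#' @param train_epochs Preprocessed training `errp_epochs`.
#' @param plan A [cv_plan()] (its inner-fold settings are used).
#' @return List with `extractor`, `model`, `cost`.
#' @export
fit_transfer_model <- function(train_epochs, plan = cv_plan()) {
  cost <- .select_cost(train_epochs, plan, derive_seed(plan$seed, "transfer_inner"))
  extractor <- fit_feature_extractor(train_epochs, plan$n_components,
                                     permitted_folds = NULL, strict = FALSE)
  x <- transform_features(extractor, train_epochs)
  model <- fit_errp_model(x, train_epochs$info$label, cost, plan$class_weights)
  list(extractor = extractor, model = model, cost = cost)
}

#' Evaluate a frozen pipeline on another scenario
#'
#' Test features are transformed with the training-scenario extractor state
#' (filters, reference point, normalization statistics all frozen); no
#' component is refitted on test data.
#'
#' @param extractor Fitted `errp_extractor` from the training scenario.
#' @param model Fitted `errp_model` from the training scenario.
#' @param test_epochs Preprocessed `errp_epochs` from the test scenario.
#' @return One-row metrics tibble from [compute_metrics()].
#' @export
transfer_evaluate <- function(extractor, model, test_epochs) {
  x <- transform_features(extractor, test_epochs)
  cc <- confusion_counts(test_epochs$info$label, predict(model, x))
  compute_metrics(cc$tp, cc$fn, cc$tn, cc$fp)
}
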