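#' Fit the class-weighted linear max-margin classifier
#'
#' A linear support-vector machine on the 105-dimensional tangent-space
#' features, with per-class misclassification penalties `C * weight(class)`.
#' The error (ErrP) class is the positive class and is weighted twice as
#' heavily as the correct (NoErrP) class by default, compensating the 26:6
#' class imbalance of the design.
#'
#' @param features Numeric matrix, rows = epochs, columns = feature
#'   dimensions.
#' @param labels Character or factor labels (`"ErrP"` / `"NoErrP"`); both
#'   classes must be present.
#' @param cost SVM cost parameter C.
#' @param class_weights Named weights (default `c(NoErrP = 1, ErrP = 2)`).
#' @return An `errp_model`: list with the fitted svm, `weights` (the primal
#'   weight vector), `bias`, `cost`, `class_weights`.
#' @export
fit_errp_model <- function(features, labels,
                           cost = 1,
                           class_weights = c(NoErrP = 1, ErrP = 2)) {
  y <- factor(labels, levels = c("NoErrP", "ErrP"))
  if (any(table(y) == 0)) abort("both classes must be present to fit the classifier.")
  fit <- e1071::svm(
    x = features, y = y, kernel = "linear", cost = cost,
    class.weights = class_weights, scale = FALSE
  )
  w <- drop(t(fit$coefs) %*% fit$SV)
  structure(
    list(svm = fit, weights = w, bias = -fit$rho, cost = cost,
         class_weights = class_weights),
    class = "errp_model"
  )
}

#' @export
predict.errp_model <- function(object, newdata, ...) {
  as.character(predict(object$svm, newdata))
}

#' @export
print.errp_model <- function(x, ...) {
  cat(sprintf(
    "<errp_model> linear SVM, C = %g, class weights NoErrP:ErrP = %g:%g, %d SVs\n",
    x$cost, x$class_weights[["NoErrP"]], x$class_weights[["ErrP"]],
    nrow(x$svm$SV)
  ))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' ErrP is the positive class. Balanced accuracy is the arithmetic mean of
#' the true positive rate and the true negative rate; the F measure is the F1
#' score of the positive class. A metric whose denominator is zero is
#' reported as `NA` and named in the `undefined` attribute — never as 0.
#'
#' @param tp,fn,tn,fp Confusion counts (TP/FN on error trials, TN/FP on
#'   correct trials).
#' @return One-row tibble with columns `tp`, `fn`, `tn`, `fp`, `tpr`, `tnr`,
#'   `bacc`, `precision`, `f1`; attribute `undefined` lists absent metrics.
#' @export
compute_metrics <- function(tp, fn, tn, fp) {
  tp <- as.numeric(tp); fn <- as.numeric(fn)
  tn <- as.numeric(tn); fp <- as.numeric(fp)
  undef <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      undef <<- c(undef, name)
      return(NA_real_)
    }
    num / den
  }
  tpr <- ratio(tp, tp + fn, "tpr")
  tnr <- ratio(tn, tn + fp, "tnr")
  bacc <- if (is.na(tpr) || is.na(tnr)) { undef <- c(undef, "bacc"); NA_real_ } else (tpr + tnr) / 2
  precision <- ratio(tp, tp + fp, "precision")
  f1 <- if (is.na(precision) || is.na(tpr) || precision + tpr == 0) {
    undef <- c(undef, "f1")
    NA_real_
  } else 2 * precision * tpr / (precision + tpr)
  out <- tibble(tp = tp, fn = fn, tn = tn, fp = fp,
                tpr = tpr, tnr = tnr, bacc = bacc,
                precision = precision, f1 = f1)
  attr(out, "undefined") <- unique(undef)
  out
}

# confusion counts of predicted vs true labels (ErrP positive)
confusion_counts <- function(truth, predicted) {
  list(
    tp = sum(truth == "ErrP" & predicted == "ErrP"),
    fn = sum(truth == "ErrP" & predicted == "NoErrP"),
    tn = sum(truth == "NoErrP" & predicted == "NoErrP"),
    fp = sum(truth == "NoErrP" & predicted == "ErrP")
  )
}
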