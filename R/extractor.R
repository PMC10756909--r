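#' Fit the full tangent-space feature extractor
#'
#' Chains, on training epochs only: xDAWN spatial filtering (7 pseudo
#' channels), extended-epoch construction, Ledoit-Wolf shrinkage covariance
#' (14 x 14), the Frechet mean of the training covariances as tangent-space
#' reference point, tangent projection, Mandel vectorization (105
#' dimensions), and per-dimension standardization statistics.
#'
#' The fitted state records which cross-validation folds it may transform.
#' In strict mode, [transform_features()] refuses data from any other fold —
#' a guard against train/test leakage.
#'
#' @param epochs Preprocessed training `errp_epochs` (both classes present).
#' @param n_components Number of xDAWN components (default 7).
#' @param permitted_folds Fold ids this extractor may transform (`NULL`
#'   disables the check even in strict mode).
#' @param strict Enforce the fold guard (default `TRUE`).
#' @return An `errp_extractor`: list with `bank`, `reference`, `center`,
#'   `scale`, `zero_var` (indices of clamped dimensions), `permitted_folds`,
#'   `strict`.
#' @export
fit_feature_extractor <- function(epochs, n_components = 7,
                                  permitted_folds = NULL, strict = TRUE) {
  bank <- fit_xdawn(epochs, n_components)
  covs <- epoch_covariances(bank, epochs)
  ref <- frechet_mean(covs)
  raw <- vapply(covs, function(c_i) mandel_vectorize(tangent_project(c_i, ref)),
                numeric(nrow(ref) * (nrow(ref) + 1) / 2))
  raw <- t(raw)
  center <- colMeans(raw)
  scale <- apply(raw, 2, sd)
  zero_var <- which(scale == 0 | !is.finite(scale))
  if (length(zero_var) > 0) {
    warn(sprintf("%d zero-variance feature dimension(s); scale clamped to 1.",
                 length(zero_var)))
    scale[zero_var] <- 1
  }
  structure(
    list(bank = bank, reference = ref, center = center, scale = scale,
         zero_var = zero_var, permitted_folds = permitted_folds,
         strict = strict),
    class = "errp_extractor"
  )
}

#' Ledoit-Wolf covariances of the extended epochs
#'
#' @param bank An `xdawn_bank`.
#' @param epochs Preprocessed `errp_epochs`.
#' @return List of SPD covariance matrices, one per epoch.
#' @export
epoch_covariances <- function(bank, epochs) {
  d <- dim(epochs$data)
  lapply(seq_len(d[1]), function(i) {
    filtered <- bank$filters %*% epochs$data[i, , ]
    ledoit_wolf_cov(extend_epoch(bank, filtered))
  })
}

#' Transform epochs into normalized tangent-space feature vectors
#'
#' @param extractor Fitted `errp_extractor`.
#' @param epochs Preprocessed `errp_epochs` to transform.
#' @param fold Fold id of the data being transformed; checked against the
#'   extractor's permitted folds when strict mode is on.
#' @return Matrix `n_epochs x 105` of standardized features, with the labels
#'   as the `labels` attribute.
#' @export
transform_features <- function(extractor, epochs, fold = NULL) {
  if (isTRUE(extractor$strict) && !is.null(extractor$permitted_folds) &&
      (is.null(fold) || !all(fold %in% extractor$permitted_folds))) {
    abort("leakage guard: this extractor is not permitted to transform this fold.")
  }
  covs <- epoch_covariances(extractor$bank, epochs)
  raw <- t(vapply(
    covs,
    function(c_i) mandel_vectorize(tangent_project(c_i, extractor$reference)),
    numeric(length(extractor$center))
  ))
  out <- sweep(sweep(raw, 2, extractor$center), 2, extractor$scale, "/")
  attr(out, "labels") <- epochs$info$label
  out
}

#' Standardize feature vectors with training statistics
#'
#' Per-dimension location/scale standardization: statistics are learned on
#' the training matrix and applied unchanged to any other matrix.
#' Zero-variance dimensions keep their values (scale clamped to 1) and are
#' reported in the `zero_var` attribute.
#'
#' @param train Training feature matrix (rows = observations).
#' @return A function that standardizes a compatible matrix; the training
#'   statistics are stored in its `center`/`scale` attributes.
#' @export
feature_normalizer <- function(train) {
  center <- colMeans(train)
  scale <- apply(train, 2, sd)
  zero_var <- which(scale == 0 | !is.finite(scale))
  if (length(zero_var) > 0) {
    warn(sprintf("%d zero-variance dimension(s); scale clamped to 1.", length(zero_var)))
    scale[zero_var] <- 1
  }
  f <- function(x) sweep(sweep(x, 2, center), 2, scale, "/")
  attr(f, "center") <- center
  attr(f, "scale") <- scale
  attr(f, "zero_var") <- zero_var
  f
}
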