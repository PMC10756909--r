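#' Symmetric-matrix eigen-functions
#'
#' Matrix square root, inverse square root, logarithm and exponential of a
#' symmetric positive-definite matrix via eigendecomposition. Eigenvalues are
#' floored at `1e-12` before any root/log so that numerically semi-definite
#' inputs remain usable.
#'
#' @param m Symmetric matrix.
#' @param fun Scalar function applied to the eigenvalues.
#' @return Symmetric matrix `V diag(fun(lambda)) V'`.
#' @keywords internal
spd_fun <- function(m, fun) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 1e-12)
  e$vectors %*% (fun(vals) * t(e$vectors))
}

spd_sqrtm <- function(m) spd_fun(m, sqrt)
spd_isqrtm <- function(m) spd_fun(m, function(v) 1 / sqrt(v))
spd_logm <- function(m) spd_fun(m, log)
spd_expm <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  e$vectors %*% (exp(e$values) * t(e$vectors))
}

#' Check symmetry and positive-definiteness
#'
#' @param m Matrix to check.
#' @param tol Symmetry tolerance (absolute, default 1e-10).
#' @return `TRUE` if `m` is symmetric within `tol` and all eigenvalues are
#'   strictly positive.
#' @export
is_spd <- function(m, tol = 1e-10) {
  if (max(abs(m - t(m))) > tol) return(FALSE)
  all(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values > 0)
}

#' Ledoit-Wolf shrinkage covariance of one extended epoch
#'
#' Estimates `C = (1 - lambda) S + lambda nu I`, where `S` is the biased
#' (divide-by-n) sample covariance over time samples after removing each
#' row's mean, `nu = trace(S) / d` is the average variance, and `lambda` is
#' the analytic Ledoit-Wolf shrinkage intensity. Shrinkage towards the scaled
#' identity guarantees a positive-definite estimate even when the number of
#' time samples is small relative to the channel count.
#'
#' @param x Channels x time matrix (e.g. a 14 x 50 extended epoch).
#' @return SPD covariance matrix with attribute `shrinkage` (the lambda
#'   used).
#' @export
ledoit_wolf_cov <- function(x) {
  d <- nrow(x)
  n <- ncol(x)
  xc <- x - rowMeans(x)
  s <- tcrossprod(xc) / n
  mu <- sum(diag(s)) / d
  delta2 <- sum((s - mu * diag(d))^2) / d
  # mean squared distance of per-sample outer products from S:
  # sum_t ||x_t x_t' - S||_F^2 = sum_t ||x_t||^4 - n ||S||_F^2
  beta_bar2 <- (sum(colSums(xc^2)^2) - n * sum(s^2)) / (n^2 * d)
  beta2 <- min(beta_bar2, delta2)
  lambda <- if (delta2 > 0) beta2 / delta2 else 1
  out <- (1 - lambda) * s + lambda * mu * diag(d)
  out <- (out + t(out)) / 2
  attr(out, "shrinkage") <- lambda
  out
}

#' Frechet (geometric) mean of SPD matrices
#'
#' The Riemannian centre of mass under the affine-invariant metric, computed
#' by the standard fixed-point iteration
#' `G <- G^{1/2} exp(mean_i log(G^{-1/2} C_i G^{-1/2})) G^{1/2}`,
#' initialized at the arithmetic mean, until the Frobenius norm of the mean
#' log falls below `tol`.
#'
#' @param covs List of SPD matrices of equal dimension.
#' @param tol Convergence tolerance on the Frobenius norm (default 1e-8).
#' @param max_iter Iteration cap (default 50).
#' @return The mean SPD matrix, with attributes `converged` (logical) and
#'   `iterations`. Non-convergence raises a warning, not an error.
#' @export
frechet_mean <- function(covs, tol = 1e-8, max_iter = 50) {
  if (length(covs) == 0) abort("need at least one matrix.")
  if (length(covs) == 1) {
    out <- covs[[1]]
    attr(out, "converged") <- TRUE
    attr(out, "iterations") <- 0L
    return(out)
  }
  g <- Reduce(`+`, covs) / length(covs)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    g_s <- spd_sqrtm(g)
    g_is <- spd_isqrtm(g)
    acc <- matrix(0, nrow(g), ncol(g))
    for (c_i in covs) acc <- acc + spd_logm(g_is %*% c_i %*% g_is)
    acc <- acc / length(covs)
    g <- g_s %*% spd_expm(acc) %*% g_s
    g <- (g + t(g)) / 2
    if (sqrt(sum(acc^2)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warn(sprintf("Frechet mean did not converge in %d iterations.", max_iter))
  attr(g, "converged") <- converged
  attr(g, "iterations") <- it
  g
}

#' Project an SPD matrix to the tangent space at a reference point
#'
#' Computes the matrix logarithm `log(ref^{-1/2} cov ref^{-1/2})`, the
#' tangent-space coordinates of `cov` at `ref` under the affine-invariant
#' metric. The Frobenius norm of the result equals the Riemannian distance
#' between `cov` and `ref`.
#'
#' @param cov SPD matrix.
#' @param ref SPD reference point (typically the Frechet mean of the training
#'   covariances).
#' @return Symmetric matrix of the same dimension.
#' @export
tangent_project <- function(cov, ref) {
  ris <- spd_isqrtm(ref)
  out <- spd_logm(ris %*% cov %*% ris)
  (out + t(out)) / 2
}

#' Mandel vectorization of a symmetric matrix
#'
#' Keeps the `d` diagonal entries as-is and multiplies the `d(d-1)/2`
#' off-diagonal entries (upper triangle, row-major order) by `sqrt(2)`, so
#' that the Euclidean norm of the vector equals the Frobenius norm of the
#' matrix. A 14 x 14 symmetric matrix becomes a 105-dimensional vector.
#'
#' @param m Symmetric matrix.
#' @return Numeric vector of length `d (d + 1) / 2`.
#' @export
mandel_vectorize <- function(m) {
  d <- nrow(m)
  diag_part <- diag(m)
  off <- t(m)[lower.tri(t(m))]  # upper triangle of m in row-major order
  c(diag_part, sqrt(2) * off)
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' @param a,b SPD matrices.
#' @return `||log(a^{-1/2} b a^{-1/2})||_F`.
#' @export
riemann_distance <- function(a, b) {
  ais <- spd_isqrtm(a)
  m <- ais %*% b %*% ais
  lam <- pmax(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  sqrt(sum(log(lam)^2))
}
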