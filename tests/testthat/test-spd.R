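# Independently coded textbook Ledoit-Wolf estimator (explicit loops)
lw_oracle <- function(x) {
  d <- nrow(x); n <- ncol(x)
  xc <- x - rowMeans(x)
  s <- matrix(0, d, d)
  for (t in seq_len(n)) s <- s + tcrossprod(xc[, t])
  s <- s / n
  mu <- mean(diag(s))
  delta2 <- sum((s - mu * diag(d))^2) / d
  beta_bar2 <- 0
  for (t in seq_len(n)) beta_bar2 <- beta_bar2 + sum((tcrossprod(xc[, t]) - s)^2)
  beta_bar2 <- beta_bar2 / (n^2 * d)
  b2 <- min(beta_bar2, delta2)
  lam <- if (delta2 > 0) b2 / delta2 else 1
  (1 - lam) * s + lam * mu * diag(d)
}

test_that("the shrinkage covariance matches the textbook formula to 1e-10", {
  for (seed in 1:6) {
    set.seed(seed)
    x <- matrix(rnorm(14 * 50), 14, 50)
    expect_equal(unname(ledoit_wolf_cov(x)), lw_oracle(x),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("rank-deficient inputs still give SPD covariances", {
  v <- rnorm(14)
  x <- outer(v, seq_len(50))  # all rows proportional
  cc <- ledoit_wolf_cov(x)
  expect_true(is_spd(cc))
  expect_gt(attr(cc, "shrinkage"), 0)
})

test_that("the shrinkage estimate converges to sigma^2 I on white noise", {
  set.seed(42)
  x <- matrix(rnorm(6 * 20000, sd = 2), 6, 20000)
  cc <- ledoit_wolf_cov(x)
  expect_equal(unname(diag(cc)), rep(4, 6), tolerance = 0.1)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.1)
})

test_that("the Frechet mean of one matrix is the matrix itself", {
  a <- random_spd(5, 1)
  m <- frechet_mean(list(a))
  expect_equal(unname(m), a, ignore_attr = TRUE)
  expect_true(attr(m, "converged"))
})

test_that("the Frechet mean of two matrices is the geodesic midpoint", {
  for (seed in 1:5) {
    a <- random_spd(6, seed)
    b <- random_spd(6, seed + 100)
    a_h <- oracle_powm(a, 0.5)
    a_ih <- oracle_powm(a, -0.5)
    midpoint <- a_h %*% oracle_powm(a_ih %*% b %*% a_ih, 0.5) %*% a_h
    m <- frechet_mean(list(a, b))
    expect_equal(unname(m), midpoint, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("a commuting family averages in the common eigenbasis", {
  set.seed(7)
  q <- qr.Q(qr(matrix(rnorm(25), 5)))
  eigs <- matrix(runif(5 * 4, 0.5, 3), 5, 4)
  covs <- lapply(seq_len(4), function(i) q %*% diag(eigs[, i]) %*% t(q))
  expected <- q %*% diag(exp(rowMeans(log(eigs)))) %*% t(q)
  m <- frechet_mean(covs)
  expect_equal(unname(m), expected, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the Frechet mean is congruence-invariant", {
  set.seed(3)
  covs <- lapply(1:4, function(i) random_spd(4, i + 20))
  w <- matrix(rnorm(16), 4)
  transformed <- lapply(covs, function(c_i) t(w) %*% c_i %*% w)
  lhs <- frechet_mean(transformed, tol = 1e-10)
  rhs <- t(w) %*% frechet_mean(covs, tol = 1e-10) %*% w
  expect_equal(unname(lhs), unname(rhs), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("tangent projection behaves at the base point and at the identity", {
  a <- random_spd(6, 9)
  expect_equal(unname(tangent_project(a, a)), matrix(0, 6, 6),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unname(tangent_project(a, diag(6))), unname(errpipe:::spd_logm(a)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the Mandel norm of a tangent vector equals the Riemannian distance", {
  for (seed in 1:5) {
    a <- random_spd(8, seed + 40)
    ref <- random_spd(8, seed + 80)
    v <- mandel_vectorize(tangent_project(a, ref))
    expect_equal(sqrt(sum(v^2)), riemann_distance(ref, a), tolerance = 1e-8)
  }
})

test_that("Mandel vectorization preserves the Frobenius norm to 1e-12", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rnorm(14 * 14), 14)
    m <- (m + t(m)) / 2
    v <- mandel_vectorize(m)
    expect_length(v, 105)
    expect_equal(sqrt(sum(v^2)), sqrt(sum(m^2)), tolerance = 1e-12)
  }
  vi <- mandel_vectorize(diag(14))
  expect_equal(vi, c(rep(1, 14), rep(0, 91)))
})
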