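#' Fit xDAWN spatial filters
#'
#' Epoch-based xDAWN: the filters are generalized eigenvectors maximizing the
#' ratio of evoked-response energy of the target (ErrP) class to total signal
#' energy. With `S_e = P P' / T` (where `P` is the ErrP-class mean epoch) and
#' `S_x` the average per-epoch covariance of all epochs, the filters solve
#' `S_e w = lambda S_x w`, ordered by decreasing eigenvalue (signal-to-noise
#' criterion). The class prototype is the filtered ErrP mean epoch.
#'
#' @param epochs Training `errp_epochs` containing both classes.
#' @param n_components Number of spatial filters to keep (default 7, reducing
#'   64 physical channels to 7 pseudo channels).
#' @param reg Relative jitter added to a rank-deficient total covariance
#'   (default 1e-9 of its mean diagonal; a warning is raised when used).
#' @return An `xdawn_bank`: list with `filters` (n_components x n_channels),
#'   `prototype` (n_components x n_time), `eigenvalues`, `montage`.
#' @export
fit_xdawn <- function(epochs, n_components = 7, reg = 1e-9) {
  labels <- epochs$info$label
  if (length(unique(labels)) < 2) abort("both classes must be present to fit xDAWN.")
  d <- dim(epochs$data)
  n_ch <- d[2]
  n_t <- d[3]
  if (n_components > n_ch) abort("`n_components` cannot exceed the channel count.")

  err_idx <- which(labels == "ErrP")
  p <- apply(epochs$data[err_idx, , , drop = FALSE], c(2, 3), mean)
  s_e <- tcrossprod(p) / n_t

  s_x <- matrix(0, n_ch, n_ch)
  for (i in seq_len(d[1])) {
    x <- epochs$data[i, , ]
    s_x <- s_x + tcrossprod(x) / n_t
  }
  s_x <- s_x / d[1]

  ev_x <- eigen((s_x + t(s_x)) / 2, symmetric = TRUE)
  if (min(ev_x$values) <= 0) {
    warn("rank-deficient total covariance; adding diagonal jitter.")
    jitter <- reg * mean(diag(s_x))
    s_x <- s_x + jitter * diag(n_ch)
    ev_x <- eigen((s_x + t(s_x)) / 2, symmetric = TRUE)
  }
  # whiten, then eigendecompose the whitened evoked covariance
  wh <- ev_x$vectors %*% (1 / sqrt(ev_x$values) * t(ev_x$vectors))
  ev_s <- eigen(wh %*% s_e %*% wh, symmetric = TRUE)
  filters <- t(wh %*% ev_s$vectors[, seq_len(n_components), drop = FALSE])

  structure(
    list(
      filters = filters,
      prototype = filters %*% p,
      eigenvalues = ev_s$values,
      montage = epochs$montage
    ),
    class = "xdawn_bank"
  )
}

#' Apply xDAWN filters to epochs
#'
#' Projects each epoch into the pseudo-channel space; with the default 7
#' components and 50-sample epochs each filtered epoch holds 350 values.
#'
#' @param bank An `xdawn_bank` from [fit_xdawn()].
#' @param epochs An `errp_epochs` object (or a single channels x time matrix).
#' @return Epochs with pseudo channels (`errp_epochs`), or a matrix when the
#'   input was a matrix.
#' @export
apply_xdawn <- function(bank, epochs) {
  if (is.matrix(epochs)) return(bank$filters %*% epochs)
  d <- dim(epochs$data)
  k <- nrow(bank$filters)
  out <- array(0, dim = c(d[1], k, d[3]))
  for (i in seq_len(d[1])) out[i, , ] <- bank$filters %*% epochs$data[i, , ]
  epochs$data <- out
  epochs$montage <- paste0("xdawn", seq_len(k))
  epochs$steps <- c(epochs$steps, "xdawn")
  epochs
}

#' Build an extended epoch (super-trial)
#'
#' Stacks the class prototype (filtered ErrP mean) on top of a filtered
#' epoch, yielding `2 * n_components` rows whose covariance captures the
#' co-variation between the epoch and the prototype.
#'
#' @param bank An `xdawn_bank`.
#' @param filtered Filtered epoch matrix (n_components x n_time).
#' @return `(2 n_components) x n_time` matrix: prototype rows, then epoch
#'   rows.
#' @export
extend_epoch <- function(bank, filtered) {
  stopifnot(nrow(filtered) == nrow(bank$prototype),
            ncol(filtered) == ncol(bank$prototype))
  rbind(bank$prototype, filtered)
}
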