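#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median rnorm runif rbinom rlnorm qnorm sd var predict
NULL

# Modular arithmetic below 2^31 - 1 using doubles; all intermediate products
# stay under 2^53 because multipliers are < 2^16.
.SEED_MOD <- 2147483647

.mod_step <- function(state, value) {
  (state * 48271 + value) %% .SEED_MOD
}

.hash_label <- function(label) {
  state <- 0
  for (code in utf8ToInt(label)) state <- .mod_step(state, code)
  state
}

#' Derive a reproducible sub-seed from a master seed
#'
#' One master seed fans out to named sub-streams (schedule, behaviour, noise,
#' fold shuffling, ...) so that any stage of a pipeline run can be re-executed
#' in isolation. The derivation is a small multiplicative-congruential hash of
#' the master seed, a stream label, and an index; the result is always a
#' strictly positive integer below 2^31.
#'
#' @param seed Integer master seed.
#' @param label Character stream label, e.g. `"schedule"`.
#' @param index Optional integer index within the stream (e.g. set number).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  state <- .mod_step(seed %% .SEED_MOD, .hash_label(label))
  state <- .mod_step(state, index %% .SEED_MOD)
  as.integer(state %% (.SEED_MOD - 2) + 1)
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# Half-open window [start, end) in seconds -> integer sample offsets relative
# to the event sample (offset 0 == event).
window_offsets <- function(window, fs) {
  start <- round(window[1] * fs)
  n <- round((window[2] - window[1]) * fs)
  seq.int(start, length.out = n)
}
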