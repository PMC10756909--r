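# Shared fixture builders. Corpora are generated in code and cached for the
# duration of the test run, keyed by their parameters.

.corpus_cache <- new.env(parent = emptyenv())

# full simulate -> synthesize -> segment -> exclude (-> preprocess) chain
build_corpus <- function(n_sets = 2, scenario = "ButtonPress", seed = 11,
                         snr = 1, montage = "reduced",
                         behavior_args = list(), noise = noise_model(),
                         preprocess = TRUE) {
  key <- rlang::hash(list(n_sets, scenario, seed, snr, montage, behavior_args,
                          noise, preprocess))
  if (!is.null(.corpus_cache[[key]])) return(.corpus_cache[[key]])
  cfg <- synth_config(montage = montage_channels(montage), noise = noise,
                      snr_scale = snr)
  sched <- generate_subject_sessions(n_sets, derive_seed(seed, "schedule"))
  model <- do.call(behavior_model, c(
    list(scenario = scenario, seed = derive_seed(seed, "behavior")),
    behavior_args
  ))
  outcomes <- simulate_behavior(sched, model)
  recs <- synthesize_session(outcomes, cfg, derive_seed(seed, "noise"))
  epochs_raw <- segment_epochs(recs)
  epochs <- exclude_behavioral_errors(epochs_raw, outcomes)
  if (preprocess) epochs <- preprocess_epochs(epochs)
  out <- list(outcomes = outcomes, recs = recs, epochs_raw = epochs_raw,
              epochs = epochs, config = cfg)
  assign(key, out, envir = .corpus_cache)
  out
}

# random SPD matrix with moderate condition number
random_spd <- function(d, seed) {
  set.seed(seed)
  a <- matrix(rnorm(d * d), d)
  crossprod(a) / d + diag(d)
}

# eigendecomposition helpers for the closed-form oracles, coded independently
# of the package's spd_* functions
oracle_powm <- function(m, p) {
  e <- eigen(m, symmetric = TRUE)
  e$vectors %*% diag(e$values^p) %*% t(e$vectors)
}
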