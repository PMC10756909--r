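#' Schedule parameters for one movement set
#'
#' One experimental set consists of alternating flexion/extension movements of
#' the arm orthosis. Errors (brief counter-movements of the orthosis, 0.25 s)
#' are planted in a fixed number of trials drawn uniformly without replacement
#' from the first `error_window` movements; the appended final trials are
#' always error-free. With the defaults (32 trials, 20% error probability over
#' a 30-trial window) each set contains 26 correct and 6 incorrect trials.
#'
#' @param n_trials Movements per set (default 32: 16 flexions, 16 extensions).
#' @param error_rate Error probability within the error window; the number of
#'   planted errors is `round(error_rate * error_window)` (default 0.2 -> 6).
#' @param error_window Trials eligible for errors, counted 1-based from the
#'   start of the set (default 30).
#' @param trial_duration_mean,trial_duration_sd Per-trial movement duration
#'   law, seconds (defaults 6.857 and 0.309; durations are truncated at 1 s).
#' @param iti_range Inter-trial interval range in seconds (default 0.5--1).
#' @param error_duration Duration of the orthosis counter-movement, seconds.
#' @param error_position_mean Named mean angular positions (degrees) at which
#'   the error occurs, per movement kind. The orthosis angle convention places
#'   the fully extended arm at -10 degrees; positions are truncated to
#'   (-90, -10).
#' @param error_position_sd Angular spread in degrees.
#' @param error_onset_frac Range of the within-trial fraction at which the
#'   error may start (default the middle 60% of the movement).
#' @return A list of validated schedule parameters.
#' @export
schedule_params <- function(n_trials = 32L,
                            error_rate = 0.2,
                            error_window = 30L,
                            trial_duration_mean = 6.857,
                            trial_duration_sd = 0.309,
                            iti_range = c(0.5, 1.0),
                            error_duration = 0.25,
                            error_position_mean = c(flexion = -42, extension = -58),
                            error_position_sd = 3,
                            error_onset_frac = c(0.2, 0.8)) {
  n_trials <- as.integer(n_trials)
  error_window <- as.integer(min(error_window, n_trials))
  n_errors <- as.integer(round(error_rate * error_window))
  if (n_trials < 2L || n_trials %% 2L != 0L) {
    abort("`n_trials` must be an even number >= 2 (alternating flexion/extension).")
  }
  if (error_rate < 0 || error_rate > 1) abort("`error_rate` must lie in [0, 1].")
  if (n_errors > error_window) {
    abort(sprintf("requested %d errors but only %d eligible trials", n_errors, error_window))
  }
  if (iti_range[1] < 0 || iti_range[2] < iti_range[1]) abort("invalid `iti_range`.")
  list(
    n_trials = n_trials, n_errors = n_errors, error_window = error_window,
    trial_duration_mean = trial_duration_mean,
    trial_duration_sd = trial_duration_sd,
    iti_range = iti_range, error_duration = error_duration,
    error_position_mean = error_position_mean,
    error_position_sd = error_position_sd,
    error_onset_frac = error_onset_frac
  )
}

.rnorm_trunc <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower | x >= upper)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x <= lower | x >= upper)
  }
  x
}

#' Generate the trial schedule of one movement set
#'
#' Movements alternate flexion/extension starting with a flexion. Exactly
#' `n_errors` trials (drawn uniformly without replacement from the error
#' window) receive a planted error; the error starts inside the middle part
#' of the movement and lasts `error_duration` seconds. The same seed always
#' yields the same schedule.
#'
#' @param seed Integer seed for this set.
#' @param params Parameters from [schedule_params()].
#' @param set_id Integer identifier stored in the `set` column.
#' @return A tibble with one row per trial: `set`, `trial`, `kind`,
#'   `is_error`, `movement_onset`, `trial_duration`, `iti`, `error_onset`,
#'   `error_duration`, `error_position` (onset columns in seconds from set
#'   start; error columns `NA` on correct trials).
#' @export
generate_set_schedule <- function(seed, params = schedule_params(), set_id = 1L) {
  with_seed(seed, {
    n <- params$n_trials
    kind <- rep(c("flexion", "extension"), length.out = n)
    dur <- pmax(1, rnorm(n, params$trial_duration_mean, params$trial_duration_sd))
    iti <- runif(n, params$iti_range[1], params$iti_range[2])
    onset <- cumsum(c(0, (dur + iti)[-n]))

    err_idx <- if (params$n_errors > 0) {
      sort(sample.int(params$error_window, params$n_errors))
    } else integer(0)
    is_error <- seq_len(n) %in% err_idx

    frac <- runif(n, params$error_onset_frac[1], params$error_onset_frac[2])
    error_onset <- ifelse(is_error, onset + frac * dur, NA_real_)
    pos_mean <- params$error_position_mean[kind]
    error_position <- rep(NA_real_, n)
    if (any(is_error)) {
      error_position[is_error] <- .rnorm_trunc(
        sum(is_error), pos_mean[is_error], params$error_position_sd, -90, -10
      )
    }

    tibble(
      set = as.integer(set_id), trial = seq_len(n), kind = kind,
      is_error = is_error, movement_onset = onset, trial_duration = dur,
      iti = iti, error_onset = error_onset,
      error_duration = ifelse(is_error, params$error_duration, NA_real_),
      error_position = error_position
    )
  })
}

#' Generate all movement sets of one simulated subject
#'
#' Derives an independent sub-seed per set from the master seed, so any set
#' can be regenerated in isolation with [generate_set_schedule()].
#'
#' @param n_sets Number of sets (datasets) to generate; the reference design
#'   records 10 sets per subject, i.e. 260 correct + 60 incorrect trials.
#' @param seed Master seed.
#' @param params Parameters from [schedule_params()].
#' @return A tibble of `32 * n_sets` trial rows (see [generate_set_schedule()]).
#' @export
generate_subject_sessions <- function(n_sets, seed, params = schedule_params()) {
  if (n_sets < 1) abort("`n_sets` must be >= 1.")
  purrr::map_dfr(seq_len(n_sets), function(s) {
    generate_set_schedule(derive_seed(seed, "schedule", s), params, set_id = s)
  })
}
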