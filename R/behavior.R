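#' Behavioural response model
#'
#' Describes how a simulated subject responds to planted orthosis errors in
#' one of three scenarios:
#' \describe{
#'   \item{ButtonPress}{the subject presses a button on detecting an error;
#'     reaction times follow a log-normal law with median `rt_median`.}
#'   \item{NoButtonPress}{no motor response is ever given; error and correct
#'     trials are still labelled by their markers.}
#'   \item{DelayedButtonPress}{the press is artificially delayed so that the
#'     mean reaction time equals `delayed_rt_mean` (about 4.5 s).}
#' }
#' Misses (undetected errors) occur with probability `miss_rate` per error
#' trial, false presses with probability `false_alarm_rate` per correct trial.
#'
#' @param scenario One of `"ButtonPress"`, `"NoButtonPress"`,
#'   `"DelayedButtonPress"`.
#' @param rt_median Median reaction time in seconds (default 0.746).
#' @param rt_spread Log-scale standard deviation of the log-normal reaction
#'   time law (dimensionless, default 0.25; reaction times are positive and
#'   right-skewed).
#' @param delayed_rt_mean Mean delayed reaction time in seconds (default 4.54).
#' @param miss_rate Probability of a miss per error trial (default 0.0188).
#' @param false_alarm_rate Probability of a spurious press per correct trial
#'   (default 0.0083).
#' @param seed Integer seed for the behaviour stream.
#' @return A list of validated model parameters.
#' @export
behavior_model <- function(scenario = c("ButtonPress", "NoButtonPress", "DelayedButtonPress"),
                           rt_median = 0.746,
                           rt_spread = 0.25,
                           delayed_rt_mean = 4.54,
                           miss_rate = 0.0188,
                           false_alarm_rate = 0.0083,
                           seed = 1L) {
  scenario <- match.arg(scenario)
  if (rt_median <= 0) abort("`rt_median` must be positive.")
  if (any(c(miss_rate, false_alarm_rate) < 0) || any(c(miss_rate, false_alarm_rate) > 1)) {
    abort("rates must lie in [0, 1].")
  }
  list(
    scenario = scenario, rt_median = rt_median, rt_spread = rt_spread,
    delayed_rt_mean = delayed_rt_mean, miss_rate = miss_rate,
    false_alarm_rate = false_alarm_rate, seed = as.integer(seed)
  )
}

#' Simulate per-trial behavioural outcomes
#'
#' Each trial of the schedule receives one outcome:
#' `TP_response` (error detected and button pressed), `FN_miss` (error not
#' responded to), `FP_press` (press on a correct trial), or `TN_silent`
#' (correct trial, no press). Reaction times are measured from the error
#' onset; false-press times are drawn uniformly within the movement. In the
#' NoButtonPress scenario `responded` is `FALSE` everywhere and no reaction
#' times exist; error trials keep the `TP_response` class because the label
#' assignment does not depend on a motor response there.
#'
#' @param schedule Trial tibble from [generate_subject_sessions()].
#' @param model Model from [behavior_model()]; per-set sub-seeds are derived
#'   from `model$seed`.
#' @return The schedule tibble with columns `responded`, `response_time`
#'   (seconds after error onset, `NA` when absent), `press_time` (seconds from
#'   set start, `NA` when no press) and `outcome_class` appended.
#' @export
simulate_behavior <- function(schedule, model = behavior_model()) {
  stopifnot(all(c("set", "trial", "is_error") %in% names(schedule)))
  meanlog <- switch(model$scenario,
    DelayedButtonPress = log(model$delayed_rt_mean) - model$rt_spread^2 / 2,
    log(model$rt_median)
  )
  out <- lapply(split(schedule, schedule$set), function(sch) {
    with_seed(derive_seed(model$seed, "behavior", sch$set[1]), {
      n <- nrow(sch)
      detected <- sch$is_error & (runif(n) >= model$miss_rate)
      false_press <- !sch$is_error & (runif(n) < model$false_alarm_rate)
      if (model$scenario == "NoButtonPress") {
        # no response is required, so misses and false presses cannot occur;
        # labels come from the markers alone
        detected <- sch$is_error
        false_press <- rep(FALSE, n)
      }
      rt <- rlnorm(n, meanlog, model$rt_spread)
      fp_frac <- runif(n)

      sch$responded <- (detected | false_press) & model$scenario != "NoButtonPress"
      sch$response_time <- ifelse(sch$is_error & detected, rt, NA_real_)
      sch$press_time <- dplyr::case_when(
        !sch$responded ~ NA_real_,
        sch$is_error ~ sch$error_onset + sch$response_time,
        TRUE ~ sch$movement_onset + fp_frac * sch$trial_duration
      )
      if (model$scenario == "NoButtonPress") sch$response_time <- NA_real_
      sch$outcome_class <- dplyr::case_when(
        sch$is_error & detected ~ "TP_response",
        sch$is_error ~ "FN_miss",
        false_press ~ "FP_press",
        TRUE ~ "TN_silent"
      )
      sch
    })
  })
  out <- dplyr::bind_rows(out)
  attr(out, "scenario") <- model$scenario
  out
}

#' Summarize behavioural outcomes
#'
#' Median reaction time is computed over responded error trials only; the
#' false-negative percentage uses error trials as denominator and the
#' false-positive percentage uses correct trials. When no responded error
#' trial exists the median is reported as `NA`, never as zero.
#'
#' @param outcomes Tibble from [simulate_behavior()].
#' @param by `"subject"` for one summary row, `"set"` for one row per set.
#' @return A tibble with columns `n_error`, `n_correct`, `n_fn`, `n_fp`,
#'   `rt_median` (seconds), `fn_pct`, `fp_pct`.
#' @export
summarize_behavior <- function(outcomes, by = c("subject", "set")) {
  by <- match.arg(by)
  if (nrow(outcomes) == 0) abort("no outcomes to summarize.")
  g <- if (by == "set") dplyr::group_by(outcomes, .data$set) else outcomes
  dplyr::summarize(
    g,
    n_error = sum(.data$is_error),
    n_correct = sum(!.data$is_error),
    n_fn = sum(.data$outcome_class == "FN_miss"),
    n_fp = sum(.data$outcome_class == "FP_press"),
    rt_median = if (any(.data$is_error & !is.na(.data$response_time))) {
      median(.data$response_time[.data$is_error], na.rm = TRUE)
    } else NA_real_,
    fn_pct = 100 * .data$n_fn / .data$n_error,
    fp_pct = 100 * .data$n_fp / .data$n_correct,
    .groups = "drop"
  )
}
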