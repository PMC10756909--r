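#' End-to-end experiment configuration
#'
#' One configuration drives a complete run: schedule simulation, behaviour,
#' EEG synthesis, a write/read round trip through the on-disk triad format,
#' preprocessing, feature extraction and evaluation. A master seed fans out
#' to named sub-seeds (schedule, behaviour, noise, fold shuffling) via
#' [derive_seed()], so every stage is independently reproducible.
#'
#' @param scenarios Named integer vector: number of sets to synthesize per
#'   scenario, e.g. `c(ButtonPress = 10)` or
#'   `c(ButtonPress = 10, DelayedButtonPress = 3)`.
#' @param design `"within_cv"` (nested CV on `cv_scenario`) or `"transfer"`
#'   (train on `train_scenario`, test on `test_scenario`).
#' @param cv_scenario,train_scenario,test_scenario Scenario names used by the
#'   two designs.
#' @param schedule [schedule_params()].
#' @param synth [synth_config()].
#' @param behavior Base arguments for [behavior_model()] (scenario and seed
#'   are filled in per scenario).
#' @param plan [cv_plan()] (its seed is overridden by the master seed).
#' @param seed Master seed.
#' @param out_dir Directory for the file round trip (default a temporary
#'   directory).
#' @return A validated configuration list.
#' @export
experiment_config <- function(scenarios = c(ButtonPress = 10),
                              design = c("within_cv", "transfer"),
                              cv_scenario = names(scenarios)[1],
                              train_scenario = "ButtonPress",
                              test_scenario = NULL,
                              schedule = schedule_params(),
                              synth = synth_config(),
                              behavior = list(),
                              plan = cv_plan(),
                              seed = 1L,
                              out_dir = NULL) {
  design <- match.arg(design)
  known <- c("ButtonPress", "NoButtonPress", "DelayedButtonPress")
  if (is.null(names(scenarios)) || !all(names(scenarios) %in% known)) {
    abort("`scenarios` must be a named vector over the three known scenarios.")
  }
  if (design == "within_cv" && !cv_scenario %in% names(scenarios)) {
    abort("`cv_scenario` is not among the synthesized scenarios.")
  }
  if (design == "transfer") {
    if (is.null(test_scenario)) abort("`test_scenario` is required for the transfer design.")
    if (!all(c(train_scenario, test_scenario) %in% names(scenarios))) {
      abort("transfer scenarios must be among the synthesized scenarios.")
    }
  }
  list(
    scenarios = scenarios, design = design, cv_scenario = cv_scenario,
    train_scenario = train_scenario, test_scenario = test_scenario,
    schedule = schedule, synth = synth, behavior = behavior,
    plan = plan, seed = as.integer(seed), out_dir = out_dir
  )
}

# simulate + synthesize + disk round trip + preprocess for one scenario
.build_scenario <- function(cfg, scenario, n_sets, dir) {
  sched <- generate_subject_sessions(
    n_sets, derive_seed(cfg$seed, paste0("schedule_", scenario)), cfg$schedule
  )
  model <- do.call(behavior_model, c(
    list(scenario = scenario,
         seed = derive_seed(cfg$seed, paste0("behavior_", scenario))),
    cfg$behavior
  ))
  outcomes <- simulate_behavior(sched, model)
  recs <- synthesize_session(outcomes, cfg$synth,
                             derive_seed(cfg$seed, paste0("noise_", scenario)))
  recs <- purrr::imap(recs, function(r, nm) {
    stem <- file.path(dir, sprintf("%s_set%s", scenario, nm))
    write_recording(r, stem)
    read_recording(stem)
  })
  epochs <- segment_epochs(unname(recs))
  epochs <- exclude_behavioral_errors(epochs, outcomes)
  list(
    outcomes = outcomes,
    epochs = preprocess_epochs(epochs),
    counts = list(
      trials = nrow(outcomes),
      epochs_kept = dim(epochs$data)[1],
      skipped_windows = sum(epochs$exclusions$reason == "window outside recording"),
      excluded_behavioral = sum(epochs$exclusions$reason %in% c("FN_miss", "FP_press"))
    )
  )
}

#' Run a complete simulated experiment
#'
#' Executes simulate -> synthesize -> write/read round trip (exercising the
#' triad file format) -> segment -> behavioural exclusion -> preprocess ->
#' feature extraction + evaluation, per the configured design, and returns
#' the evaluation report with a run manifest (seeds, per-stage counts,
#' configuration hash).
#'
#' @param config From [experiment_config()].
#' @return An `errp_experiment`: list with `report` (an `errp_cv` for the
#'   within-CV design, a metrics tibble for the transfer design), `behavior`
#'   (summary tibble per scenario), `manifest`.
#' @export
run_experiment <- function(config) {
  dir <- config$out_dir %||% tempfile("errpipe_run_")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  built <- purrr::imap(
    as.list(config$scenarios),
    function(n_sets, scenario) .build_scenario(config, scenario, n_sets, dir)
  )
  plan <- config$plan
  plan$seed <- derive_seed(config$seed, "cv")

  if (config$design == "within_cv") {
    report <- nested_cv(built[[config$cv_scenario]]$epochs, plan)
  } else {
    fitted <- fit_transfer_model(built[[config$train_scenario]]$epochs, plan)
    report <- transfer_evaluate(fitted$extractor, fitted$model,
                                built[[config$test_scenario]]$epochs)
    attr(report, "cost") <- fitted$cost
  }
  manifest <- list(
    seed = config$seed, design = config$design,
    scenarios = config$scenarios,
    stage_counts = purrr::map(built, "counts"),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    out_dir = dir
  )
  structure(
    list(
      report = report,
      behavior = purrr::map(built, function(b) summarize_behavior(b$outcomes)),
      epochs = purrr::map(built, "epochs"),
      manifest = manifest
    ),
    class = "errp_experiment"
  )
}

#' @export
print.errp_experiment <- function(x, ...) {
  cat(sprintf("<errp_experiment> design %s, seed %d, scenarios: %s\n",
              x$manifest$design, x$manifest$seed,
              paste(sprintf("%s x%d", names(x$manifest$scenarios),
                            x$manifest$scenarios), collapse = ", ")))
  print(x$report)
  invisible(x)
}

#' Materialize a synthetic corpus on disk
#'
#' `"tiny"` builds 2 ButtonPress sets on the reduced 8-channel montage (64
#' epochs, suitable for fast tests); `"full_scale"` builds 10 ButtonPress
#' sets on the full 64-channel montage (320 epochs). Each set is written as a
#' header/marker/binary triad next to a behaviour trial table.
#'
#' @param size `"tiny"` or `"full_scale"`.
#' @param seed Master seed.
#' @param dir Output directory.
#' @return Tibble manifest: one row per file with its MD5 checksum.
#' @export
make_fixtures <- function(size = c("tiny", "full_scale"), seed = 1L,
                          dir = tempfile("errpipe_fixtures_")) {
  size <- match.arg(size)
  n_sets <- if (size == "tiny") 2L else 10L
  montage <- montage_channels(if (size == "tiny") "reduced" else "full")
  cfg <- synth_config(montage = montage)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  sched <- generate_subject_sessions(n_sets, derive_seed(seed, "schedule_ButtonPress"))
  outcomes <- simulate_behavior(
    sched, behavior_model("ButtonPress", seed = derive_seed(seed, "behavior_ButtonPress"))
  )
  write_trial_table(outcomes, file.path(dir, "trials.tsv"))
  recs <- synthesize_session(outcomes, cfg, derive_seed(seed, "noise_ButtonPress"))
  purrr::iwalk(recs, function(r, nm) {
    write_recording(r, file.path(dir, sprintf("ButtonPress_set%s", nm)))
  })
  files <- sort(list.files(dir, full.names = TRUE))
  tibble(file = basename(files), md5 = unname(tools::md5sum(files)))
}
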