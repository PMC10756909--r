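silent_noise <- function() noise_model(white_sd = 0, pink_amp = 0, osc_amp = 0)

test_that("noiseless synthesis reconstructs the template exactly at FCz", {
  sched <- generate_set_schedule(3)
  out <- simulate_behavior(sched, behavior_model(miss_rate = 0, false_alarm_rate = 0,
                                                 seed = 2))
  attr(out, "scenario") <- "NoButtonPress"  # keep the motor bump out of the signal
  out$responded <- FALSE
  out$press_time <- NA_real_
  cfg <- synth_config(noise = silent_noise())
  rec <- synthesize_recording(out, cfg, seed = 1)
  wave <- render_template(default_errp_template(), 500, 1)
  fcz <- which(rec$montage == "FCz")
  s96 <- rec$markers$sample[rec$markers$code == "S96"]
  for (at in s96) {
    expect_equal(rec$samples[fcz, at + 0:499], wave, tolerance = 1e-12)
  }
})

test_that("one default set yields 6 S96 and 26 S48 markers and matching responses", {
  sched <- generate_set_schedule(4)
  out <- simulate_behavior(sched, behavior_model(seed = 8))
  rec <- synthesize_recording(out, synth_config(), seed = 2)
  expect_equal(sum(rec$markers$code == "S96"), 6)
  expect_equal(sum(rec$markers$code == "S48"), 26)
  expect_equal(sum(rec$markers$code == "response"), sum(out$responded))
  expect_equal(sum(grepl("movement_", rec$markers$code)), 32)
  expect_true(all(rec$markers$sample >= 1 & rec$markers$sample <= ncol(rec$samples)))
})

test_that("NoButtonPress synthesis contains no response markers", {
  sched <- generate_set_schedule(4)
  out <- simulate_behavior(sched, behavior_model("NoButtonPress", seed = 8))
  rec <- synthesize_recording(out, synth_config(), seed = 2)
  expect_equal(sum(rec$markers$code == "response"), 0)
})

test_that("the SNR sweep shares noise realizations and is linear in the scale", {
  sched <- generate_set_schedule(5)
  out <- simulate_behavior(sched, behavior_model(seed = 3))
  sweep <- snr_sweep_corpus(out, synth_config(), levels = c(0, 1, 2), seed = 6)
  r0 <- sweep[["0"]][[1]]$samples
  r1 <- sweep[["1"]][[1]]$samples
  r2 <- sweep[["2"]][[1]]$samples
  # identical markers, identical noise, template contribution scales linearly
  expect_identical(sweep[["0"]][[1]]$markers, sweep[["2"]][[1]]$markers)
  expect_equal(r2, r0 + 2 * (r1 - r0), tolerance = 1e-9)
  expect_gt(max(abs(r1 - r0)), 1)  # the template is actually present
})

test_that("epoch averaging converges to the planted template (1/sqrt(n) decay)", {
  corp <- build_corpus(n_sets = 10, seed = 101)
  raw <- corp$epochs_raw
  fcz <- which(raw$montage == "FCz")
  idx <- which(raw$info$label == "ErrP")
  wave <- render_template(default_errp_template(), 500, 1)
  post <- errpipe:::window_offsets(raw$window, raw$fs) >= 0

  avg_err <- function(k) {
    avg <- apply(raw$data[idx[seq_len(k)], fcz, , drop = FALSE], 3, mean)
    sqrt(mean((avg[post] - wave)^2))
  }
  err_small <- avg_err(6)
  err_large <- avg_err(60)
  expect_lt(err_large, err_small)
  # noise sd at FCz is sqrt(3^2 + 6^2) ~ 6.7 uV -> standard error ~ 0.87 at n=60
  expect_lt(err_large, 2)
})

test_that("marker bookkeeping is conserved across a session", {
  corp <- build_corpus(n_sets = 2, seed = 11)
  for (rec in corp$recs) {
    n_events <- sum(rec$markers$code %in% c("S48", "S96"))
    expect_equal(n_events, 32)
  }
  total_resp <- sum(vapply(corp$recs, function(r) sum(r$markers$code == "response"),
                           numeric(1)))
  expect_equal(total_resp, sum(corp$outcomes$responded))
})
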