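# epochs holding pure sinusoids, for filter-response oracles
sine_epochs <- function(freq, fs = 500, n_ep = 1, n_ch = 2, dur = 1.1) {
  n <- round(fs * dur)
  t <- (seq_len(n) - 1) / fs - 0.1
  dat <- array(rep(sin(2 * pi * freq * t), each = n_ep * n_ch),
               dim = c(n_ep, n_ch, n))
  new_epochs(dat, fs, c(-0.1, 1.0),
             tibble::tibble(set = 1L, trial = seq_len(n_ep), label = "NoErrP",
                            scenario = "ButtonPress", marker_sample = 1L)[rep(1, n_ep), ],
             paste0("ch", seq_len(n_ch)))
}

mid_amplitude <- function(epochs, margin = 0.15) {
  n <- dim(epochs$data)[3]
  sel <- seq.int(ceiling(n * margin), floor(n * (1 - margin)))
  max(abs(epochs$data[1, 1, sel]))
}

test_that("segmentation yields 550-sample epochs with the 6/26 label split", {
  corp <- build_corpus(n_sets = 1, seed = 31)
  raw <- corp$epochs_raw
  expect_equal(dim(raw$data)[3], 550)
  expect_equal(dim(raw$data)[1], 32)
  expect_equal(sum(raw$info$label == "ErrP"), 6)
  expect_equal(sum(raw$info$label == "NoErrP"), 26)
  # the marker maps to relative time 0
  expect_equal(errpipe:::window_offsets(raw$window, raw$fs)[51], 0)
})

test_that("epochs whose window leaves the recording are skipped and logged", {
  rec <- build_corpus(n_sets = 1, seed = 31)$recs[[1]]
  rec$markers <- dplyr::bind_rows(
    tibble::tibble(sample = 10L, code = "S48"),
    rec$markers
  )
  ep <- segment_epochs(rec)
  expect_equal(dim(ep$data)[1], 32)  # the boundary epoch is gone
  expect_true(any(ep$exclusions$reason == "window outside recording"))
})

test_that("behavioural exclusion removes exactly the invalid-response trials", {
  corp <- build_corpus(n_sets = 1, seed = 31)
  out <- corp$outcomes
  # force one miss among the six errors
  first_err <- which(out$is_error)[1]
  out$outcome_class[first_err] <- "FN_miss"
  ep <- exclude_behavioral_errors(corp$epochs_raw, out)
  expect_equal(sum(ep$info$label == "ErrP"), 5)
  expect_true(any(ep$exclusions$reason == "FN_miss"))

  # with clean outcomes the operation is the identity
  clean <- corp$outcomes
  clean$outcome_class[clean$is_error] <- "TP_response"
  clean$outcome_class[!clean$is_error] <- "TN_silent"
  ep2 <- exclude_behavioral_errors(corp$epochs_raw, clean)
  expect_equal(dim(ep2$data)[1], dim(corp$epochs_raw$data)[1])

  # unmatched provenance is a hard error
  expect_error(exclude_behavioral_errors(corp$epochs_raw, out[-1, ]), "provenance")
})

test_that("exclusion count matches the outcome table over many sets", {
  corp <- build_corpus(n_sets = 10, seed = 101)
  n_fn <- sum(corp$outcomes$outcome_class == "FN_miss")
  n_fp <- sum(corp$outcomes$outcome_class == "FP_press")
  expect_equal(sum(corp$epochs$info$label == "ErrP"), 60 - n_fn)
  expect_equal(sum(corp$epochs$info$label == "NoErrP"), 260 - n_fp)
})

test_that("NoButtonPress exclusion is an identity pass", {
  corp <- build_corpus(n_sets = 1, scenario = "NoButtonPress", seed = 31)
  ep <- exclude_behavioral_errors(corp$epochs_raw, corp$outcomes)
  expect_equal(dim(ep$data)[1], dim(corp$epochs_raw$data)[1])
})

test_that("zero-meaning removes constant offsets and leaves centred data alone", {
  ep <- sine_epochs(5)
  ep$data <- ep$data + 3
  zm <- zero_mean(ep)
  expect_lt(max(abs(apply(zm$data, c(1, 2), mean))), 1e-9)
  again <- zero_mean(zm)
  expect_equal(again$data, zm$data, tolerance = 1e-12)
  const <- ep
  const$data[] <- 7
  expect_lt(max(abs(zero_mean(const)$data)), 1e-12)
})

test_that("decimation keeps 50 feature samples and rejects non-integer factors", {
  corp <- build_corpus(n_sets = 1, seed = 31)
  dec <- decimate_epochs(zero_mean(corp$epochs_raw), 50)
  cropped <- crop_epochs(dec, c(0, 1))
  expect_equal(dim(cropped$data)[3], 50)
  expect_error(decimate_epochs(corp$epochs_raw, 33), "integer multiple")
})

test_that("decimation preserves a 2 Hz tone and rejects a 100 Hz alias", {
  slow <- decimate_epochs(sine_epochs(2), 50)
  expect_gt(mid_amplitude(slow), 0.99)
  fast <- decimate_epochs(sine_epochs(100), 50)
  expect_lt(mid_amplitude(fast), 0.01)
})

test_that("the band-pass passes 5 Hz, rejects 25 Hz, and maps zero to zero", {
  pass <- bandpass_epochs(sine_epochs(5), 0.1, 12)
  expect_gt(mid_amplitude(pass), 0.90)
  stop <- bandpass_epochs(sine_epochs(25), 0.1, 12)
  expect_lt(mid_amplitude(stop), 0.10)
  zero <- sine_epochs(5)
  zero$data[] <- 0
  expect_equal(max(abs(bandpass_epochs(zero)$data)), 0)
})

test_that("the zero-phase chain shifts a planted peak by less than one sample", {
  fs <- 500
  n <- round(fs * 1.1)
  t <- (seq_len(n) - 1) / fs - 0.1
  bump <- 5 * exp(-(t - 0.4)^2 / (2 * 0.05^2))
  dat <- array(rep(bump, each = 2), dim = c(1, 2, n))
  ep <- new_epochs(dat, fs, c(-0.1, 1.0),
                   tibble::tibble(set = 1L, trial = 1L, label = "ErrP",
                                  scenario = "ButtonPress", marker_sample = 1L),
                   c("a", "b"))
  out <- bandpass_epochs(decimate_epochs(zero_mean(ep), 50), 0.1, 12)
  tt <- errpipe:::window_offsets(out$window, out$fs) / out$fs
  peak <- tt[which.max(out$data[1, 1, ])]
  expect_lt(abs(peak - 0.4), 1 / out$fs)
})

test_that("preprocessing conserves labels and epoch order after exclusion", {
  corp <- build_corpus(n_sets = 1, seed = 31)
  pre <- preprocess_epochs(corp$epochs_raw)
  expect_identical(pre$info$label, corp$epochs_raw$info$label)
  expect_identical(pre$info$trial, corp$epochs_raw$info$trial)
})
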