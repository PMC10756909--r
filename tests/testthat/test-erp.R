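test_that("ERP preprocessing re-references, downsamples and high-passes", {
  rec <- build_corpus(n_sets = 1, seed = 31)$recs[[1]]
  out <- preprocess_for_erp(rec)
  expect_equal(out$fs, 250)
  expect_equal(ncol(out$samples), ceiling(ncol(rec$samples) / 2))
  # average reference: instantaneous mean across channels is zero
  expect_lt(max(abs(colMeans(out$samples))), 1e-6)
  # marker timing survives within one decimated sample
  expect_equal(
    out$markers$sample / out$fs,
    rec$markers$sample / rec$fs,
    tolerance = 2 / out$fs
  )

  const <- rec
  const$samples[] <- 5
  flat <- preprocess_for_erp(const)
  expect_lt(max(abs(flat$samples)), 1e-6)
})

test_that("baseline correction zeroes the pre-stimulus mean exactly", {
  corp <- build_corpus(n_sets = 2, seed = 11)
  avg <- condition_average(corp$epochs_raw, "S96")
  bl <- avg$time >= -0.1 & avg$time < 0
  expect_lt(max(abs(rowMeans(avg$waveform[, bl]))), 1e-9)
  expect_equal(avg$n_epochs, sum(corp$epochs_raw$info$label == "ErrP"))
})

test_that("averaging identical epochs returns the baseline-corrected epoch", {
  n <- 220
  t <- (seq_len(n) - 1) / 200 - 0.1
  trace <- sin(2 * pi * 3 * t) + 2
  dat <- array(rep(trace, each = 5 * 2), dim = c(5, 2, n))
  ep <- new_epochs(dat, 200, c(-0.1, 1.0),
                   tibble::tibble(set = 1L, trial = 1:5, label = "ErrP",
                                  scenario = "ButtonPress", marker_sample = 1:5),
                   c("FCz", "Cz"))
  avg <- condition_average(ep, "S96")
  bl <- t >= -0.1 & t < 0
  expected <- trace - mean(trace[bl])
  expect_equal(avg$waveform[1, ], expected, tolerance = 1e-12)
})

test_that("grand averaging is the unweighted subject mean", {
  corp <- build_corpus(n_sets = 2, seed = 11)
  a <- condition_average(corp$epochs_raw, "S96")
  expect_equal(grand_average(list(a, a))$waveform, a$waveform)

  b <- a
  b$waveform <- -a$waveform
  expect_equal(max(abs(grand_average(list(a, b))$waveform)), 0)
})

test_that("grand average equals the pooled average for equal subject sizes", {
  corp <- build_corpus(n_sets = 2, seed = 11)
  raw <- corp$epochs_raw
  idx <- which(raw$info$label == "ErrP")
  half1 <- subset_epochs(raw, seq_len(dim(raw$data)[1]) %in% idx[1:6])
  half2 <- subset_epochs(raw, seq_len(dim(raw$data)[1]) %in% idx[7:12])
  pooled <- condition_average(subset_epochs(raw, seq_len(dim(raw$data)[1]) %in% idx), "S96")
  ga <- grand_average(list(condition_average(half1, "S96"),
                           condition_average(half2, "S96")))
  expect_equal(ga$waveform, pooled$waveform, tolerance = 1e-9)
})

test_that("a high-SNR average at FCz shows the tri-phasic ErrP ordering", {
  corp <- build_corpus(n_sets = 2, seed = 55, snr = 3)
  avg <- condition_average(corp$epochs_raw, "S96")
  ex <- erp_extrema(avg, "FCz")
  expect_lt(ex$amplitude[ex$which == "neg1"], 0)
  expect_gt(ex$amplitude[ex$which == "pos"], 0)
  expect_lt(ex$amplitude[ex$which == "neg2"], 0)
  expect_true(ex$time[1] < ex$time[2] && ex$time[2] < ex$time[3])
})

test_that("tidy and autoplot work on averaged ERPs", {
  corp <- build_corpus(n_sets = 1, seed = 31)
  avg <- condition_average(corp$epochs_raw, "S48")
  td <- tidy(avg)
  expect_equal(nrow(td), length(avg$time) * length(avg$montage))
  fcz <- td$amplitude[td$channel == "FCz"]
  expect_equal(fcz, avg$waveform[match("FCz", avg$montage), ])
  p <- ggplot2::autoplot(avg, channels = c("FCz", "Cz"))
  expect_s3_class(p, "ggplot")
})
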