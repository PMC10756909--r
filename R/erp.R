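#' Preprocess a continuous recording for ERP averaging
#'
#' Sequentially: zero-phase anti-alias low-pass and downsampling to
#' `target_fs` (marker positions are remapped to the nearest retained
#' sample), re-referencing to the instantaneous average across channels, and
#' zero-phase 0.1--15 Hz band-pass. Synthesized recordings already carry the
#' original FCz reference site as a data channel, so no channel
#' reconstruction is needed before re-referencing. Re-referencing changes
#' signals but never marker timing.
#'
#' @param rec An `errp_recording`.
#' @param target_fs Downsampling target, Hz (default 250).
#' @param band Band-pass edges, Hz (default `c(0.1, 15)`).
#' @return The processed `errp_recording`.
#' @export
preprocess_for_erp <- function(rec, target_fs = 250, band = c(0.1, 15)) {
  factor <- rec$fs / target_fs
  if (factor != round(factor)) abort("fs must be an integer multiple of target_fs.")
  factor <- as.integer(factor)
  samples <- rec$samples
  if (factor > 1L) {
    lp <- signal::butter(4, (0.4 * target_fs) / (rec$fs / 2), type = "low")
    for (ch in seq_len(nrow(samples))) {
      samples[ch, ] <- signal::filtfilt(lp, samples[ch, ])
    }
    keep <- seq.int(1L, ncol(samples), by = factor)
    samples <- samples[, keep, drop = FALSE]
    rec$markers$sample <- as.integer(round((rec$markers$sample - 1) / factor) + 1)
    rec$fs <- target_fs
  }
  samples <- sweep(samples, 2, colMeans(samples))  # average reference
  hp <- signal::butter(2, band[1] / (rec$fs / 2), type = "high")
  lpb <- signal::butter(4, band[2] / (rec$fs / 2), type = "low")
  for (ch in seq_len(nrow(samples))) {
    samples[ch, ] <- signal::filtfilt(lpb, signal::filtfilt(hp, samples[ch, ]))
  }
  rec$samples <- samples
  rec
}

#' Condition average (event-related potential)
#'
#' Subtracts each epoch's per-channel baseline mean (default the 100 ms
#' before the event) and averages across all epochs of one condition.
#'
#' @param epochs `errp_epochs` whose window covers the baseline.
#' @param condition `"S96"` (error trials, label ErrP) or `"S48"` (correct
#'   trials, label NoErrP).
#' @param baseline Baseline window `c(start, end)` seconds (default
#'   `c(-0.1, 0)`).
#' @return An `errp_erp`: list with `waveform` (channels x time, microvolts),
#'   `time`, `montage`, `condition`, `n_epochs`, `fs`, `baseline`.
#' @export
condition_average <- function(epochs, condition = c("S96", "S48"),
                              baseline = c(-0.1, 0)) {
  condition <- match.arg(condition)
  label <- if (condition == "S96") "ErrP" else "NoErrP"
  idx <- which(epochs$info$label == label)
  if (length(idx) == 0) abort(sprintf("no epochs with condition %s.", condition))
  offs <- window_offsets(epochs$window, epochs$fs)
  bl <- which(offs >= round(baseline[1] * epochs$fs) & offs < round(baseline[2] * epochs$fs))
  if (length(bl) == 0) abort("baseline window has no samples inside the epoch window.")
  dat <- epochs$data[idx, , , drop = FALSE]
  blmean <- apply(dat[, , bl, drop = FALSE], c(1, 2), mean)
  dat <- dat - as.vector(blmean)
  structure(
    list(
      waveform = apply(dat, c(2, 3), mean),
      time = offs / epochs$fs,
      montage = epochs$montage, condition = condition,
      n_epochs = length(idx), fs = epochs$fs, baseline = baseline
    ),
    class = "errp_erp"
  )
}

#' Grand average across subjects
#'
#' Unweighted arithmetic mean of per-subject condition averages on the same
#' montage, window and condition.
#'
#' @param erps List of `errp_erp` objects.
#' @return An `errp_erp` whose `n_epochs` is the number of subjects averaged.
#' @export
grand_average <- function(erps) {
  if (length(erps) == 0) abort("need at least one average.")
  ref <- erps[[1]]
  for (e in erps[-1]) {
    if (!identical(e$montage, ref$montage) || !identical(dim(e$waveform), dim(ref$waveform)) ||
        !identical(e$condition, ref$condition)) {
      abort("averages must share montage, window and condition.")
    }
  }
  out <- ref
  out$waveform <- Reduce(`+`, lapply(erps, `[[`, "waveform")) / length(erps)
  out$n_epochs <- length(erps)
  out
}

#' @export
print.errp_erp <- function(x, ...) {
  cat(sprintf("<errp_erp> condition %s, %d epochs, %d ch, %g Hz, [%g, %g) s\n",
              x$condition, x$n_epochs, nrow(x$waveform), x$fs,
              min(x$time), max(x$time) + 1 / x$fs))
  invisible(x)
}

#' Locate the tri-phasic ErrP extrema in an averaged waveform
#'
#' Finds the most negative deflection in the early window, the most positive
#' deflection in the middle window, and the most negative deflection in the
#' late window of one channel's average, for checking the
#' negativity-positivity-negativity ordering of the interaction ErrP.
#'
#' @param erp An `errp_erp`.
#' @param channel Channel name (default `"FCz"`).
#' @param windows List of three `c(start, end)` second windows (defaults
#'   `0.15--0.32`, `0.3--0.5`, `0.5--0.7`).
#' @return Tibble with one row per extremum: `which`, `time`, `amplitude`.
#' @export
erp_extrema <- function(erp, channel = "FCz",
                        windows = list(neg1 = c(0.15, 0.32),
                                       pos = c(0.30, 0.50),
                                       neg2 = c(0.50, 0.70))) {
  ch <- match(channel, erp$montage)
  if (is.na(ch)) abort(sprintf("channel '%s' not in montage.", channel))
  w <- erp$waveform[ch, ]
  purrr::imap_dfr(windows, function(win, name) {
    sel <- which(erp$time >= win[1] & erp$time <= win[2])
    v <- w[sel]
    i <- if (grepl("neg", name)) which.min(v) else which.max(v)
    tibble(which = name, time = erp$time[sel][i], amplitude = v[i])
  })
}
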