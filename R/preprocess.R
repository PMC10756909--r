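#' Epoch container
#'
#' Epochs are stored as a 3-d array `[epoch, channel, time]` together with
#' homogeneous sampling rate and window, a provenance table (`set`, `trial`,
#' `label`, `scenario`, `marker_sample`) and an exclusion log. Labels follow
#' the marker codes: `ErrP` for `S96` events, `NoErrP` for `S48` events.
#'
#' @param data Numeric array `[epoch, channel, time]`.
#' @param fs Sampling rate, Hz.
#' @param window Half-open epoch window `c(start, end)` seconds relative to
#'   the marker (marker maps to relative time 0).
#' @param info Provenance tibble, one row per epoch.
#' @param montage Channel names.
#' @param exclusions Exclusion-log tibble (may be empty).
#' @param steps Character record of processing steps applied so far.
#' @return An `errp_epochs` object.
#' @export
new_epochs <- function(data, fs, window, info, montage,
                       exclusions = tibble(set = integer(0), trial = integer(0),
                                           reason = character(0)),
                       steps = character(0)) {
  stopifnot(length(dim(data)) == 3, dim(data)[1] == nrow(info))
  structure(
    list(data = data, fs = fs, window = window, info = info,
         montage = montage, exclusions = exclusions, steps = steps),
    class = "errp_epochs"
  )
}

#' @export
print.errp_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<errp_epochs> %d epochs x %d ch x %d samples @ %g Hz, window [%g, %g); %d ErrP / %d NoErrP; steps: %s\n",
    d[1], d[2], d[3], x$fs, x$window[1], x$window[2],
    sum(x$info$label == "ErrP"), sum(x$info$label == "NoErrP"),
    if (length(x$steps)) paste(x$steps, collapse = " -> ") else "(raw)"
  ))
  invisible(x)
}

#' @export
dim.errp_epochs <- function(x) dim(x$data)

#' Cut labelled epochs around the S48/S96 event markers
#'
#' One epoch per probe marker, windowed `[window[1], window[2])` seconds
#' around the marker sample (default -0.1 to 1 s; 550 samples at 500 Hz).
#' The i-th S48/S96 marker of a set, in chronological order, belongs to the
#' i-th trial; that ordinal is recorded as the epoch's trial id. Epochs whose
#' window would leave the recording are skipped and logged, never silently
#' truncated.
#'
#' @param rec An `errp_recording` or a list of them (multiple sets).
#' @param window Epoch window in seconds, default `c(-0.1, 1.0)`.
#' @return An `errp_epochs` object.
#' @export
segment_epochs <- function(rec, window = c(-0.1, 1.0)) {
  recs <- if (inherits(rec, "errp_recording")) list(rec) else rec
  offs <- window_offsets(window, recs[[1]]$fs)
  pieces <- purrr::map(recs, function(r) {
    if (r$fs != recs[[1]]$fs) abort("all recordings must share one sampling rate.")
    ev <- dplyr::filter(r$markers, .data$code %in% c("S48", "S96"))
    ev <- dplyr::arrange(ev, .data$sample)
    n <- ncol(r$samples)
    keep <- (ev$sample + offs[1]) >= 1 & (ev$sample + offs[length(offs)]) <= n
    skipped <- which(!keep)
    dat <- array(0, dim = c(sum(keep), nrow(r$samples), length(offs)))
    ki <- which(keep)
    for (j in seq_along(ki)) {
      dat[j, , ] <- r$samples[, ev$sample[ki[j]] + offs]
    }
    list(
      data = dat,
      info = tibble(
        set = r$set, trial = ki,
        label = ifelse(ev$code[ki] == "S96", "ErrP", "NoErrP"),
        scenario = r$scenario, marker_sample = ev$sample[ki]
      ),
      excl = tibble(
        set = rep(r$set, length(skipped)), trial = skipped,
        reason = rep("window outside recording", length(skipped))
      )
    )
  })
  dat <- abind_epochs(purrr::map(pieces, "data"))
  new_epochs(
    dat, recs[[1]]$fs, window,
    dplyr::bind_rows(purrr::map(pieces, "info")),
    recs[[1]]$montage,
    exclusions = dplyr::bind_rows(purrr::map(pieces, "excl")),
    steps = "segment"
  )
}

# bind 3-d arrays along the first (epoch) dimension
abind_epochs <- function(arrs) {
  arrs <- arrs[vapply(arrs, function(a) dim(a)[1] > 0, logical(1))]
  if (length(arrs) == 0) abort("no epochs to bind.")
  d <- dim(arrs[[1]])
  total <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(0, dim = c(total, d[2], d[3]))
  at <- 1L
  for (a in arrs) {
    k <- dim(a)[1]
    out[at:(at + k - 1), , ] <- a
    at <- at + k
  }
  out
}

#' Subset epochs by index
#'
#' @param epochs An `errp_epochs` object.
#' @param idx Logical or integer index over epochs.
#' @return The subsetted `errp_epochs` (metadata kept consistent).
#' @export
subset_epochs <- function(epochs, idx) {
  new_epochs(
    epochs$data[idx, , , drop = FALSE], epochs$fs, epochs$window,
    epochs$info[idx, ], epochs$montage, epochs$exclusions, epochs$steps
  )
}

#' Drop epochs with behaviourally invalid responses
#'
#' Error trials that the simulated subject missed (`FN_miss`) and correct
#' trials with a spurious press (`FP_press`) are removed, so that only epochs
#' with a correct response to the orthosis behaviour keep their label. In the
#' NoButtonPress scenario no responses exist to validate, so the operation is
#' an identity pass.
#'
#' @param epochs An `errp_epochs` object.
#' @param outcomes Behaviour tibble from [simulate_behavior()]; every epoch's
#'   `(set, trial)` must resolve to exactly one outcome row.
#' @return The filtered `errp_epochs`, with each removal appended to the
#'   exclusion log.
#' @export
exclude_behavioral_errors <- function(epochs, outcomes) {
  scen <- unique(epochs$info$scenario)
  if (length(scen) == 1 && identical(scen, "NoButtonPress")) {
    return(epochs)
  }
  key <- paste(epochs$info$set, epochs$info$trial)
  okey <- paste(outcomes$set, outcomes$trial)
  pos <- match(key, okey)
  if (anyNA(pos)) {
    abort(sprintf("epoch provenance not found in outcomes for %s",
                  paste(key[is.na(pos)][1])))
  }
  cls <- outcomes$outcome_class[pos]
  drop <- cls %in% c("FN_miss", "FP_press")
  out <- subset_epochs(epochs, !drop)
  out$exclusions <- dplyr::bind_rows(
    epochs$exclusions,
    tibble(set = epochs$info$set[drop], trial = epochs$info$trial[drop],
           reason = cls[drop])
  )
  out$steps <- c(epochs$steps, "exclude")
  out
}

#' Remove the per-channel mean of every epoch
#'
#' @param epochs An `errp_epochs` object.
#' @return Epochs with zero mean in every (epoch, channel) trace.
#' @export
zero_mean <- function(epochs) {
  m <- apply(epochs$data, c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(m)  # recycles over time (3rd dim)
  epochs$steps <- c(epochs$steps, "zero_mean")
  epochs
}

# zero-phase filter of each (epoch, channel) trace
.filt_epochs <- function(data, filt) {
  d <- dim(data)
  for (i in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      data[i, ch, ] <- signal::filtfilt(filt, data[i, ch, ])
    }
  }
  data
}

#' Decimate epochs to a lower sampling rate
#'
#' A zero-phase 4th-order Butterworth low-pass (cut-off `0.4 * target_fs`,
#' below the new Nyquist frequency) is applied before keeping every
#' `fs / target_fs`-th sample. The sample grid is aligned so that relative
#' time 0 remains a retained sample; with the default -0.1 to 1 s window the
#' 1-second feature portion keeps exactly `target_fs` samples.
#'
#' @param epochs An `errp_epochs` object.
#' @param target_fs Target rate in Hz (default 50); `fs` must be an integer
#'   multiple.
#' @return Decimated `errp_epochs` at `target_fs`.
#' @export
decimate_epochs <- function(epochs, target_fs = 50) {
  factor <- epochs$fs / target_fs
  if (factor != round(factor)) {
    abort(sprintf("fs = %g is not an integer multiple of target_fs = %g",
                  epochs$fs, target_fs))
  }
  factor <- as.integer(factor)
  if (factor > 1L) {
    lp <- signal::butter(4, (0.4 * target_fs) / (epochs$fs / 2), type = "low")
    epochs$data <- .filt_epochs(epochs$data, lp)
    i0 <- round(-epochs$window[1] * epochs$fs) + 1  # index of relative time 0
    start <- ((i0 - 1L) %% factor) + 1L
    keep <- seq.int(start, dim(epochs$data)[3], by = factor)
    epochs$data <- epochs$data[, , keep, drop = FALSE]
    epochs$fs <- target_fs
  }
  epochs$steps <- c(epochs$steps, sprintf("decimate_%g", target_fs))
  epochs
}

#' Band-pass filter epochs
#'
#' Zero-phase (forward-backward) cascade of a 2nd-order Butterworth high-pass
#' at `low` Hz and a 4th-order Butterworth low-pass at `high` Hz, so ERP peak
#' latencies are not shifted. The cascade attenuates by more than 20 dB one
#' octave outside the pass band.
#'
#' @param epochs An `errp_epochs` object.
#' @param low,high Band edges in Hz (defaults 0.1 and 12).
#' @return Filtered `errp_epochs`.
#' @export
bandpass_epochs <- function(epochs, low = 0.1, high = 12) {
  nyq <- epochs$fs / 2
  if (high >= nyq) abort("`high` must be below the Nyquist frequency.")
  hp <- signal::butter(2, low / nyq, type = "high")
  lp <- signal::butter(4, high / nyq, type = "low")
  epochs$data <- .filt_epochs(.filt_epochs(epochs$data, hp), lp)
  epochs$steps <- c(epochs$steps, sprintf("bandpass_%g_%g", low, high))
  epochs
}

#' Crop epochs to a sub-window
#'
#' Used to drop the pre-stimulus baseline before feature extraction, leaving
#' the half-open `[0, 1)` second window (50 samples at 50 Hz).
#'
#' @param epochs An `errp_epochs` object.
#' @param window New window `c(start, end)`, must lie inside the current one.
#' @return Cropped `errp_epochs`.
#' @export
crop_epochs <- function(epochs, window = c(0, 1)) {
  if (window[1] < epochs$window[1] || window[2] > epochs$window[2]) {
    abort("crop window must lie inside the current epoch window.")
  }
  cur <- window_offsets(epochs$window, epochs$fs)
  want <- window_offsets(window, epochs$fs)
  idx <- match(want, cur)
  if (anyNA(idx)) abort("crop window is not aligned to the sample grid.")
  epochs$data <- epochs$data[, , idx, drop = FALSE]
  epochs$window <- window
  epochs$steps <- c(epochs$steps, "crop")
  epochs
}

#' Standard preprocessing chain for classification
#'
#' Applies, in this order: per-channel zero-meaning, decimation to 50 Hz,
#' 0.1--12 Hz band-pass, and the crop to the `[0, 1)` s feature window. The
#' applied order is recorded in the `steps` field for provenance.
#'
#' @param epochs Segmented (and optionally behaviourally excluded) epochs.
#' @param target_fs Decimation target, Hz.
#' @param band Band-pass edges, Hz.
#' @param feature_window Final crop, seconds.
#' @return Preprocessed `errp_epochs` ready for feature extraction.
#' @export
preprocess_epochs <- function(epochs, target_fs = 50, band = c(0.1, 12),
                              feature_window = c(0, 1)) {
  epochs |>
    zero_mean() |>
    decimate_epochs(target_fs) |>
    bandpass_epochs(band[1], band[2]) |>
    crop_epochs(feature_window)
}
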