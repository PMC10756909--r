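#' Write a continuous recording as a header/marker/binary file triad
#'
#' The on-disk dialect mirrors the BrainVision layout: a text header
#' (`<path>.hdr`) with `key=value` sections declaring the sampling rate,
#' channel list and binary layout; a text marker file (`<path>.mrk`) with one
#' `type, code, sample` line per event; and a raw binary file (`<path>.bin`)
#' holding the samples as multiplexed little-endian IEEE-754 float32
#' (channels fastest). Marker positions are stored 1-based in the files and
#' used 1-based throughout the package. Float32 payloads round-trip
#' losslessly; float64 input is rounded to float32 precision on write.
#'
#' @param rec An `errp_recording`.
#' @param path File stem; the three files get `.hdr`, `.mrk`, `.bin` suffixes.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "errp_recording"))
  if (anyNA(rec$samples)) abort("recording contains NaN/NA samples; refusing to write.")
  n_ch <- nrow(rec$samples)
  n <- ncol(rec$samples)

  hdr <- c(
    "[CommonInfo]",
    sprintf("DataFile=%s.bin", basename(path)),
    sprintf("MarkerFile=%s.mrk", basename(path)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    "BinaryFormat=IEEE_FLOAT_32",
    sprintf("NumberOfChannels=%d", n_ch),
    sprintf("NumberOfSamples=%d", n),
    sprintf("SamplingRate=%g", rec$fs),
    sprintf("Set=%s", rec$set),
    sprintf("Scenario=%s", rec$scenario),
    "[Channels]",
    sprintf("Ch%d=%s,1.0", seq_len(n_ch), rec$montage)
  )
  writeLines(hdr, paste0(path, ".hdr"))

  mrk <- c(
    "[Markers]",
    sprintf("Mk%d=Stimulus,%s,%d", seq_len(nrow(rec$markers)),
            rec$markers$code, rec$markers$sample)
  )
  writeLines(mrk, paste0(path, ".mrk"))

  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  # multiplexed: channel index varies fastest, as in the vendor layout
  writeBin(as.numeric(rec$samples), con, size = 4L, endian = "little")
  invisible(path)
}

.parse_kv <- function(lines) {
  kv <- lines[grepl("=", lines, fixed = TRUE) & !grepl("^Ch[0-9]+=|^Mk[0-9]+=", lines)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(vals), keys)
}

#' Read a recording written by [write_recording()]
#'
#' Validates the triad before reconstructing the in-memory object: the
#' declared channel count and sample count must match the binary payload
#' length, channel names must be unique, and all marker positions must fall
#' inside the data block. Any mismatch raises a format error naming the
#' offending field instead of silently truncating.
#'
#' @param path File stem used at write time.
#' @return An `errp_recording`.
#' @export
read_recording <- function(path) {
  hdr_file <- paste0(path, ".hdr")
  if (!file.exists(hdr_file)) abort(sprintf("missing header file '%s'", hdr_file))
  lines <- readLines(hdr_file)
  kv <- .parse_kv(lines)
  n_ch <- as.integer(kv$NumberOfChannels)
  n <- as.integer(kv$NumberOfSamples)
  fs <- as.numeric(kv$SamplingRate)
  if (is.na(n_ch) || is.na(n) || is.na(fs) || fs <= 0) {
    abort("header fields NumberOfChannels/NumberOfSamples/SamplingRate invalid.")
  }
  ch_lines <- lines[grepl("^Ch[0-9]+=", lines)]
  montage <- sub(",.*$", "", sub("^Ch[0-9]+=", "", ch_lines))
  if (length(montage) != n_ch) {
    abort(sprintf("header NumberOfChannels=%d but %d channel lines found", n_ch, length(montage)))
  }
  if (anyDuplicated(montage)) abort("channel names are not unique.")

  bin_file <- paste0(path, ".bin")
  expected <- as.numeric(n_ch) * n
  payload <- file.size(bin_file) / 4
  if (is.na(payload) || payload != expected) {
    abort(sprintf(
      "binary payload has %s float32 values but header declares NumberOfSamples=%d x NumberOfChannels=%d",
      format(payload), n, n_ch
    ))
  }
  con <- file(bin_file, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = expected, size = 4L, endian = "little")
  samples <- matrix(x, nrow = n_ch, ncol = n)

  mrk_lines <- readLines(paste0(path, ".mrk"))
  mk <- mrk_lines[grepl("^Mk[0-9]+=", mrk_lines)]
  if (length(mk) > 0) {
    parts <- strsplit(sub("^Mk[0-9]+=", "", mk), ",", fixed = TRUE)
    markers <- tibble(
      sample = as.integer(vapply(parts, `[`, "", 3)),
      code = vapply(parts, `[`, "", 2)
    )
  } else {
    markers <- tibble(sample = integer(0), code = character(0))
  }
  if (nrow(markers) > 0 && (anyNA(markers$sample) ||
      any(markers$sample < 1) || any(markers$sample > n))) {
    abort("marker sample positions fall outside the data block.")
  }

  structure(
    list(
      samples = samples, fs = fs, montage = montage, markers = markers,
      set = as.integer(kv$Set %||% NA), scenario = kv$Scenario %||% NA_character_
    ),
    class = "errp_recording"
  )
}

#' Write / read the behaviour-annotated trial table
#'
#' Tab-separated, one row per trial, preserving schedule and outcome columns.
#'
#' @param trials Trial tibble.
#' @param path TSV file path.
#' @return `write_trial_table()`: `path`, invisibly. `read_trial_table()`:
#'   the trial tibble with the `scenario` attribute restored.
#' @export
write_trial_table <- function(trials, path) {
  df <- as.data.frame(trials)
  scenario <- attr(trials, "scenario")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(scenario)) writeLines(sprintf("# scenario=%s", scenario), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  first <- readLines(path, n = 1)
  scenario <- if (startsWith(first, "# scenario=")) sub("^# scenario=", "", first) else NULL
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  out <- as_tibble(df)
  if (!is.null(scenario)) attr(out, "scenario") <- scenario
  out
}
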