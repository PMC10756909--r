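#' Electrode montages
#'
#' Channel-name vectors for the two montages the simulator supports: the full
#' 64-electrode extended 10-20 layout used for acquisition-fidelity synthesis
#' (reference electrode FCz included as a data channel), and a reduced
#' 8-channel fronto-central montage (Fz, FCz, Cz, Pz, C3, C4, F3, F4) for
#' fast experimentation and tests.
#'
#' @param size `"full"` (64 channels) or `"reduced"` (8 channels).
#' @return Character vector of channel names, in recording order.
#' @export
montage_channels <- function(size = c("full", "reduced")) {
  size <- match.arg(size)
  if (size == "reduced") {
    return(c("Fz", "FCz", "Cz", "Pz", "C3", "C4", "F3", "F4"))
  }
  c(
    "Fp1", "Fp2", "AF7", "AF3", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT9", "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8", "FT10",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO9", "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2"
  )
}

# Anterior-posterior row weight for a 10-20 channel name prefix.
.row_gain <- function(name, gains) {
  prefix <- sub("[0-9z]+$", "", name)
  gains[[prefix]] %||% 0.1
}

#' Scalp topography for a planted component
#'
#' A topography is a per-channel gain vector, normalized so that the maximum
#' absolute gain is 1. Two built-in shapes are provided:
#' \describe{
#'   \item{errp}{fronto-central, peaking at FCz/Fz and decaying towards
#'     parietal sites, matching the scalp distribution of interaction-error
#'     potentials (amplitudes at Cz and Pz smaller than at Fz and FCz).}
#'   \item{motor}{right-central, peaking at C4 — the motor potential of a
#'     left-hand button press is lateralized contralateral to the responding
#'     hand.}
#' }
#'
#' @param montage Character vector of channel names.
#' @param kind `"errp"` or `"motor"`.
#' @return Named numeric gain vector over `montage`, `max(abs(gain)) == 1`.
#' @export
topography <- function(montage, kind = c("errp", "motor")) {
  kind <- match.arg(kind)
  if (kind == "errp") {
    gains <- list(
      Fp = 0.45, AF = 0.55, F = 0.80, FT = 0.35, FC = 0.92,
      T = 0.25, C = 0.55, TP = 0.20, CP = 0.40, P = 0.28,
      PO = 0.15, O = 0.10
    )
    g <- vapply(montage, .row_gain, numeric(1), gains = gains)
    # midline maximum at FCz, slight boost at Fz
    g[montage == "FCz"] <- 1.0
    g[montage == "Fz"] <- 0.90
    g[montage == "Cz"] <- 0.60
    g[montage == "Pz"] <- 0.30
  } else {
    gains <- list(
      Fp = 0.05, AF = 0.05, F = 0.15, FT = 0.15, FC = 0.45,
      T = 0.20, C = 0.55, TP = 0.15, CP = 0.45, P = 0.20,
      PO = 0.05, O = 0.05
    )
    g <- vapply(montage, .row_gain, numeric(1), gains = gains)
    # lateralization: right-hemisphere (even-numbered) sites up, left down
    num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", montage)))
    right <- !is.na(num) & num %% 2 == 0
    left <- !is.na(num) & num %% 2 == 1
    g[right] <- g[right] * 1.6
    g[left] <- g[left] * 0.35
    g[montage == "C4"] <- 1.0
  }
  g <- g / max(abs(g))
  names(g) <- montage
  g
}
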