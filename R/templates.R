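#' Event-related potential templates
#'
#' A template is a tibble of signed unimodal (Gaussian-bump) components, one
#' row per deflection, with strictly increasing peak latencies. The default
#' error-potential template reproduces the tri-phasic interaction-ErrP
#' morphology: a first negativity around 250 ms, a positivity between 300 and
#' 500 ms, and a second negativity around 600 ms after the error onset.
#'
#' @param polarity Character vector, `"negative"` or `"positive"` per
#'   component.
#' @param peak_latency Peak latencies in seconds after the time-locking event,
#'   strictly increasing.
#' @param width Gaussian standard deviation per component, seconds.
#' @param amplitude Peak magnitude per component, microvolts (positive).
#' @return A tibble with class `errp_template`.
#' @export
erp_template <- function(polarity, peak_latency, width, amplitude) {
  stopifnot(
    length(polarity) == length(peak_latency),
    length(width) == length(peak_latency),
    length(amplitude) == length(peak_latency)
  )
  if (length(peak_latency) > 1 && any(diff(peak_latency) <= 0)) {
    abort("`peak_latency` must be strictly increasing.")
  }
  if (any(width <= 0)) abort("`width` must be positive.")
  if (!all(polarity %in% c("negative", "positive"))) {
    abort("`polarity` must be 'negative' or 'positive'.")
  }
  out <- tibble(
    polarity = polarity, peak_latency = peak_latency,
    width = width, amplitude = abs(amplitude)
  )
  class(out) <- c("errp_template", class(out))
  out
}

#' @rdname erp_template
#' @export
default_errp_template <- function() {
  erp_template(
    polarity = c("negative", "positive", "negative"),
    peak_latency = c(0.25, 0.40, 0.60),
    width = c(0.04, 0.07, 0.05),
    amplitude = c(5, 8, 4)
  )
}

#' @rdname erp_template
#' @details The default motor template is a biphasic negative-then-positive
#'   bump whose negativity peaks just after the button press, emulating the
#'   movement-related cortical potential of the responding (left) hand.
#' @export
default_motor_template <- function() {
  erp_template(
    polarity = c("negative", "positive"),
    peak_latency = c(0.05, 0.30),
    width = c(0.06, 0.10),
    amplitude = c(4, 3)
  )
}

#' Render a template as a single-channel waveform
#'
#' Components are summed as signed Gaussian bumps; each bump is truncated to
#' exact zero beyond four standard deviations from its peak, so the waveform
#' has compact support.
#'
#' @param template An [erp_template()] tibble (may have zero rows).
#' @param fs Sampling rate, Hz.
#' @param duration Waveform duration in seconds; must cover the last
#'   component's peak latency plus its width.
#' @return Numeric vector of `round(fs * duration)` samples (microvolts),
#'   sample 1 at time 0.
#' @export
render_template <- function(template, fs, duration) {
  n <- round(fs * duration)
  w <- numeric(n)
  if (nrow(template) == 0) return(w)
  if (duration < max(template$peak_latency + template$width)) {
    abort("`duration` must cover the last component's peak latency plus width.")
  }
  t <- (seq_len(n) - 1) / fs
  for (i in seq_len(nrow(template))) {
    s <- if (template$polarity[i] == "negative") -1 else 1
    bump <- template$amplitude[i] *
      exp(-(t - template$peak_latency[i])^2 / (2 * template$width[i]^2))
    bump[abs(t - template$peak_latency[i]) > 4 * template$width[i]] <- 0
    w <- w + s * bump
  }
  w
}
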