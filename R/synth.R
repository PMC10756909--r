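#' Background-noise model for synthesized EEG
#'
#' Additive background activity per channel: Gaussian white noise, 1/f
#' ("pink") noise shaped in the frequency domain, and an optional narrow-band
#' oscillation with a random phase per channel. The ongoing EEG of the study
#' itself is not characterized beyond its ERPs, so this model provides a
#' generic, configurable noise floor.
#'
#' @param white_sd White-noise standard deviation, microvolts.
#' @param pink_amp Amplitude scale of the 1/f component, microvolts.
#' @param osc_freq,osc_amp Centre frequency (Hz) and amplitude (microvolts)
#'   of the optional oscillatory component.
#' @return A list of validated noise parameters.
#' @export
noise_model <- function(white_sd = 3, pink_amp = 6, osc_freq = 10, osc_amp = 0) {
  if (any(c(white_sd, pink_amp, osc_amp) < 0)) abort("noise amplitudes must be >= 0.")
  list(white_sd = white_sd, pink_amp = pink_amp,
       osc_freq = osc_freq, osc_amp = osc_amp)
}

# channels x n matrix of 1/f-shaped Gaussian noise, unit variance, scaled.
# Shaping runs at the next 2-3-5-smooth length so the FFT stays O(n log n).
.pink_noise <- function(n_ch, n, amp) {
  if (amp == 0) return(matrix(0, n_ch, n))
  m <- stats::nextn(n)
  f <- c(1, seq_len(m - 1))  # avoid dividing by zero at DC
  scale <- 1 / sqrt(pmin(f, m - f + 1))
  out <- matrix(0, n_ch, n)
  for (ch in seq_len(n_ch)) {
    spec <- stats::fft(rnorm(m)) * scale
    x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)] / m
    out[ch, ] <- amp * x / sd(x)
  }
  out
}

#' Synthesis configuration
#'
#' Bundles every knob of the forward model: montage, sampling rate, ERP and
#' motor templates with their scalp topographies, noise model, the latency of
#' the correct-trial probe marker after movement onset, padding around the
#' set, and a global template scale used for signal-to-noise sweeps.
#'
#' @param montage Channel names (default the reduced 8-channel montage).
#' @param fs Sampling rate, Hz (default 500).
#' @param errp_template,motor_template [erp_template()] tibbles.
#' @param errp_topography,motor_topography Named gain vectors over `montage`;
#'   defaults from [topography()].
#' @param noise [noise_model()] parameters.
#' @param probe_offset Latency of the correct-trial (S48) probe marker after
#'   movement onset, seconds (default 0.5).
#' @param pad Seconds of signal prepended/appended around the set.
#' @param snr_scale Multiplier applied to both template amplitudes at
#'   synthesis time (1 = calibrated default; 0 = pure noise).
#' @return A list of validated synthesis settings.
#' @export
synth_config <- function(montage = montage_channels("reduced"),
                         fs = 500,
                         errp_template = default_errp_template(),
                         motor_template = default_motor_template(),
                         errp_topography = topography(montage, "errp"),
                         motor_topography = topography(montage, "motor"),
                         noise = noise_model(),
                         probe_offset = 0.5,
                         pad = c(2, 3),
                         snr_scale = 1) {
  if (fs <= 0) abort("`fs` must be positive.")
  if (length(errp_topography) != length(montage) ||
      length(motor_topography) != length(montage)) {
    abort("topography length must match the montage.")
  }
  list(
    montage = montage, fs = fs,
    errp_template = errp_template, motor_template = motor_template,
    errp_topography = errp_topography, motor_topography = motor_topography,
    noise = noise, probe_offset = probe_offset, pad = pad,
    snr_scale = snr_scale
  )
}

.add_component <- function(samples, topo, waveform, at_sample) {
  n <- ncol(samples)
  idx <- at_sample + seq_along(waveform) - 1
  keep <- idx >= 1 & idx <= n
  if (!any(keep)) return(samples)
  samples[, idx[keep]] <- samples[, idx[keep]] + outer(topo, waveform[keep])
  samples
}

#' Synthesize the continuous EEG of one movement set
#'
#' Renders background noise over the whole set, then adds (a) the ErrP
#' template, scaled by its fronto-central topography, at every error onset
#' (marker `S96`), and (b) the motor template, scaled by its right-central
#' topography, at every button press (marker `response`). Correct trials
#' receive a probe marker `S48` at a fixed latency after movement onset;
#' movement onsets are marked `movement_flexion` / `movement_extension`.
#' Synthesized signals represent recordings referenced at FCz, with FCz kept
#' as a data channel.
#'
#' @param trials Behaviour-annotated trial tibble for one set (one `set`
#'   value), from [simulate_behavior()].
#' @param config [synth_config()].
#' @param seed Seed for the noise realization of this set.
#' @return An `errp_recording`: list with `samples` (channels x time matrix,
#'   microvolts), `fs`, `montage`, `markers` (tibble `sample`, `code`;
#'   1-based sample indices), `set`, `scenario`.
#' @export
synthesize_recording <- function(trials, config = synth_config(), seed = 1L) {
  stopifnot(length(unique(trials$set)) == 1)
  fs <- config$fs
  n_ch <- length(config$montage)
  t_end <- max(trials$movement_onset + trials$trial_duration)
  n <- round(fs * (config$pad[1] + t_end + config$pad[2]))
  shift <- config$pad[1]
  to_sample <- function(t) round((t + shift) * fs) + 1

  noise <- config$noise
  samples <- with_seed(seed, {
    s <- matrix(rnorm(n_ch * n, sd = noise$white_sd), n_ch, n)
    s <- s + .pink_noise(n_ch, n, noise$pink_amp)
    if (noise$osc_amp > 0) {
      phase <- runif(n_ch, 0, 2 * pi)
      tt <- (seq_len(n) - 1) / fs
      for (ch in seq_len(n_ch)) {
        s[ch, ] <- s[ch, ] + noise$osc_amp * sin(2 * pi * noise$osc_freq * tt + phase[ch])
      }
    }
    s
  })

  errp_wave <- config$snr_scale *
    render_template(config$errp_template, fs, duration = 1.0)
  motor_wave <- config$snr_scale *
    render_template(config$motor_template, fs, duration = 0.8)

  markers <- list()
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    markers[[length(markers) + 1]] <- tibble(
      sample = to_sample(tr$movement_onset),
      code = paste0("movement_", tr$kind)
    )
    if (tr$is_error) {
      at <- to_sample(tr$error_onset)
      samples <- .add_component(samples, config$errp_topography, errp_wave, at)
      markers[[length(markers) + 1]] <- tibble(sample = at, code = "S96")
    } else {
      markers[[length(markers) + 1]] <- tibble(
        sample = to_sample(tr$movement_onset + config$probe_offset),
        code = "S48"
      )
    }
    if (isTRUE(tr$responded) && !is.na(tr$press_time)) {
      at <- to_sample(tr$press_time)
      samples <- .add_component(samples, config$motor_topography, motor_wave, at)
      markers[[length(markers) + 1]] <- tibble(sample = at, code = "response")
    }
  }
  markers <- dplyr::arrange(dplyr::bind_rows(markers), .data$sample)
  stopifnot(all(markers$sample >= 1), all(markers$sample <= n))

  structure(
    list(
      samples = samples, fs = fs, montage = config$montage,
      markers = markers, set = trials$set[1],
      scenario = attr(trials, "scenario") %||% "ButtonPress"
    ),
    class = "errp_recording"
  )
}

#' @export
print.errp_recording <- function(x, ...) {
  cat(sprintf(
    "<errp_recording> set %s (%s): %d ch x %d samples @ %g Hz, %d markers\n",
    x$set, x$scenario, nrow(x$samples), ncol(x$samples), x$fs, nrow(x$markers)
  ))
  invisible(x)
}

#' Synthesize all sets of a simulated subject
#'
#' @param outcomes Behaviour-annotated trial tibble covering one or more sets.
#' @param config [synth_config()].
#' @param seed Master seed; per-set noise seeds are derived from it.
#' @return A list of `errp_recording`, one per set.
#' @export
synthesize_session <- function(outcomes, config = synth_config(), seed = 1L) {
  scenario <- attr(outcomes, "scenario")
  purrr::map(split(outcomes, outcomes$set), function(tr) {
    attr(tr, "scenario") <- scenario
    synthesize_recording(tr, config, derive_seed(seed, "noise", tr$set[1]))
  })
}

#' Render a corpus of recordings at several template scales
#'
#' The schedule, behaviour and noise realizations are identical across
#' levels; only the planted template amplitudes are scaled. Used to probe the
#' classifier's dependence on single-trial signal-to-noise ratio.
#'
#' @param outcomes Behaviour-annotated trial tibble.
#' @param config Base [synth_config()] (its `snr_scale` is overridden).
#' @param levels Numeric template-scale multipliers, `>= 0`.
#' @param seed Master noise seed, shared across levels.
#' @return Named list (one element per level) of lists of `errp_recording`.
#' @export
snr_sweep_corpus <- function(outcomes, config = synth_config(),
                             levels = c(0, 0.25, 0.5, 1), seed = 1L) {
  if (any(levels < 0)) abort("`levels` must be >= 0.")
  out <- purrr::map(levels, function(lv) {
    cfg <- config
    cfg$snr_scale <- lv
    synthesize_session(outcomes, cfg, seed)
  })
  names(out) <- as.character(levels)
  out
}
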