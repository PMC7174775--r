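#' Contraction protocol
#'
#' The gesture protocol: alternating rest and contraction periods, repeated.
#' Each repetition is `rest_s` seconds of rest followed by `contraction_s`
#' seconds of contraction, so with the defaults (10 repetitions of 3 s
#' contractions with 3 s resting periods) a session lasts 60 s and the
#' contractions start at 3, 9, 15, ... s.
#'
#' @param n_repetitions Number of repetitions (default 10).
#' @param contraction_s Contraction duration in seconds (default 3).
#' @param rest_s Rest duration in seconds (default 3).
#' @param fs Sampling rate in Hz (default 2048). Must exceed twice the upper
#'   EMG band edge of 450 Hz.
#' @param ramp_s Rise/fall time of the contraction envelope in seconds
#'   (default 0.25); instructed transitions are abrupt but real muscle force
#'   is not.
#' @return A `contraction_protocol` list.
#' @export
contraction_protocol <- function(n_repetitions = 10, contraction_s = 3,
                                 rest_s = 3, fs = 2048, ramp_s = 0.25) {
  check_number(n_repetitions, "n_repetitions", lower = 1)
  check_number(contraction_s, "contraction_s", lower = 0, allow_equal_lower = FALSE)
  check_number(rest_s, "rest_s", lower = 0)
  check_number(fs, "fs", lower = 2 * 450, allow_equal_lower = FALSE)
  check_number(ramp_s, "ramp_s", lower = 0)
  if (ramp_s > contraction_s / 2) {
    stop_param("`ramp_s` (%g) must not exceed half the contraction (%g s)",
               ramp_s, contraction_s)
  }
  structure(
    list(n_repetitions = as.integer(n_repetitions),
         contraction_s = contraction_s, rest_s = rest_s,
         fs = fs, ramp_s = ramp_s),
    class = "contraction_protocol"
  )
}

#' Interference and artifact model for synthetic sessions
#'
#' @param carrier_band EMG carrier band in Hz (default 20-450): white
#'   Gaussian noise band-passed to this range and amplitude-modulated by the
#'   contraction envelope forms the myoelectric carrier of each channel.
#' @param baseline_sd Standard deviation of additive broadband baseline noise
#'   in uV (default 3).
#' @param powerline_amplitude Amplitude of the additive 50 Hz powerline
#'   sinusoid in uV (default 10), with a random phase per channel.
#' @param powerline_hz Powerline frequency (default 50, EU mains).
#' @param faulty_channels Optional data frame with columns `channel` and
#'   `mode` (`"dead"` or `"saturated"`): dead channels carry only 1% of the
#'   baseline noise, saturated channels 50 times it.
#' @param seed Integer seed making a synthesized session fully reproducible,
#'   or `NULL` to draw from the current RNG stream.
#' @return A `noise_model` list.
#' @export
noise_model <- function(carrier_band = c(20, 450), baseline_sd = 3,
                        powerline_amplitude = 10, powerline_hz = 50,
                        faulty_channels = NULL, seed = NULL) {
  if (length(carrier_band) != 2 || carrier_band[1] <= 0 ||
      carrier_band[1] >= carrier_band[2]) {
    stop_param("`carrier_band` must be increasing positive (low, high) Hz")
  }
  check_number(baseline_sd, "baseline_sd", lower = 0)
  check_number(powerline_amplitude, "powerline_amplitude", lower = 0)
  check_number(powerline_hz, "powerline_hz", lower = 0, allow_equal_lower = FALSE)
  if (!is.null(faulty_channels)) {
    faulty_channels <- tibble::as_tibble(faulty_channels)
    if (!all(c("channel", "mode") %in% names(faulty_channels)) ||
        !all(faulty_channels$mode %in% c("dead", "saturated"))) {
      stop_param("`faulty_channels` needs columns channel and mode (dead | saturated)")
    }
  }
  if (!is.null(seed)) check_number(seed, "seed")
  structure(
    list(carrier_band = as.numeric(carrier_band), baseline_sd = baseline_sd,
         powerline_amplitude = powerline_amplitude, powerline_hz = powerline_hz,
         faulty_channels = faulty_channels, seed = seed),
    class = "noise_model"
  )
}

#' Cohort activation profile
#'
#' Parametrizes the group-level activation structure a synthetic cohort
#' emulates. The built-in defaults encode the contrast between healthy and
#' dystrophic (DMD) forearms: DMD participants activate close to their
#' maximal contraction level (normalized activation 0.63 vs 0.26) yet produce
#' lower absolute amplitudes (about 35 vs 89 uV), and their gesture
#' repertoire spans fewer distinct spatial patterns (3 vs 5), with the
#' remaining gestures expressed as blends of the base patterns.
#'
#' `pattern_variability` is the standard deviation of per-repetition mixing
#' noise in base-template space — a simple model of co-contraction
#' variability. It lives in the span of the base templates, so the planted
#' pattern rank is preserved.
#'
#' @param group `"healthy"` or `"dmd"`; selects the default parameter set.
#' @param n_templates_distinct Number of distinct base activation patterns
#'   (1-7).
#' @param template_spread Gaussian spatial spread of base templates in grid
#'   units.
#' @param normalized_activation_level Fraction of the per-channel maximum
#'   reached during comfortable gestures (0-1].
#' @param absolute_scale Peak envelope amplitude of comfortable gestures in
#'   uV.
#' @param pattern_variability Per-repetition co-contraction mixing sd.
#' @param rep_jitter_sd Lognormal sd of per-repetition amplitude jitter.
#' @param center_jitter Half-width (grid units) of the uniform per-participant
#'   jitter applied to the base pattern centers; 0 pins every participant to
#'   the canonical cell-centered layout.
#' @param mvc_floor Minimum fraction of the maximal-effort amplitude reached
#'   by every electrode during the maximal-effort reference recording.
#' @return A `cohort_profile` list.
#' @export
cohort_profile <- function(group = c("healthy", "dmd"),
                           n_templates_distinct = NULL,
                           template_spread = NULL,
                           normalized_activation_level = NULL,
                           absolute_scale = NULL,
                           pattern_variability = NULL,
                           rep_jitter_sd = 0.1,
                           center_jitter = 0.4,
                           mvc_floor = 0.25) {
  group <- match.arg(group)
  defaults <- if (group == "healthy") {
    list(k = 5L, spread = 1.0, level = 0.26, scale = 89, mix = 0.2)
  } else {
    list(k = 3L, spread = 0.7, level = 0.63, scale = 35, mix = 0.3)
  }
  k <- as.integer(n_templates_distinct %||% defaults$k)
  if (k < 1 || k > 7) stop_param("`n_templates_distinct` must be in 1..7")
  spread <- template_spread %||% defaults$spread
  check_number(spread, "template_spread", lower = 0, allow_equal_lower = FALSE)
  level <- normalized_activation_level %||% defaults$level
  check_number(level, "normalized_activation_level", lower = 0, upper = 1,
               allow_equal_lower = FALSE)
  scale <- absolute_scale %||% defaults$scale
  check_number(scale, "absolute_scale", lower = 0, allow_equal_lower = FALSE)
  mix <- pattern_variability %||% defaults$mix
  check_number(mix, "pattern_variability", lower = 0)
  check_number(rep_jitter_sd, "rep_jitter_sd", lower = 0)
  check_number(center_jitter, "center_jitter", lower = 0)
  check_number(mvc_floor, "mvc_floor", lower = 0, upper = 1)
  structure(
    list(group = group, n_templates_distinct = k, template_spread = spread,
         normalized_activation_level = level, absolute_scale = scale,
         pattern_variability = mix, rep_jitter_sd = rep_jitter_sd,
         center_jitter = center_jitter, mvc_floor = mvc_floor),
    class = "cohort_profile"
  )
}

#' Default gesture set
#'
#' The seven hand/wrist gestures of the acquisition protocol, in listing
#' order (also the default ordering for accuracy-versus-gesture-count
#' curves).
#' @return Character vector of 7 gesture labels.
#' @export
default_gestures <- function() {
  c("hand_open", "hand_close", "thumb_flexion", "thumb_extension",
    "wrist_flexion", "wrist_extension", "index_extension")
}
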