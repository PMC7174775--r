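#' Trapezoidal contraction envelope of a protocol
#'
#' The instructed on/off profile: zero during rests, rising linearly over
#' `ramp_s` at each contraction onset, holding 1 through the contraction and
#' falling over `ramp_s` after it ends.
#'
#' @param protocol A [contraction_protocol()].
#' @param repetition Single repetition index, or `NULL` (default) for the
#'   profile of all repetitions summed into one trace.
#' @return Numeric vector over the session's samples, in `[0, 1]`.
#' @export
protocol_envelope <- function(protocol, repetition = NULL) {
  stopifnot(inherits(protocol, "contraction_protocol"))
  fs <- protocol$fs
  period <- protocol$rest_s + protocol$contraction_s
  n <- round(protocol$n_repetitions * period * fs)
  t <- (seq_len(n) - 1) / fs
  reps <- repetition %||% seq_len(protocol$n_repetitions)
  env <- numeric(n)
  for (j in reps) {
    on <- protocol$rest_s + (j - 1) * period
    off <- on + protocol$contraction_s
    if (protocol$ramp_s > 0) {
      up <- pmin(pmax((t - on) / protocol$ramp_s, 0), 1)
      down <- pmin(pmax((t - off) / protocol$ramp_s, 0), 1)
      env <- env + up - down
    } else {
      env <- env + as.numeric(t >= on & t < off)
    }
  }
  pmin(pmax(env, 0), 1)
}

#' Planted contraction onsets of a protocol
#'
#' @param protocol A [contraction_protocol()].
#' @return Numeric vector of onset times in seconds (start of each
#'   contraction ramp).
#' @export
protocol_onsets <- function(protocol) {
  period <- protocol$rest_s + protocol$contraction_s
  protocol$rest_s + (seq_len(protocol$n_repetitions) - 1) * period
}

#' Synthesize a recording session
#'
#' Generates a multi-channel monopolar recording: per channel, a trapezoidal
#' contraction envelope times the channel's template amplitude modulates a
#' band-limited (20-450 Hz by default) unit-variance Gaussian carrier,
#' regenerated independently per channel; broadband baseline noise and a
#' powerline sinusoid (random phase per channel) are added, and faulty
#' channels are overwritten according to their mode. Rectifying and low-pass
#' filtering such a signal recovers the modulation envelope scaled by the
#' rectified-Gaussian mean factor sqrt(2/pi).
#'
#' @param template A `spatial_template`, or a list of `n_repetitions`
#'   templates to vary the spatial pattern per repetition.
#' @param protocol A [contraction_protocol()].
#' @param noise A [noise_model()].
#' @param participant List with `id` and anthropometrics (`forearm_length_cm`,
#'   `circumference_cm`, optional `handedness`). A plain default is used when
#'   `NULL`.
#' @param gesture_label Label stored in the session.
#' @param grid Electrode grid (defaults to the participant's).
#' @param seed Overrides `noise$seed` when given.
#' @return A [recording_session()] whose `truth` element records the planted
#'   templates, onset times, protocol envelope parameters and seed.
#' @export
synthesize_session <- function(template, protocol, noise,
                               participant = NULL,
                               gesture_label = "gesture",
                               grid = NULL, seed = NULL) {
  stopifnot(inherits(protocol, "contraction_protocol"),
            inherits(noise, "noise_model"))
  templates <- if (inherits(template, "spatial_template")) {
    rep(list(template), protocol$n_repetitions)
  } else {
    template
  }
  if (length(templates) != protocol$n_repetitions ||
      !all(vapply(templates, inherits, TRUE, "spatial_template"))) {
    stop_param("`template` must be a spatial_template or a list of %d of them",
               protocol$n_repetitions)
  }
  if (noise$carrier_band[2] >= protocol$fs / 2) {
    stop_param("carrier band upper edge %g Hz must be below Nyquist %g Hz",
               noise$carrier_band[2], protocol$fs / 2)
  }
  participant <- participant %||%
    list(id = "synthetic", forearm_length_cm = 24.8, circumference_cm = 25.9,
         handedness = "right")
  grid <- grid %||% grid_from_anthropometrics(
    participant$forearm_length_cm, participant$circumference_cm,
    handedness = participant$handedness %||% "right")

  fs <- protocol$fs
  n_chan <- grid$n_rows * grid$n_cols
  n <- round(protocol$n_repetitions * (protocol$rest_s + protocol$contraction_s) * fs)
  seed <- seed %||% noise$seed

  # per-repetition amplitude profile: (channels x reps) %*% (reps x samples)
  env_reps <- vapply(seq_len(protocol$n_repetitions),
                     function(j) protocol_envelope(protocol, j), numeric(n))
  amp_reps <- t(vapply(templates,
                       function(tp) amps_by_channel(grid, tp$amplitudes),
                       numeric(n_chan)))
  amp_t <- t(amp_reps) %*% t(env_reps)  # channels x samples

  sig <- with_seed_maybe(seed, {
    bpf <- design_bandpass(fs, noise$carrier_band[1], noise$carrier_band[2])
    carrier <- .iir_rows(bpf$b, bpf$a, matrix(rnorm(n * n_chan), nrow = n_chan))
    m1 <- rowMeans(carrier)
    sds <- sqrt((rowMeans(carrier^2) - m1^2) * n / (n - 1))
    s <- (amp_t / sds) * carrier
    if (noise$baseline_sd > 0) {
      s <- s + matrix(rnorm(n * n_chan, sd = noise$baseline_sd), nrow = n_chan)
    }
    if (noise$powerline_amplitude > 0) {
      wt <- 2 * pi * noise$powerline_hz * (seq_len(n) - 1) / fs
      phase <- runif(n_chan, 0, 2 * pi)
      s <- s + noise$powerline_amplitude *
        (outer(cos(phase), sin(wt)) + outer(sin(phase), cos(wt)))
    }
    if (!is.null(noise$faulty_channels) && nrow(noise$faulty_channels)) {
      for (i in seq_len(nrow(noise$faulty_channels))) {
        ch <- noise$faulty_channels$channel[i]
        mult <- if (noise$faulty_channels$mode[i] == "dead") 0.01 else 50
        s[ch, ] <- rnorm(n, sd = mult * max(noise$baseline_sd, .Machine$double.eps))
      }
    }
    s
  })

  recording_session(
    signals = sig, fs = fs, gesture_label = gesture_label,
    participant_id = participant$id, protocol = protocol,
    anthropometrics = list(
      forearm_length_cm = participant$forearm_length_cm,
      circumference_cm = participant$circumference_cm,
      handedness = participant$handedness %||% "right"
    ),
    truth = list(
      onsets_s = protocol_onsets(protocol),
      templates = templates,
      center = templates[[1]]$center,
      peak = max(vapply(templates, function(tp) max(tp$amplitudes), 0)),
      seed = seed
    )
  )
}
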