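#' Recording session
#'
#' The unit of acquisition: one gesture's multi-channel monopolar recording
#' with its protocol and participant metadata.
#'
#' @param signals Numeric channels x samples matrix in uV (64 channels in the
#'   standard configuration).
#' @param fs Sampling rate in Hz.
#' @param gesture_label Gesture performed.
#' @param participant_id Participant identifier.
#' @param protocol A [contraction_protocol()].
#' @param anthropometrics List with `forearm_length_cm`, `circumference_cm`,
#'   and optionally `start_offset_fraction` (default 0.20) and `handedness`.
#' @param truth Optional ground-truth list carried by synthetic sessions
#'   (planted template, onsets, seed).
#' @return A `recording_session`.
#' @export
recording_session <- function(signals, fs, gesture_label, participant_id,
                              protocol, anthropometrics, truth = NULL) {
  signals <- as_signal_matrix(signals)
  check_number(fs, "fs", lower = 0, allow_equal_lower = FALSE)
  if (is.null(gesture_label) || is.null(participant_id)) {
    stop_format("`gesture_label` and `participant_id` are required metadata")
  }
  if (!inherits(protocol, "contraction_protocol")) {
    stop_format("`protocol` must be a contraction_protocol")
  }
  if (!is.list(anthropometrics) ||
      is.null(anthropometrics$forearm_length_cm) ||
      is.null(anthropometrics$circumference_cm)) {
    stop_format("`anthropometrics` needs forearm_length_cm and circumference_cm")
  }
  anthropometrics$start_offset_fraction <-
    anthropometrics$start_offset_fraction %||% 0.20
  anthropometrics$handedness <- anthropometrics$handedness %||% "right"
  structure(
    list(signals = signals, fs = fs,
         gesture_label = as.character(gesture_label),
         participant_id = as.character(participant_id),
         protocol = protocol, anthropometrics = anthropometrics,
         truth = truth),
    class = "recording_session"
  )
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("<recording_session> %s / %s: %d channels x %d samples @ %g Hz\n",
              x$participant_id, x$gesture_label,
              nrow(x$signals), ncol(x$signals), x$fs))
  invisible(x)
}

#' Grid of a session
#'
#' Convenience accessor building the [electrode_grid()] implied by a
#' session's anthropometrics.
#' @param session A `recording_session`.
#' @return An `electrode_grid`.
#' @export
session_grid <- function(session) {
  stopifnot(inherits(session, "recording_session"))
  a <- session$anthropometrics
  grid_from_anthropometrics(a$forearm_length_cm, a$circumference_cm,
                            handedness = a$handedness %||% "right")
}
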