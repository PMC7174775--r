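#' Extract amplitude envelopes
#'
#' Full-wave rectifies each channel and applies a zero-phase low-pass
#' (third-order Butterworth, 2 Hz by default). Tiny negative excursions from
#' filter ringing are clamped to zero: envelopes are amplitudes.
#'
#' @param signals Numeric channels x samples matrix of band-pass filtered EMG.
#' @param fs Sampling rate in Hz.
#' @param lp Low-pass cutoff in Hz (default 2).
#' @param order Butterworth order (default 3).
#' @return An `envelope_set`: list with `envelopes` (channels x samples,
#'   non-negative), `fs`, and `provenance` (the filter parameters).
#' @examples
#' x <- matrix(rnorm(2 * 4096), nrow = 2)
#' e <- envelope(x, fs = 2048)
#' all(e$envelopes >= 0)
#' @export
envelope <- function(signals, fs, lp = 2, order = 3) {
  signals <- as_signal_matrix(signals)
  filt <- design_lowpass(fs, cutoff = lp, order = order)
  env <- zero_phase(filt, abs(signals))
  env[env < 0] <- 0
  structure(
    list(envelopes = env, fs = fs,
         provenance = list(lp = lp, order = order, rectification = "full-wave")),
    class = "envelope_set"
  )
}

#' @export
print.envelope_set <- function(x, ...) {
  cat(sprintf("<envelope_set> %d channels x %d samples @ %g Hz (low-pass %g Hz)\n",
              nrow(x$envelopes), ncol(x$envelopes), x$fs, x$provenance$lp))
  invisible(x)
}

#' Centered moving average
#'
#' Running mean over a centered window; positions whose window does not fit
#' entirely inside the series are `NA`.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @param w Window length in samples.
#' @return Same shape as `x`.
#' @export
moving_average <- function(x, w) {
  check_number(w, "w", lower = 1)
  vec <- is.null(dim(x))
  x <- as_signal_matrix(x)
  out <- .moving_average_rows(x, as.integer(w))
  if (vec) as.vector(out) else out
}

#' Per-channel normalization factors
#'
#' The normalization value of each electrode is the maximum, across the
#' participant's complete dataset, of the 1-s centered moving average of its
#' envelope. The moving average suppresses short artifacts so a single-sample
#' spike cannot set the factor.
#'
#' @param envelopes One `envelope_set` or a list of them (the complete
#'   dataset of one participant).
#' @param window_s Moving-average window in seconds (default 1).
#' @return Numeric vector of per-channel factors (uV), with attribute
#'   `window_s`. An error is raised if any factor is not strictly positive.
#' @export
normalization_factors <- function(envelopes, window_s = 1) {
  if (inherits(envelopes, "envelope_set")) envelopes <- list(envelopes)
  if (!length(envelopes) || !all(vapply(envelopes, inherits, TRUE, "envelope_set"))) {
    stop_param("`envelopes` must be an envelope_set or a list of envelope_sets")
  }
  per_session <- lapply(envelopes, function(e) {
    w <- max(1L, as.integer(round(window_s * e$fs)))
    sm <- moving_average(e$envelopes, w)
    apply(sm, 1, max, na.rm = TRUE)
  })
  factors <- do.call(pmax, per_session)
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    bad <- which(!is.finite(factors) | factors <= 0)
    stop_param("normalization factor not strictly positive for channel(s) %s",
               toString(head(bad, 5)))
  }
  attr(factors, "window_s") <- window_s
  factors
}
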