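#' Filter designs used by the processing chain
#'
#' `design_bandpass()` returns the Butterworth band-pass used on raw EMG
#' (order 4 per band edge, 20-450 Hz by default), `design_lowpass()` the
#' envelope low-pass (order 3, 2 Hz), and `design_notch()` the narrow
#' powerline notch (constrained biquad with zeros on the unit circle at `f0`,
#' bandwidth `f0/Q`). All return transfer-function coefficients `list(b, a)`
#' suitable for [signal::freqz()].
#'
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz.
#' @param cutoff Low-pass cutoff in Hz.
#' @param order Filter order passed to [signal::butter()].
#' @param f0 Notch center frequency in Hz.
#' @param Q Notch quality factor; the -3 dB bandwidth is `f0/Q`.
#' @return `list(b, a)` transfer-function coefficients.
#' @name filter_designs
NULL

#' @rdname filter_designs
#' @export
design_bandpass <- function(fs, low = 20, high = 450, order = 4) {
  check_number(fs, "fs", lower = 0, allow_equal_lower = FALSE)
  check_number(low, "low", lower = 0, allow_equal_lower = FALSE)
  check_number(order, "order", lower = 1)
  if (high >= fs / 2) {
    stop_param("band edge `high` = %g Hz must be below the Nyquist frequency %g Hz",
               high, fs / 2)
  }
  if (low >= high) stop_param("`low` (%g) must be below `high` (%g)", low, high)
  bt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  list(b = bt$b, a = bt$a)
}

#' @rdname filter_designs
#' @export
design_lowpass <- function(fs, cutoff = 2, order = 3) {
  check_number(fs, "fs", lower = 0, allow_equal_lower = FALSE)
  if (cutoff <= 0 || cutoff >= fs / 2) {
    stop_param("`cutoff` = %g Hz must lie in (0, fs/2)", cutoff)
  }
  bt <- signal::butter(order, cutoff / (fs / 2), type = "low")
  list(b = bt$b, a = bt$a)
}

#' @rdname filter_designs
#' @export
design_notch <- function(fs, f0 = 50, Q = 50) {
  check_number(fs, "fs", lower = 0, allow_equal_lower = FALSE)
  check_number(Q, "Q", lower = 0, allow_equal_lower = FALSE)
  if (f0 <= 0 || f0 >= fs / 2) {
    stop_param("`f0` = %g Hz must lie in (0, fs/2)", f0)
  }
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

# Zero-phase (forward-backward) application of a transfer function down the
# time axis. x is channels x samples; returns the same shape. Padding uses
# odd reflection over 3x the filter order at each end.
zero_phase <- function(filt, x) {
  vec <- is.null(dim(x))
  x <- as_signal_matrix(x)
  npad <- 3L * (max(length(filt$a), length(filt$b)) - 1L)
  out <- .filtfilt_rows(filt$b, filt$a, x, npad)
  if (vec) as.vector(out) else out
}

#' Band-pass filter multi-channel EMG
#'
#' Zero-phase (forward-backward) Butterworth band-pass applied to every
#' channel. Zero-phase filtering is used throughout the package because the
#' analysis is offline and group delay would bias onset times.
#'
#' @param signals Numeric channels x samples matrix (or a vector for a single
#'   channel).
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz (defaults 20 and 450).
#' @param order Butterworth order per band edge (default 4).
#' @return Filtered matrix with the same shape as the input.
#' @export
bandpass <- function(signals, fs, low = 20, high = 450, order = 4) {
  zero_phase(design_bandpass(fs, low, high, order), signals)
}

#' Notch filter powerline interference
#'
#' Zero-phase narrow-band rejection at `f0` (50 Hz by default, the EU
#' powerline frequency) using a constrained biquad notch with quality factor
#' `Q`; the passband elsewhere is unity to within a fraction of a percent.
#'
#' @inheritParams bandpass
#' @param f0 Notch center frequency in Hz.
#' @param Q Quality factor (default 50, i.e. 1 Hz bandwidth at 50 Hz).
#' @return Filtered matrix with the same shape as the input.
#' @export
notch <- function(signals, fs, f0 = 50, Q = 50) {
  zero_phase(design_notch(fs, f0, Q), signals)
}
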