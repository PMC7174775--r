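#' Write / read a session bundle
#'
#' A session bundle is a directory holding `metadata.json` (sampling rate,
#' labels, protocol, anthropometrics, matrix shape) and `signals.dat`, the
#' signal matrix as little-endian 32-bit floats in row-major channel x sample
#' order — a documented, language-neutral layout. Signals are quantized to
#' float32 on write (about 7 significant digits, ample for microvolt-scale
#' EMG); a written bundle round-trips bit-exactly thereafter.
#'
#' @param session A [recording_session()].
#' @param path Bundle directory (created if needed).
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   returns a [recording_session()].
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "recording_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    format = "hdemg-session-bundle-v1",
    fs = session$fs,
    gesture_label = session$gesture_label,
    participant_id = session$participant_id,
    n_channels = nrow(session$signals),
    n_samples = ncol(session$signals),
    storage = "float32-little-endian-row-major",
    protocol = unclass(session$protocol),
    anthropometrics = session$anthropometrics
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(path, "signals.dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(session$signals)), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  meta_path <- file.path(path, "metadata.json")
  dat_path <- file.path(path, "signals.dat")
  if (!file.exists(meta_path)) stop_format("bundle %s: missing metadata.json", path)
  if (!file.exists(dat_path)) stop_format("bundle %s: missing signals.dat", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("fs", "gesture_label", "participant_id", "n_channels",
                  "n_samples", "protocol", "anthropometrics")) {
    if (is.null(meta[[field]])) {
      stop_format("bundle %s: metadata field `%s` is missing", path, field)
    }
  }
  expected <- meta$n_channels * meta$n_samples
  actual <- file.size(dat_path) / 4
  if (actual != expected) {
    stop_format("bundle %s: signals.dat holds %g values but metadata declares %d channels x %d samples",
                path, actual, meta$n_channels, meta$n_samples)
  }
  con <- file(dat_path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "numeric", n = expected, size = 4L, endian = "little")
  signals <- t(matrix(v, nrow = meta$n_samples, ncol = meta$n_channels))
  proto <- do.call(contraction_protocol, meta$protocol[
    c("n_repetitions", "contraction_s", "rest_s", "fs", "ramp_s")])
  recording_session(signals, meta$fs, meta$gesture_label, meta$participant_id,
                    proto, as.list(meta$anthropometrics))
}

#' Import a delimited signal export
#'
#' Reads a delimited text file whose columns are channels in channel-index
#' order and whose values are microvolts, one sample per row — the ingestion
#' path for externally exported recordings.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz.
#' @param gesture_label,participant_id Session metadata.
#' @param protocol A [contraction_protocol()] (defaults to the standard
#'   10 x 3 s protocol at `fs`).
#' @param anthropometrics List with `forearm_length_cm` and
#'   `circumference_cm`.
#' @param delim Field delimiter (default `","`).
#' @return A [recording_session()].
#' @export
import_delimited <- function(path, fs, gesture_label = "imported",
                             participant_id = "imported",
                             protocol = NULL, anthropometrics = NULL,
                             delim = ",") {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  df <- suppressWarnings(
    readr::read_delim(path, delim = delim, col_names = FALSE,
                      col_types = readr::cols(.default = readr::col_double()),
                      progress = FALSE)
  )
  prob <- readr::problems(df)
  if (nrow(prob)) {
    stop_format("parse error in %s at row %d: %s", path, prob$row[1],
                prob$expected[1])
  }
  m <- as.matrix(df)
  dimnames(m) <- NULL
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_format("non-numeric or non-finite cell in %s at row %d, column %d",
                path, bad[1, 1], bad[1, 2])
  }
  protocol <- protocol %||% contraction_protocol(fs = fs)
  anthropometrics <- anthropometrics %||%
    list(forearm_length_cm = 24.8, circumference_cm = 25.9)
  recording_session(t(m), fs, gesture_label, participant_id, protocol,
                    anthropometrics)
}

#' Export session signals as delimited text
#'
#' Columns are channels in channel-index order, values in microvolts.
#'
#' @param session A [recording_session()].
#' @param path Output file.
#' @param digits Significant digits written (default 7, float32-equivalent).
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
export_delimited <- function(session, path, digits = 7, delim = ",") {
  stopifnot(inherits(session, "recording_session"))
  m <- signif(t(session$signals), digits)
  utils::write.table(m, path, sep = delim, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
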