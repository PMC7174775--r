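#' Spatial activation template
#'
#' Builds an isotropic Gaussian activation bump on the electrode grid,
#' representing the spatial distribution of one gesture's muscle activity.
#' Rows can wrap circumferentially (the grid encircles the forearm). The
#' template's amplitude-weighted centroid equals the requested `center`
#' exactly: the sampled Gaussian's nominal center is moment-corrected per
#' axis so grid truncation does not bias the planted ground truth (linear
#' centroid without wrap; circular row centroid with wrap).
#'
#' @param grid An [electrode_grid()].
#' @param center Length-2 numeric `(row, col)` in zero-based grid
#'   coordinates.
#' @param spread Gaussian spread in grid units (> 0).
#' @param peak Maximum amplitude in uV (envelope scale at full contraction).
#' @param wrap_circumferential Wrap the row axis (default `TRUE`).
#' @param gesture_id Optional label.
#' @return A `spatial_template`: list with `amplitudes` (n_rows x n_cols,
#'   non-negative, max = `peak`), `center`, `spread`, `gesture_id`.
#' @examples
#' g <- electrode_grid()
#' tp <- make_spatial_template(g, center = c(2, 5), spread = 1, peak = 50)
#' template_centroid(tp) # (2, 5)
#' @export
make_spatial_template <- function(grid, center, spread, peak = 1,
                                  wrap_circumferential = TRUE,
                                  gesture_id = NULL) {
  stopifnot(inherits(grid, "electrode_grid"))
  if (length(center) != 2 || !is.numeric(center)) {
    stop_param("`center` must be numeric (row, col)")
  }
  check_number(spread, "spread", lower = 0, allow_equal_lower = FALSE)
  check_number(peak, "peak", lower = 0)
  if (center[1] < -0.5 || center[1] > grid$n_rows - 0.5 ||
      center[2] < -0.5 || center[2] > grid$n_cols - 0.5) {
    stop_param("`center` (%g, %g) outside the grid extent", center[1], center[2])
  }
  w_row <- axis_weights(grid$n_rows, center[1], spread, wrap = wrap_circumferential)
  w_col <- axis_weights(grid$n_cols, center[2], spread, wrap = FALSE)
  amplitudes <- outer(w_row, w_col)
  m <- max(amplitudes)
  if (m > 0) amplitudes <- amplitudes * (peak / m)
  structure(
    list(amplitudes = amplitudes, center = as.numeric(center),
         spread = spread, peak = peak,
         wrap_circumferential = wrap_circumferential,
         gesture_id = gesture_id),
    class = "spatial_template"
  )
}

# Discrete Gaussian weights along one axis whose amplitude-weighted centroid
# equals `center` exactly. For a truncated (non-wrapped) axis the nominal
# Gaussian center is shifted (uniroot) to cancel the truncation bias; for a
# wrapped axis the wrapped Gaussian's circular first moment is zeroed the
# same way. Below spread 0.05 a single cell holds all mass and the
# correction is skipped.
axis_weights <- function(n, center, spread, wrap) {
  x <- seq_len(n) - 1
  gauss <- function(c0) {
    if (wrap) {
      w <- 0
      for (k in -2:2) w <- w + exp(-((x - c0 + k * n)^2) / (2 * spread^2))
      w
    } else {
      exp(-((x - c0)^2) / (2 * spread^2))
    }
  }
  w <- gauss(center)
  if (max(w) == 0) {
    # degenerate spread: all mass on the nearest cell
    w[which.min(abs(x - center))] <- 1
    return(w)
  }
  if (spread < 0.05) return(w / max(w))
  resid <- function(c0) {
    w <- gauss(c0)
    if (wrap) sum(w * sin(2 * pi * (x - center) / n)) else sum(w * (x - center))
  }
  root <- tryCatch(
    uniroot(resid, lower = center - 1 - spread, upper = center + 1 + spread,
            extendInt = "upX", tol = 1e-13)$root,
    error = function(e) center
  )
  w <- gauss(root)
  w / max(w)
}

#' Amplitude-weighted centroid of a template or cell matrix
#'
#' @param x A `spatial_template` or a non-negative n_rows x n_cols matrix.
#' @param circular_rows Compute the row coordinate as a circular
#'   (wrap-aware) mean. Defaults to the template's wrap flag, or `FALSE`
#'   for a plain matrix.
#' @return Length-2 numeric `(row, col)`, zero-based.
#' @export
template_centroid <- function(x, circular_rows = NULL) {
  if (inherits(x, "spatial_template")) {
    circular_rows <- circular_rows %||% x$wrap_circumferential
    x <- x$amplitudes
  }
  circular_rows <- circular_rows %||% FALSE
  if (sum(x) <= 0) stop_param("centroid undefined: all amplitudes are zero")
  n_rows <- nrow(x)
  rows <- row(x) - 1
  cols <- col(x) - 1
  w <- x / sum(x)
  row_c <- if (circular_rows) {
    th <- 2 * pi * rows / n_rows
    ang <- atan2(sum(w * sin(th)), sum(w * cos(th)))
    r <- ang * n_rows / (2 * pi)
    ((r + 0.5) %% n_rows) - 0.5
  } else {
    sum(w * rows)
  }
  c(row_c, sum(w * cols))
}

#' @export
print.spatial_template <- function(x, ...) {
  cat(sprintf("<spatial_template> center (%.2f, %.2f), spread %.2f, peak %.3g uV%s\n",
              x$center[1], x$center[2], x$spread, x$peak,
              if (!is.null(x$gesture_id)) paste0(" [", x$gesture_id, "]") else ""))
  invisible(x)
}
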