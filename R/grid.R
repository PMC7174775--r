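#' Forearm electrode grid
#'
#' Describes the 8 x 8 high-density electrode grid wrapped around the forearm:
#' 8 circumferential rows encircling the arm and 8 longitudinal columns running
#' proximal to distal. Channel 1 sits on the first (dorsal-start) row at the
#' proximal end; channels 1-8 fill that row proximal to distal, and successive
#' rows continue counterclockwise as seen on a right arm, so channels 1-32
#' cover the dorsal and 33-64 the ventral side. For a left arm the
#' circumferential direction is mirrored.
#'
#' Cell coordinates throughout the package are zero-based real numbers:
#' `row` in `[-0.5, 7.5)` (circumferential, wrap-aware) and `col` in
#' `[-0.5, 7.5]` (longitudinal). The longitudinal inter-electrode distance
#' (LID) is fixed at 2 cm; the circumferential inter-electrode distance (CID)
#' is the forearm circumference divided by the number of rows.
#'
#' @param n_rows,n_cols Grid dimensions (circumferential rows, longitudinal
#'   columns). Default 8 x 8.
#' @param lid_cm Longitudinal inter-electrode distance in cm (default 2).
#' @param circumference_cm Forearm circumference in cm at the proximal
#'   placement line, or `NULL` if unknown.
#' @param length_cm Forearm length (lateral epicondyle to ulnar styloid) in
#'   cm, or `NULL`.
#' @param handedness `"right"` or `"left"`; mirrors the circumferential
#'   channel order for left arms.
#' @param start_offset_fraction Fraction of the forearm length from the elbow
#'   where the first electrode column sits (default 0.20).
#' @return An object of class `electrode_grid`.
#' @examples
#' g <- electrode_grid(circumference_cm = 27, length_cm = 26)
#' g$cid_cm # 27 / 8 = 3.375
#' channel_of(g, row = 0, col = 0) # channel 1
#' @export
electrode_grid <- function(n_rows = 8, n_cols = 8, lid_cm = 2,
                           circumference_cm = NULL, length_cm = NULL,
                           handedness = c("right", "left"),
                           start_offset_fraction = 0.20) {
  handedness <- match.arg(handedness)
  check_number(n_rows, "n_rows", lower = 2)
  check_number(n_cols, "n_cols", lower = 2)
  check_number(lid_cm, "lid_cm", lower = 0, allow_equal_lower = FALSE)
  if (!is.null(circumference_cm)) {
    check_number(circumference_cm, "circumference_cm", lower = 0,
                 allow_equal_lower = FALSE)
  }
  if (!is.null(length_cm)) {
    check_number(length_cm, "length_cm", lower = 0, allow_equal_lower = FALSE)
  }
  check_number(start_offset_fraction, "start_offset_fraction", 0, 1)

  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  # map[r, c] (1-based matrix indices) = channel at 0-based cell (r-1, c-1)
  map <- matrix(seq_len(n_rows * n_cols), nrow = n_rows, ncol = n_cols,
                byrow = TRUE)
  if (handedness == "left") {
    # mirror the circumferential direction, keeping the starting row
    map <- map[c(1L, rev(seq_len(n_rows)[-1L])), , drop = FALSE]
  }
  structure(
    list(
      n_rows = n_rows, n_cols = n_cols,
      lid_cm = lid_cm,
      cid_cm = if (is.null(circumference_cm)) NA_real_ else
        circumference_cm / n_rows,
      circumference_cm = circumference_cm %||% NA_real_,
      length_cm = length_cm %||% NA_real_,
      start_offset_fraction = start_offset_fraction,
      handedness = handedness,
      map = map
    ),
    class = "electrode_grid"
  )
}

#' @export
print.electrode_grid <- function(x, ...) {
  cat(sprintf("<electrode_grid> %d x %d (%s arm), LID %.3g cm, CID %s cm\n",
              x$n_rows, x$n_cols, x$handedness, x$lid_cm,
              if (is.na(x$cid_cm)) "?" else format(x$cid_cm, digits = 4)))
  invisible(x)
}

#' Build an electrode grid from forearm anthropometrics
#'
#' @param length_cm Forearm length in cm.
#' @param circumference_cm Forearm circumference in cm measured at 20% of the
#'   forearm length from the elbow.
#' @param handedness `"right"` (default) or `"left"`.
#' @return An `electrode_grid` with LID 2 cm and CID `circumference_cm / 8`.
#' @examples
#' grid_from_anthropometrics(26, 27)$cid_cm # 3.375
#' @export
grid_from_anthropometrics <- function(length_cm, circumference_cm,
                                      handedness = "right") {
  electrode_grid(circumference_cm = circumference_cm, length_cm = length_cm,
                 handedness = handedness)
}

#' Channel number at a grid cell
#'
#' @param grid An [electrode_grid()].
#' @param row,col Zero-based integer cell coordinates.
#' @return Integer channel number(s).
#' @export
channel_of <- function(grid, row, col) {
  stopifnot(inherits(grid, "electrode_grid"))
  if (any(row < 0 | row >= grid$n_rows | col < 0 | col >= grid$n_cols)) {
    stop_param("cell (%s, %s) outside the %d x %d grid",
               toString(row), toString(col), grid$n_rows, grid$n_cols)
  }
  grid$map[cbind(as.integer(row) + 1L, as.integer(col) + 1L)]
}

#' Grid cell of each channel
#'
#' @param grid An [electrode_grid()].
#' @return A tibble with one row per channel: `channel`, `row`, `col`
#'   (zero-based).
#' @export
cell_of <- function(grid) {
  stopifnot(inherits(grid, "electrode_grid"))
  idx <- arrayInd(order(grid$map), dim(grid$map))
  tibble::tibble(
    channel = sort(as.vector(grid$map)),
    row = idx[, 1] - 1L,
    col = idx[, 2] - 1L
  )
}

#' Neighboring channels of a grid cell
#'
#' The 8-neighborhood of a cell, wrapping circumferentially across rows (the
#' grid encircles the forearm) and truncating at the longitudinal extremes, so
#' cells in the first or last column have 5 neighbors.
#'
#' @param grid An [electrode_grid()].
#' @param row,col Zero-based integer cell coordinates.
#' @return A tibble of neighbor cells: `row`, `col`, `channel`.
#' @export
grid_neighbors <- function(grid, row, col) {
  stopifnot(inherits(grid, "electrode_grid"))
  dr <- rep(-1:1, times = 3)
  dc <- rep(-1:1, each = 3)
  keep <- !(dr == 0 & dc == 0)
  nr <- (row + dr[keep]) %% grid$n_rows
  nc <- col + dc[keep]
  ok <- nc >= 0 & nc < grid$n_cols
  tibble::tibble(
    row = nr[ok], col = nc[ok],
    channel = channel_of(grid, nr[ok], nc[ok])
  )
}

# per-channel amplitudes (length n_channels) from an 8x8 cell matrix
amps_by_channel <- function(grid, values) {
  out <- numeric(grid$n_rows * grid$n_cols)
  out[as.vector(grid$map)] <- as.vector(values)
  out
}

# 8x8 cell matrix from per-channel values
cells_from_channels <- function(grid, values) {
  matrix(values[as.vector(grid$map)], nrow = grid$n_rows, ncol = grid$n_cols)
}
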