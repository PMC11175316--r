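#' Imaging-grid specification
#'
#' Describes the mm-to-pixel mapping of the model space shared by target
#' maps, reconstructed maps and defect maps. The default field of view is
#' the instrument's standard acquisition window, a closed square extent of
#' \eqn{[-5, 5]} mm sampled at 1024 x 1024 pixels; wide-field imaging uses
#' \eqn{[-9.5, 9.5]} mm.
#'
#' Pixel centers sit at \code{extent_min + (i - 0.5) * pitch} for column /
#' row index \code{i = 1..n}, so the closed extent is covered symmetrically.
#' Millimetre coordinates are mapped to the nearest pixel center, with ties
#' broken toward +Inf.
#'
#' @param x_extent_mm,y_extent_mm length-2 numeric, closed extents in mm.
#' @param nx,ny pixel counts (>= 2).
#' @param wide_field if TRUE and extents are not given, both extents default
#'   to \code{c(-9.5, 9.5)}.
#' @return an object of class \code{grid_spec}.
#' @export
grid_spec <- function(x_extent_mm = NULL, y_extent_mm = NULL,
                      nx = 1024L, ny = 1024L, wide_field = FALSE) {
  default_extent <- if (wide_field) c(-9.5, 9.5) else c(-5, 5)
  if (is.null(x_extent_mm)) x_extent_mm <- default_extent
  if (is.null(y_extent_mm)) y_extent_mm <- default_extent
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(length(x_extent_mm) == 2, length(y_extent_mm) == 2,
            diff(x_extent_mm) > 0, diff(y_extent_mm) > 0,
            nx >= 2L, ny >= 2L)
  structure(
    list(x_extent_mm = as.numeric(x_extent_mm),
         y_extent_mm = as.numeric(y_extent_mm),
         nx = nx, ny = ny,
         pitch_x = diff(x_extent_mm) / nx,
         pitch_y = diff(y_extent_mm) / ny),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d px over x [%g, %g] mm, y [%g, %g] mm (pitch %.6g x %.6g mm/px)\n",
              x$nx, x$ny, x$x_extent_mm[1], x$x_extent_mm[2],
              x$y_extent_mm[1], x$y_extent_mm[2], x$pitch_x, x$pitch_y))
  invisible(x)
}

# nearest-center index; ties toward +Inf; clamped to [1, n]
.mm_to_index <- function(v, vmin, pitch, n) {
  idx <- floor((v - vmin) / pitch) + 1L
  pmin(pmax(as.integer(idx), 1L), n)
}

#' Convert millimetre coordinates to pixel indices
#'
#' @param grid a [grid_spec()].
#' @param x_mm,y_mm numeric vectors of coordinates in mm.
#' @return a tibble with integer columns \code{col} (x index) and \code{row}
#'   (y index); row 1 corresponds to the minimum-y edge of the extent.
#' @export
mm_to_pixel <- function(grid, x_mm, y_mm) {
  stopifnot(inherits(grid, "grid_spec"), length(x_mm) == length(y_mm))
  tibble::tibble(
    col = .mm_to_index(x_mm, grid$x_extent_mm[1], grid$pitch_x, grid$nx),
    row = .mm_to_index(y_mm, grid$y_extent_mm[1], grid$pitch_y, grid$ny))
}

#' Convert pixel indices to millimetre coordinates (pixel centers)
#'
#' @param grid a [grid_spec()].
#' @param col,row integer vectors of pixel indices.
#' @return a tibble with numeric columns \code{x_mm}, \code{y_mm}.
#' @export
pixel_to_mm <- function(grid, col, row) {
  stopifnot(inherits(grid, "grid_spec"), length(col) == length(row))
  tibble::tibble(
    x_mm = grid$x_extent_mm[1] + (col - 0.5) * grid$pitch_x,
    y_mm = grid$y_extent_mm[1] + (row - 0.5) * grid$pitch_y)
}

.same_grid <- function(a, b) {
  isTRUE(all.equal(a$x_extent_mm, b$x_extent_mm)) &&
    isTRUE(all.equal(a$y_extent_mm, b$y_extent_mm)) &&
    a$nx == b$nx && a$ny == b$ny
}
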