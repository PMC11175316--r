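#' OCT-style intensity volume
#'
#' Container for a 3D intensity volume as produced by swept-source OCT
#' after reconstruction: lateral axes x/y and an axial (depth) axis z. The
#' internal convention is depth-down: the axial index increases with depth
#' into the sample, so a taller deposit has a smaller first-surface index.
#' Volumes acquired with the opposite orientation are flipped on
#' construction.
#'
#' @param intensity numeric array, dim \code{c(ny, nx, nz)}, non-negative.
#' @param dz_mm axial pixel resolution (mm per axial pixel).
#' @param pitch_mm lateral pixel pitch (mm per lateral pixel).
#' @param depth_down TRUE if the axial index increases with depth (default);
#'   FALSE flips the volume along z.
#' @return object of class \code{oct_volume}.
#' @export
oct_volume <- function(intensity, dz_mm, pitch_mm = NA_real_, depth_down = TRUE) {
  stopifnot(length(dim(intensity)) == 3, dim(intensity)[3] >= 2, dz_mm > 0)
  if (!depth_down) intensity <- intensity[, , rev(seq_len(dim(intensity)[3])), drop = FALSE]
  structure(list(intensity = intensity, dz_mm = dz_mm, pitch_mm = pitch_mm),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("oct_volume: %d x %d lateral, %d axial px (dz = %g mm)\n",
              d[2], d[1], d[3], x$dz_mm))
  invisible(x)
}

#' Acquisition metadata for one print-imaging round
#'
#' @param round round index i (1-based).
#' @param z_set_height_px number of axial pixels by which the print
#'   platform has moved down since the base acquisition (>= 0).
#' @return a list of class \code{acquisition_meta}.
#' @export
acquisition_meta <- function(round = 1L, z_set_height_px = 0) {
  stopifnot(z_set_height_px >= 0)
  structure(list(round = as.integer(round),
                 z_set_height_px = as.numeric(z_set_height_px)),
            class = "acquisition_meta")
}

#' Detect the first surface in an OCT volume
#'
#' For every lateral column the axial intensity profile is smoothed with a
#' centred moving average and the shallowest axial index whose smoothed
#' intensity exceeds the threshold is recorded. Columns that never cross
#' the threshold are marked invalid (with a warning if that is every
#' column).
#'
#' @param volume an [oct_volume()].
#' @param threshold absolute intensity threshold; when NULL it defaults to
#'   \code{mean(I) + k * sd(I)} over the whole volume.
#' @param k multiplier for the default threshold.
#' @param smooth_window odd moving-average window length along z (1 =
#'   no smoothing).
#' @return object of class \code{surface_map}: list with
#'   \code{surface_z_px} (ny x nx, NA where invalid) and \code{valid}
#'   (logical ny x nx).
#' @export
detect_surface <- function(volume, threshold = NULL, k = 2, smooth_window = 3) {
  stopifnot(inherits(volume, "oct_volume"),
            smooth_window >= 1, smooth_window %% 2 == 1)
  vol <- volume$intensity
  ny <- dim(vol)[1]; nx <- dim(vol)[2]; nz <- dim(vol)[3]
  if (is.null(threshold))
    threshold <- mean(vol) + k * stats::sd(vol)
  M <- matrix(aperm(vol, c(3, 1, 2)), nz, ny * nx)
  if (smooth_window > 1) {
    r <- (smooth_window - 1L) / 2L
    # centred moving average along z, borders replicated
    M <- Reduce(`+`, lapply(-r:r, function(o)
      M[pmin(pmax(seq_len(nz) + o, 1L), nz), , drop = FALSE])) / smooth_window
  }
  L <- M > threshold
  f <- rep(NA_integer_, ny * nx)
  for (kk in rev(seq_len(nz))) f[L[kk, ]] <- kk
  surface <- matrix(as.numeric(f), ny, nx)
  valid <- !is.na(surface)
  if (!any(valid))
    warning("no column crossed the surface-detection threshold", call. = FALSE)
  structure(list(surface_z_px = surface, valid = valid, nz = nz),
            class = "surface_map")
}

#' Reconstructed printed-thickness map
#'
#' Wraps a per-pixel printed-thickness field (mm). Use this constructor
#' directly when thickness maps are already available (e.g. precomputed
#' height maps); [compute_thickness()] builds one from surface maps.
#'
#' @param thickness_mm ny x nx numeric matrix of printed thickness (mm).
#' @param grid optional [grid_spec()].
#' @param valid logical matrix of valid columns (default: all finite).
#' @param round round index.
#' @param dz_mm axial resolution the map was derived at (NA if unknown).
#' @param n_negative_clipped count of negative thickness values clipped to
#'   zero during reconstruction.
#' @return object of class \code{recon_model_map}.
#' @export
recon_model_map <- function(thickness_mm, grid = NULL, valid = NULL,
                            round = 1L, dz_mm = NA_real_,
                            n_negative_clipped = 0L) {
  stopifnot(is.matrix(thickness_mm))
  if (is.null(valid)) valid <- is.finite(thickness_mm)
  structure(list(thickness = thickness_mm, grid = grid, valid = valid,
                 round = as.integer(round), dz_mm = dz_mm,
                 n_negative_clipped = as.integer(n_negative_clipped)),
            class = "recon_model_map")
}

#' @export
print.recon_model_map <- function(x, ...) {
  cat(sprintf("recon_model_map: round %d, %d x %d px, thickness %.3g-%.3g mm (%d invalid, %d clipped)\n",
              x$round, nrow(x$thickness), ncol(x$thickness),
              min(x$thickness, na.rm = TRUE), max(x$thickness, na.rm = TRUE),
              sum(!x$valid), x$n_negative_clipped))
  invisible(x)
}

#' Printed thickness from surface maps
#'
#' Converts a print-round surface map and the base-platform surface map to
#' printed thickness per pixel:
#' \deqn{Thickness = (Z_{base} + Z_{set} - Z_{print}) \cdot \Delta Z}
#' where all Z are axial pixel indices, \eqn{Z_{set}} is the platform
#' descent since the base acquisition in pixels, and \eqn{\Delta Z} is the
#' axial resolution in mm. Referencing every column to its own base index
#' cancels base-plate unevenness. Negative thickness (surface detected
#' below base + descent, i.e. a registration error) is clipped to 0 and
#' counted.
#'
#' @param print_surface,base [detect_surface()] results of the print round
#'   and of the bare platform.
#' @param meta an [acquisition_meta()] (or a number, taken as
#'   \code{z_set_height_px}).
#' @param dz_mm axial resolution (mm per axial pixel).
#' @param grid optional [grid_spec()] carried into the result.
#' @return a [recon_model_map()]; invalid columns propagate as NA
#'   thickness with \code{valid = FALSE}.
#' @export
compute_thickness <- function(print_surface, base, meta, dz_mm, grid = NULL) {
  stopifnot(inherits(print_surface, "surface_map"), inherits(base, "surface_map"))
  if (!all(dim(print_surface$surface_z_px) == dim(base$surface_z_px)))
    stop("print and base surface maps have different lateral shapes", call. = FALSE)
  if (is.numeric(meta)) meta <- acquisition_meta(z_set_height_px = meta)
  th <- (base$surface_z_px + meta$z_set_height_px - print_surface$surface_z_px) * dz_mm
  valid <- print_surface$valid & base$valid
  th[!valid] <- NA_real_
  neg <- valid & th < 0
  th[neg] <- 0
  recon_model_map(th, grid = grid, valid = valid, round = meta$round,
                  dz_mm = dz_mm, n_negative_clipped = sum(neg))
}

#' Accumulate per-round thickness maps into cumulative printed height
#'
#' @param maps list of [recon_model_map()] with strictly increasing round
#'   indices, on a shared grid.
#' @return list with \code{cumulative} (ny x nx mm matrix; invalid columns
#'   contribute 0), \code{valid} (columns valid in every round), and
#'   \code{rounds} (the input maps, retained for per-layer analysis).
#' @export
accumulate_rounds <- function(maps) {
  stopifnot(length(maps) >= 1,
            all(vapply(maps, inherits, logical(1), "recon_model_map")))
  rounds <- vapply(maps, function(m) m$round, integer(1))
  if (any(diff(rounds) <= 0))
    stop("round indices must be strictly increasing", call. = FALSE)
  cum <- matrix(0, nrow(maps[[1]]$thickness), ncol(maps[[1]]$thickness))
  valid <- matrix(TRUE, nrow(cum), ncol(cum))
  for (m in maps) {
    t <- m$thickness
    t[!m$valid] <- 0
    cum <- cum + t
    valid <- valid & m$valid
  }
  list(cumulative = cum, valid = valid, rounds = maps)
}

#' Extract a 1D profile along a row or column
#'
#' @param x a matrix, [recon_model_map()], or \code{target_model_map}
#'   (thickness field used).
#' @param row,col give exactly one: the pixel row (profile along x) or
#'   column (profile along y).
#' @param grid optional [grid_spec()] to add mm positions.
#' @return tibble with \code{index}, \code{value}, and \code{position_mm}
#'   when a grid is available.
#' @export
extract_cross_section <- function(x, row = NULL, col = NULL, grid = NULL) {
  m <- if (is.matrix(x)) x else x$thickness
  if (is.null(grid) && !is.matrix(x)) grid <- x$grid
  if (is.null(row) == is.null(col))
    stop("give exactly one of 'row' or 'col'", call. = FALSE)
  if (!is.null(row)) {
    v <- m[row, ]
    out <- tibble::tibble(index = seq_len(ncol(m)), value = as.numeric(v))
    if (!is.null(grid)) out$position_mm <- pixel_to_mm(grid, out$index, rep(row, nrow(out)))$x_mm
  } else {
    v <- m[, col]
    out <- tibble::tibble(index = seq_len(nrow(m)), value = as.numeric(v))
    if (!is.null(grid)) out$position_mm <- pixel_to_mm(grid, rep(col, nrow(out)), out$index)$y_mm
  }
  out
}
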