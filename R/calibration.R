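#' Filament-geometry calibration table
#'
#' Maps print parameters (speed, pressure) to the expected deposited
#' filament width and height. On the instrument this relationship comes
#' from a pre-print calibration experiment; here it is supplied by the user
#' as a table. Lookups at an exact table point return the tabulated pair;
#' other queries are interpolated according to \code{mode} and clamped to
#' the table's range.
#'
#' @param speed_mm_s,pressure_mpa,width_mm,height_mm parallel numeric
#'   vectors, one entry per calibrated operating point.
#' @param mode \code{"linear"} (piecewise-linear, clamped) or
#'   \code{"nearest"}.
#' @return a tibble of class \code{calibration_table}.
#' @export
calibration_table <- function(speed_mm_s, pressure_mpa, width_mm, height_mm,
                              mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(length(speed_mm_s) >= 1,
            all(width_mm > 0), all(height_mm > 0), all(speed_mm_s > 0))
  out <- tibble::tibble(speed_mm_s = as.numeric(speed_mm_s),
                        pressure_mpa = as.numeric(pressure_mpa),
                        width_mm = as.numeric(width_mm),
                        height_mm = as.numeric(height_mm))
  attr(out, "mode") <- mode
  class(out) <- c("calibration_table", class(out))
  out
}

#' Default calibration from nozzle geometry
#'
#' When no calibration table is available, the deposited filament is taken
#' to have the nozzle's inner diameter as width and the programmed layer
#' thickness as height — the nominal geometry used for every configuration
#' in routine printing.
#'
#' @param nozzle_diameter_mm nozzle inner diameter.
#' @param layer_thickness_mm programmed layer thickness.
#' @return a single-entry [calibration_table()].
#' @export
default_calibration <- function(nozzle_diameter_mm, layer_thickness_mm) {
  calibration_table(speed_mm_s = 10, pressure_mpa = NA_real_,
                    width_mm = nozzle_diameter_mm,
                    height_mm = layer_thickness_mm, mode = "nearest")
}

.interp_1d <- function(xq, x, y) {
  if (length(unique(x)) == 1) return(y[1])
  o <- order(x)
  stats::approx(x[o], y[o], xout = xq, rule = 2, ties = mean)$y
}

#' Look up filament geometry for given print parameters
#'
#' @param speed_mm_s,pressure_mpa query operating point.
#' @param table a [calibration_table()].
#' @return named numeric vector \code{c(width_mm=, height_mm=)}.
#' @export
lookup_filament_geometry <- function(speed_mm_s, pressure_mpa, table) {
  if (is.null(table) || nrow(table) == 0)
    stop("calibration table is empty", call. = FALSE)
  exact <- which(table$speed_mm_s == speed_mm_s &
                 (is.na(pressure_mpa) | is.na(table$pressure_mpa) |
                    table$pressure_mpa == pressure_mpa))
  if (length(exact) > 0) {
    i <- exact[1]
    return(c(width_mm = table$width_mm[i], height_mm = table$height_mm[i]))
  }
  if (nrow(table) == 1)
    return(c(width_mm = table$width_mm[1], height_mm = table$height_mm[1]))
  mode <- attr(table, "mode") %||% "linear"
  if (mode == "nearest" || is.na(pressure_mpa) ||
      length(unique(table$pressure_mpa)) == 1) {
    if (mode == "nearest") {
      # scale-normalized nearest neighbour over (speed, pressure)
      ds <- (table$speed_mm_s - speed_mm_s) / max(diff(range(table$speed_mm_s)), 1e-9)
      dp <- if (is.na(pressure_mpa) || all(is.na(table$pressure_mpa))) 0 else
        (table$pressure_mpa - pressure_mpa) / max(diff(range(table$pressure_mpa)), 1e-9)
      i <- which.min(ds^2 + dp^2)
      return(c(width_mm = table$width_mm[i], height_mm = table$height_mm[i]))
    }
    return(c(width_mm = .interp_1d(speed_mm_s, table$speed_mm_s, table$width_mm),
             height_mm = .interp_1d(speed_mm_s, table$speed_mm_s, table$height_mm)))
  }
  # bilinear: interpolate over speed within each pressure level, then over pressure
  levels <- sort(unique(table$pressure_mpa))
  w_at <- vapply(levels, function(p) {
    sub <- table[table$pressure_mpa == p, ]
    .interp_1d(speed_mm_s, sub$speed_mm_s, sub$width_mm)
  }, numeric(1))
  h_at <- vapply(levels, function(p) {
    sub <- table[table$pressure_mpa == p, ]
    .interp_1d(speed_mm_s, sub$speed_mm_s, sub$height_mm)
  }, numeric(1))
  c(width_mm = .interp_1d(pressure_mpa, levels, w_at),
    height_mm = .interp_1d(pressure_mpa, levels, h_at))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
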