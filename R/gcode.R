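#' GCode dialect description
#'
#' The toolpath source is plain line-oriented GCode with motion words
#' \code{G0}/\code{G1} carrying \code{X}/\code{Y}/\code{Z}/\code{F} words.
#' Extrusion state is encoded either through an \code{E} word (a positive
#' E delta on a motion line means the filament advances; a negative delta is
#' a retraction) or through paired start/stop command codes emitted between
#' motion lines. Print pressure is not a GCode word: it is set per job in
#' the configuration and attached to every segment.
#'
#' @param extrusion one of \code{"auto"} (use E deltas when any E word is
#'   present, else command codes), \code{"e_delta"}, or \code{"commands"}.
#' @param extrude_on,extrude_off command codes that switch extrusion on/off
#'   in \code{"commands"} mode.
#' @return a list describing the dialect.
#' @export
gcode_dialect <- function(extrusion = c("auto", "e_delta", "commands"),
                          extrude_on = "M101", extrude_off = "M103") {
  list(extrusion = match.arg(extrusion),
       extrude_on = toupper(extrude_on), extrude_off = toupper(extrude_off))
}

.parse_words <- function(body, lineno) {
  words <- strsplit(trimws(body), "\\s+")[[1]]
  words <- words[nzchar(words)]
  out <- list()
  for (w in words) {
    letter <- toupper(substr(w, 1, 1))
    value <- substr(w, 2, nchar(w))
    if (letter %in% c("X", "Y", "Z", "F", "E")) {
      num <- suppressWarnings(as.numeric(value))
      if (is.na(num))
        stop(sprintf("malformed coordinate word '%s' on line %d", w, lineno),
             call. = FALSE)
      out[[letter]] <- num
    }
  }
  out
}

#' Parse GCode into print segments
#'
#' Walks a GCode program line by line, tracking modal state (current
#' position, Z, feed rate, extrusion flag) and emitting one segment per
#' motion line that moves from a previously established position. Feed
#' rates (\code{F}, mm/min) are converted to mm/s. Comments introduced by
#' \code{;} are stripped.
#'
#' @param text character: either a single string (possibly with newlines),
#'   a character vector of lines, or a file path to a .gcode file.
#' @param dialect a [gcode_dialect()].
#' @param pressure_mpa print pressure attached to every segment (one
#'   pressure per job, as set on the machine); NA if unknown.
#' @return a tibble with one row per motion segment: \code{line},
#'   \code{x0}, \code{y0}, \code{x1}, \code{y1} (mm), \code{z_mm},
#'   \code{speed_mm_s}, \code{pressure_mpa}, \code{extruding}.
#' @export
parse_gcode <- function(text, dialect = gcode_dialect(), pressure_mpa = NA_real_) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)

  use_e <- switch(dialect$extrusion,
    e_delta = TRUE,
    commands = FALSE,
    auto = any(grepl("(^|\\s)[Ee]-?[0-9.]", sub(";.*$", "", lines))))

  pos <- c(NA_real_, NA_real_)   # current x, y
  z <- NA_real_; feed <- NA_real_; e_pos <- 0
  extrude_cmd_state <- FALSE
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    body <- sub(";.*$", "", lines[i])
    body <- trimws(body)
    if (!nzchar(body)) next
    code <- toupper(strsplit(body, "\\s+")[[1]][1])
    if (!use_e) {
      if (code == dialect$extrude_on) { extrude_cmd_state <- TRUE; next }
      if (code == dialect$extrude_off) { extrude_cmd_state <- FALSE; next }
    }
    if (!code %in% c("G0", "G1", "G00", "G01")) next
    w <- .parse_words(sub("^\\S+", "", body), i)
    if (!is.null(w$Z)) z <- w$Z
    if (!is.null(w$F)) feed <- w$F
    new_pos <- c(if (!is.null(w$X)) w$X else pos[1],
                 if (!is.null(w$Y)) w$Y else pos[2])
    moved_xy <- (!is.null(w$X) || !is.null(w$Y))
    if (moved_xy && is.na(z))
      stop(sprintf("motion on line %d before any Z coordinate is set", i),
           call. = FALSE)
    if (use_e) {
      e_delta <- if (is.null(w$E)) 0 else w$E - e_pos
      if (!is.null(w$E)) e_pos <- w$E
      extruding <- code %in% c("G1", "G01") && e_delta > 0
    } else {
      extruding <- code %in% c("G1", "G01") && extrude_cmd_state
    }
    if (moved_xy && !anyNA(pos)) {
      rows[[i]] <- tibble::tibble(
        line = i, x0 = pos[1], y0 = pos[2], x1 = new_pos[1], y1 = new_pos[2],
        z_mm = z, speed_mm_s = feed / 60, pressure_mpa = pressure_mpa,
        extruding = extruding)
    }
    pos <- new_pos
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    out <- tibble::tibble(line = integer(), x0 = numeric(), y0 = numeric(),
                          x1 = numeric(), y1 = numeric(), z_mm = numeric(),
                          speed_mm_s = numeric(), pressure_mpa = numeric(),
                          extruding = logical())
  out
}

#' Group print segments into layers
#'
#' Partitions segments by Z coordinate: segments whose Z differs from a
#' layer's reference Z by less than half the layer thickness belong to that
#' layer. Layers are ordered by ascending Z and given ordinals 1..K.
#'
#' @param segments a segment tibble from [parse_gcode()].
#' @param layer_thickness_mm nominal layer thickness, used for the grouping
#'   tolerance (|dz| < thickness/2).
#' @return the segment tibble with added integer column \code{layer} and a
#'   \code{z_mm} snapped to the layer reference Z, ordered by layer.
#' @export
group_layers <- function(segments, layer_thickness_mm = 0.25) {
  if (nrow(segments) == 0) {
    segments$layer <- integer()
    return(segments)
  }
  tol <- layer_thickness_mm / 2
  zs <- sort(unique(segments$z_mm))
  ref <- zs[1]; z_ref <- numeric(length(zs)); z_ref[1] <- ref
  for (i in seq_along(zs)[-1]) {
    if (zs[i] - ref >= tol) ref <- zs[i]
    z_ref[i] <- ref
  }
  segments$z_layer <- z_ref[match(segments$z_mm, zs)]
  refs <- sort(unique(segments$z_layer))
  segments$layer <- match(segments$z_layer, refs)
  segments <- dplyr::arrange(segments, .data$layer, .data$line)
  segments$z_mm <- segments$z_layer
  segments$z_layer <- NULL
  segments
}
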