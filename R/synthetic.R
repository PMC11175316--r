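#' Defect specification for the scaffold simulator
#'
#' Describes the defects injected into a simulated print of one layer:
#' breakage gaps and under-/over-extrusion stretches as arc-length
#' intervals along the toolpath centerline, accumulation blobs (radially
#' tapered extra height, typically at path turnarounds), and stringing
#' threads (thin out-of-path polylines). Identical seeds give identical
#' rendered outputs.
#'
#' @param breakage tibble/data.frame with \code{start_mm}, \code{end_mm}
#'   (arc intervals along the centerline).
#' @param under,over tibble with \code{start_mm}, \code{end_mm},
#'   \code{scale} (thickness scale factor, > 0).
#' @param blobs tibble with \code{x_mm}, \code{y_mm}, \code{radius_mm},
#'   \code{extra_mm}.
#' @param threads list of tibbles with \code{x_mm}, \code{y_mm} polyline
#'   vertices plus attributes via columns-free arguments; each list
#'   element may carry \code{thickness_mm} and \code{width_mm} attributes
#'   (defaults 0.12 / 0.08).
#' @param seed random seed for noise rendering.
#' @return list of class \code{defect_spec}.
#' @export
defect_spec <- function(breakage = NULL, under = NULL, over = NULL,
                        blobs = NULL, threads = NULL, seed = 1L) {
  as_tbl <- function(x, cols) {
    if (is.null(x)) return(tibble::as_tibble(stats::setNames(
      rep(list(numeric()), length(cols)), cols)))
    x <- tibble::as_tibble(x)
    stopifnot(all(cols %in% names(x)))
    x
  }
  spec <- list(breakage = as_tbl(breakage, c("start_mm", "end_mm")),
               under = as_tbl(under, c("start_mm", "end_mm", "scale")),
               over = as_tbl(over, c("start_mm", "end_mm", "scale")),
               blobs = as_tbl(blobs, c("x_mm", "y_mm", "radius_mm", "extra_mm")),
               threads = threads %||% list(),
               seed = as.integer(seed))
  stopifnot(all(spec$under$scale > 0), all(spec$over$scale > 0),
            all(spec$breakage$end_mm > spec$breakage$start_mm))
  class(spec) <- "defect_spec"
  spec
}

# arc position of the owning centerline pixel, NA off-path
.owner_arc <- function(target) {
  arc <- matrix(NA_real_, target$grid$ny, target$grid$nx)
  on <- which(target$owner > 0L)
  arc[on] <- target$centerline$arc_mm[target$owner[on]]
  arc
}

#' Render a defect-injected height map from a target model map
#'
#' The filament is rendered as the target footprint at target thickness
#' (a flat-topped cross-section), then defects are injected: breakage
#' intervals are zeroed, under-/over-extrusion intervals scaled,
#' accumulation blobs added as radially tapered extra height restricted to
#' the path, and stringing threads painted off-path. Arc intervals act on
#' the pixels owned (nearest-centerline) by centerline points inside the
#' interval, so the induced centerline defect run has exactly the
#' injected arc length (to one pixel).
#'
#' @param target a \code{target_model_map}.
#' @param spec a [defect_spec()].
#' @return list of class \code{synthetic_print}: \code{height} (ny x nx
#'   mm), \code{truth} — a ground-truth list with \code{labels} (integer
#'   code matrix), \code{centerline_codes}, \code{runs} (tibble of
#'   injected in-path defect runs with class/arc interval/endpoints), and
#'   \code{spec}.
#' @export
render_heightmap <- function(target, spec = defect_spec()) {
  stopifnot(inherits(target, "target_model_map"))
  h <- target$thickness
  g <- target$grid
  cl <- target$centerline
  total_arc <- if (nrow(cl)) max(cl$arc_mm) else 0
  arc_px <- .owner_arc(target)

  check_interval <- function(s, e) {
    if (any(s < 0) || any(e > total_arc + 1e-9))
      stop(sprintf("defect interval outside path arc length (0..%.3f mm)",
                   total_arc), call. = FALSE)
  }
  # a centerline pixel covers [arc - pitch/2, arc + pitch/2] of path; select
  # pixels whose footprint overlaps the interval so the induced run length
  # matches the injected length to within one pixel
  half <- g$pitch_x / 2
  apply_interval <- function(h, s, e, f) {
    sel <- !is.na(arc_px) & arc_px >= s - half & arc_px <= e + half
    h[sel] <- f(h[sel])
    h
  }
  check_interval(spec$breakage$start_mm, spec$breakage$end_mm)
  check_interval(spec$under$start_mm, spec$under$end_mm)
  check_interval(spec$over$start_mm, spec$over$end_mm)
  for (i in seq_len(nrow(spec$breakage)))
    h <- apply_interval(h, spec$breakage$start_mm[i], spec$breakage$end_mm[i],
                        function(v) 0)
  for (i in seq_len(nrow(spec$under)))
    h <- apply_interval(h, spec$under$start_mm[i], spec$under$end_mm[i],
                        function(v) v * spec$under$scale[i])
  for (i in seq_len(nrow(spec$over)))
    h <- apply_interval(h, spec$over$start_mm[i], spec$over$end_mm[i],
                        function(v) v * spec$over$scale[i])

  if (nrow(spec$blobs)) {
    xy <- pixel_to_mm(g, rep(seq_len(g$nx), each = g$ny),
                      rep(seq_len(g$ny), times = g$nx))
    X <- matrix(xy$x_mm, g$ny, g$nx); Y <- matrix(xy$y_mm, g$ny, g$nx)
    for (i in seq_len(nrow(spec$blobs))) {
      d <- sqrt((X - spec$blobs$x_mm[i])^2 + (Y - spec$blobs$y_mm[i])^2)
      sel <- target$path_mask & d <= spec$blobs$radius_mm[i]
      h[sel] <- h[sel] + spec$blobs$extra_mm[i] *
        (1 - (d[sel] / spec$blobs$radius_mm[i])^2)
    }
  }

  thread_mask <- matrix(FALSE, g$ny, g$nx)
  for (th in spec$threads) {
    t_mm <- attr(th, "thickness_mm") %||%
      (if ("thickness_mm" %in% names(th)) th$thickness_mm[1] else NULL) %||% 0.12
    w_mm <- attr(th, "width_mm") %||%
      (if ("width_mm" %in% names(th)) th$width_mm[1] else NULL) %||% 0.08
    r_px <- max(0L, as.integer(round(w_mm / (2 * g$pitch_x))))
    px <- mm_to_pixel(g, th$x_mm, th$y_mm)
    pts <- NULL
    for (j in seq_len(nrow(px) - 1))
      pts <- rbind(pts, bresenham_points(c(px$col[j], px$row[j]),
                                         c(px$col[j + 1], px$row[j + 1]), g))
    m <- matrix(FALSE, g$ny, g$nx)
    o <- .disc_offsets(r_px)
    for (j in seq_len(nrow(pts))) {
      cc <- pts$col[j] + o$dc; rr <- pts$row[j] + o$dr
      keep <- cc >= 1L & cc <= g$nx & rr >= 1L & rr <= g$ny
      m[rr[keep] + (cc[keep] - 1L) * g$ny] <- TRUE
    }
    m <- m & !target$path_mask   # threads live outside the path
    h[m] <- pmax(h[m], t_mm)
    thread_mask <- thread_mask | m
  }

  # ground truth: in-path labels from the true heights along the centerline,
  # propagated laterally; stringing at thread pixels
  codes <- integer(nrow(cl))
  labels <- matrix(0L, g$ny, g$nx)
  if (nrow(cl)) {
    lin <- cl$row + (cl$col - 1L) * g$ny
    codes <- .classify_thickness(h[lin], target$thickness[lin],
                                 tolerance_mm = 0.05, zero_eps_mm = 1e-9)
    on_path <- which(target$path_mask)
    labels[on_path] <- codes[target$owner[on_path]]
  }
  labels[thread_mask] <- 5L

  runs <- .truth_runs(spec, target)
  structure(list(height = h,
                 truth = list(labels = labels, centerline_codes = codes,
                              thread_mask = thread_mask, runs = runs),
                 spec = spec, target = target),
            class = "synthetic_print")
}

# injected in-path runs (class, arc interval, endpoint coordinates)
.truth_runs <- function(spec, target) {
  cl <- target$centerline
  one <- function(tbl, class) {
    if (nrow(tbl) == 0) return(NULL)
    purrr::map_dfr(seq_len(nrow(tbl)), function(i) {
      i0 <- which.min(abs(cl$arc_mm - tbl$start_mm[i]))
      i1 <- which.min(abs(cl$arc_mm - tbl$end_mm[i]))
      p0 <- pixel_to_mm(target$grid, cl$col[i0], cl$row[i0])
      p1 <- pixel_to_mm(target$grid, cl$col[i1], cl$row[i1])
      tibble::tibble(class = class,
                     start_mm = tbl$start_mm[i], end_mm = tbl$end_mm[i],
                     length_mm = tbl$end_mm[i] - tbl$start_mm[i],
                     x0_mm = p0$x_mm, y0_mm = p0$y_mm,
                     x1_mm = p1$x_mm, y1_mm = p1$y_mm)
    })
  }
  dplyr::bind_rows(one(spec$breakage, "filament_breakage"),
                   one(spec$under, "under_extrusion"),
                   one(spec$over, "over_extrusion"))
}

#' Render an OCT-style volume from a height map
#'
#' Emulates the acquisition geometry: every lateral column is filled with
#' high intensity from its first-surface index downward and low background
#' intensity above it. The surface index is the inverse of the thickness
#' relation: \code{round(base + descent - height/dz)}, so surface
#' detection plus thickness computation recovers the height field up to dz
#' quantization. The base profile may be tilted or uneven to exercise the
#' base-referencing correction. Optional multiplicative speckle
#' (gamma-distributed, mean 1) emulates OCT intensity noise.
#'
#' @param height ny x nx height field (mm) or a \code{synthetic_print}.
#' @param base_px base-platform surface index: scalar or ny x nx matrix.
#' @param dz_mm axial resolution.
#' @param z_set_height_px platform descent since base acquisition (px).
#' @param nz axial size; default fits the deepest surface plus margin.
#' @param noise NULL for noiseless, or list(shape =) for multiplicative
#'   gamma speckle with the given shape (larger = less noise).
#' @param background,signal intensity levels.
#' @param seed seed for the noise draw (defaults to the spec seed for a
#'   \code{synthetic_print}).
#' @param round round index stored in the metadata.
#' @return list with \code{volume} ([oct_volume()]) and \code{meta}
#'   ([acquisition_meta()]).
#' @export
render_volume <- function(height, base_px = 100, dz_mm = 0.01,
                          z_set_height_px = 0, nz = NULL, noise = NULL,
                          background = 0.05, signal = 1,
                          seed = NULL, round = 1L) {
  if (inherits(height, "synthetic_print")) {
    if (is.null(seed)) seed <- height$spec$seed
    height <- height$height
  }
  if (is.null(seed)) seed <- 1L
  stopifnot(is.matrix(height))
  ny <- nrow(height); nx <- ncol(height)
  if (length(base_px) == 1) base_px <- matrix(base_px, ny, nx)
  surf <- round(base_px + z_set_height_px - height / dz_mm)
  if (any(surf < 1))
    stop("height exceeds volume depth: surface index above the first axial pixel",
         call. = FALSE)
  if (is.null(nz)) nz <- max(surf) + 5L
  if (any(surf > nz))
    stop("base + descent exceeds the axial size nz", call. = FALSE)
  vol <- array(background, c(ny, nx, nz))
  for (k in seq_len(nz)) {
    sel <- surf <= k
    if (any(sel)) {
      plane <- vol[, , k]
      plane[sel] <- signal
      vol[, , k] <- plane
    }
  }
  if (!is.null(noise)) {
    shape <- noise$shape %||% 16
    set.seed(seed)
    vol <- vol * array(stats::rgamma(length(vol), shape = shape,
                                     rate = shape), dim(vol))
  }
  list(volume = oct_volume(vol, dz_mm = dz_mm),
       meta = acquisition_meta(round = round,
                               z_set_height_px = z_set_height_px))
}

# Liang-Barsky clipping of segment (x0,y0)-(x1,y1) to rect [xmin,xmax]x[ymin,ymax]
.clip_segment <- function(x0, y0, x1, y1, xmin, xmax, ymin, ymax) {
  dx <- x1 - x0; dy <- y1 - y0
  p <- c(-dx, dx, -dy, dy)
  q <- c(x0 - xmin, xmax - x0, y0 - ymin, ymax - y0)
  t0 <- 0; t1 <- 1
  for (i in 1:4) {
    if (p[i] == 0) { if (q[i] < 0) return(NULL) } else {
      t <- q[i] / p[i]
      if (p[i] < 0) t0 <- max(t0, t) else t1 <- min(t1, t)
    }
  }
  if (t0 > t1) return(NULL)
  c(x0 + t0 * dx, y0 + t0 * dy, x0 + t1 * dx, y0 + t1 * dy)
}

# serpentine GCode over given pass y-positions
.serpentine_gcode <- function(x_range, y_pass, z, feed_straight, feed_turn,
                              dialect = gcode_dialect()) {
  lines <- c(sprintf("G0 X%g Y%g Z%g F%g", x_range[1], y_pass[1], z,
                     feed_straight), dialect$extrude_on)
  left <- FALSE   # after first pass nozzle is at x_range[2]
  for (i in seq_along(y_pass)) {
    xe <- if (left) x_range[1] else x_range[2]
    lines <- c(lines, sprintf("G1 X%g Y%g F%g", xe, y_pass[i], feed_straight))
    if (i < length(y_pass))
      lines <- c(lines, sprintf("G1 X%g Y%g F%g", xe, y_pass[i + 1], feed_turn))
    left <- !left
  }
  c(lines, dialect$extrude_off)
}

# hatch segments at given angle (deg) and spacing inside a rectangle
.hatch_segments <- function(xmin, xmax, ymin, ymax, angle_deg, spacing) {
  a <- angle_deg * pi / 180
  dir <- c(cos(a), sin(a))
  nrm <- c(-dir[2], dir[1])
  corners <- rbind(c(xmin, ymin), c(xmax, ymin), c(xmin, ymax), c(xmax, ymax))
  proj <- corners %*% nrm
  offs <- seq(min(proj) + spacing / 2, max(proj) - spacing / 4, by = spacing)
  L <- 2 * sqrt((xmax - xmin)^2 + (ymax - ymin)^2)
  segs <- list()
  for (o in offs) {
    c0 <- o * nrm
    s <- .clip_segment(c0[1] - L * dir[1], c0[2] - L * dir[2],
                       c0[1] + L * dir[1], c0[2] + L * dir[2],
                       xmin, xmax, ymin, ymax)
    if (!is.null(s)) segs[[length(segs) + 1]] <- s
  }
  segs
}

.hatch_gcode <- function(segs, z, feed, dialect = gcode_dialect()) {
  lines <- character()
  flip <- FALSE
  for (s in segs) {
    if (flip) s <- s[c(3, 4, 1, 2)]
    lines <- c(lines,
               sprintf("G0 X%g Y%g Z%g F%g", s[1], s[2], z, feed),
               dialect$extrude_on,
               sprintf("G1 X%g Y%g F%g", s[3], s[4], feed),
               dialect$extrude_off)
    flip <- !flip
  }
  lines
}

#' Built-in simulation scenarios
#'
#' Small, scaled-down print programs in the spirit of the validation
#' models, with their print parameters:
#' \describe{
#'   \item{minimal_line}{one 9 mm segment, no defects (HAP parameters:
#'     0.41 mm nozzle, 0.18 MPa, 0.25 mm layer, 10 mm/s).}
#'   \item{gradient_scaffold}{a serpentine with monotonically increasing
#'     pass spacing (1.0 to 2.0 mm) over 9 x 9 mm, straight passes at
#'     10 mm/s and turnarounds at 12 mm/s; default defect spec injects a
#'     3.6 mm breakage, a 1.2 mm control gap, a 2 mm under-extrusion
#'     stretch, one turnaround accumulation blob and one stringing
#'     thread.}
#'   \item{nose_like}{a closed irregular contour with two small inner
#'     loops (silicone parameters: 0.21 mm nozzle, 0.15 MPa, 0.18 mm
#'     layer, 10 mm/s).}
#'   \item{ear_like_90, ear_like_60}{identical rectangular outlines with
#'     90 or 60 degree hatch infill (PCL parameters: 0.15 mm nozzle,
#'     0.55 MPa, 0.18 mm layer, 2 mm/s).}
#' }
#'
#' @param name scenario name.
#' @param nx,ny grid size for the scenario's grid (default 256, matching
#'   the reduced desk-scale fixtures).
#' @return list of class \code{print_scenario}: \code{name}, \code{gcode}
#'   (character lines), \code{grid}, \code{config} (list of print
#'   parameters), \code{spec} (default [defect_spec()]).
#' @export
scenario_fixtures <- function(name, nx = 256L, ny = nx) {
  valid <- c("minimal_line", "gradient_scaffold", "nose_like",
             "ear_like_90", "ear_like_60")
  if (!name %in% valid)
    stop(sprintf("unknown scenario '%s'; valid names: %s", name,
                 paste(valid, collapse = ", ")), call. = FALSE)
  grid <- grid_spec(nx = nx, ny = ny)
  hap <- list(nozzle_diameter_mm = 0.41, pressure_mpa = 0.18,
              layer_thickness_mm = 0.25, speed_mm_s = 10, turn_speed_mm_s = 12)
  sil <- list(nozzle_diameter_mm = 0.21, pressure_mpa = 0.15,
              layer_thickness_mm = 0.18, speed_mm_s = 10, turn_speed_mm_s = 10)
  pcl <- list(nozzle_diameter_mm = 0.15, pressure_mpa = 0.55,
              layer_thickness_mm = 0.18, speed_mm_s = 2, turn_speed_mm_s = 2,
              temperature_c = 130)
  gc <- switch(name,
    minimal_line = c("; minimal_line: one 9 mm segment",
                     "G0 X-4.5 Y0 Z0.25 F600", "M101",
                     "G1 X4.5 Y0 F600", "M103"),
    gradient_scaffold = {
      y <- -4.5 + cumsum(c(0, 1.0, 1.2, 1.4, 1.6, 1.8, 2.0))
      c("; gradient_scaffold: serpentine, increasing pass spacing",
        .serpentine_gcode(c(-4.5, 4.5), y, z = 0.25,
                          feed_straight = hap$speed_mm_s * 60,
                          feed_turn = hap$turn_speed_mm_s * 60))
    },
    nose_like = {
      outline <- rbind(c(0, 4.2), c(2.2, 1.2), c(2.8, -1.8), c(1.6, -3.4),
                       c(0, -3.8), c(-1.6, -3.4), c(-2.8, -1.8),
                       c(-2.2, 1.2), c(0, 4.2))
      loop <- function(cx, cy, r) {
        t <- seq(0, 2 * pi, length.out = 9)
        cbind(cx + r * cos(t), cy + r * sin(t))
      }
      poly_gc <- function(p, z, feed) {
        c(sprintf("G0 X%g Y%g Z%g F%g", p[1, 1], p[1, 2], z, feed), "M101",
          sprintf("G1 X%g Y%g F%g", p[-1, 1], p[-1, 2], feed), "M103")
      }
      c("; nose_like: closed contour with two inner loops",
        poly_gc(outline, 0.18, sil$speed_mm_s * 60),
        poly_gc(loop(-0.9, -2.4, 0.55), 0.18, sil$speed_mm_s * 60),
        poly_gc(loop(0.9, -2.4, 0.55), 0.18, sil$speed_mm_s * 60))
    },
    ear_like_90 = ,
    ear_like_60 = {
      angle <- if (name == "ear_like_60") 60 else 90
      rect <- c(-3.5, 3.5, -4.5, 4.5)
      outline <- c(sprintf("G0 X%g Y%g Z0.18 F%g", rect[1], rect[3],
                           pcl$speed_mm_s * 60), "M101",
                   sprintf("G1 X%g Y%g F%g",
                           c(rect[2], rect[2], rect[1], rect[1]),
                           c(rect[3], rect[4], rect[4], rect[3]),
                           pcl$speed_mm_s * 60), "M103")
      segs <- .hatch_segments(rect[1], rect[2], rect[3], rect[4],
                              angle_deg = angle, spacing = 1.2)
      c(sprintf("; %s: rectangular outline with %d-degree infill", name, angle),
        outline, .hatch_gcode(segs, 0.18, pcl$speed_mm_s * 60))
    })
  spec <- if (name == "gradient_scaffold") {
    defect_spec(
      breakage = data.frame(start_mm = c(12, 24), end_mm = c(15.6, 25.2)),
      under = data.frame(start_mm = 33, end_mm = 35, scale = 0.5),
      blobs = data.frame(x_mm = 4.5, y_mm = 1.6, radius_mm = 0.45,
                         extra_mm = 0.15),
      threads = list(tibble::tibble(x_mm = c(-2.5, 2.5), y_mm = c(3.4, 3.6))),
      seed = 1L)
  } else defect_spec(seed = 1L)
  config <- switch(name, minimal_line = hap, gradient_scaffold = hap,
                   nose_like = sil, pcl)
  structure(list(name = name, gcode = gc, grid = grid, config = config,
                 spec = spec),
            class = "print_scenario")
}
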