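#' Bresenham line raster
#'
#' Integer line interpolation between two pixel coordinates, the classical
#' Bresenham midpoint walk: the returned chain is 8-connected, includes
#' both endpoints exactly once, and visits one pixel per major-axis step.
#'
#' @param p0,p1 length-2 integer vectors \code{c(col, row)}.
#' @param grid optional [grid_spec()]; when given, endpoints outside the
#'   grid raise an error.
#' @return a tibble with integer columns \code{col}, \code{row}, ordered
#'   from \code{p0} to \code{p1}.
#' @export
bresenham_points <- function(p0, p1, grid = NULL) {
  p0 <- as.integer(p0); p1 <- as.integer(p1)
  stopifnot(length(p0) == 2, length(p1) == 2, !anyNA(p0), !anyNA(p1))
  if (!is.null(grid)) {
    for (p in list(p0, p1))
      if (p[1] < 1 || p[1] > grid$nx || p[2] < 1 || p[2] > grid$ny)
        stop(sprintf("endpoint (%d, %d) outside %d x %d grid",
                     p[1], p[2], grid$nx, grid$ny), call. = FALSE)
  }
  x <- p0[1]; y <- p0[2]
  dx <- abs(p1[1] - x); sx <- if (p0[1] < p1[1]) 1L else -1L
  dy <- -abs(p1[2] - y); sy <- if (p0[2] < p1[2]) 1L else -1L
  err <- dx + dy
  n <- max(dx, -dy) + 1L
  cols <- integer(n); rows <- integer(n)
  for (i in seq_len(n)) {
    cols[i] <- x; rows[i] <- y
    if (x == p1[1] && y == p1[2]) break
    e2 <- 2L * err
    if (e2 >= dy) { err <- err + dy; x <- x + sx }
    if (e2 <= dx) { err <- err + dx; y <- y + sy }
  }
  tibble::tibble(col = cols, row = rows)
}

# disc structuring offsets for an integer pixel radius
.disc_offsets <- function(radius_px) {
  r <- max(0L, as.integer(radius_px))
  g <- expand.grid(dc = -r:r, dr = -r:r)
  d <- sqrt(g$dc^2 + g$dr^2)
  keep <- d <= r + 1e-9
  list(dc = as.integer(g$dc[keep]), dr = as.integer(g$dr[keep]), dist = d[keep])
}

#' Rasterize one layer of toolpath into a target model map
#'
#' Extruding segments are converted to pixel chains with [bresenham_points()]
#' and dilated to the calibrated filament width: every centerline pixel
#' paints a disc of radius \code{round(width / (2 * pitch))} carrying the
#' calibrated filament height as target thickness. Where deposits of
#' different geometry overlap, the larger width/height wins. Non-extruding
#' segments contribute nothing.
#'
#' Alongside the thickness field the map keeps the ordered centerline
#' (with cumulative arc length in mm) and a nearest-centerline owner index
#' per path pixel, used downstream for lateral label propagation and for
#' mapping arc intervals to pixels.
#'
#' @param segments segment tibble (as from [parse_gcode()]/[group_layers()]),
#'   all on one layer.
#' @param grid a [grid_spec()].
#' @param table a [calibration_table()]; defaults to
#'   [default_calibration()] built from \code{nozzle_diameter_mm} and
#'   \code{layer_thickness_mm}.
#' @param nozzle_diameter_mm,layer_thickness_mm nominal geometry used when
#'   no calibration table is supplied.
#' @return an object of class \code{target_model_map}: list with
#'   \code{grid}, \code{z_mm}, \code{thickness} (ny x nx mm matrix),
#'   \code{width} (ny x nx mm), \code{path_mask}, \code{centerline_mask}
#'   (logical matrices), \code{centerline} (ordered tibble with
#'   \code{col,row,segment,arc_mm,width_mm,height_mm,connected}), and
#'   \code{owner} (integer matrix of owning centerline row, 0 off-path).
#' @export
rasterize_layer <- function(segments, grid, table = NULL,
                            nozzle_diameter_mm = 0.41,
                            layer_thickness_mm = 0.25) {
  stopifnot(inherits(grid, "grid_spec"))
  if (abs(grid$pitch_x - grid$pitch_y) > 1e-9 * grid$pitch_x)
    stop("rasterization requires square pixels", call. = FALSE)
  pitch <- grid$pitch_x
  if (is.null(table))
    table <- default_calibration(nozzle_diameter_mm, layer_thickness_mm)
  ny <- grid$ny; nx <- grid$nx
  z_mm <- if (nrow(segments)) segments$z_mm[1] else NA_real_
  ext <- segments[segments$extruding, , drop = FALSE]

  thickness <- matrix(0, ny, nx)
  width <- matrix(0, ny, nx)
  owner <- matrix(0L, ny, nx)

  cl <- NULL
  if (nrow(ext) > 0) {
    bad <- ext$x0 < grid$x_extent_mm[1] | ext$x0 > grid$x_extent_mm[2] |
      ext$x1 < grid$x_extent_mm[1] | ext$x1 > grid$x_extent_mm[2] |
      ext$y0 < grid$y_extent_mm[1] | ext$y0 > grid$y_extent_mm[2] |
      ext$y1 < grid$y_extent_mm[1] | ext$y1 > grid$y_extent_mm[2]
    if (any(bad))
      stop(sprintf("segment endpoint(s) outside grid extents (segment rows: %s)",
                   paste(which(bad), collapse = ", ")), call. = FALSE)
    pieces <- vector("list", nrow(ext))
    for (s in seq_len(nrow(ext))) {
      geom <- lookup_filament_geometry(ext$speed_mm_s[s], ext$pressure_mpa[s], table)
      a <- mm_to_pixel(grid, ext$x0[s], ext$y0[s])
      b <- mm_to_pixel(grid, ext$x1[s], ext$y1[s])
      pts <- bresenham_points(c(a$col, a$row), c(b$col, b$row), grid)
      pts$segment <- s
      pts$width_mm <- unname(geom["width_mm"])
      pts$height_mm <- unname(geom["height_mm"])
      pieces[[s]] <- pts
    }
    cl <- dplyr::bind_rows(pieces)
    # drop duplicated joints where one segment ends where the next begins
    dup <- c(FALSE, cl$col[-1] == cl$col[-nrow(cl)] &
               cl$row[-1] == cl$row[-nrow(cl)])
    cl <- cl[!dup, , drop = FALSE]
    step_c <- diff(cl$col); step_r <- diff(cl$row)
    cl$connected <- c(TRUE, pmax(abs(step_c), abs(step_r)) <= 1L)
    cl$arc_mm <- cumsum(c(0, sqrt(step_c^2 + step_r^2) * pitch))

    best <- matrix(Inf, ny, nx)
    radii <- as.integer(round(cl$width_mm / (2 * pitch)))
    offs <- lapply(stats::setNames(nm = sort(unique(radii))), .disc_offsets)
    for (i in seq_len(nrow(cl))) {
      o <- offs[[as.character(radii[i])]]
      cc <- cl$col[i] + o$dc; rr <- cl$row[i] + o$dr
      keep <- cc >= 1L & cc <= nx & rr >= 1L & rr <= ny
      lin <- rr[keep] + (cc[keep] - 1L) * ny
      d <- o$dist[keep]
      thickness[lin] <- pmax(thickness[lin], cl$height_mm[i])
      width[lin] <- pmax(width[lin], cl$width_mm[i])
      closer <- d < best[lin]
      if (any(closer)) {
        sel <- lin[closer]
        owner[sel] <- i
        best[sel] <- d[closer]
      }
    }
  } else {
    cl <- tibble::tibble(col = integer(), row = integer(), segment = integer(),
                         width_mm = numeric(), height_mm = numeric(),
                         connected = logical(), arc_mm = numeric())
  }
  centerline_mask <- matrix(FALSE, ny, nx)
  if (nrow(cl)) centerline_mask[cbind(cl$row, cl$col)] <- TRUE

  structure(list(grid = grid, z_mm = z_mm,
                 thickness = thickness, width = width,
                 path_mask = thickness > 0,
                 centerline_mask = centerline_mask,
                 centerline = cl, owner = owner),
            class = "target_model_map")
}

#' @export
print.target_model_map <- function(x, ...) {
  cat(sprintf("target_model_map: z = %g mm, %d centerline px, %d path px (%.2f mm^2)\n",
              x$z_mm, nrow(x$centerline), sum(x$path_mask),
              sum(x$path_mask) * x$grid$pitch_x * x$grid$pitch_y))
  invisible(x)
}

#' Layer colour coding for composite renderings
#'
#' Z-ordered colour assignment for multi-layer composites: the first two
#' layers use deep blue and green; further layers continue along a
#' perceptually ordered colormap.
#'
#' @param k number of layers.
#' @return character vector of k colours.
#' @export
layer_colors <- function(k) {
  base <- c("#00008B", "#00A651")
  if (k <= 2) return(base[seq_len(k)])
  c(base, grDevices::hcl.colors(k - 2, "Viridis", rev = FALSE))
}

#' Stack per-layer target maps into a multi-layer model
#'
#' @param maps list of \code{target_model_map}, ascending in z.
#' @return object of class \code{multilayer_target_model}: list with
#'   \code{layers}, \code{colors}, shared \code{grid}.
#' @export
stack_layers <- function(maps) {
  stopifnot(length(maps) >= 1,
            all(vapply(maps, inherits, logical(1), "target_model_map")))
  grid <- maps[[1]]$grid
  for (m in maps[-1])
    if (!.same_grid(grid, m$grid))
      stop("all layers must share the same grid_spec", call. = FALSE)
  zs <- vapply(maps, function(m) m$z_mm, numeric(1))
  if (is.unsorted(zs, strictly = FALSE))
    maps <- maps[order(zs)]
  structure(list(layers = maps, colors = layer_colors(length(maps)),
                 grid = grid),
            class = "multilayer_target_model")
}

#' Render a multi-layer target model as an RGB composite
#'
#' Each layer's path is painted in its Z colour; later (higher) layers
#' paint over earlier ones.
#'
#' @param model a [stack_layers()] result.
#' @return ny x nx x 3 numeric RGB array in [0, 1].
#' @export
composite_target <- function(model) {
  stopifnot(inherits(model, "multilayer_target_model"))
  g <- model$grid
  img <- array(0, c(g$ny, g$nx, 3))
  for (k in seq_along(model$layers)) {
    rgb <- grDevices::col2rgb(model$colors[k])[, 1] / 255
    m <- model$layers[[k]]$path_mask
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[m] <- rgb[ch]
      img[, , ch] <- plane
    }
  }
  img
}
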