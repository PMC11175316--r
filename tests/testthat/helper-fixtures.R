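# shared fixtures: everything is generated in code at test time

tiny_grid <- function(n = 64, extent = c(-5, 5)) {
  grid_spec(extent, extent, nx = n, ny = n)
}

# one-row segment tibble
seg <- function(x0, y0, x1, y1, z = 0.25, speed = 10, pressure = 0.18,
                extruding = TRUE) {
  tibble::tibble(line = 1L, x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                 z_mm = z, speed_mm_s = speed, pressure_mpa = pressure,
                 extruding = extruding)
}

# independent nearest-pixel line sampler: walk the major axis one pixel at
# a time and take the closest integer minor coordinate, ties broken toward
# the direction of travel (the midpoint convention)
oracle_line <- function(p0, p1) {
  dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
  if (dx == 0 && dy == 0) return(cbind(p0[1], p0[2]))
  round_toward <- function(v, dir) {
    if (dir >= 0) floor(v + 0.5) else ceiling(v - 0.5)
  }
  if (abs(dx) >= abs(dy)) {
    xs <- seq(p0[1], p1[1], by = sign(dx))
    ys <- vapply(xs, function(x)
      round_toward(p0[2] + dy * (x - p0[1]) / dx, sign(dy)), numeric(1))
  } else {
    ys <- seq(p0[2], p1[2], by = sign(dy))
    xs <- vapply(ys, function(y)
      round_toward(p0[1] + dx * (y - p0[2]) / dy, sign(dx)), numeric(1))
  }
  cbind(xs, ys)
}

# full noiseless gradient-scaffold pipeline products, computed once per run
scaffold_case <- local({
  cache <- NULL
  function(nx = 256) {
    if (!is.null(cache)) return(cache)
    sc <- scenario_fixtures("gradient_scaffold", nx = nx)
    segs <- group_layers(parse_gcode(sc$gcode,
                                     pressure_mpa = sc$config$pressure_mpa),
                         sc$config$layer_thickness_mm)
    target <- rasterize_layer(segs, sc$grid,
                              nozzle_diameter_mm = sc$config$nozzle_diameter_mm,
                              layer_thickness_mm = sc$config$layer_thickness_mm)
    sim <- render_heightmap(target, sc$spec)
    dz <- 0.01
    pv <- render_volume(sim, base_px = 60, dz_mm = dz, z_set_height_px = 25)
    nz <- dim(pv$volume$intensity)[3]
    bv <- render_volume(matrix(0, nx, nx), base_px = 60, dz_mm = dz,
                        z_set_height_px = 0, nz = nz)
    recon <- compute_thickness(detect_surface(pv$volume, threshold = 0.5),
                               detect_surface(bv$volume, threshold = 0.5),
                               acquisition_meta(1, 25), dz_mm = dz,
                               grid = sc$grid)
    dmap <- defect_map(recon, target)
    cache <<- list(scenario = sc, target = target, sim = sim, recon = recon,
                   dmap = dmap, runs = measure_defect_runs(dmap, target),
                   dz = dz)
    cache
  }
})
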