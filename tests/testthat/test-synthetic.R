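test_that("an empty defect spec reproduces the target exactly", {
  g <- tiny_grid(128)
  tm <- rasterize_layer(seg(-4, 0, 4, 0), g)
  sp <- render_heightmap(tm, defect_spec())
  expect_identical(sp$height, tm$thickness)
  expect_equal(nrow(sp$truth$runs), 0)
  expect_true(all(sp$truth$centerline_codes == 1L))
})

test_that("injected intervals and scales produce the intended classes", {
  g <- tiny_grid(256)
  tm <- rasterize_layer(seg(-4.5, 0, 4.5, 0), g)
  sp <- render_heightmap(tm, defect_spec(
    breakage = data.frame(start_mm = 1, end_mm = 4.6),
    over = data.frame(start_mm = 6, end_mm = 7, scale = 1.3)))
  # over-extrusion: 0.25 * 1.3 = 0.325 > 0.30
  expect_true(any(sp$truth$centerline_codes == 3L))
  dm <- defect_map(sp$height, tm)
  runs <- measure_defect_runs(dm, tm)
  br <- runs[runs$class == "filament_breakage", ]
  expect_equal(nrow(br), 1)
  expect_lt(abs(br$length_mm - 3.6), g$pitch_x)
  expect_error(render_heightmap(tm, defect_spec(
    breakage = data.frame(start_mm = 1, end_mm = 99))), "arc length")
})

test_that("volume rendering inverts the thickness relation", {
  g <- tiny_grid(96)
  tm <- rasterize_layer(seg(-4, 0, 4, 0), g)
  sp <- render_heightmap(tm, defect_spec())
  dz <- 0.01
  rv <- render_volume(sp, base_px = 50, dz_mm = dz, z_set_height_px = 25)
  bv <- render_volume(matrix(0, 96, 96), base_px = 50, dz_mm = dz,
                      z_set_height_px = 0, nz = dim(rv$volume$intensity)[3])
  rec <- compute_thickness(detect_surface(rv$volume, threshold = 0.5),
                           detect_surface(bv$volume, threshold = 0.5),
                           25, dz_mm = dz)
  expect_lt(max(abs(rec$thickness - sp$height)), dz + 1e-12)
})

test_that("a tilted base still reconstructs the flat deposit", {
  g <- tiny_grid(64)
  tm <- rasterize_layer(seg(-4, 0, 4, 0), g)
  sp <- render_heightmap(tm, defect_spec())
  tilt <- matrix(rep(round(seq(40, 60, length.out = 64)), each = 64), 64, 64)
  dz <- 0.01
  rv <- render_volume(sp, base_px = tilt, dz_mm = dz, z_set_height_px = 25)
  bv <- render_volume(matrix(0, 64, 64), base_px = tilt, dz_mm = dz,
                      z_set_height_px = 0, nz = dim(rv$volume$intensity)[3])
  rec <- compute_thickness(detect_surface(rv$volume, threshold = 0.5),
                           detect_surface(bv$volume, threshold = 0.5),
                           25, dz_mm = dz)
  expect_lt(max(abs(rec$thickness - sp$height)), dz + 1e-12)
})

test_that("rendering is deterministic under a fixed seed", {
  g <- tiny_grid(48)
  tm <- rasterize_layer(seg(-4, 0, 4, 0), g)
  sp <- render_heightmap(tm, defect_spec(seed = 7))
  v1 <- render_volume(sp, base_px = 40, dz_mm = 0.01,
                      noise = list(shape = 16))
  v2 <- render_volume(sp, base_px = 40, dz_mm = 0.01,
                      noise = list(shape = 16))
  expect_identical(v1$volume$intensity, v2$volume$intensity)
  v3 <- render_volume(sp, base_px = 40, dz_mm = 0.01,
                      noise = list(shape = 16), seed = 8)
  expect_false(identical(v1$volume$intensity, v3$volume$intensity))
})

test_that("surface detection tolerates speckle on the synthetic ridge", {
  g <- tiny_grid(96)
  tm <- rasterize_layer(seg(-4, 0, 4, 0), g)
  sp <- render_heightmap(tm, defect_spec(seed = 3))
  dz <- 0.01
  rv <- render_volume(sp, base_px = 50, dz_mm = dz, z_set_height_px = 25,
                      noise = list(shape = 60))
  truth_surface <- round(50 + 25 - sp$height / dz)
  s <- detect_surface(rv$volume, threshold = 0.5, smooth_window = 5)
  err <- abs(s$surface_z_px - truth_surface)
  expect_gt(mean(err[s$valid] <= 1), 0.99)
})

test_that("scenario fixtures cover the documented set", {
  expect_error(scenario_fixtures("nope"), "valid names")
  ml <- scenario_fixtures("minimal_line", nx = 64)
  segs <- parse_gcode(ml$gcode)
  ext <- segs[segs$extruding, ]
  expect_equal(nrow(ext), 1)
  expect_equal(abs(ext$x1 - ext$x0), 9)
  gs <- scenario_fixtures("gradient_scaffold", nx = 64)
  y <- sort(unique(c(parse_gcode(gs$gcode)$y0, parse_gcode(gs$gcode)$y1)))
  expect_true(all(diff(diff(y)) > 0))  # monotonically increasing spacing
  e90 <- scenario_fixtures("ear_like_90", nx = 64)
  e60 <- scenario_fixtures("ear_like_60", nx = 64)
  expect_equal(e60$config$nozzle_diameter_mm, 0.15)
  expect_equal(e60$config$pressure_mpa, 0.55)
  expect_equal(e60$config$speed_mm_s, 2)
  # same outline, different infill angles
  s90 <- parse_gcode(e90$gcode); s60 <- parse_gcode(e60$gcode)
  ang <- function(s) {
    infill <- s[s$extruding & abs(s$x1 - s$x0) + abs(s$y1 - s$y0) > 0, ]
    infill <- infill[-(1:4), ]  # drop the outline
    sort(unique(round(atan2(infill$y1 - infill$y0,
                            infill$x1 - infill$x0) * 180 / pi)) %% 180)
  }
  expect_true(all(ang(s90) %in% c(90)))
  expect_true(all(ang(s60) %in% c(60, 120)))
  nose <- scenario_fixtures("nose_like", nx = 64)
  expect_equal(nose$config$nozzle_diameter_mm, 0.21)
  expect_gt(nrow(parse_gcode(nose$gcode)), 10)
})
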