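fake_run <- function(class, length_mm, x0 = -1.75, y0 = -2.142,
                     x1 = 1.85, y1 = -2.142, z = 0.75) {
  tibble::tibble(class = class, z_mm = z, x0_mm = x0, y0_mm = y0,
                 x1_mm = x1, y1_mm = y1, length_mm = length_mm,
                 n_pixels = 10L, start_index = 1L, end_index = 10L,
                 path = list(tibble::tibble(
                   x_mm = seq(x0, x1, length.out = 10),
                   y_mm = seq(y0, y1, length.out = 10))))
}

test_that("repair selection is inclusive at 1.5 mm and class-restricted", {
  runs <- dplyr::bind_rows(fake_run("filament_breakage", 1.5),
                           fake_run("filament_breakage", 1.2),
                           fake_run("under_extrusion", 2.0),
                           fake_run("over_extrusion", 5.0))
  sel <- select_repairable(runs)
  expect_equal(sel$length_mm, c(1.5, 2.0))
  expect_false("over_extrusion" %in% sel$class)
})

test_that("repair gcode re-prints the run between its endpoints", {
  plan <- repair_plan(fake_run("filament_breakage", 3.6),
                      speed_mm_s = 10, pressure_mpa = 0.18)
  gc <- generate_repair_gcode(plan)
  segs <- parse_gcode(gc, pressure_mpa = 0.18)
  ext <- segs[segs$extruding, ]
  expect_equal(nrow(ext), 1)  # collinear run collapses to one move
  expect_equal(unlist(ext[1, c("x0", "y0", "x1", "y1")], use.names = FALSE),
               c(-1.75, -2.142, 1.85, -2.142), tolerance = 1e-3)
  expect_equal(ext$z_mm, 0.75, tolerance = 1e-6)
})

test_that("an empty plan yields a program with zero motion lines", {
  plan <- repair_plan(select_repairable(fake_run("filament_breakage", 0.5)))
  gc <- generate_repair_gcode(plan)
  expect_true(any(grepl("^;", gc)))
  expect_equal(nrow(parse_gcode(gc)), 0)
})

test_that("repair plans round-trip through the gcode parser", {
  # an L-shaped under-extrusion run survives with its corner
  path <- tibble::tibble(x_mm = c(0, 1, 2, 2, 2), y_mm = c(0, 0, 0, 1, 2))
  run <- fake_run("under_extrusion", 4)
  run$path <- list(path)
  run$x0_mm <- 0; run$y0_mm <- 0; run$x1_mm <- 2; run$y1_mm <- 2
  plan <- repair_plan(run)
  segs <- parse_gcode(generate_repair_gcode(plan))
  ext <- segs[segs$extruding, ]
  expect_equal(nrow(ext), 2)  # two straight legs after collinear merging
  expect_equal(c(ext$x1[1], ext$y1[1]), c(2, 0), tolerance = 1e-3)
  expect_equal(c(ext$x1[2], ext$y1[2]), c(2, 2), tolerance = 1e-3)
})

test_that("verify_repair reports the relative fidelity improvement", {
  expect_equal(relative_improvement(0.8273, 0.9241), 11.70, tolerance = 1e-2)
  g <- tiny_grid(128)
  tm <- rasterize_layer(seg(-4.5, 0, 4.5, 0), g)
  broken <- render_heightmap(tm, defect_spec(
    breakage = data.frame(start_mm = 2, end_mm = 5.6)))$height
  rep <- verify_repair(tm, broken, tm$thickness)
  expect_gt(rep$improvement_pct, 0)
  expect_equal(nrow(rep$runs_after), 0)
  expect_equal(nrow(rep$runs_before), 1)
  # identical reconstructions: zero improvement
  same <- verify_repair(tm, broken, broken)
  expect_equal(same$improvement_pct, 0)
})
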