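test_that("bresenham handles degenerate and axis-aligned lines", {
  expect_equal(as.data.frame(bresenham_points(c(3, 3), c(3, 3))),
               data.frame(col = 3L, row = 3L))
  h <- bresenham_points(c(1, 1), c(4, 1))
  expect_equal(h$col, 1:4)
  expect_equal(h$row, rep(1L, 4))
  g <- tiny_grid(8)
  expect_error(bresenham_points(c(0, 1), c(3, 3), g), "outside")
})

test_that("bresenham matches the brute-force nearest-pixel sampler", {
  set.seed(7)
  for (i in 1:50) {
    d <- sample(-16:16, 2, replace = TRUE)
    p0 <- c(20L, 20L); p1 <- p0 + d
    got <- bresenham_points(p0, p1)
    want <- oracle_line(p0, p1)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$col, unname(want[, 1]))
    expect_equal(got$row, unname(want[, 2]))
  }
})

test_that("calibration lookup is exact at table points and interpolates", {
  tab <- calibration_table(10, 0.18, 0.41, 0.25)
  expect_equal(lookup_filament_geometry(10, 0.18, tab),
               c(width_mm = 0.41, height_mm = 0.25))
  # single entry answers any query (nearest / clamped)
  expect_equal(lookup_filament_geometry(99, 0.9, tab)[["width_mm"]], 0.41)
  lin <- calibration_table(c(10, 12), c(0.18, 0.18), c(0.40, 0.36),
                           c(0.25, 0.23), mode = "linear")
  got <- lookup_filament_geometry(11, 0.18, lin)
  expect_equal(got[["width_mm"]], 0.38)
  expect_equal(got[["height_mm"]], 0.24)
  # clamped outside the calibrated range
  expect_equal(lookup_filament_geometry(100, 0.18, lin)[["width_mm"]], 0.36)
  expect_error(lookup_filament_geometry(10, 0.18, NULL), "empty")
})

test_that("a single stripe rasterizes at the calibrated width and height", {
  g <- grid_spec()  # pitch 10/1024
  tm <- rasterize_layer(seg(-4.5, 0, 4.5, 0), g)
  expect_equal(max(tm$thickness), 0.25)
  # stripe pixel width = 2*round(0.205/pitch) + 1
  expected_w <- 2 * round(0.205 / g$pitch_x) + 1
  mid_col <- 512
  expect_equal(sum(tm$path_mask[, mid_col]), expected_w)
  expect_equal(expected_w, 43)
  # footprint area = length x width plus the rounded end caps, up to the
  # one-pixel boundary ring of the footprint
  expected_area <- 9 * 0.41 + pi * 0.205^2
  perimeter <- 2 * 9 + 2 * pi * 0.205
  area_px <- sum(tm$path_mask) * g$pitch_x * g$pitch_y
  expect_lt(abs(area_px - expected_area), 2 * perimeter * g$pitch_x)
})

test_that("path mask is exactly where target thickness is positive", {
  g <- tiny_grid(128)
  tm <- rasterize_layer(dplyr::bind_rows(seg(-4, -2, 4, -2),
                                         seg(-4, 2, 4, 2, speed = 12)), g)
  expect_identical(tm$path_mask, tm$thickness > 0)
  expect_true(all(tm$thickness[tm$centerline_mask] > 0))  # centerline in path
})

test_that("non-extruding layers produce empty maps and bad endpoints error", {
  g <- tiny_grid(64)
  tm <- rasterize_layer(seg(-4, 0, 4, 0, extruding = FALSE), g)
  expect_equal(sum(tm$thickness), 0)
  expect_equal(nrow(tm$centerline), 0)
  expect_error(rasterize_layer(seg(-7, 0, 4, 0), g), "outside grid")
})

test_that("rasterization is order-insensitive for non-overlapping segments", {
  g <- tiny_grid(128)
  s <- dplyr::bind_rows(seg(-4, -3, 4, -3), seg(-4, 0, 4, 0), seg(-4, 3, 4, 3))
  a <- rasterize_layer(s, g)
  b <- rasterize_layer(s[c(3, 1, 2), ], g)
  expect_identical(a$thickness, b$thickness)
  expect_identical(a$path_mask, b$path_mask)
  expect_identical(a$centerline_mask, b$centerline_mask)
})

test_that("overlapping deposits keep the larger width and height", {
  g <- tiny_grid(128)
  tab <- calibration_table(c(10, 20), c(0.18, 0.18), c(0.41, 0.82),
                           c(0.25, 0.50), mode = "nearest")
  s <- dplyr::bind_rows(seg(-4, 0, 4, 0, speed = 10),
                        seg(0, -4, 0, 4, speed = 20))
  tm <- rasterize_layer(s, g, table = tab)
  centre <- mm_to_pixel(g, 0, 0)
  expect_equal(tm$thickness[centre$row, centre$col], 0.50)
  expect_equal(tm$width[centre$row, centre$col], 0.82)
})

test_that("layer stacking validates grids and orders by z", {
  g <- tiny_grid(64)
  l1 <- rasterize_layer(seg(-4, 0, 4, 0, z = 0.25), g)
  l2 <- rasterize_layer(seg(0, -4, 0, 4, z = 0.50), g)
  m <- stack_layers(list(l2, l1))
  expect_equal(vapply(m$layers, function(x) x$z_mm, numeric(1)), c(0.25, 0.5))
  expect_equal(m$colors[1:2], layer_colors(2))
  expect_error(stack_layers(list(l1, rasterize_layer(seg(0, 0, 1, 1), tiny_grid(32)))),
               "same grid")
  # single empty layer renders black; one-layer composite shows layer 1 colour
  img <- composite_target(stack_layers(list(rasterize_layer(
    seg(0, 0, 1, 0, extruding = FALSE), g))))
  expect_equal(sum(img), 0)
  img1 <- composite_target(stack_layers(list(l1)))
  expect_true(all(img1[, , 3][l1$path_mask] > 0))  # deep blue channel
})
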