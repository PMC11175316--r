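test_that("path masking is a pointwise product with the target mask", {
  g <- tiny_grid(64)
  tm <- rasterize_layer(seg(-4, 0, 4, 0), g)
  uniform <- matrix(0.25, 64, 64)
  masked <- mask_recon_in_path(uniform, tm)
  expect_true(all(masked[tm$path_mask] == 0.25))
  expect_true(all(masked[!tm$path_mask] == 0))
  empty <- rasterize_layer(seg(-4, 0, 4, 0, extruding = FALSE), g)
  expect_true(all(mask_recon_in_path(uniform, empty) == 0))
  expect_error(mask_recon_in_path(matrix(0, 3, 3), tm), "grids")
})

test_that("thickness rules classify the worked boundary cases", {
  # direct application of the in-path rules at T = 0.25, delta = 0.05
  t_vals <- c(0.25, 0, 0.31, 0.12, 0.30, 0.20, 0.199, 0.301)
  want <- c("normal", "filament_breakage", "over_extrusion",
            "under_extrusion", "normal", "normal", "under_extrusion",
            "over_extrusion")
  codes <- bioprintqc:::.classify_thickness(t_vals, rep(0.25, length(t_vals)),
                                            0.05, 1e-6)
  got <- defect_classes()$class[codes + 1]
  expect_equal(got, want)
})

test_that("exactly one in-path rule fires for every (t, T) pair", {
  T_grid <- c(0.18, 0.25, 0.5)
  t_grid <- c(seq(0, 0.6, by = 0.01), 0.25 - 0.05, 0.25 + 0.05, 1e-7)
  for (T in T_grid) for (t in t_grid) {
    code <- bioprintqc:::.classify_thickness(t, T, 0.05, 1e-6)
    expect_length(code, 1)
    expect_true(code %in% 1:4)
  }
})

test_that("widening the tolerance never shrinks the normal band", {
  g <- tiny_grid(96)
  tm <- rasterize_layer(seg(-4, 0, 4, 0), g)
  set.seed(3)
  noisy <- tm$thickness * matrix(runif(96 * 96, 0.5, 1.5), 96, 96)
  count <- function(tol) {
    lab <- classify_in_path(mask_recon_in_path(noisy, tm), tm,
                            tolerance_mm = tol)$labels
    c(normal = sum(lab == 1), under = sum(lab == 2), over = sum(lab == 3))
  }
  a <- count(0.02); b <- count(0.05); c <- count(0.10)
  expect_true(b["normal"] >= a["normal"] && c["normal"] >= b["normal"])
  expect_true(b["under"] <= a["under"] && c["under"] <= b["under"])
  expect_true(b["over"] <= a["over"] && c["over"] <= b["over"])
})

test_that("a perfect print classifies all-normal with no stringing", {
  g <- tiny_grid(128)
  tm <- rasterize_layer(dplyr::bind_rows(seg(-4, -2, 4, -2), seg(4, -2, 4, 2),
                                         seg(4, 2, -4, 2)), g)
  dm <- defect_map(tm$thickness, tm)
  expect_true(all(dm$centerline_codes == 1L))
  expect_equal(sum(dm$labels == 5L), 0)
  in_path_labels <- dm$labels[tm$path_mask]
  expect_true(all(in_path_labels == 1L))
})

test_that("stringing survives opening only when thread-like", {
  g <- tiny_grid(128)
  tm <- rasterize_layer(seg(-4, -3, 4, -3), g)
  # a 1-px-wide thread well outside the path
  recon <- tm$thickness
  thread_row <- mm_to_pixel(g, 0, 2)$row
  recon[thread_row, 30:100] <- 0.12
  s <- detect_stringing(recon, tm)
  expect_true(any(s[thread_row, 40:90]))
  expect_true(all(!s[tm$path_mask]))
  # an isolated out-of-path pixel is removed by the opening
  recon2 <- tm$thickness
  recon2[thread_row, 64] <- 0.12
  s2 <- detect_stringing(recon2, tm, dilation_radius_px = 0)
  expect_equal(sum(s2), 0)
  # a recon identical to the target leaves nothing outside the path
  expect_equal(sum(detect_stringing(tm$thickness, tm)), 0)
})

test_that("composed maps partition the grid and keep supports disjoint", {
  case <- scaffold_case()
  dm <- case$dmap
  counts <- tidy(dm)
  expect_equal(sum(counts$n_pixels), 256 * 256)
  # stringing never on the path
  expect_true(all(dm$labels[case$target$path_mask] != 5L))
  expect_error(compose_defect_map(
    list(labels = matrix(1L, 4, 4), centerline_codes = integer()),
    matrix(TRUE, 4, 4),
    list(grid = tiny_grid(4), z_mm = 0)), "overlap")
})

test_that("defect runs are maximal, measured in mm, and never merged", {
  g <- tiny_grid(256)
  tm <- rasterize_layer(seg(-4.5, 0, 4.5, 0), g)
  # no defects -> no runs
  dm0 <- defect_map(tm$thickness, tm)
  expect_equal(nrow(measure_defect_runs(dm0, tm)), 0)
  # two gaps separated by normal pixels stay two runs
  sp <- render_heightmap(tm, defect_spec(
    breakage = data.frame(start_mm = c(1, 6), end_mm = c(2.5, 7.2))))
  dm <- defect_map(sp$height, tm)
  runs <- measure_defect_runs(dm, tm)
  expect_equal(nrow(runs), 2)
  expect_equal(runs$class, rep("filament_breakage", 2))
  expect_lt(abs(runs$length_mm[1] - 1.5), g$pitch_x)
  expect_lt(abs(runs$length_mm[2] - 1.2), g$pitch_x)
  # arc length accounts for diagonal steps at pitch*sqrt(2)
  diag_tm <- rasterize_layer(seg(-4, -4, 4, 4), g)
  sp2 <- render_heightmap(diag_tm, defect_spec(
    breakage = data.frame(start_mm = 2, end_mm = 4)))
  dm2 <- defect_map(sp2$height, diag_tm)
  runs2 <- measure_defect_runs(dm2, diag_tm)
  expect_equal(nrow(runs2), 1)
  expect_lt(abs(runs2$length_mm - 2), g$pitch_x * sqrt(2))
})
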