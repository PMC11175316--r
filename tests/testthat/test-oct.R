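step_volume <- function(ny, nx, nz, surface_idx, lo = 0.05, hi = 1) {
  if (length(surface_idx) == 1) surface_idx <- matrix(surface_idx, ny, nx)
  vol <- array(lo, c(ny, nx, nz))
  for (k in seq_len(nz)) {
    sel <- surface_idx <= k
    plane <- vol[, , k]; plane[sel] <- hi; vol[, , k] <- plane
  }
  oct_volume(vol, dz_mm = 0.01)
}

test_that("surface detection finds a step surface and flags empty columns", {
  v <- step_volume(8, 8, 60, 40)
  s <- detect_surface(v, threshold = 0.5)
  expect_true(all(s$valid))
  expect_true(all(s$surface_z_px == 40))
  empty <- oct_volume(array(0, c(4, 4, 10)), dz_mm = 0.01)
  expect_warning(s0 <- detect_surface(empty, threshold = 0.5), "threshold")
  expect_false(any(s0$valid))
})

test_that("thickness follows the base + descent - surface relation", {
  base <- detect_surface(step_volume(4, 4, 150, 100), threshold = 0.5)
  print_s <- detect_surface(step_volume(4, 4, 150, 90), threshold = 0.5)
  r <- compute_thickness(print_s, base, acquisition_meta(1, 20), dz_mm = 0.01)
  expect_true(all(abs(r$thickness - 0.30) < 1e-12))
  # nothing printed: identical surfaces, no descent
  r0 <- compute_thickness(base, base, 0, dz_mm = 0.01)
  expect_true(all(r0$thickness == 0))
  expect_error(compute_thickness(
    detect_surface(step_volume(3, 3, 150, 90), threshold = 0.5),
    base, 0, 0.01), "shapes")
})

test_that("an uneven base cancels out of the reconstruction", {
  tilt <- matrix(rep(round(seq(100, 110, length.out = 16)), each = 16), 16, 16)
  base <- detect_surface(step_volume(16, 16, 160, tilt), threshold = 0.5)
  print_s <- detect_surface(step_volume(16, 16, 160, tilt - 25), threshold = 0.5)
  r <- compute_thickness(print_s, base, 0, dz_mm = 0.01)
  expect_true(all(abs(r$thickness - 0.25) < 1e-12))
})

test_that("thickness is linear in platform descent and shift-invariant", {
  set.seed(11)
  b <- matrix(sample(80:120, 64, replace = TRUE), 8, 8)
  p <- b - 10
  mk <- function(m) structure(list(surface_z_px = m,
                                   valid = matrix(TRUE, nrow(m), ncol(m))),
                              class = "surface_map")
  t0 <- compute_thickness(mk(p), mk(b), 0, 0.01)$thickness
  # add a constant to both surfaces: unchanged
  t1 <- compute_thickness(mk(p + 7), mk(b + 7), 0, 0.01)$thickness
  expect_equal(t1, t0)
  # add c to the descent: every thickness grows by c*dz
  t2 <- compute_thickness(mk(p), mk(b), 5, 0.01)$thickness
  expect_equal(t2, t0 + 0.05)
})

test_that("negative thickness is clipped to zero and counted", {
  mk <- function(m) structure(list(surface_z_px = m,
                                   valid = matrix(TRUE, nrow(m), ncol(m))),
                              class = "surface_map")
  b <- matrix(100, 2, 2); p <- matrix(c(100, 100, 100, 105), 2, 2)
  r <- compute_thickness(mk(p), mk(b), 0, 0.01)
  expect_equal(r$n_negative_clipped, 1L)
  expect_true(all(r$thickness >= 0))
})

test_that("rounds accumulate additively and keep per-round maps", {
  m1 <- recon_model_map(matrix(0.25, 4, 4), round = 1)
  m2 <- recon_model_map(matrix(0.25, 4, 4), round = 2)
  acc <- accumulate_rounds(list(m1, m2))
  expect_true(all(acc$cumulative == 0.5))
  expect_length(acc$rounds, 2)
  expect_equal(accumulate_rounds(list(m1))$cumulative, m1$thickness)
  expect_error(accumulate_rounds(list(m2, m1)), "increasing")
})

test_that("cross sections report plateau widths and gap lengths", {
  g <- tiny_grid(256)
  tm <- rasterize_layer(seg(-4.5, 0, 4.5, 0), g)
  mid <- mm_to_pixel(g, 0, 0)
  prof <- extract_cross_section(tm$thickness, col = mid$col, grid = g)
  expect_equal(sum(prof$value > 0), 2 * round(0.205 / g$pitch_x) + 1)
  flat <- extract_cross_section(matrix(2, 5, 5), row = 3)
  expect_true(all(flat$value == 2))
  # a rendered breakage shows as a zero interval of the injected length
  sp <- render_heightmap(tm, defect_spec(
    breakage = data.frame(start_mm = 3, end_mm = 5)))
  row0 <- mm_to_pixel(g, 0, 0)$row
  gap <- extract_cross_section(sp$height, row = row0, grid = g)
  on_path <- gap$value == 0 &
    gap$position_mm > -4.5 & gap$position_mm < 4.5 &
    abs(gap$position_mm) < 4.3
  gap_mm <- sum(on_path) * g$pitch_x
  expect_lt(abs(gap_mm - 2), 3 * g$pitch_x)
})
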