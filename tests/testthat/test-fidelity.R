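test_that("SSIM of a field with itself is exactly one", {
  set.seed(5)
  x <- matrix(runif(64 * 64), 64, 64)
  r <- ssim(x, x, window_px = 11)
  expect_true(all(abs(r$ssim_map - 1) < 1e-9))
  expect_equal(r$mean_ssim, 1, tolerance = 1e-9)
})

test_that("constant fields reproduce the closed-form SSIM", {
  a <- 0.25; b <- 0.4
  x <- matrix(a, 32, 32); y <- matrix(b, 32, 32)
  L <- max(a, b); c1 <- (0.01 * L)^2
  want <- (2 * a * b + c1) / (a^2 + b^2 + c1)
  r <- ssim(x, y, window_px = 7)
  expect_true(all(abs(r$ssim_map - want) < 1e-9))
})

test_that("SSIM is symmetric and bounded", {
  set.seed(9)
  x <- matrix(runif(48 * 48), 48, 48)
  y <- matrix(runif(48 * 48), 48, 48)
  p <- ssim_params(9, L = 1)
  rxy <- ssim(x, y, params = p); ryx <- ssim(y, x, params = p)
  expect_equal(rxy$ssim_map, ryx$ssim_map, tolerance = 1e-12)
  expect_true(all(rxy$ssim_map >= -1 - 1e-9 & rxy$ssim_map <= 1 + 1e-9))
})

test_that("window validation and filament-based sizing behave", {
  expect_error(ssim(matrix(0, 5, 5), matrix(0, 5, 5), window_px = 7), "larger")
  expect_equal(ssim_window_from_filament(0.41, 10 / 1024), 43L)
  expect_equal(ssim_window_from_filament(0.41, 10 / 256), 11L)
  expect_true(ssim_params(10, L = 1)$window_px %% 2 == 1)
})

test_that("the evaluation field keeps deposit in and out of path", {
  case <- scaffold_case()
  ev <- build_recon_full(case$dmap, case$recon)
  # background excluded
  expect_true(all(ev[case$dmap$labels == 0L] == 0))
  # stringing thickness included
  str_px <- case$dmap$labels == 5L
  expect_true(any(ev[str_px] > 0))
  # all-background map zeroes everything
  dm0 <- case$dmap; dm0$labels[] <- 0L
  expect_true(all(build_recon_full(dm0, case$recon) == 0))
})

test_that("fidelity series summarises layers with mean and spread", {
  fs <- fidelity_series(c(0.9, 0.9, 0.9))
  g <- glance(fs)
  expect_equal(g$mean, 0.9)
  expect_equal(g$sd, 0)
  g1 <- glance(fidelity_series(0.83))
  expect_equal(g1$n, 1)
  expect_equal(g1$sd, 0)
})

test_that("fidelity strictly decreases as injected breakage grows", {
  g <- tiny_grid(128)
  tm <- rasterize_layer(seg(-4.5, 0, 4.5, 0), g)
  fid_for_gap <- function(len) {
    spec <- if (len > 0)
      defect_spec(breakage = data.frame(start_mm = 2, end_mm = 2 + len))
    else defect_spec()
    sp <- render_heightmap(tm, spec)
    print_fidelity(tm, sp$height)$mean_ssim
  }
  fids <- vapply(c(0, 1, 2.5, 4), fid_for_gap, numeric(1))
  expect_true(all(diff(fids) < 0))
  expect_equal(fids[1], 1, tolerance = 1e-9)
})
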