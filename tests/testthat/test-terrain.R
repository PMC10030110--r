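# Terrain fields, patch statistics, and roughness measures.

test_that("terrain files round-trip bit-exactly and invalid grids are rejected", {
  set.seed(42)
  h <- matrix(rnorm(60 * 20, sd = 0.01), 60, 20)
  field <- terrain_field(h, 0.005, origin = c(0.1, -0.2))
  path <- file.path(tempdir(), "grid.csv")
  write_terrain(field, path)
  back <- load_terrain(path)
  expect_identical(back$heights, field$heights)
  expect_equal(back$resolution, field$resolution)
  expect_equal(back$origin, field$origin)

  # flat 3x3 grid: extents follow the node-registered convention
  tiny <- terrain_field(matrix(0, 3, 3), 0.005)
  expect_equal(tiny$track_length, 0.01)
  expect_equal(tiny$track_width, 0.01)

  h_bad <- h; h_bad[7, 3] <- NA
  expect_error(terrain_field(h_bad, 0.005), "finite")
  bad_path <- file.path(tempdir(), "bad.csv")
  writeLines(c("0,0,0", "0,NA,0", "0,0,0"), bad_path)
  jsonlite::write_json(list(resolution = 0.005, origin = c(0, 0)),
                       paste0(bad_path, ".json"), auto_unbox = TRUE)
  expect_error(load_terrain(bad_path), "row")
  expect_error(terrain_field(h, -1), "resolution")
})

test_that("patch statistics match order-statistic oracles and translation invariance", {
  # constant patch
  const <- terrain_field(matrix(0.004, 41, 41), 0.005)
  ps <- patch_stats(const, c(0.1, 0.1))
  expect_equal(ps$h_iqr, 0)
  expect_equal(ps$h_median, 0.004)

  # four distinct heights {1,2,3,4} mm: brute-force type-7 quantile oracle
  h4 <- matrix(c(0.001, 0.002, 0.003, 0.004), 2, 2)
  f4 <- terrain_field(h4, 0.05)
  ps4 <- patch_stats(f4, c(0.025, 0.025), patch_size = c(0.2, 0.2))
  expect_equal(ps4$n_nodes, 4L)
  oracle_q <- function(x, p) {            # direct order-statistic rule
    x <- sort(x); hh <- (length(x) - 1) * p
    x[floor(hh) + 1] + (hh - floor(hh)) * (x[min(floor(hh) + 2, length(x))] -
                                             x[floor(hh) + 1])
  }
  expect_equal(ps4$h_iqr, oracle_q(c(1, 2, 3, 4), 0.75) / 1000 -
                 oracle_q(c(1, 2, 3, 4), 0.25) / 1000)
  expect_equal(ps4$h_median, 0.0025)
  expect_true(ps4$clipped)

  # sinusoid patch spanning one full period: median zero by symmetry
  fs <- sinusoid_field(A = 0.01, wl = 0.1)
  ps_sin <- patch_stats(fs, c(0.05, 3.0), patch_size = c(0.02, 0.1 - 0.005))
  expect_equal(ps_sin$h_median, 0, tolerance = 1e-9)

  # translation invariance of the IQR; median shifts by the offset
  set.seed(7)
  base <- matrix(rnorm(50 * 30, sd = 0.01), 50, 30)
  for (off in c(-0.02, 0.013, 1)) {
    fa <- terrain_field(base, 0.005)
    fb <- terrain_field(base + off, 0.005)
    pa <- patch_stats(fa, c(0.06, 0.12))
    pb <- patch_stats(fb, c(0.06, 0.12))
    expect_equal(pb$h_iqr, pa$h_iqr)
    expect_equal(pb$h_median, pa$h_median + off)
  }

  expect_error(patch_stats(fs, c(10, 10)), "outside")
})

test_that("patch lookup table equals node-centred patch_stats, including clipped edges", {
  set.seed(11)
  f <- terrain_field(matrix(rnorm(120 * 40, sd = 0.01), 120, 40), 0.005)
  lut <- patch_lookup(f, 0.095)
  for (node in list(c(30, 20), c(1, 1), c(120, 40), c(5, 2))) {
    ctr <- c((node[2L] - 1L) * 0.005, (node[1L] - 1L) * 0.005)  # (x, y)
    ps <- patch_stats(f, ctr, c(0.095, 0.095))
    expect_equal(lut$iqr[node[1L], node[2L]], ps$h_iqr)
    expect_equal(lut$median[node[1L], node[2L]], ps$h_median)
  }
})

test_that("amplitude and wavelength are recovered from analytic fields", {
  fs <- sinusoid_field(A = 0.01, wl = 0.1, length = 6)
  st <- measure_amplitude_wavelength(fs)
  # peak-to-valley 2A and period wl, to within one grid spacing
  expect_equal(st$amplitude_mean, 0.02, tolerance = 0.1)
  expect_lt(st$amplitude_sd, 1e-3)
  expect_equal(st$wavelength_mean, 0.1, tolerance = 0.005 / 0.1)
  expect_lt(st$wavelength_sd, 1e-6)

  flat <- flat_field(length = 2, width = 0.1)
  st0 <- measure_amplitude_wavelength(flat)
  expect_equal(st0$amplitude_mean, 0)
  expect_true(st0$flat)
  expect_true(is.nan(st0$wavelength_mean))
})

test_that("cell grids tile the region and assign boundary points uniquely", {
  f <- flat_field(length = 9.88, width = 0.57)
  grid <- build_cell_grid(f, foot_length = 0.19)
  expect_equal(grid$n_rows, 52L)    # floor(9.88 / 0.19)
  expect_equal(grid$n_cols, 6L)     # floor(0.57 / 0.095)
  expect_true(all(grid$h_iqr == 0, na.rm = TRUE))

  # a point exactly on an interior boundary belongs to exactly one cell
  b <- assign_cells(grid, x = 0.095, y = 0.19)
  expect_equal(b$i, 2L)
  expect_equal(b$j, 2L)
  outside <- assign_cells(grid, x = -0.01, y = 100)
  expect_true(is.na(outside$i) && is.na(outside$j))

  expect_error(build_cell_grid(f, foot_length = 5), "width")
})
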