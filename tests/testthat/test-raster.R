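test_that("class_fraction matches direct block counting and handles degenerate covers", {
  codes <- lc_codes()
  target <- grid_spec(0, 200, 100, 2, 2)

  all_tree <- const_lc(codes[["TREE"]], 40, 40, 5)
  expect_equal(class_fraction(all_tree, target, codes[["TREE"]])$values,
               matrix(1, 2, 2))

  no_tree <- const_lc(codes[["GRASS"]], 40, 40, 5)
  expect_equal(class_fraction(no_tree, target, codes[["TREE"]])$values,
               matrix(0, 2, 2))

  lc <- random_lc(120, 120, res = 25, p_tree = 0.4, seed = 11)
  tgt <- grid_spec(0, 3000, 1000, 3, 3)
  got <- class_fraction(lc, tgt, codes[["TREE"]])
  expect_equal(got$values, bf_class_fraction(lc, tgt, codes[["TREE"]]))
  expect_true(all(got$values >= 0 & got$values <= 1))
})

test_that("a 3 km cell over 600x600 5 m cells with 90000 tree cells has woodfrac 0.25", {
  codes <- lc_codes()
  v <- matrix(codes[["GRASS"]], 600, 600)
  v[seq_len(90000)] <- codes[["TREE"]]
  lc <- eq_raster(v, grid_spec(0, 3000, 5, 600, 600), role = "landcover")
  tgt <- grid_spec(0, 3000, 3000, 1, 1)
  expect_equal(class_fraction(lc, tgt, codes[["TREE"]])$values[1, 1], 0.25)
})

test_that("fractions over complementary code sets sum to one per target cell", {
  codes <- lc_codes()
  lc <- random_lc(60, 60, res = 50, seed = 3)
  tgt <- grid_spec(0, 3000, 1000, 3, 3)
  green <- class_fraction(lc, tgt, codes[c("TREE", "GRASS", "WATER")])
  rest <- class_fraction(lc, tgt, codes[c("BUILDING", "MINERAL", "BARE")])
  expect_equal(green$values + rest$values, matrix(1, 3, 3))
})

test_that("class_fraction rejects non-nesting grids naming the offence", {
  lc <- const_lc(lc_codes()[["TREE"]], 40, 40, 5)
  expect_error(class_fraction(lc, grid_spec(0, 200, 72, 2, 2), 1L),
               "not a multiple")
  expect_error(class_fraction(lc, grid_spec(10, 200, 100, 2, 2), 1L),
               "does not tile")
})

test_that("cells_within equals brute-force enumeration on random rasters", {
  set.seed(42)
  for (i in 1:6) {
    lc <- random_lc(sample(20:60, 1), sample(20:60, 1), res = 5,
                    p_tree = runif(1, 0.1, 0.6), seed = i)
    ext <- grid_extent(lc$grid)
    x <- runif(1, ext["xmin"] - 20, ext["xmax"] + 20)
    y <- runif(1, ext["ymin"] - 20, ext["ymax"] + 20)
    r <- runif(1, 5, 120)
    got <- cells_within(lc, x, y, r, lc_codes()[["TREE"]])
    exp <- bf_cells_within(lc, x, y, r, lc_codes()[["TREE"]])
    expect_identical(got$count, exp$count)
    expect_identical(got$area_m2, exp$area_m2)
  }
})

test_that("cells_within counts by centre distance with boundary conventions", {
  codes <- lc_codes()
  # tree cells with centres at 10 m and 25 m from the query point
  v <- matrix(codes[["GRASS"]], 20, 20)
  g <- grid_spec(0, 100, 5, 20, 20)
  lc0 <- eq_raster(v, g, role = "landcover")
  # centres along row at y = 47.5: x = 2.5, 7.5, ..., query at (2.5, 47.5)
  v[11, 3] <- codes[["TREE"]]  # centre (12.5, 47.5): 10 m away
  v[11, 6] <- codes[["TREE"]]  # centre (27.5, 47.5): 25 m away
  lc <- eq_raster(v, g, role = "landcover")
  expect_identical(cells_within(lc, 2.5, 47.5, 30, codes[["TREE"]])$count, 2L)

  # a single tree centre exactly 31 m away is outside a 30 m radius
  v0 <- matrix(codes[["GRASS"]], 20, 20)
  v0[11, 1] <- codes[["TREE"]]  # centre (2.5, 47.5)
  lc1 <- eq_raster(v0, g, role = "landcover")
  expect_identical(cells_within(lc1, 33.5, 47.5, 30, codes[["TREE"]])$count, 0L)
  # and exactly 30 m away is inside (boundary inclusive)
  expect_identical(cells_within(lc1, 32.5, 47.5, 30, codes[["TREE"]])$count, 1L)
})

test_that("circular tree-cover area approximates the disc and is monotone in radius", {
  lc <- const_lc(lc_codes()[["TREE"]], 200, 200, 5)
  a <- cells_within(lc, 500, 500, 300, lc_codes()[["TREE"]])
  expect_identical(a$count, bf_cells_within(lc, 500, 500, 300, 1L)$count)
  expect_lt(abs(a$area_m2 - pi * 300^2) / (pi * 300^2), 0.002)
  radii <- c(10, 30, 100, 150, 300)
  counts <- vapply(radii, function(r) cells_within(lc, 500, 500, r, 1L)$count,
                   integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("sample_at returns the containing cell value with half-open edges", {
  r <- const_conc(10.64, 4, 4, 1000)
  expect_equal(sample_at(r, c(1, 3999, 2000), c(1, 3999, 2000)),
               rep(10.64, 3))

  # checkerboard against direct index arithmetic at random points
  v <- matrix(runif(50 * 50, 1, 20), 50, 50)
  cb <- eq_raster(v, grid_spec(0, 500, 10, 50, 50))
  set.seed(7)
  x <- runif(1000, 0, 500 - 1e-9)
  y <- runif(1000, 1e-9, 500)
  expect_equal(sample_at(cb, x, y), bf_sample_at(cb, x, y))

  # interior edge point belongs to the right/lower neighbour
  v2 <- matrix(1:4, 2, 2)
  r2 <- eq_raster(v2 + 0, grid_spec(0, 20, 10, 2, 2))
  expect_equal(sample_at(r2, 10, 15), v2[1, 2])  # vertical edge -> right cell
  expect_equal(sample_at(r2, 5, 10), v2[2, 1])   # horizontal edge -> lower cell

  expect_error(sample_at(r2, 25, 5), "outside the raster extent")
})

test_that("bilinear resampling preserves constants and reproduces linear ramps", {
  src <- const_conc(3, 4, 4, 1000)
  tgt <- grid_spec(0, 4000, 250, 16, 16)
  expect_equal(bilinear_resample(src, tgt)$values, matrix(3, 16, 16))

  # values linear in x: a + b*x at cell centres
  g <- grid_spec(0, 4000, 1000, 4, 4)
  cx <- grid_centres(g)$x
  ramp <- eq_raster(matrix(rep(2 + 0.003 * cx, each = 4), 4, 4), g)
  # target strictly inside the source centre lattice so no edge clamping
  tgt2 <- grid_spec(500, 3500, 250, 12, 12)
  got <- bilinear_resample(ramp, tgt2)
  expect_equal(got$values,
               matrix(rep(2 + 0.003 * grid_centres(tgt2)$x, each = 12), 12, 12),
               tolerance = 1e-9)
})

test_that("bilinear output hits source values at coincident centres and never overshoots", {
  set.seed(9)
  g <- grid_spec(0, 5000, 1000, 5, 5)
  src <- eq_raster(matrix(runif(25, 5, 20), 5, 5), g)
  same <- bilinear_resample(src, g)
  expect_equal(same$values, src$values)

  tgt <- grid_spec(0, 5000, 100, 50, 50)
  out <- bilinear_resample(src, tgt)
  expect_true(all(out$values >= min(src$values) - 1e-12))
  expect_true(all(out$values <= max(src$values) + 1e-12))

  big <- grid_spec(-100, 5100, 100, 54, 54)
  expect_error(bilinear_resample(src, big), "not contained")
})

test_that("rasters round-trip through the ASCII grid format", {
  dir <- withr::local_tempdir()
  set.seed(4)
  r <- eq_raster(matrix(runif(12, 1, 30), 3, 4), grid_spec(100, 700, 200, 3, 4))
  p <- file.path(dir, "r.asc")
  write_ascii_grid(r, p)
  back <- read_ascii_grid(p)
  expect_equal(back$values, r$values, tolerance = 1e-12)
  expect_true(grid_equal(back$grid, r$grid))

  lc <- random_lc(10, 10, seed = 2)
  write_ascii_grid(lc, file.path(dir, "lc.asc"))
  lc2 <- read_ascii_grid(file.path(dir, "lc.asc"), role = "landcover")
  expect_identical(lc2$values, lc$values)
})
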