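# Closed forms: a disk is the normalisation reference for roundness, shape
# factor, aspect ratio and deformity (all 1); a 200 x 4 bar has height ~200,
# width ~4, straight skeleton (fractal dimension 1) and 4 corners; an
# axis-aligned square has exact area and a perimeter known up to the Crofton
# estimator's documented bias on rectangles.

test_that("disk descriptors equal their normalisation reference", {
  d <- measure_fiber(raster_disk(20), 1)
  expect_lt(abs(d$shape_factor - 1), 0.05)
  expect_lt(abs(d$roundness - 1), 0.05)
  expect_lt(abs(d$aspect_ratio - 1), 0.05)
  expect_lt(abs(d$deformity - 1), 0.05)
  expect_lt(abs(d$area - pi * 400) / (pi * 400), 0.02)
  expect_lt(abs(d$height - 40) / 40, 0.02)
  expect_lt(abs(d$perimeter - 2 * pi * 20) / (2 * pi * 20), 0.02)
})

test_that("bar descriptors match rectangle closed forms", {
  d <- measure_fiber(raster_bar(200, 4), 1)
  expect_lt(abs(d$height - 200) / 200, 0.02)
  expect_lt(abs(d$width - 4) / 4, 0.25)
  expect_lt(abs(d$fractal_dimension - 1), 0.05)
  expect_lte(abs(d$vertices - 4), 1)
  expect_equal(d$area, 800)
  expect_gt(d$aspect_ratio, 20)
})

test_that("square area is exact and perimeter within the estimator tolerance", {
  d <- measure_fiber(raster_square(20), 1)
  expect_equal(d$area, 400)
  expect_lt(abs(d$perimeter - 80) / 80, 0.08)
  expect_equal(d$vertices, 4L)
})

test_that("height and deformity agree with brute-force pixel oracles", {
  for (mk in list(raster_L(), raster_bar(60, 6), raster_disk(12))) {
    d <- measure_fiber(mk, 1)
    expect_lt(abs(d$height - oracle_feret(mk)) / oracle_feret(mk), 0.01)
    rg <- oracle_radius_gyration(mk)
    rg_disk <- sqrt(sum(mk) / pi) / sqrt(2)
    expect_lt(abs(d$deformity - rg / rg_disk), 1e-6)
  }
})

test_that("box-count slope of the implementation matches the oracle counts", {
  m <- raster_bar(120, 2)
  pts <- which(itfprofiler:::skeletonize(m), arr.ind = TRUE)
  sizes <- c(2, 4, 8, 16, 32)
  n_oracle <- oracle_box_count(pts, sizes)
  fit <- lm(log(n_oracle) ~ log(1 / sizes))
  d <- measure_fiber(m, 1)
  expect_lt(abs(d$fractal_dimension - unname(coef(fit)[2])), 0.05)
})

test_that("descriptors are scale covariant", {
  m <- raster_L()
  d1 <- measure_fiber(m, 1)
  d2 <- measure_fiber(m, 2)
  expect_equal(d2$area, 4 * d1$area)
  expect_equal(d2$width, 2 * d1$width)
  expect_equal(d2$height, 2 * d1$height)
  expect_equal(d2$perimeter, 2 * d1$perimeter)
  for (p in c("roundness", "aspect_ratio", "perimeter_ratio",
              "shape_factor", "deformity", "fractal_dimension")) {
    expect_lt(abs(d2[[p]] - d1[[p]]) / d1[[p]], 0.05)
  }
})

test_that("descriptor bounds hold on segmented synthetic fibers", {
  sim <- get_loose_tile(42)
  od <- deconvolve_stain(sim$image, pixel_size_um = 0.46)
  seg <- segment_fibers(od)
  m <- measure_fibers(seg)
  expect_equal(nrow(m), seg$n_fibers)
  expect_true(all(m$area > 0 & m$width > 0 & m$height > 0 &
                    m$perimeter > 0))
  expect_true(all(m$roundness > 0 & m$roundness <= 1))
  expect_true(all(m$shape_factor > 0 & m$shape_factor <= 1))
  expect_true(all(m$aspect_ratio >= 1))
  expect_true(all(m$perimeter_ratio >= 1))
  expect_true(all(m$vertices >= 3))
  expect_true(all(m$fractal_dimension >= 1 & m$fractal_dimension <= 2))
})

test_that("an empty mask is a value error", {
  expect_error(measure_fiber(matrix(FALSE, 5, 5), 1),
               class = "itf_value_error")
})
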