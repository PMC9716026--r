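test_that("fiber tiles are byte-identical under a fixed seed", {
  p <- fiber_preset("loose_plexus", n_fibers = 10L, seed = 7)
  a <- simulate_fiber_roi(p)
  b <- simulate_fiber_roi(p)
  expect_identical(a$image, b$image)
  expect_identical(a$fibers$pixels, b$fibers$pixels)
})

test_that("zero fibers give a clean background tile", {
  p <- fiber_preset("loose_plexus", n_fibers = 0L, seed = 1)
  sim <- simulate_fiber_roi(p)
  expect_equal(nrow(sim$fibers), 0L)
  expect_true(all(sim$od_truth == 0))
})

test_that("dense bundles are more orientation-aligned than loose plexus", {
  for (s in 1:3) {
    cv_loose <- circular_variance(
      simulate_fiber_roi(fiber_preset("loose_plexus",
                                      seed = s))$fibers$base_orientation_rad)
    cv_dense <- circular_variance(
      simulate_fiber_roi(fiber_preset("dense_bundle",
                                      seed = s))$fibers$base_orientation_rad)
    expect_lt(cv_dense, cv_loose)
  }
})

test_that("ground-truth masks are disjoint and match rendered pixels", {
  sim <- get_loose_tile(42)
  all_pix <- unlist(sim$fibers$pixels)
  # no crossings allowed in the preset, so masks must not overlap
  expect_equal(length(all_pix), length(unique(all_pix)))
  expect_equal(sum(sim$od_truth > 0), length(all_pix))
  expect_equal(sum(sim$fibers$n_pixels), length(all_pix))
})

test_that("hole punching removes the requested tissue fraction", {
  p <- fiber_preset("loose_plexus", n_fibers = 5L, hole_fraction = 0.2,
                    seed = 3)
  sim <- simulate_fiber_roi(p)
  expect_lt(abs(mean(!sim$tissue_mask) - 0.2), 0.05)
  # fibers avoid the holes entirely
  expect_true(all(sim$tissue_mask[unlist(sim$fibers$pixels)]))
})

test_that("invalid simulator parameters are rejected", {
  expect_error(fiber_sim_params(pixel_size_um = 0),
               class = "itf_parameter_error")
  expect_error(fiber_sim_params(field_width_mm = -1),
               class = "itf_parameter_error")
  expect_error(fiber_sim_params(hole_fraction = 1),
               class = "itf_parameter_error")
  expect_error(fiber_sim_params(bundle_fraction = 1.2),
               class = "itf_parameter_error")
})
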