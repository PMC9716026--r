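test_that("density is the exact fiber count per tissue area", {
  labs <- matrix(0L, 100, 100)
  labs[10:12, 10:30] <- 1L
  labs[50:52, 50:70] <- 2L
  tis <- matrix(TRUE, 100, 100)
  px <- 10  # 100 px = 1 mm -> tissue area = 1 mm^2
  st <- summarize_roi(labs, tis, pixel_size_um = px)
  expect_equal(st$n_fibers, 2L)
  expect_equal(st$density, 2 / st$tissue_area_mm2)
  expect_equal(st$pct_stained_area,
               100 * sum(labs > 0) / sum(tis))
})

test_that("an empty label map gives zero density and %SA", {
  st <- summarize_roi(matrix(0L, 50, 50), matrix(TRUE, 50, 50),
                      pixel_size_um = 1)
  expect_equal(st$n_fibers, 0L)
  expect_equal(st$density, 0)
  expect_equal(st$pct_stained_area, 0)
  expect_true(is.na(st$mean_area))
})

test_that("zero tissue area raises the no-tissue error", {
  expect_error(summarize_roi(matrix(0L, 10, 10), matrix(FALSE, 10, 10), 1),
               class = "itf_no_tissue_error")
})

test_that("%SA and per-parameter summaries are internally consistent", {
  sim <- get_loose_tile(42)
  od <- deconvolve_stain(sim$image, pixel_size_um = 0.46)
  tis <- compute_tissue_mask(sim$image, pixel_size_um = 0.46)
  seg <- segment_fibers(od, tissue_mask = tis$mask)
  st <- summarize_roi(seg, tis)
  per <- st$fibers[[1]]
  expect_equal(st$n_fibers, nrow(per))
  expect_equal(st$mean_roundness, mean(per$roundness))
  expect_equal(st$sd_area, sd(per$area))
  expect_true(st$pct_stained_area > 0 && st$pct_stained_area < 100)
})

test_that("staining QC separates blank, nominal, and saturated tiles", {
  blank <- array(1, dim = c(40, 40, 3))
  tis_all <- matrix(TRUE, 40, 40)
  expect_equal(qc_roi(NULL, summarize_od(blank, tis_all))$reason,
               "insufficient staining")
  black <- array(0.01, dim = c(40, 40, 3))
  expect_equal(qc_roi(NULL, summarize_od(black, tis_all))$reason,
               "excessive staining")
  sim <- get_loose_tile(42)
  tis <- compute_tissue_mask(sim$image, pixel_size_um = 0.46)
  verdict <- qc_roi(NULL, summarize_od(sim$image, tis$mask))
  expect_true(verdict$pass)
  expect_false(qc_roi(NULL, summarize_od(sim$image, tis$mask),
                      degenerate = TRUE)$pass)
})
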