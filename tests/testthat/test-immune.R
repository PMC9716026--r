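make_mif <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- mif_sim_params(field_width_mm = 0.5, field_height_mm = 0.5,
                          densities_per_mm2 = c(`CD8 T` = 200, `CD4 T` = 300,
                                                `B cell` = 150,
                                                macrophage = 100,
                                                neutrophil = 50,
                                                other = 150),
                          background_sd = 0, seed = 21)
      sim <- simulate_mif_roi(p)
      nuc <- detect_nuclei(sim$image[, , "DAPI"], pixel_size_um = 1)
      cells <- classify_phenotypes(measure_cell_intensities(sim$image, nuc))
      cache <<- list(sim = sim, nuc = nuc, cells = cells)
    }
    cache
  }
})

test_that("a blank DAPI channel yields zero nuclei", {
  expect_equal(nrow(detect_nuclei(matrix(0, 100, 100))$cells), 0L)
  noise <- matrix(abs(rnorm(100 * 100, 0, 0.01)), 100)
  expect_equal(nrow(detect_nuclei(noise)$cells), 0L)
})

test_that("planted non-overlapping nuclei are detected within 5%", {
  x <- make_mif()
  n_true <- nrow(x$sim$truth_cells)
  expect_gt(n_true, 150)
  expect_lte(abs(nrow(x$nuc$cells) - n_true) / n_true, 0.05)
})

test_that("nucleus detection is deterministic", {
  x <- make_mif()
  again <- detect_nuclei(x$sim$image[, , "DAPI"], pixel_size_um = 1)
  expect_identical(x$nuc$labels, again$labels)
})

test_that("marker logic implements the panel definitions", {
  base <- tibble::tibble(cell_id = 1:5, x_um = 1:5, y_um = 1:5,
                         area_um2 = 30,
                         ring_CD3 = c(1, 1, 0, 0, 0),
                         ring_CD8 = c(0, 1, 0, 0, 0),
                         ring_CD20 = c(0, 0, 1, 0, 0),
                         ring_CD68 = c(0, 0, 1, 1, 0),
                         ring_CD66b = c(0, 0, 0, 0, 0))
  cfg <- phenotype_config(thresholds = list(CD3 = 0.5, CD8 = 0.5,
                                            CD20 = 0.5, CD68 = 0.5,
                                            CD66b = 0.5))
  out <- classify_phenotypes(base, cfg)
  # CD3+CD8- is a CD4 T cell; CD3+CD8+ a CD8 T cell; CD20 beats CD68 in
  # the precedence order; an all-negative cell is "other"
  expect_equal(out$phenotype,
               c("CD4 T", "CD8 T", "B cell", "macrophage", "other"))
})

test_that("missing channels raise a configuration error", {
  bad <- tibble::tibble(ring_CD3 = 1, ring_CD8 = 0)
  expect_error(classify_phenotypes(bad), class = "itf_configuration_error")
})

test_that("CD4 plus CD8 T cells equal CD3-positive cells on noiseless tiles", {
  cells <- make_mif()$cells
  n_cd3 <- sum(cells$CD3_pos)
  expect_identical(sum(cells$phenotype %in% c("CD4 T", "CD8 T")), n_cd3)
})

test_that("raising a threshold never increases that phenotype's count", {
  cells <- make_mif()$cells
  thr <- attr(cells, "thresholds")
  n_b <- function(f) {
    cfg <- phenotype_config(thresholds = list(
      CD3 = thr[["CD3"]], CD8 = thr[["CD8"]], CD20 = f * thr[["CD20"]],
      CD68 = thr[["CD68"]], CD66b = thr[["CD66b"]]))
    sum(classify_phenotypes(cells, cfg)$phenotype == "B cell")
  }
  counts <- vapply(c(0.5, 1, 2, 10), n_b, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("densities partition the total and match planted rates", {
  x <- make_mif()
  s <- 500
  poly <- cbind(c(0, s, s, 0, 0), c(0, 0, s, s, 0))
  dens <- compute_density(x$cells, poly, category = "ITF", roi_id = "t")
  tot <- dens$density_per_mm2[dens$phenotype == "total"]
  expect_equal(sum(dens$density_per_mm2[dens$phenotype != "total"]), tot)
  truth_n <- table(factor(x$sim$truth_cells$phenotype,
                          levels = c("CD8 T", "CD4 T", "B cell",
                                     "macrophage", "neutrophil", "other")))
  for (ph in names(truth_n)) {
    est <- dens$n_cells[dens$phenotype == ph]
    expect_lte(abs(est - truth_n[[ph]]), max(3, 0.1 * truth_n[[ph]]))
  }
})

test_that("zero-area polygons are rejected", {
  x <- make_mif()
  degenerate <- cbind(c(0, 0, 0), c(0, 1, 0))
  expect_error(compute_density(x$cells, degenerate),
               class = "itf_value_error")
})

test_that("TTF1 positivity follows the threshold", {
  x <- make_mif()
  nuc <- x$nuc
  n <- nrow(nuc$cells)
  # synthetic nuclear stain: 40% of nuclei saturated, rest blank
  withr::with_seed(4, {
    pos_ids <- sample.int(n, round(0.4 * n))
  })
  ttf1 <- matrix(0, nrow(nuc$labels), ncol(nuc$labels))
  ttf1[nuc$labels %in% pos_ids] <- 1
  res <- ttf1_positive_density(ttf1, nuc, threshold = 0.5,
                               roi_area_mm2 = 0.25)
  expect_lt(abs(res$positive_fraction - 0.4), 0.05)
  expect_equal(res$density_per_mm2, res$n_positive / 0.25)
  # threshold above every intensity -> zero positives
  none <- ttf1_positive_density(ttf1, nuc, threshold = 2,
                                roi_area_mm2 = 0.25)
  expect_equal(none$n_positive, 0L)
  # saturated stain -> all nuclei positive
  all_pos <- ttf1_positive_density(matrix(1, nrow(nuc$labels),
                                          ncol(nuc$labels)),
                                   nuc, threshold = 0.5,
                                   roi_area_mm2 = 0.25)
  expect_equal(all_pos$n_positive, n)
})
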