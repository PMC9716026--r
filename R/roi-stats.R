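FIBER_PARAMS <- c("area", "width", "height", "perimeter", "deformity",
                  "roundness", "aspect_ratio", "perimeter_ratio",
                  "shape_factor", "vertices", "fractal_dimension")

#' ROI-level fiber statistics
#'
#' Density (fibers per mm^2 of tissue, not of tile) and the percentage of
#' fiber-stained area (sum of fiber areas over the valid tissue area), plus
#' the mean and SD of each of the eleven per-fiber descriptors. With zero
#' fibers, density and %SA are 0 and the per-parameter summaries are
#' missing.
#'
#' @param labels A `fiber_labels` object or integer label matrix.
#' @param tissue A `tissue_mask` object or logical matrix.
#' @param pixel_size_um Pixel size (um); inferred from `labels` when
#'   possible.
#' @param per_fiber Optional precomputed [measure_fibers()] table.
#' @return One-row tibble: `n_fibers`, `tissue_area_mm2`, `density`,
#'   `pct_stained_area`, `mean_*` and `sd_*` for each descriptor, plus a
#'   `fibers` list-column holding the per-fiber table.
#' @export
summarize_roi <- function(labels, tissue, pixel_size_um = NULL,
                          per_fiber = NULL) {
  if (inherits(labels, "fiber_labels")) {
    if (is.null(pixel_size_um)) pixel_size_um <- labels$pixel_size_um
    lab_mat <- labels$labels
  } else lab_mat <- labels
  if (is.null(pixel_size_um)) pixel_size_um <- 0.46
  tmask <- if (inherits(tissue, "tissue_mask")) tissue$mask else tissue
  tissue_area_mm2 <- sum(tmask) * (pixel_size_um / 1000)^2
  if (tissue_area_mm2 <= 0) {
    abort("No tissue in ROI; density and %SA are undefined.",
          class = "itf_no_tissue_error")
  }
  if (is.null(per_fiber)) per_fiber <- measure_fibers(lab_mat, pixel_size_um)
  n_fib <- nrow(per_fiber)
  fiber_area_mm2 <- sum(as.integer(lab_mat) > 0) * (pixel_size_um / 1000)^2
  out <- tibble(n_fibers = n_fib, tissue_area_mm2 = tissue_area_mm2,
                density = n_fib / tissue_area_mm2,
                pct_stained_area = 100 * fiber_area_mm2 / tissue_area_mm2)
  for (p in FIBER_PARAMS) {
    v <- per_fiber[[p]]
    out[[paste0("mean_", p)]] <- if (n_fib) mean(v) else NA_real_
    out[[paste0("sd_", p)]] <- if (n_fib > 1L) sd(v) else NA_real_
  }
  out$fibers <- list(per_fiber)
  out
}

#' Default staining-quality bounds
#'
#' @param understain_od Median channel-mean tissue optical density below
#'   which the tile is called insufficiently stained.
#' @param overstain_od Median above which it is called excessively stained.
#' @return Named list of bounds.
#' @export
qc_bounds <- function(understain_od = 0.03, overstain_od = 1.0) {
  list(understain_od = understain_od, overstain_od = overstain_od)
}

#' Staining / segmentation quality verdict for an ROI
#'
#' Tiles whose staining is insufficient or excessive for the segmentation
#' algorithm, or whose intensity mixture degenerated, are excluded from the
#' cohort analysis, mirroring the study's exclusion rules.
#'
#' @param stats A [summarize_roi()] row (may be `NULL` when segmentation
#'   failed outright).
#' @param od_summary A [summarize_od()] row.
#' @param bounds A [qc_bounds()] list.
#' @param degenerate Set `TRUE` when [segment_fibers()] flagged a
#'   degenerate mixture.
#' @return One-row tibble with `pass` (logical) and `reason`
#'   (`"ok"`, `"insufficient staining"`, `"excessive staining"`, or
#'   `"unsatisfactory segmentation"`).
#' @export
qc_roi <- function(stats, od_summary, bounds = qc_bounds(),
                   degenerate = FALSE) {
  med <- od_summary$median_tissue_od
  reason <- if (med < bounds$understain_od) {
    "insufficient staining"
  } else if (med > bounds$overstain_od) {
    "excessive staining"
  } else if (isTRUE(degenerate)) {
    "unsatisfactory segmentation"
  } else "ok"
  tibble(pass = reason == "ok", reason = reason)
}
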