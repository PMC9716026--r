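#' Specification of a parent-ROI tiling
#'
#' Describes how a parent region of interest (default 5 x 4 mm, the size
#' drawn over the invasive front in the study design) is broken into
#' 1 x 1 mm analysis tiles carrying a tumor-fraction gradient from the tumor
#' side towards the target-tissue side.
#'
#' @param parent_width_mm,parent_height_mm Parent ROI size (mm).
#' @param tile_mm Tile edge (mm); must not exceed either parent dimension.
#' @param gradient_axis `"x"` or `"y"`: axis along which the tumor fraction
#'   decreases.
#' @param jitter Uniform half-width of per-tile jitter on the fraction,
#'   bounded below half the between-column step so the gradient stays
#'   monotone within each row.
#' @param seed Integer seed.
#' @return A list of class `roi_layout_spec`.
#' @export
roi_layout_spec <- function(parent_width_mm = 5, parent_height_mm = 4,
                            tile_mm = 1, gradient_axis = c("x", "y"),
                            jitter = 0.05, seed = 1L) {
  gradient_axis <- match.arg(gradient_axis)
  stop_if_not_scalar_pos(tile_mm, "tile_mm")
  stop_if_not_scalar_pos(parent_width_mm, "parent_width_mm")
  stop_if_not_scalar_pos(parent_height_mm, "parent_height_mm")
  if (tile_mm > parent_width_mm || tile_mm > parent_height_mm) {
    abort("`tile_mm` must fit inside the parent ROI.",
          class = "itf_parameter_error")
  }
  structure(list(parent_width_mm = parent_width_mm,
                 parent_height_mm = parent_height_mm, tile_mm = tile_mm,
                 gradient_axis = gradient_axis, jitter = jitter,
                 seed = as.integer(seed)),
            class = "roi_layout_spec")
}

#' Tile a parent ROI and assign a tumor-fraction gradient
#'
#' A 5 x 4 mm parent with 1 x 1 mm tiles yields 20 tiles. Tumor fraction
#' decreases monotonically along the gradient axis (tumor side at the
#' origin); category labels are left `"unassigned"` for
#' [assign_categories()].
#'
#' @param spec A [roi_layout_spec()] object.
#' @return A tibble with one row per tile: `roi_id`, `row`, `col`, `x0_mm`,
#'   `y0_mm`, `tile_mm`, `tumor_fraction`, `category`, and a `polygon`
#'   list-column (closed 2-column matrices in um, y-down).
#' @export
simulate_roi_layout <- function(spec) {
  if (!inherits(spec, "roi_layout_spec")) {
    abort("`spec` must come from roi_layout_spec().",
          class = "itf_parameter_error")
  }
  n_cols <- as.integer(floor(spec$parent_width_mm / spec$tile_mm))
  n_rows <- as.integer(floor(spec$parent_height_mm / spec$tile_mm))
  grid <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  n_axis <- if (spec$gradient_axis == "x") n_cols else n_rows
  axis_pos <- if (spec$gradient_axis == "x") grid$col else grid$row
  step <- 1 / max(n_axis - 1L, 1L)
  base <- if (n_axis == 1L) rep(0.5, nrow(grid)) else
    (n_axis - axis_pos) / (n_axis - 1L)

  withr::with_seed(spec$seed, {
    b <- min(spec$jitter, 0.45 * step)
    frac <- pmin(pmax(base + runif(nrow(grid), -b, b), 0), 1)
    poly <- purrr::map2(grid$col, grid$row, function(cc, rr) {
      x0 <- (cc - 1) * spec$tile_mm * 1000
      y0 <- (rr - 1) * spec$tile_mm * 1000
      s <- spec$tile_mm * 1000
      cbind(x_um = c(x0, x0 + s, x0 + s, x0, x0),
            y_um = c(y0, y0, y0 + s, y0 + s, y0))
    })
    tibble(roi_id = sprintf("tile_r%d_c%d", grid$row, grid$col),
           row = grid$row, col = grid$col,
           x0_mm = (grid$col - 1) * spec$tile_mm,
           y0_mm = (grid$row - 1) * spec$tile_mm,
           tile_mm = spec$tile_mm, tumor_fraction = frac,
           category = "unassigned", polygon = poly)
  })
}
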