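rgb_to_od <- function(rgb_image, floor = 1e-3) {
  if (length(dim(rgb_image)) != 3L || dim(rgb_image)[3] != 3L) {
    abort("Expected an H x W x 3 RGB array.", class = "itf_format_error")
  }
  x <- rgb_image
  if (max(x) > 1.5) x <- x / 255   # 8/16-bit input
  -log10(pmin(pmax(x, floor), 1))
}

#' Isolate the silver-stain optical density from an RGB tile
#'
#' Converts transmitted-light RGB to per-channel optical density via the
#' Beer-Lambert law and solves the per-pixel least-squares unmixing onto the
#' supplied stain basis, returning the silver (fiber stain) component.
#' Background pixels come out near zero.
#'
#' @param rgb_image H x W x 3 array, values in `[0, 1]` (or 8/16-bit scale).
#' @param stain_vectors 2 x 3 matrix of unit-normalised stain absorbance
#'   vectors, silver first; defaults to [gomori_stain_vectors()].
#' @param pixel_size_um Pixel size carried along for downstream geometry.
#' @return A list of class `od_map` with `od` (H x W matrix, >= 0) and
#'   `pixel_size_um`.
#' @export
deconvolve_stain <- function(rgb_image,
                             stain_vectors = gomori_stain_vectors(),
                             pixel_size_um = 0.46) {
  od <- rgb_to_od(rgb_image)
  S <- stain_vectors / sqrt(rowSums(stain_vectors^2))
  # least-squares concentrations: C = (S S')^-1 S od
  A <- solve(S %*% t(S)) %*% S
  H <- dim(od)[1]; W <- dim(od)[2]
  flat <- matrix(od, H * W, 3)
  conc <- flat %*% t(A)
  silver <- matrix(pmax(conc[, 1], 0), H, W)
  structure(list(od = silver, pixel_size_um = pixel_size_um),
            class = "od_map")
}

#' Per-channel mean optical density summary over tissue
#'
#' @param rgb_image H x W x 3 RGB array.
#' @param tissue_mask Logical H x W matrix (TRUE = tissue).
#' @return One-row tibble with `median_tissue_od` and `mean_tissue_od`
#'   (channel-averaged optical density over tissue pixels).
#' @export
summarize_od <- function(rgb_image, tissue_mask) {
  od <- rgb_to_od(rgb_image)
  mean_od <- (od[, , 1] + od[, , 2] + od[, , 3]) / 3
  vals <- mean_od[tissue_mask]
  tibble(median_tissue_od = if (length(vals)) median(vals) else 0,
         mean_tissue_od = if (length(vals)) mean(vals) else 0)
}

#' Tissue mask from an RGB tile
#'
#' Tissue is any pixel with appreciable total absorbance (counterstain or
#' stain); holes and blank background transmit fully and drop out. The raw
#' mask is cleaned with a small morphological closing then opening.
#'
#' @param rgb_image H x W x 3 RGB array.
#' @param pixel_size_um Pixel size (um), used for the reported area.
#' @param od_threshold Channel-mean optical density above which a pixel
#'   counts as tissue.
#' @return A list of class `tissue_mask` with `mask` (logical H x W),
#'   `area_mm2`, and `pixel_size_um`. A fully blank tile gives an empty
#'   mask, not an error.
#' @export
compute_tissue_mask <- function(rgb_image, pixel_size_um = 0.46,
                                od_threshold = 0.04) {
  od <- rgb_to_od(rgb_image)
  mean_od <- (od[, , 1] + od[, , 2] + od[, , 3]) / 3
  raw <- mean_od > od_threshold
  if (any(raw)) {
    kern <- EBImage::makeBrush(5, shape = "disc")
    m <- EBImage::opening(EBImage::closing(raw * 1, kern), kern) > 0.5
  } else {
    m <- raw
  }
  structure(list(mask = m,
                 area_mm2 = sum(m) * (pixel_size_um / 1000)^2,
                 pixel_size_um = pixel_size_um),
            class = "tissue_mask")
}
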