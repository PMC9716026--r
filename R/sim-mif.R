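MIF_CHANNELS <- c("DAPI", "CD3", "CD8", "CD20", "CD68", "CD66b")
MIF_PHENOTYPES <- c("CD8 T", "CD4 T", "B cell", "macrophage", "neutrophil",
                    "other")

# Marker channels lit up by each phenotype (DAPI is implicit for all).
phenotype_marker_map <- function() {
  list(`CD8 T` = c("CD3", "CD8"), `CD4 T` = "CD3", `B cell` = "CD20",
       macrophage = "CD68", neutrophil = "CD66b", other = character())
}

#' Parameters for the multiplex-immunofluorescence tile simulator
#'
#' @param field_width_mm,field_height_mm Tile size (mm).
#' @param pixel_size_um Pixel size (um).
#' @param densities_per_mm2 Named vector of planted phenotype densities
#'   (cells/mm^2); names must be among `"CD8 T"`, `"CD4 T"`, `"B cell"`,
#'   `"macrophage"`, `"neutrophil"`, `"other"`.
#' @param nucleus_radius_um_mean,nucleus_radius_um_sd Nucleus size.
#' @param marker_intensity_mean,marker_intensity_sd Signal on positive
#'   marker rings and DAPI nuclei.
#' @param background_sd Additive background noise SD (0 gives noiseless
#'   tiles).
#' @param seed Integer seed.
#' @return A list of class `mif_sim_params`.
#' @export
mif_sim_params <- function(field_width_mm = 1, field_height_mm = 1,
                           pixel_size_um = 1,
                           densities_per_mm2 = c(`CD8 T` = 200, `CD4 T` = 300,
                                                 `B cell` = 150,
                                                 macrophage = 100,
                                                 neutrophil = 50,
                                                 other = 200),
                           nucleus_radius_um_mean = 3.5,
                           nucleus_radius_um_sd = 0.4,
                           marker_intensity_mean = 0.8,
                           marker_intensity_sd = 0.08,
                           background_sd = 0.01, seed = 1L) {
  stop_if_not_scalar_pos(pixel_size_um, "pixel_size_um")
  stop_if_not_scalar_pos(field_width_mm, "field_width_mm")
  stop_if_not_scalar_pos(field_height_mm, "field_height_mm")
  bad <- setdiff(names(densities_per_mm2), MIF_PHENOTYPES)
  if (length(bad) || is.null(names(densities_per_mm2))) {
    abort(paste0("Unknown phenotype key(s): ",
                 paste(bad, collapse = ", ")),
          class = "itf_parameter_error")
  }
  if (any(densities_per_mm2 < 0)) {
    abort("Densities must be non-negative.", class = "itf_parameter_error")
  }
  structure(list(field_width_mm = field_width_mm,
                 field_height_mm = field_height_mm,
                 pixel_size_um = pixel_size_um,
                 densities_per_mm2 = densities_per_mm2,
                 nucleus_radius_um_mean = nucleus_radius_um_mean,
                 nucleus_radius_um_sd = nucleus_radius_um_sd,
                 marker_intensity_mean = marker_intensity_mean,
                 marker_intensity_sd = marker_intensity_sd,
                 background_sd = background_sd, seed = as.integer(seed)),
            class = "mif_sim_params")
}

#' Simulate a multichannel immunofluorescence tile with a truth table
#'
#' Plants cells at Poisson(density x area) counts per phenotype, renders a
#' DAPI nucleus disk for each and marker signal on a 2-um perinuclear ring
#' for the channels its phenotype expresses (CD8 T: CD3+CD8; CD4 T: CD3;
#' B cell: CD20; macrophage: CD68; neutrophil: CD66b; other: DAPI only).
#' Cells are placed without overlap so ring measurements stay unmixed.
#'
#' @param params A [mif_sim_params()] object.
#' @return A list of class `mif_roi` with `image` (H x W x 6 array, channels
#'   DAPI, CD3, CD8, CD20, CD68, CD66b), `truth_cells` (tibble: `cell_id`,
#'   `x_um`, `y_um`, `radius_um`, `phenotype`), and `params`.
#' @export
simulate_mif_roi <- function(params) {
  if (!inherits(params, "mif_sim_params")) {
    abort("`params` must come from mif_sim_params().",
          class = "itf_parameter_error")
  }
  px <- params$pixel_size_um
  W <- as.integer(round(params$field_width_mm * 1000 / px))
  H <- as.integer(round(params$field_height_mm * 1000 / px))
  area_mm2 <- params$field_width_mm * params$field_height_mm
  ring_um <- 2

  withr::with_seed(params$seed, {
    dens <- params$densities_per_mm2
    counts <- rpois(length(dens), dens * area_mm2)
    names(counts) <- names(dens)

    min_sep <- 2 * (params$nucleus_radius_um_mean +
                      3 * params$nucleus_radius_um_sd + ring_um) + 1
    total <- sum(counts)
    xs <- ys <- numeric(total)
    n_acc <- 0L
    guard <- 0L
    while (n_acc < total && guard < 200L * total + 1000L) {
      guard <- guard + 1L
      cx <- runif(1, min_sep / 2, params$field_width_mm * 1000 - min_sep / 2)
      cy <- runif(1, min_sep / 2, params$field_height_mm * 1000 - min_sep / 2)
      if (n_acc > 0L &&
          min((xs[1:n_acc] - cx)^2 + (ys[1:n_acc] - cy)^2) < min_sep^2) next
      n_acc <- n_acc + 1L
      xs[n_acc] <- cx; ys[n_acc] <- cy
    }
    if (n_acc < total) {
      warn("Tile too crowded; placed fewer cells than drawn counts.")
      # trim per-phenotype counts proportionally from the end
    }
    phenos <- rep(names(counts), counts)[seq_len(n_acc)]
    radii <- pmax(rnorm(n_acc, params$nucleus_radius_um_mean,
                        params$nucleus_radius_um_sd), 1.5)

    # buffer pixel indices/values per channel, then composite once (cells
    # are disjoint by construction, so plain addition is exact)
    mmap <- phenotype_marker_map()
    ch_idx <- ch_val <- setNames(vector("list", length(MIF_CHANNELS)),
                                 MIF_CHANNELS)
    for (i in seq_len(n_acc)) {
      cr <- as.integer(floor(ys[i] / px)) + 1L
      cc <- as.integer(floor(xs[i] / px)) + 1L
      r_px <- radii[i] / px
      nuc <- stamp_centerline(cr, cc, r_px, H, W, clip = TRUE)
      ring <- setdiff(stamp_centerline(cr, cc, r_px + ring_um / px, H, W,
                                       clip = TRUE), nuc)
      dapi <- max(rnorm(1, params$marker_intensity_mean,
                        params$marker_intensity_sd), 0.2)
      ch_idx[["DAPI"]][[i]] <- nuc
      ch_val[["DAPI"]][[i]] <- rep(dapi, length(nuc))
      for (ch in mmap[[phenos[i]]]) {
        sig <- max(rnorm(1, params$marker_intensity_mean,
                         params$marker_intensity_sd), 0.2)
        ch_idx[[ch]][[i]] <- ring
        ch_val[[ch]][[i]] <- rep(sig, length(ring))
      }
    }
    img <- array(0, dim = c(H, W, length(MIF_CHANNELS)),
                 dimnames = list(NULL, NULL, MIF_CHANNELS))
    if (params$background_sd > 0) {
      img[] <- abs(rnorm(length(img), 0, params$background_sd))
    }
    for (k in seq_along(MIF_CHANNELS)) {
      ch <- MIF_CHANNELS[k]
      idx <- unlist(ch_idx[[ch]])
      if (!length(idx)) next
      sl <- img[, , k]
      sl[idx] <- sl[idx] + unlist(ch_val[[ch]])
      img[, , k] <- sl
    }

    truth <- tibble(cell_id = seq_len(n_acc), x_um = xs[seq_len(n_acc)],
                    y_um = ys[seq_len(n_acc)], radius_um = radii,
                    phenotype = phenos)
    structure(list(image = img, truth_cells = truth, params = params),
              class = "mif_roi")
  })
}
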