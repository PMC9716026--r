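#' Parameters for the reticulin-fiber tile simulator
#'
#' Builds the parameter record consumed by [simulate_fiber_roi()]. Defaults
#' describe a 1 x 1 mm Gomori-stained tile scanned at 0.46 um/pixel with a
#' moderately curly, isotropic ("loose plexus") fiber field. The two named
#' presets in [fiber_preset()] reproduce the loose-plexus versus dense-bundle
#' phenotypes seen at the invasive front of adenocarcinoma versus
#' leiomyosarcoma tissue.
#'
#' @param field_width_mm,field_height_mm Physical tile size in millimetres.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @param n_fibers Number of fibers to place.
#' @param length_um_mean,length_um_sd Fiber path-length distribution (um).
#' @param width_um_mean,width_um_sd Fiber width distribution (um); reticulin
#'   fibers are thin, typically under 2 um.
#' @param curliness Standard deviation of the per-step turning angle
#'   (radians); 0 gives straight fibers, larger values curlier ones.
#' @param orientation_kappa Concentration of the base-orientation
#'   distribution around the dominant direction; 0 (or negative) means
#'   isotropic, large values mean aligned.
#' @param bundle_fraction Fraction of fibers snapped to the dominant
#'   orientation (with a small jitter), emulating bundling.
#' @param allow_crossings If `FALSE`, fibers are placed with a one-pixel
#'   separation so ground-truth masks are disjoint.
#' @param stain_od_mean Optical density of the silver stain on fiber pixels.
#' @param background_od Optical density of the counterstain over tissue.
#' @param noise_sd Additive optical-density noise.
#' @param hole_fraction Fraction of the tile removed as tissue holes.
#' @param seed Integer seed; identical parameters and seed give
#'   byte-identical output.
#'
#' @return A list of class `fiber_sim_params`.
#' @export
fiber_sim_params <- function(field_width_mm = 1, field_height_mm = 1,
                             pixel_size_um = 0.46, n_fibers = 300,
                             length_um_mean = 60, length_um_sd = 20,
                             width_um_mean = 1.5, width_um_sd = 0.3,
                             curliness = 0.15, orientation_kappa = 0,
                             bundle_fraction = 0, allow_crossings = TRUE,
                             stain_od_mean = 1.0, background_od = 0.15,
                             noise_sd = 0.02, hole_fraction = 0,
                             seed = 1L) {
  stop_if_not_scalar_pos(field_width_mm, "field_width_mm")
  stop_if_not_scalar_pos(field_height_mm, "field_height_mm")
  stop_if_not_scalar_pos(pixel_size_um, "pixel_size_um")
  if (!is.numeric(n_fibers) || length(n_fibers) != 1L || n_fibers < 0) {
    abort("`n_fibers` must be a single non-negative number.",
          class = "itf_parameter_error")
  }
  stop_if_not_fraction(bundle_fraction, "bundle_fraction")
  stop_if_not_fraction(hole_fraction, "hole_fraction", open_upper = TRUE)
  structure(list(
    field_width_mm = field_width_mm, field_height_mm = field_height_mm,
    pixel_size_um = pixel_size_um, n_fibers = as.integer(n_fibers),
    length_um_mean = length_um_mean, length_um_sd = length_um_sd,
    width_um_mean = width_um_mean, width_um_sd = width_um_sd,
    curliness = curliness, orientation_kappa = orientation_kappa,
    bundle_fraction = bundle_fraction, allow_crossings = allow_crossings,
    stain_od_mean = stain_od_mean, background_od = background_od,
    noise_sd = noise_sd, hole_fraction = hole_fraction,
    seed = as.integer(seed)), class = "fiber_sim_params")
}

#' Named fiber-phenotype presets
#'
#' `"loose_plexus"` mimics the large, loose, curly reticulin network of
#' adenocarcinoma fronts; `"dense_bundle"` the short, thick, aligned bundles
#' of leiomyosarcoma. Both use the 0.25 x 0.25 mm fast tile so a full
#' simulate-segment-measure cycle stays quick.
#'
#' @param name `"loose_plexus"` or `"dense_bundle"`.
#' @param ... Overrides passed to [fiber_sim_params()].
#' @return A `fiber_sim_params` object.
#' @export
fiber_preset <- function(name = c("loose_plexus", "dense_bundle"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    loose_plexus = list(field_width_mm = 0.25, field_height_mm = 0.25,
                        n_fibers = 50L, length_um_mean = 80, length_um_sd = 20,
                        width_um_mean = 1.5, width_um_sd = 0.3,
                        curliness = 0.1, orientation_kappa = 0,
                        bundle_fraction = 0, allow_crossings = FALSE),
    dense_bundle = list(field_width_mm = 0.25, field_height_mm = 0.25,
                        n_fibers = 90L, length_um_mean = 30, length_um_sd = 8,
                        width_um_mean = 2.5, width_um_sd = 0.4,
                        curliness = 0.03, orientation_kappa = 8,
                        bundle_fraction = 0.8, allow_crossings = FALSE))
  do.call(fiber_sim_params, modifyList(base, list(...)))
}

disk_offsets <- function(r_px) {
  r <- max(r_px, 0.5)
  k <- ceiling(r)
  g <- expand.grid(dr = -k:k, dc = -k:k)
  keep <- g$dr^2 + g$dc^2 <= r^2
  cbind(dr = g$dr[keep], dc = g$dc[keep])
}

# Stamp disks of radius r_px at integer pixel centres (rows, cols); returns
# unique linear indices (column-major) inside an H x W grid, or NULL if any
# centre falls outside the grid.
stamp_centerline <- function(rows, cols, r_px, H, W, clip = FALSE) {
  if (any(rows < 1 | rows > H | cols < 1 | cols > W)) {
    if (!clip) return(NULL)
    keep <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
    rows <- rows[keep]; cols <- cols[keep]
    if (!length(rows)) return(integer())
  }
  off <- disk_offsets(r_px)
  rr <- rep(rows, each = nrow(off)) + off[, "dr"]
  cc <- rep(cols, each = nrow(off)) + off[, "dc"]
  ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  unique((cc[ok] - 1L) * H + rr[ok])
}

# Beer-Lambert stain vectors (unit-normalised RGB optical densities) for the
# silver impregnation (near-neutral grey/black) and an eosin-like pink
# counterstain. Overridable wherever stain vectors are accepted.
#' Default Gomori stain optical-density vectors
#'
#' Unit-normalised RGB absorbance vectors for the silver (fiber) stain and
#' the pink counterstain, used by the simulator and by [deconvolve_stain()].
#'
#' @return A 2 x 3 matrix with rows `silver` and `counterstain`.
#' @export
gomori_stain_vectors <- function() {
  v <- rbind(silver = c(1, 1, 1), counterstain = c(0.17, 0.95, 0.27))
  sw <- v / sqrt(rowSums(v^2))
  colnames(sw) <- c("R", "G", "B")
  sw
}

#' Simulate a Gomori-stained reticulin tile with ground truth
#'
#' Draws fibers as random-walk polylines (per-step turning angle
#' `Normal(0, curliness)`), strokes each with a disk of its width, composes a
#' two-stain optical-density image (silver fibers plus counterstain) and
#' converts it to RGB through the Beer-Lambert law. Tissue holes are punched
#' out as white regions. Every fiber's exact pixel set is returned as ground
#' truth, so segmentation and descriptor recovery can be scored directly.
#'
#' @param params A [fiber_sim_params()] object.
#' @return A list of class `fiber_roi` with elements `image` (H x W x 3 RGB
#'   array in `[0, 1]`), `od_truth` (noise-free silver optical density),
#'   `tissue_mask` (logical H x W), `fibers` (tibble: `fiber_id`,
#'   `true_length_um`, `true_mean_width_um`, `base_orientation_rad`,
#'   `n_pixels`, list-columns `centerline` and `pixels`), and `params`.
#' @export
simulate_fiber_roi <- function(params) {
  if (!inherits(params, "fiber_sim_params")) {
    abort("`params` must come from fiber_sim_params().",
          class = "itf_parameter_error")
  }
  px <- params$pixel_size_um
  W <- max(2L, as.integer(round(params$field_width_mm * 1000 / px)))
  H <- max(2L, as.integer(round(params$field_height_mm * 1000 / px)))

  withr::with_seed(params$seed, {
    tissue <- matrix(TRUE, H, W)
    if (params$hole_fraction > 0) {
      target <- params$hole_fraction * H * W
      guard <- 0L
      while (sum(!tissue) < target && guard < 10000L) {
        guard <- guard + 1L
        # hole radius scaled to the tile so the target fraction is hit
        # with little overshoot
        r_um <- runif(1, 0.02, 0.05) *
          min(params$field_width_mm, params$field_height_mm) * 1000
        cr <- sample.int(H, 1); cc <- sample.int(W, 1)
        idx <- stamp_centerline(cr, cc, r_um / px, H, W, clip = TRUE)
        tissue[idx] <- FALSE
      }
    }

    theta0 <- runif(1, 0, 2 * pi)
    occupied <- logical(H * W)
    step_um <- px
    fibers <- vector("list", params$n_fibers)
    n_placed <- 0L
    if (params$n_fibers > 0) {
      for (i in seq_len(params$n_fibers)) {
        for (attempt in seq_len(200L)) {
          theta <- if (runif(1) < params$bundle_fraction) {
            theta0 + rnorm(1, 0, 0.05)
          } else if (params$orientation_kappa > 0) {
            theta0 + rnorm(1, 0, 1 / sqrt(params$orientation_kappa))
          } else {
            runif(1, 0, 2 * pi)
          }
          len <- max(rnorm(1, params$length_um_mean, params$length_um_sd), 5)
          wid <- max(rnorm(1, params$width_um_mean, params$width_um_sd),
                     px)
          n_steps <- max(as.integer(ceiling(len / step_um)) + 1L, 2L)
          turns <- rnorm(n_steps - 1L, 0, params$curliness)
          headings <- theta + cumsum(c(0, turns[-1]))
          x0 <- runif(1, 0, params$field_width_mm * 1000)
          y0 <- runif(1, 0, params$field_height_mm * 1000)
          xs <- x0 + c(0, cumsum(step_um * cos(headings)))
          ys <- y0 + c(0, cumsum(step_um * sin(headings)))
          cols <- as.integer(floor(xs / px)) + 1L
          rows <- as.integer(floor(ys / px)) + 1L
          r_px <- (wid / 2) / px
          pix <- stamp_centerline(rows, cols, r_px, H, W)
          if (is.null(pix) || !all(tissue[pix])) next
          if (!params$allow_crossings) {
            guard_pix <- stamp_centerline(rows, cols, r_px + 1.5, H, W,
                                          clip = TRUE)
            if (any(occupied[guard_pix])) next
          }
          occupied[pix] <- TRUE
          n_placed <- n_placed + 1L
          fibers[[n_placed]] <- list(
            fiber_id = n_placed,
            centerline = cbind(x_um = xs, y_um = ys),
            true_length_um = step_um * (n_steps - 1L),
            true_mean_width_um = wid,
            base_orientation_rad = theta %% (2 * pi),
            pixels = pix)
          break
        }
      }
    }
    fibers <- fibers[seq_len(n_placed)]

    od_fiber <- matrix(0, H, W)
    for (f in fibers) od_fiber[f$pixels] <- params$stain_od_mean
    od_cs <- matrix(0, H, W)
    od_cs[tissue] <- params$background_od
    noise <- matrix(rnorm(H * W, 0, params$noise_sd), H, W)

    sv <- gomori_stain_vectors()
    img <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) {
      od_ch <- od_fiber * sv["silver", ch] +
        od_cs * sv["counterstain", ch] + noise
      od_ch[od_ch < 0] <- 0
      img[, , ch] <- 10^(-od_ch)
    }

    fiber_tbl <- tibble(
      fiber_id = vapply(fibers, `[[`, integer(1) + 0, "fiber_id"),
      true_length_um = vapply(fibers, `[[`, numeric(1), "true_length_um"),
      true_mean_width_um = vapply(fibers, `[[`, numeric(1),
                                  "true_mean_width_um"),
      base_orientation_rad = vapply(fibers, `[[`, numeric(1),
                                    "base_orientation_rad"),
      n_pixels = vapply(fibers, function(f) length(f$pixels), integer(1)),
      centerline = lapply(fibers, `[[`, "centerline"),
      pixels = lapply(fibers, `[[`, "pixels"))

    structure(list(image = img, od_truth = od_fiber, tissue_mask = tissue,
                   fibers = fiber_tbl, params = params),
              class = "fiber_roi")
  })
}

#' Circular variance of a set of angles
#'
#' `1 - |mean resultant vector|`; 0 for perfectly aligned angles, 1 for a
#' balanced spread. Used to verify that the dense-bundle preset really is
#' more aligned than the loose plexus.
#'
#' @param theta Angles in radians.
#' @return A number in `[0, 1]`.
#' @export
circular_variance <- function(theta) {
  if (!length(theta)) return(NA_real_)
  1 - sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
}
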