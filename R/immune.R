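#' Otsu threshold of a numeric vector
#'
#' Histogram-based two-class threshold maximising between-class variance;
#' used for automatic per-marker positivity cutoffs.
#'
#' @param x Numeric values.
#' @param n_bins Histogram resolution.
#' @return The threshold value.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) < 1e-12) return(rng[2])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), n_bins)
  w <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  mt <- cm[n_bins]
  bcv <- (mt * cw - cm)^2 / (cw * (1 - cw))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

#' Configuration for nucleus detection
#'
#' @param smooth_sigma_um Gaussian smoothing scale before thresholding.
#' @param min_area_um2 Minimum nucleus area kept.
#' @param watershed_tolerance Intensity tolerance of the distance-map
#'   watershed used to split touching nuclei.
#' @return A list of class `nuclei_config`.
#' @export
nuclei_config <- function(smooth_sigma_um = 1.5, min_area_um2 = 8,
                          watershed_tolerance = 1) {
  structure(list(smooth_sigma_um = smooth_sigma_um,
                 min_area_um2 = min_area_um2,
                 watershed_tolerance = watershed_tolerance),
            class = "nuclei_config")
}

#' Detect nuclei on a DAPI channel
#'
#' Classical deterministic detector: Gaussian smoothing, Otsu foreground
#' threshold, distance-map watershed to split touching nuclei, minimum-area
#' filter. A blank channel yields zero nuclei.
#'
#' @param dapi Single-channel matrix.
#' @param pixel_size_um Pixel size (um).
#' @param config A [nuclei_config()].
#' @return A list of class `nuclei` with `labels` (integer matrix) and
#'   `cells` (tibble: `cell_id`, `x_um`, `y_um`, `area_um2`).
#' @export
detect_nuclei <- function(dapi, pixel_size_um = 1,
                          config = nuclei_config()) {
  if (length(dim(dapi)) != 2L) {
    abort("`dapi` must be a single-channel matrix.",
          class = "itf_format_error")
  }
  empty <- function() {
    structure(list(labels = matrix(0L, nrow(dapi), ncol(dapi)),
                   cells = tibble(cell_id = integer(), x_um = numeric(),
                                  y_um = numeric(), area_um2 = numeric()),
                   pixel_size_um = pixel_size_um), class = "nuclei")
  }
  if (max(dapi) - min(dapi) < 1e-9) return(empty())
  sm <- EBImage::gblur(dapi, sigma = config$smooth_sigma_um / pixel_size_um)
  thr <- otsu_threshold(as.numeric(sm))
  fg <- sm > thr
  # an Otsu split inside pure background noise marks a blank channel
  if (!any(fg) || mean(fg) > 0.3) return(empty())
  dm <- EBImage::distmap(fg * 1)
  labs <- EBImage::watershed(dm, tolerance = config$watershed_tolerance)
  labs <- matrix(as.integer(labs), nrow(dapi), ncol(dapi))
  min_px <- config$min_area_um2 / pixel_size_um^2
  tab <- tabulate(labs[labs > 0])
  drop <- which(tab < min_px)
  if (length(drop)) labs[labs %in% drop] <- 0L
  ids <- setdiff(sort(unique(as.integer(labs))), 0L)
  if (!length(ids)) return(empty())
  relab <- labs
  relab[labs > 0] <- match(labs[labs > 0], ids)
  rr <- row(relab); cc <- col(relab)
  sel <- relab > 0
  cx <- tapply((cc[sel] - 0.5) * pixel_size_um, relab[sel], mean)
  cy <- tapply((rr[sel] - 0.5) * pixel_size_um, relab[sel], mean)
  ar <- tabulate(relab[sel]) * pixel_size_um^2
  structure(list(labels = relab,
                 cells = tibble(cell_id = seq_along(ids),
                                x_um = as.numeric(cx), y_um = as.numeric(cy),
                                area_um2 = ar),
                 pixel_size_um = pixel_size_um), class = "nuclei")
}

#' Per-cell marker intensities on nucleus and perinuclear ring
#'
#' Membrane/cytoplasmic markers (CD3, CD8, CD20, CD68, CD66b) are measured
#' on a ring obtained by dilating each nucleus by `ring_um`; nuclear signals
#' (DAPI, TTF1) on the nucleus itself.
#'
#' @param image H x W x C array with channel names in `dimnames`.
#' @param nuclei A [detect_nuclei()] result.
#' @param ring_um Ring width (um).
#' @return The `cells` tibble of `nuclei` extended with `nucleus_<channel>`
#'   and `ring_<channel>` mean intensities.
#' @export
measure_cell_intensities <- function(image, nuclei, ring_um = 2) {
  chans <- dimnames(image)[[3]]
  if (is.null(chans)) {
    abort("`image` must carry channel names in dimnames.",
          class = "itf_configuration_error")
  }
  labs <- nuclei$labels
  px <- nuclei$pixel_size_um
  cells <- nuclei$cells
  if (!nrow(cells)) return(cells)
  brush_r <- max(1L, as.integer(round(ring_um / px)))
  kern <- EBImage::makeBrush(2L * brush_r + 1L, shape = "disc")
  dil <- matrix(as.integer(EBImage::dilate(labs, kern)), nrow(labs),
                ncol(labs))
  ring_lab <- ifelse(labs == 0L, dil, 0L)
  nuc_sel <- labs > 0L
  ring_sel <- ring_lab > 0L
  n_cells <- nrow(cells)
  for (ch in chans) {
    sl <- image[, , ch]
    nm <- tapply(sl[nuc_sel], labs[nuc_sel], mean)
    rmu <- tapply(sl[ring_sel], ring_lab[ring_sel], mean)
    nv <- rv <- rep(0, n_cells)
    nv[as.integer(names(nm))] <- as.numeric(nm)
    rv[as.integer(names(rmu))] <- as.numeric(rmu)
    cells[[paste0("nucleus_", ch)]] <- nv
    cells[[paste0("ring_", ch)]] <- rv
  }
  cells
}

#' Phenotype-classification configuration
#'
#' @param thresholds Named list, one entry per marker (`CD3`, `CD8`,
#'   `CD20`, `CD68`, `CD66b`): `"auto"` for a per-channel Otsu threshold or
#'   an absolute positive number.
#' @param precedence Order resolving cross-lineage multi-positives after the
#'   CD3 lineage (which always takes priority).
#' @param min_auto_threshold Floor for automatic thresholds, guarding
#'   against channels containing only background.
#' @return A list of class `phenotype_config`.
#' @export
phenotype_config <- function(thresholds = list(CD3 = "auto", CD8 = "auto",
                                               CD20 = "auto", CD68 = "auto",
                                               CD66b = "auto"),
                             precedence = c("CD20", "CD68", "CD66b"),
                             min_auto_threshold = 0.1) {
  structure(list(thresholds = thresholds, precedence = precedence,
                 min_auto_threshold = min_auto_threshold),
            class = "phenotype_config")
}

#' Assign immune phenotypes from marker positivity
#'
#' Applies the marker logic of the six-plex panel: CD3+CD8+ cells are CD8 T,
#' CD3+CD8- are CD4 T, then CD20+ B cells, CD68+ macrophages, CD66b+
#' neutrophils; cells negative for every marker are "other". Cross-lineage
#' multi-positives are resolved by the configured precedence (CD3 lineage
#' first), then by the largest threshold-normalised intensity.
#'
#' @param cells Tibble from [measure_cell_intensities()] (needs the five
#'   `ring_<marker>` columns).
#' @param config A [phenotype_config()].
#' @return `cells` with logical `<marker>_pos` columns, the resolved
#'   `phenotype`, and the thresholds used as an attribute.
#' @export
classify_phenotypes <- function(cells, config = phenotype_config()) {
  markers <- c("CD3", "CD8", "CD20", "CD68", "CD66b")
  need <- paste0("ring_", markers)
  missing_ch <- setdiff(need, names(cells))
  if (length(missing_ch)) {
    abort(paste0("Missing channel measurement(s): ",
                 paste(missing_ch, collapse = ", ")),
          class = "itf_configuration_error")
  }
  thr <- vapply(markers, function(mk) {
    t0 <- config$thresholds[[mk]]
    if (identical(t0, "auto")) {
      max(otsu_threshold(cells[[paste0("ring_", mk)]]),
          config$min_auto_threshold)
    } else {
      if (!is.numeric(t0) || t0 <= 0) {
        abort(sprintf("Absolute threshold for %s must be positive.", mk),
              class = "itf_configuration_error")
      }
      t0
    }
  }, numeric(1))
  pos <- vapply(markers, function(mk) cells[[paste0("ring_", mk)]] >= thr[mk],
                logical(nrow(cells)))
  if (nrow(cells) == 1L) pos <- matrix(pos, 1L, dimnames = list(NULL, markers))
  pheno <- rep("other", nrow(cells))
  lineage_order <- config$precedence
  norm_int <- vapply(lineage_order, function(mk)
    cells[[paste0("ring_", mk)]] / thr[mk], numeric(nrow(cells)))
  if (nrow(cells) == 1L) norm_int <- matrix(norm_int, 1L)
  for (i in seq_len(nrow(cells))) {
    if (pos[i, "CD3"]) {
      pheno[i] <- if (pos[i, "CD8"]) "CD8 T" else "CD4 T"
    } else {
      hits <- lineage_order[pos[i, lineage_order]]
      if (length(hits) == 1L) {
        pheno[i] <- switch(hits, CD20 = "B cell", CD68 = "macrophage",
                           CD66b = "neutrophil")
      } else if (length(hits) > 1L) {
        pheno[i] <- switch(hits[1], CD20 = "B cell", CD68 = "macrophage",
                           CD66b = "neutrophil")
      }
    }
  }
  out <- cells
  for (mk in markers) out[[paste0(mk, "_pos")]] <- pos[, mk]
  out$phenotype <- pheno
  attr(out, "thresholds") <- thr
  out
}

point_in_polygon <- function(x, y, poly) {
  # even-odd ray casting; poly is a closed or open 2-column matrix
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1L
  }
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

polygon_area_mm2 <- function(poly) {
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2 / 1e6
}

#' Phenotype densities over an ROI polygon
#'
#' Counts classified cells whose centroids fall inside the polygon and
#' reports cells per mm^2 for each phenotype plus the total (the phenotype
#' densities partition the total exactly).
#'
#' @param cells Tibble from [classify_phenotypes()].
#' @param roi_polygon 2-column matrix of polygon vertices (um).
#' @param category Tile category label carried through.
#' @param roi_id ROI identifier carried through.
#' @return Tibble: `roi_id`, `category`, `phenotype` (six phenotypes plus
#'   `"total"`), `n_cells`, `density_per_mm2`.
#' @export
compute_density <- function(cells, roi_polygon, category = "unassigned",
                            roi_id = "roi") {
  area <- polygon_area_mm2(roi_polygon)
  if (area <= 0) {
    abort("ROI polygon has zero area.", class = "itf_value_error")
  }
  inside <- if (nrow(cells)) {
    point_in_polygon(cells$x_um, cells$y_um, roi_polygon)
  } else logical()
  counts <- table(factor(cells$phenotype[inside], levels = MIF_PHENOTYPES))
  tibble(roi_id = roi_id, category = category,
         phenotype = c(MIF_PHENOTYPES, "total"),
         n_cells = c(as.integer(counts), sum(counts)),
         density_per_mm2 = c(as.numeric(counts), sum(counts)) / area)
}

#' TTF1-positive nucleus density
#'
#' A nucleus is positive when its mean nuclear signal reaches the
#' threshold; density is positives per mm^2 of ROI area.
#'
#' @param ttf1 Single-channel matrix of the nuclear stain.
#' @param nuclei A [detect_nuclei()] result.
#' @param threshold Positivity threshold (`"auto"` for Otsu over nuclear
#'   means).
#' @param roi_area_mm2 Analysed area (mm^2).
#' @return One-row tibble: `n_nuclei`, `n_positive`, `positive_fraction`,
#'   `density_per_mm2`.
#' @export
ttf1_positive_density <- function(ttf1, nuclei, threshold = "auto",
                                  roi_area_mm2 = 1) {
  if (roi_area_mm2 <= 0) {
    abort("ROI area must be positive.", class = "itf_value_error")
  }
  labs <- nuclei$labels
  n_nuc <- nrow(nuclei$cells)
  if (!n_nuc) {
    return(tibble(n_nuclei = 0L, n_positive = 0L,
                  positive_fraction = NA_real_, density_per_mm2 = 0))
  }
  sel <- labs > 0L
  mu <- tapply(ttf1[sel], labs[sel], mean)
  means <- rep(0, n_nuc)
  means[as.integer(names(mu))] <- as.numeric(mu)
  thr <- if (identical(threshold, "auto")) {
    max(otsu_threshold(means), 0.05)
  } else threshold
  n_pos <- sum(means >= thr)
  tibble(n_nuclei = n_nuc, n_positive = n_pos,
         positive_fraction = n_pos / n_nuc,
         density_per_mm2 = n_pos / roi_area_mm2)
}
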