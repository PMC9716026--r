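#' Extract the physical pixel size from OME-XML metadata
#'
#' @param description The TIFF ImageDescription string.
#' @return Pixel size in um, or `NA` when the tag is absent.
#' @export
parse_ome_pixel_size <- function(description) {
  if (is.null(description) || !length(description)) return(NA_real_)
  m <- regmatches(description,
                  regexpr('PhysicalSizeX="[0-9.eE+-]+"', description))
  if (!length(m)) return(NA_real_)
  as.numeric(sub('PhysicalSizeX="([0-9.eE+-]+)"', "\\1", m))
}

parse_ome_channels <- function(description) {
  if (is.null(description) || !length(description)) return(NULL)
  m <- regmatches(description,
                  gregexpr('Channel[^>]*Name="[^"]+"', description))[[1]]
  if (!length(m)) return(NULL)
  sub('.*Name="([^"]+)".*', "\\1", m)
}

sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Read a TIFF / OME-TIFF image with pixel-size metadata
#'
#' Pixel size is taken, in order, from OME-XML in the ImageDescription tag,
#' from a `<path>.meta.yaml` sidecar (written by [write_image()]), or from
#' the `pixel_size_um` override; with none of the three, reading fails.
#' Multi-page files are stacked into an H x W x C array; channel names come
#' from the same metadata sources.
#'
#' @param path TIFF file path.
#' @param pixel_size_um Optional override (um).
#' @return List with `image` (matrix or H x W x C array), `pixel_size_um`,
#'   `channels` (names or `NULL`).
#' @export
read_image <- function(path, pixel_size_um = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Image file not found: %s", path),
          class = "itf_path_error")
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) {
                      abort(sprintf("Cannot read TIFF %s: %s", path,
                                    conditionMessage(e)),
                            class = "itf_format_error")
                    })
  if (!is.list(pages)) pages <- list(pages)
  desc <- attr(pages[[1]], "description")
  meta_px <- parse_ome_pixel_size(desc)
  channels <- parse_ome_channels(desc)
  if (is.na(meta_px) && file.exists(sidecar_path(path))) {
    sc <- yaml::read_yaml(sidecar_path(path))
    meta_px <- sc$pixel_size_um %||% NA_real_
    channels <- channels %||% sc$channels
  }
  px <- pixel_size_um %||% (if (!is.na(meta_px)) meta_px else NULL)
  if (is.null(px)) {
    abort(sprintf("No pixel size metadata in %s and no override given.",
                  path), class = "itf_format_error")
  }
  to_mat <- function(p) if (length(dim(p)) == 3L) p else
    matrix(p, nrow(p), ncol(p))
  if (length(pages) == 1L) {
    img <- pages[[1]]
    attr(img, "description") <- NULL
    if (length(dim(img)) == 3L && !is.null(channels) &&
        length(channels) == dim(img)[3]) {
      dimnames(img) <- list(NULL, NULL, channels)
    }
  } else {
    mats <- lapply(pages, to_mat)
    img <- array(unlist(mats), dim = c(dim(mats[[1]])[1:2], length(mats)))
    if (!is.null(channels) && length(channels) == length(mats)) {
      dimnames(img) <- list(NULL, NULL, channels)
    }
  }
  list(image = img, pixel_size_um = as.numeric(px), channels = channels)
}

#' Write an image as multi-page TIFF plus a metadata sidecar
#'
#' Values are clipped to `[0, 1]` and written 16-bit; pixel size and channel
#' names go to a `<path>.meta.yaml` sidecar that [read_image()] consumes.
#'
#' @param image Matrix or H x W x C array.
#' @param path Output path.
#' @param pixel_size_um Pixel size (um).
#' @param channels Optional channel names (defaults to array dimnames).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, pixel_size_um, channels = NULL) {
  if (length(dim(image)) == 3L) {
    channels <- channels %||% dimnames(image)[[3]]
    pages <- lapply(seq_len(dim(image)[3]), function(k) {
      pmin(pmax(image[, , k], 0), 1)
    })
  } else {
    pages <- list(pmin(pmax(image, 0), 1))
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(list(pixel_size_um = pixel_size_um,
                        channels = channels), sidecar_path(path))
  invisible(path)
}

ring_self_intersects <- function(poly) {
  # poly: open ring (no repeated last point); checks non-adjacent edges
  n <- nrow(poly)
  if (n < 4L) return(FALSE)
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) -
      (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) -
      (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) -
      (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) -
      (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L) next
      if (i == 1L && j == n) next
      a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
      c_ <- poly[j, ]; d_ <- poly[if (j == n) 1L else j + 1L, ]
      if (seg_int(a, b, c_, d_)) return(TRUE)
    }
  }
  FALSE
}

#' Read ROI tiles from a GeoJSON FeatureCollection
#'
#' Polygons are expected in pixel coordinates (0-based, y-down, QuPath
#' style) and are converted to um using `pixel_size_um`. Feature properties
#' `name`/`roi_id`, `category`, and `tumor_fraction` are preserved when
#' present. Invalid geometries fail with the offending feature index.
#'
#' @param path GeoJSON file.
#' @param pixel_size_um Pixel size (um).
#' @return Tibble: `roi_id`, `category`, `tumor_fraction`, `area_mm2`,
#'   `polygon` list-column (um).
#' @export
read_rois <- function(path, pixel_size_um = 0.46) {
  if (!file.exists(path)) {
    abort(sprintf("ROI file not found: %s", path), class = "itf_path_error")
  }
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features %||% list()
  rows <- lapply(seq_along(feats), function(i) {
    ft <- feats[[i]]
    geom <- ft$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon")) {
      abort(sprintf("Feature %d: missing or non-Polygon geometry.", i),
            class = "itf_format_error")
    }
    ring <- geom$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, function(pt)
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
    if (nrow(xy) >= 2L && all(xy[1, ] == xy[nrow(xy), ])) {
      xy <- xy[-nrow(xy), , drop = FALSE]
    }
    if (nrow(xy) < 3L) {
      abort(sprintf("Feature %d: polygon needs at least 3 vertices.", i),
            class = "itf_format_error")
    }
    if (ring_self_intersects(xy)) {
      abort(sprintf("Feature %d: self-intersecting polygon.", i),
            class = "itf_format_error")
    }
    um <- xy * pixel_size_um
    colnames(um) <- c("x_um", "y_um")
    props <- ft$properties %||% list()
    tibble(roi_id = as.character(props$roi_id %||% props$name %||%
                                   sprintf("roi_%03d", i)),
           category = as.character(props$category %||% "unassigned"),
           tumor_fraction = as.numeric(props$tumor_fraction %||% NA_real_),
           area_mm2 = polygon_area_mm2(um),
           polygon = list(um))
  })
  dplyr::bind_rows(rows)
}

#' Write ROI tiles as GeoJSON
#'
#' Inverse of [read_rois()]: polygons in um are emitted in 0-based pixel
#' coordinates.
#'
#' @param tiles Tibble with `roi_id`, `category`, `tumor_fraction`,
#'   `polygon` (um).
#' @param path Output path.
#' @param pixel_size_um Pixel size (um).
#' @return `path`, invisibly.
#' @export
write_rois <- function(tiles, path, pixel_size_um = 0.46) {
  feats <- lapply(seq_len(nrow(tiles)), function(i) {
    um <- tiles$polygon[[i]]
    if (!all(um[1, ] == um[nrow(um), ])) um <- rbind(um, um[1, ])
    px <- um / pixel_size_um
    list(type = "Feature",
         properties = list(roi_id = tiles$roi_id[i],
                           category = tiles$category[i],
                           tumor_fraction = tiles$tumor_fraction[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(px)),
                                                   function(k)
                                                     as.numeric(px[k, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
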