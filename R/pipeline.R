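#' Demo pipeline configuration
#'
#' Configures the end-to-end synthetic demonstration run: tile layout and
#' categorisation, fiber simulation/segmentation per category, immune
#' profiling, and the differential-methylation stage. Every stochastic
#' stage derives its stream from the single `seed`. Stage blocks can be set
#' to `NULL` to skip them (noted in the manifest).
#'
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed); `NULL` keeps
#'   results in memory only.
#' @param layout A [roi_layout_spec()]; its seed is overridden.
#' @param fiber List: `tiles_per_category`, per-category preset overrides.
#' @param mif List: `tiles_per_category`, `field_mm`, per-category density
#'   scaling.
#' @param meth A [meth_sim_params()], or `NULL` to skip the stage.
#' @param categories [assign_categories()] thresholds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL,
                            layout = roi_layout_spec(),
                            fiber = list(tiles_per_category = 2L),
                            mif = list(tiles_per_category = 1L,
                                       field_mm = 0.5),
                            meth = meth_sim_params(n_probes = 4000,
                                                   n_pairs = 6,
                                                   n_dm = 40),
                            categories = list(t_hi = 0.9, t_lo = 0.1,
                                              itf_width = 0.2)) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 layout = layout, fiber = fiber, mif = mif, meth = meth,
                 categories = categories, version = "0.1.0"),
            class = "pipeline_config")
}

config_hash <- function(x) {
  # strip non-semantic fields, serialise canonically, md5
  x$out_dir <- NULL
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

category_fiber_params <- function(category, seed) {
  switch(category,
    tumor = fiber_preset("dense_bundle", seed = seed),
    target_tissue = fiber_preset("loose_plexus", seed = seed),
    ITF = fiber_preset("loose_plexus", n_fibers = 65L, seed = seed),
    fiber_preset("loose_plexus", seed = seed))
}

category_mif_density <- function(category) {
  base <- c(`CD8 T` = 150, `CD4 T` = 200, `B cell` = 80, macrophage = 90,
            neutrophil = 40, other = 150)
  mult <- switch(category, tumor = 0.6, target_tissue = 0.8, ITF = 1.4, 1)
  out <- base * mult
  # the invasion front accumulates B cells in this cohort
  if (category == "ITF") out["B cell"] <- base[["B cell"]] * 2.5
  out
}

#' Run the end-to-end synthetic demonstration pipeline
#'
#' Executes layout -> categorisation -> fiber morphometry (simulate,
#' deconvolve, mask, segment, measure, QC) -> immune profiling (simulate,
#' detect, classify, densities) -> methylation (simulate, beta, Greedycut,
#' normalise, per-CpG tests, signature, PCA) -> group comparisons, writing
#' CSV outputs and a JSON run manifest when `out_dir` is set. Reruns with
#' the same configuration and seed produce identical manifests.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `itf_manifest`: tool version, config hash,
#'   per-stage row counts and exclusions, manifest hash; stage result
#'   tables are attached as the `"results"` attribute.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config().",
          class = "itf_parameter_error")
  }
  layout <- config$layout
  layout$seed <- derive_seed(config$seed, 1L)
  tiles <- simulate_roi_layout(layout)
  tiles <- assign_categories(tiles, t_hi = config$categories$t_hi,
                             t_lo = config$categories$t_lo,
                             itf_width = config$categories$itf_width)
  cat_counts <- table(tiles$category)

  results <- list(tiles = tiles)
  excluded <- list()

  # ---- fiber stage ----------------------------------------------------
  fiber_rows <- list(); fiber_qc <- list()
  n_fibers_total <- 0L
  if (!is.null(config$fiber)) {
    per_cat <- config$fiber$tiles_per_category %||% 2L
    sel <- tiles %>%
      filter(.data$category %in% c("tumor", "target_tissue", "ITF")) %>%
      group_by(.data$category) %>%
      dplyr::slice_head(n = per_cat) %>%
      ungroup()
    for (i in seq_len(nrow(sel))) {
      cat_i <- sel$category[i]
      sim <- simulate_fiber_roi(category_fiber_params(
        cat_i, derive_seed(config$seed, 100L + i)))
      odm <- deconvolve_stain(sim$image,
                              pixel_size_um = sim$params$pixel_size_um)
      tis <- compute_tissue_mask(sim$image,
                                 pixel_size_um = sim$params$pixel_size_um)
      seg <- segment_fibers(odm, tissue_mask = tis$mask)
      stats <- summarize_roi(seg, tis)
      qc <- qc_roi(stats, summarize_od(sim$image, tis$mask),
                   degenerate = seg$degenerate)
      fiber_qc[[i]] <- qc %>% mutate(roi_id = sel$roi_id[i],
                                     category = cat_i, .before = 1)
      if (!qc$pass) {
        excluded[[length(excluded) + 1L]] <-
          tibble(stage = "fiber", id = sel$roi_id[i], reason = qc$reason)
        next
      }
      n_fibers_total <- n_fibers_total + stats$n_fibers
      fiber_rows[[length(fiber_rows) + 1L]] <- stats %>%
        select(-"fibers") %>%
        mutate(roi_id = sel$roi_id[i], category = cat_i, .before = 1)
    }
  }
  fiber_stats <- dplyr::bind_rows(fiber_rows)
  results$fiber_stats <- fiber_stats
  results$fiber_qc <- dplyr::bind_rows(fiber_qc)

  # ---- immune stage ---------------------------------------------------
  dens_rows <- list()
  n_cells_total <- 0L
  if (!is.null(config$mif)) {
    per_cat <- config$mif$tiles_per_category %||% 1L
    fld <- config$mif$field_mm %||% 0.5
    sel <- tiles %>%
      filter(.data$category %in% c("tumor", "target_tissue", "ITF")) %>%
      group_by(.data$category) %>%
      dplyr::slice_head(n = per_cat) %>%
      ungroup()
    for (i in seq_len(nrow(sel))) {
      cat_i <- sel$category[i]
      mp <- mif_sim_params(field_width_mm = fld, field_height_mm = fld,
                           densities_per_mm2 = category_mif_density(cat_i),
                           seed = derive_seed(config$seed, 200L + i))
      sim <- simulate_mif_roi(mp)
      nuc <- detect_nuclei(sim$image[, , "DAPI"],
                           pixel_size_um = mp$pixel_size_um)
      cells <- measure_cell_intensities(sim$image, nuc)
      cells <- classify_phenotypes(cells)
      s_um <- fld * 1000
      poly <- cbind(x_um = c(0, s_um, s_um, 0, 0),
                    y_um = c(0, 0, s_um, s_um, 0))
      dens_rows[[length(dens_rows) + 1L]] <-
        compute_density(cells, poly, category = cat_i,
                        roi_id = paste0("mif_", sel$roi_id[i]))
      n_cells_total <- n_cells_total + nrow(cells)
    }
  }
  densities <- dplyr::bind_rows(dens_rows)
  results$densities <- densities

  # ---- methylation stage ----------------------------------------------
  meth_summary <- NULL
  if (!is.null(config$meth)) {
    mp <- config$meth
    mp$seed <- derive_seed(config$seed, 300L)
    sim <- simulate_methylation(mp)
    gc <- greedycut_filter(sim$detection_p)
    keep_p <- gc$kept_probes; keep_s <- gc$kept_samples
    bm <- compute_beta(sim$M[keep_p, keep_s, drop = FALSE],
                       sim$U[keep_p, keep_s, drop = FALSE])
    ptypes <- sim$probes$probe_type[match(keep_p, sim$probes$probe_id)]
    bm <- normalize_beta(bm, ptypes, method = "type2-quantile")
    samp <- sim$samples %>% filter(.data$sample %in% keep_s)
    design <- if (!is.null(mp$n_pairs)) "paired" else "group"
    fit <- test_dm(bm, samp, design = design,
                   group_a = mp$group_labels[1],
                   group_b = mp$group_labels[2])
    sig <- suppressWarnings(build_signature(fit, bm, k = 1000))
    pca <- pca_beta(bm)
    for (p in gc$removed_probes) {
      excluded[[length(excluded) + 1L]] <-
        tibble(stage = "meth", id = p, reason = "greedycut")
    }
    meth_summary <- glance(fit)
    results$dm <- tidy(fit)
    results$dm_glance <- meth_summary
    results$signature_probes <- sig$probes
    results$pca <- tidy(pca)
  }

  # ---- reporting stage ------------------------------------------------
  comparisons <- NULL
  if (nrow(fiber_stats) > 0) {
    long <- fiber_stats %>%
      select("roi_id", "category", "density", "pct_stained_area",
             dplyr::starts_with("mean_")) %>%
      tidyr::pivot_longer(-c("roi_id", "category"),
                          names_to = "parameter", values_to = "value")
    comparisons <- suppressWarnings(
      compare_groups(long, value = "value", group = "category",
                     parameter = "parameter"))
    results$comparisons <- comparisons
    results$comparison_matrix <- build_comparison_matrix(
      comparisons, abbrev = c(tumor = "T", target_tissue = "TT",
                              ITF = "ITF"))
  }

  excl <- dplyr::bind_rows(excluded)
  if (!nrow(excl)) excl <- tibble(stage = character(), id = character(),
                                  reason = character())
  manifest <- list(
    tool = "itfprofiler", version = config$version,
    config_hash = config_hash(unclass(config)),
    seed = config$seed,
    stages = list(
      layout = list(n_tiles = nrow(tiles),
                    categories = as.list(cat_counts)),
      fiber = if (is.null(config$fiber)) "skipped" else
        list(n_rois = nrow(fiber_stats),
             n_excluded = sum(excl$stage == "fiber"),
             n_fibers = n_fibers_total),
      mif = if (is.null(config$mif)) "skipped" else
        list(n_rois = length(dens_rows), n_cells = n_cells_total),
      meth = if (is.null(config$meth)) "skipped" else
        list(n_probes_tested = meth_summary$n_tested,
             n_excluded = sum(excl$stage == "meth"),
             n_significant = meth_summary$n_significant)),
    exclusions = if (nrow(excl)) purrr::transpose(as.list(excl)) else
      list())
  mf <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = 12),
             mf)
  manifest$manifest_hash <- unname(tools::md5sum(mf))
  unlink(mf)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wcsv <- function(x, nm) {
      if (is.null(x) || !nrow(x)) return(invisible())
      x <- x[, !vapply(x, is.list, logical(1)), drop = FALSE]
      write.csv(x, file.path(config$out_dir, nm), row.names = FALSE)
    }
    wcsv(fiber_stats, "fiber_roi_stats.csv")
    wcsv(densities, "immune_densities.csv")
    if (!is.null(results$dm)) wcsv(results$dm, "dm_results.csv")
    if (!is.null(comparisons))
      wcsv(as_tibble(comparisons), "comparisons.csv")
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = 12),
               file.path(config$out_dir, "manifest.json"))
  }
  structure(manifest, class = "itf_manifest", results = results)
}

#' @export
print.itf_manifest <- function(x, ...) {
  cat(sprintf("%s %s run manifest (seed %d)\n", x$tool, x$version, x$seed))
  cat(sprintf("  config hash:   %s\n", x$config_hash))
  cat(sprintf("  manifest hash: %s\n", x$manifest_hash))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    if (identical(st, "skipped")) {
      cat(sprintf("  %-7s skipped\n", nm))
    } else {
      cat(sprintf("  %-7s %s\n", nm,
                  paste(names(st), unlist(lapply(st, function(v)
                    paste(unlist(v), collapse = "/"))), sep = "=",
                    collapse = ", ")))
    }
  }
  invisible(x)
}
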