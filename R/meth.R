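#' Beta values from methylated/unmethylated intensities
#'
#' `beta = M / (M + U + offset)`; the default offset of 0 matches the plain
#' ratio, so `M = 0` gives 0 (no methylation) and `U = 0` gives 1
#' (completely methylated). Probes with `M = U = 0` are missing.
#'
#' @param M,U Aligned non-negative probes x samples matrices.
#' @param offset Non-negative stabilising offset added to the denominator.
#' @return A list of class `beta_matrix` with `beta` (values in `[0, 1]`,
#'   `NA` where undefined) and `missing` (logical mask).
#' @export
compute_beta <- function(M, U, offset = 0) {
  if (!identical(dim(M), dim(U))) {
    abort("M and U must share dimensions.", class = "itf_value_error")
  }
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE)) {
    abort("Intensities must be non-negative.", class = "itf_value_error")
  }
  if (offset < 0) {
    abort("`offset` must be >= 0.", class = "itf_parameter_error")
  }
  denom <- M + U + offset
  beta <- M / denom
  beta[denom == 0] <- NA_real_
  structure(list(beta = beta, missing = is.na(beta)),
            class = "beta_matrix")
}

as_beta_matrix <- function(x) {
  if (inherits(x, "beta_matrix")) return(x)
  structure(list(beta = x, missing = is.na(x)), class = "beta_matrix")
}

#' Greedycut quality filter on detection p-values
#'
#' Iteratively removes the probe (row) or sample (column) with the highest
#' fraction of detection failures (`p >= p_threshold`) until no remaining
#' row or column exceeds `max_fail_frac`. Ties are broken probe-first, then
#' by lowest index.
#'
#' @param detection_p Probes x samples matrix of detection p-values.
#' @param p_threshold Failure cutoff, in (0, 1).
#' @param max_fail_frac Largest tolerated failure fraction per row/column.
#' @return List with `kept_probes`, `kept_samples` (names when available,
#'   otherwise indices), `removed_probes`, `removed_samples`.
#' @export
greedycut_filter <- function(detection_p, p_threshold = 0.01,
                             max_fail_frac = 0.05) {
  if (p_threshold <= 0 || p_threshold >= 1) {
    abort("`p_threshold` must be inside (0, 1).",
          class = "itf_parameter_error")
  }
  fail <- detection_p >= p_threshold
  rn <- rownames(detection_p) %||% as.character(seq_len(nrow(fail)))
  cn <- colnames(detection_p) %||% as.character(seq_len(ncol(fail)))
  keep_r <- rep(TRUE, nrow(fail)); keep_c <- rep(TRUE, ncol(fail))
  repeat {
    sub <- fail[keep_r, keep_c, drop = FALSE]
    if (!nrow(sub) || !ncol(sub)) break
    rfrac <- rowMeans(sub)
    cfrac <- colMeans(sub)
    worst_r <- max(rfrac); worst_c <- max(cfrac)
    if (worst_r <= max_fail_frac && worst_c <= max_fail_frac) break
    if (worst_r >= worst_c) {
      keep_r[which(keep_r)[which.max(rfrac)]] <- FALSE
    } else {
      keep_c[which(keep_c)[which.max(cfrac)]] <- FALSE
    }
  }
  list(kept_probes = rn[keep_r], kept_samples = cn[keep_c],
       removed_probes = rn[!keep_r], removed_samples = cn[!keep_c])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove SNP-overlapping and cross-reactive probes
#'
#' @param probes Character vector of probe ids.
#' @param snp_list,crossreactive_list Blacklists (probe ids).
#' @return List with `kept`, and removal counts `n_snp`, `n_crossreactive`
#'   (a probe on both lists is removed once but counted in both logs).
#' @export
remove_blacklisted <- function(probes, snp_list = character(),
                               crossreactive_list = character()) {
  n_snp <- sum(probes %in% snp_list)
  n_cross <- sum(probes %in% crossreactive_list)
  kept <- setdiff(probes, union(snp_list, crossreactive_list))
  list(kept = kept, n_snp = n_snp, n_crossreactive = n_cross)
}

#' Probe-type bias normalisation
#'
#' `"type2-quantile"` maps, per sample, the type II beta distribution onto
#' the type I distribution by quantile matching (the same type I/type II
#' design bias that BMIQ addresses); `"none"` is the identity. Output stays
#' in `[0, 1]`.
#'
#' @param beta A `beta_matrix` or plain matrix.
#' @param probe_types Character vector (`"I"`/`"II"`) aligned with rows.
#' @param method `"type2-quantile"` or `"none"`.
#' @return A `beta_matrix`.
#' @export
normalize_beta <- function(beta, probe_types,
                           method = c("type2-quantile", "none")) {
  if (!is.character(method) ||
      !method[1] %in% c("type2-quantile", "none")) {
    abort("Unknown normalisation method.", class = "itf_parameter_error")
  }
  method <- method[1]
  bm <- as_beta_matrix(beta)
  if (method == "none") return(bm)
  b <- bm$beta
  i1 <- probe_types == "I"
  i2 <- probe_types == "II"
  if (!any(i1) || !any(i2)) return(bm)
  for (j in seq_len(ncol(b))) {
    v2 <- b[i2, j]
    ok <- !is.na(v2)
    if (sum(ok) < 2L) next
    ref <- b[i1, j]
    ref <- ref[!is.na(ref)]
    if (length(ref) < 2L) next
    q <- (rank(v2[ok], ties.method = "first") - 0.5) / sum(ok)
    v2[ok] <- as.numeric(quantile(ref, probs = q, type = 7, names = FALSE))
    b[i2, j] <- v2
  }
  b <- pmin(pmax(b, 0), 1)
  structure(list(beta = b, missing = is.na(b)), class = "beta_matrix")
}

#' Per-CpG differential methylation testing
#'
#' Fits a per-probe linear model on beta values: for the paired design this
#' includes pair intercepts and is equivalent to a paired t-test on
#' within-pair differences; for the two-group design it is the pooled
#' two-sample t-test. The effect is reported as
#' `delta_beta = mean(beta, group A) - mean(beta, group B)` (positive =
#' hypermethylated in the first-named group). P-values are adjusted across
#' all tested probes by Benjamini-Hochberg; a probe is significant when
#' both p and FDR are below `alpha`. Probes whose effect cannot be tested
#' (all missing, or fewer than two complete pairs / two values per group)
#' are excluded and logged. A probe with zero residual variance gets p = 1
#' when its effect is 0 and is flagged degenerate otherwise.
#'
#' @param beta A `beta_matrix` or matrix (probes x samples).
#' @param samples Tibble with `sample`, `group`, and `pair_id` (paired
#'   design); sample order must match the matrix columns.
#' @param design `"paired"` or `"group"`.
#' @param group_a,group_b Group labels defining the contrast
#'   (`group_a - group_b`); default the first two levels encountered with
#'   `group_a` = the first.
#' @param alpha Significance level on both p and FDR.
#' @return An object of class `dm_fit`; use [tidy()] for the per-probe
#'   table (`probe_id`, `delta_beta`, `statistic`, `df`, `p`, `fdr`,
#'   `significant`, `degenerate`) and [glance()] for a one-row summary.
#' @export
test_dm <- function(beta, samples, design = c("paired", "group"),
                    group_a = NULL, group_b = NULL, alpha = 0.05) {
  design <- match.arg(design)
  bm <- as_beta_matrix(beta)
  b <- bm$beta
  if (is.null(group_a)) group_a <- unique(samples$group)[1]
  if (is.null(group_b)) group_b <- setdiff(unique(samples$group), group_a)[1]
  a_cols <- which(samples$group == group_a)
  b_cols <- which(samples$group == group_b)
  if (length(a_cols) < 2L || length(b_cols) < 2L) {
    abort("Need at least two samples per group.",
          class = "itf_value_error")
  }
  probe_ids <- rownames(b) %||% as.character(seq_len(nrow(b)))

  if (design == "paired") {
    pa <- samples$pair_id[a_cols]
    pb <- samples$pair_id[b_cols]
    common <- intersect(pa, pb)
    if (length(common) < 2L) {
      abort("Paired design needs at least two complete pairs.",
            class = "itf_value_error")
    }
    A <- b[, a_cols[match(common, pa)], drop = FALSE]
    B <- b[, b_cols[match(common, pb)], drop = FALSE]
    D <- A - B
    n_eff <- rowSums(!is.na(D))
    dbar <- rowMeans(D, na.rm = TRUE)
    dsd <- apply(D, 1, sd, na.rm = TRUE)
    df <- n_eff - 1
    se <- dsd / sqrt(n_eff)
    tstat <- dbar / se
    delta <- dbar
    testable <- n_eff >= 2
  } else {
    A <- b[, a_cols, drop = FALSE]
    B <- b[, b_cols, drop = FALSE]
    na <- rowSums(!is.na(A)); nb <- rowSums(!is.na(B))
    ma <- rowMeans(A, na.rm = TRUE); mb <- rowMeans(B, na.rm = TRUE)
    va <- apply(A, 1, var, na.rm = TRUE)
    vb <- apply(B, 1, var, na.rm = TRUE)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    tstat <- (ma - mb) / se
    delta <- ma - mb
    df <- na + nb - 2
    testable <- na >= 2 & nb >= 2
  }

  zero_var <- testable & is.finite(delta) & se < 1e-12
  degen <- zero_var & abs(delta) > 1e-12
  p <- 2 * pt(-abs(tstat), df)
  p[zero_var & !degen] <- 1          # identical groups: no evidence
  p[degen] <- 0                      # flagged separately
  p[!testable] <- NA_real_

  tested <- testable & !is.na(p)
  fdr <- rep(NA_real_, length(p))
  fdr[tested] <- p.adjust(p[tested], method = "BH")

  res <- tibble(probe_id = probe_ids, delta_beta = unname(delta),
                statistic = unname(tstat), df = unname(df),
                p = unname(p), fdr = unname(fdr),
                significant = !is.na(p) & p < alpha & !is.na(fdr) &
                  fdr < alpha,
                degenerate = unname(degen))
  structure(list(results = res, design = design, group_a = group_a,
                 group_b = group_b, alpha = alpha,
                 n_tested = sum(tested), n_excluded = sum(!tested),
                 excluded_probes = probe_ids[!tested]),
            class = "dm_fit")
}

#' @method tidy dm_fit
#' @export
tidy.dm_fit <- function(x, ...) x$results

#' @method glance dm_fit
#' @export
glance.dm_fit <- function(x, ...) {
  tibble(design = x$design, group_a = x$group_a, group_b = x$group_b,
         n_tested = x$n_tested, n_excluded = x$n_excluded,
         n_significant = sum(x$results$significant),
         alpha = x$alpha)
}

#' @export
print.dm_fit <- function(x, ...) {
  cat(sprintf(
    "Differential methylation fit (%s design): %s vs %s\n",
    x$design, x$group_a, x$group_b))
  cat(sprintf("  probes tested: %d (excluded: %d)\n", x$n_tested,
              x$n_excluded))
  cat(sprintf("  significant at p<%.2g & FDR<%.2g: %d\n", x$alpha, x$alpha,
              sum(x$results$significant)))
  invisible(x)
}

#' CpG-context and gene-region annotation
#'
#' Assigns the standard density contexts relative to CpG islands: Island
#' (inside an island interval), Shore (within 2 kb of an island edge),
#' Shelf (2-4 kb), open sea (beyond). Coordinates are 1-based and interval
#' queries closed on both ends. Gene regions are joined from the supplied
#' gene model. Probes on chromosomes absent from the island set are flagged
#' unannotated.
#'
#' @param probes Tibble with `probe_id`, `chr`, `pos`.
#' @param islands Tibble of island intervals: `chr`, `start`, `end`.
#' @param gene_model Optional tibble `probe_id`, `gene`, `gene_region`.
#' @param shore_bp,shelf_bp Context distances (bp from the island edge).
#' @return `probes` with `context` (`"Island"`, `"Shore"`, `"Shelf"`,
#'   `"open sea"`, or `NA` when unannotated), `island_distance_bp`, and
#'   gene columns when a model is given.
#' @export
annotate_context <- function(probes, islands, gene_model = NULL,
                             shore_bp = 2000, shelf_bp = 4000) {
  pr <- GenomicRanges::GRanges(probes$chr,
                               IRanges::IRanges(probes$pos, probes$pos))
  isl <- GenomicRanges::GRanges(islands$chr,
                                IRanges::IRanges(islands$start,
                                                 islands$end))
  context <- rep(NA_character_, nrow(probes))
  edge_dist <- rep(NA_real_, nrow(probes))
  shared <- probes$chr %in% unique(islands$chr)
  if (any(shared)) {
    d <- GenomicRanges::distanceToNearest(pr[shared], isl)
    qi <- which(shared)[S4Vectors::queryHits(d)]
    gap <- S4Vectors::mcols(d)$distance
    # distance() counts the positions strictly between the ranges; the
    # bp-from-edge convention used here is gap + 1 for disjoint ranges.
    edge <- ifelse(gap == 0, 0, gap + 1)
    ov <- GenomicRanges::countOverlaps(pr[shared], isl) > 0
    edge[ov] <- 0
    ctx <- ifelse(ov, "Island",
                  ifelse(edge <= shore_bp, "Shore",
                         ifelse(edge <= shelf_bp, "Shelf", "open sea")))
    context[qi] <- ctx
    edge_dist[qi] <- edge
  }
  out <- probes
  out$context <- context
  out$island_distance_bp <- edge_dist
  if (!is.null(gene_model)) {
    out <- left_join(out, gene_model, by = "probe_id")
    out$gene_region[is.na(out$gene_region)] <- "Intergenic"
  }
  out
}

#' Differential-methylation signature with hierarchical clustering
#'
#' Selects the top `k` probes by p-value among those significant at both
#' p and FDR below the fit's alpha (the study used k = 10,000) and clusters
#' the beta sub-matrix by average-linkage hierarchical clustering on
#' Euclidean distances, rows and columns, with deterministic leaf ordering.
#'
#' @param fit A `dm_fit`.
#' @param beta The `beta_matrix` (or matrix) the fit was run on.
#' @param k Signature size; when more than the available significant
#'   probes, all are used with a warning.
#' @return A list of class `dm_signature`: `probes` (ids in p order),
#'   `beta` (signature sub-matrix), `row_order`, `col_order`,
#'   `row_hclust`, `col_hclust`. With `k = 0` (or nothing significant) the
#'   signature is empty and no clustering is done.
#' @export
build_signature <- function(fit, beta, k = 10000) {
  bm <- as_beta_matrix(beta)
  res <- fit$results %>% filter(.data$significant) %>% arrange(.data$p)
  if (k < nrow(res)) {
    res <- res[seq_len(k), ]
  } else if (k > nrow(res)) {
    if (nrow(res) > 0 && k > 0) {
      warn(sprintf("Requested k = %d but only %d significant probes; using all.",
                   k, nrow(res)))
    }
  }
  if (k == 0 || nrow(res) == 0) {
    return(structure(list(probes = character(), beta = NULL,
                          row_order = integer(), col_order = integer(),
                          row_hclust = NULL, col_hclust = NULL),
                     class = "dm_signature"))
  }
  rn <- rownames(bm$beta) %||% as.character(seq_len(nrow(bm$beta)))
  sub <- bm$beta[match(res$probe_id, rn), , drop = FALSE]
  rownames(sub) <- res$probe_id
  imp <- impute_probe_means(sub)
  rh <- hclust(dist(imp), method = "average")
  ch <- hclust(dist(t(imp)), method = "average")
  structure(list(probes = res$probe_id, beta = sub,
                 row_order = rh$order, col_order = ch$order,
                 row_hclust = rh, col_hclust = ch),
            class = "dm_signature")
}

impute_probe_means <- function(b) {
  miss <- is.na(b)
  if (any(miss)) {
    mu <- rowMeans(b, na.rm = TRUE)
    mu[is.nan(mu)] <- 0.5
    b[miss] <- mu[row(b)[miss]]
  }
  b
}

#' Principal component analysis of a beta matrix
#'
#' Samples are observations, probes variables; probe-mean imputation for
#' missing values (logged via attribute), centring without scaling, and a
#' deterministic sign convention (the largest-magnitude loading of each
#' component is positive).
#'
#' @param beta A `beta_matrix` or matrix.
#' @return A list of class `beta_pca` with `scores` (tibble: `sample`,
#'   `PC1`, `PC2`, ...), `var_explained_pct`, and `n_imputed`.
#' @export
pca_beta <- function(beta) {
  bm <- as_beta_matrix(beta)
  b <- bm$beta
  if (ncol(b) < 2L) {
    abort("PCA needs at least two samples.", class = "itf_value_error")
  }
  n_imp <- sum(is.na(b))
  b <- impute_probe_means(b)
  pc <- prcomp(t(b), center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  ve <- 100 * pc$sdev^2 / max(sum(pc$sdev^2), .Machine$double.eps)
  samp <- colnames(b) %||% paste0("S", seq_len(ncol(b)))
  sc <- as_tibble(scores)
  sc <- dplyr::bind_cols(tibble(sample = samp), sc)
  structure(list(scores = sc, var_explained_pct = ve, n_imputed = n_imp),
            class = "beta_pca")
}

#' @method tidy beta_pca
#' @export
tidy.beta_pca <- function(x, ...) x$scores

#' @method glance beta_pca
#' @export
glance.beta_pca <- function(x, ...) {
  tibble(n_components = length(x$var_explained_pct),
         pc1_var_pct = x$var_explained_pct[1],
         pc2_var_pct = if (length(x$var_explained_pct) > 1)
           x$var_explained_pct[2] else NA_real_,
         n_imputed = x$n_imputed)
}
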