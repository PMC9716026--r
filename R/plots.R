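#' Volcano plot of a differential-methylation fit
#'
#' @param object A `dm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dm_fit
#' @export
autoplot.dm_fit <- function(object, ...) {
  d <- tidy(object) %>% filter(!is.na(.data$p))
  d$neglog10p <- -log10(pmax(d$p, 1e-300))
  ggplot2::ggplot(d, ggplot2::aes(.data$delta_beta, .data$neglog10p,
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(Delta * beta ~ "(group A - group B)"),
                  y = expression(-log[10] ~ italic(p)),
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' PCA score plot of a beta matrix
#'
#' @param object A `beta_pca`.
#' @param groups Optional named group per sample for colouring.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot beta_pca
#' @export
autoplot.beta_pca <- function(object, groups = NULL, ...) {
  d <- tidy(object)
  if (!is.null(groups)) d$group <- unname(groups[d$sample])
  ve <- object$var_explained_pct
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ve[1]),
                  y = sprintf("PC2 (%.1f%%)", ve[2])) +
    ggplot2::theme_minimal()
  if (is.null(groups)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  }
}

#' Clustered heatmap of a methylation signature
#'
#' @param object A `dm_signature`.
#' @param ... Unused.
#' @return A ggplot (empty plot for an empty signature).
#' @method autoplot dm_signature
#' @export
autoplot.dm_signature <- function(object, ...) {
  if (!length(object$probes)) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty signature"))
  }
  b <- object$beta[object$row_order, object$col_order, drop = FALSE]
  d <- as_tibble(as.data.frame.table(b, responseName = "beta"))
  names(d)[1:2] <- c("probe", "sample")
  d$probe <- factor(d$probe, levels = rev(rownames(b)))
  d$sample <- factor(d$sample, levels = colnames(b))
  ggplot2::ggplot(d, ggplot2::aes(.data$sample, .data$probe,
                                  fill = .data$beta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "royalblue", mid = "white",
                                  high = "firebrick", midpoint = 0.5,
                                  limits = c(0, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = sprintf("%d probes",
                                        length(object$probes)),
                  fill = expression(beta))
}

#' Significance-matrix tile plot
#'
#' Table-1-style display: one tile per parameter and tissue pair, labelled
#' with the higher group's abbreviation and the star level.
#'
#' @param comparison_matrix Output of [build_comparison_matrix()].
#' @return A ggplot.
#' @export
plot_comparison_matrix <- function(comparison_matrix) {
  d <- tidyr::pivot_longer(comparison_matrix, -"parameter",
                           names_to = "pair", values_to = "cell")
  ggplot2::ggplot(d, ggplot2::aes(.data$pair, .data$parameter)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$cell != ""),
                       colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$cell), size = 3) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white",
                                          `TRUE` = "lightsteelblue"),
                               guide = "none") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Dot plot of immune-cell densities per region
#'
#' @param densities A [compute_density()] table (rows from several ROIs).
#' @param drop_total Hide the `"total"` rows.
#' @return A ggplot.
#' @export
plot_density_table <- function(densities, drop_total = TRUE) {
  d <- densities
  if (drop_total) d <- filter(d, .data$phenotype != "total")
  ggplot2::ggplot(d, ggplot2::aes(.data$category, .data$density_per_mm2,
                                  colour = .data$category)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 2) +
    ggplot2::facet_wrap(~phenotype, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = expression(cells / mm^2)) +
    ggplot2::theme(legend.position = "none")
}
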