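#' Assign tile categories from tumor fraction
#'
#' Tiles are labelled `tumor` when the tumor fraction reaches `t_hi`,
#' `target_tissue` when at or below `t_lo`, `ITF` when within `itf_width`
#' of the balanced 50/50 front, and `unassigned` otherwise (excluded from
#' comparisons and logged). The three bands must not overlap.
#'
#' @param tiles Tibble with a `tumor_fraction` column (e.g. from
#'   [simulate_roi_layout()]).
#' @param t_hi,t_lo Tumor / target-tissue cutoffs.
#' @param itf_width Half-width of the ITF band around 0.5.
#' @return `tiles` with `category` filled in.
#' @export
assign_categories <- function(tiles, t_hi = 0.9, t_lo = 0.1,
                              itf_width = 0.2) {
  if (0.5 - itf_width <= t_lo || 0.5 + itf_width >= t_hi) {
    abort("Category bands overlap; adjust t_hi/t_lo/itf_width.",
          class = "itf_configuration_error")
  }
  f <- tiles$tumor_fraction
  if (any(is.na(f) | f < 0 | f > 1)) {
    abort("tumor_fraction must be in [0, 1].", class = "itf_value_error")
  }
  tiles$category <- dplyr::case_when(
    f >= t_hi ~ "tumor",
    f <= t_lo ~ "target_tissue",
    abs(f - 0.5) <= itf_width ~ "ITF",
    TRUE ~ "unassigned")
  tiles
}

star_level <- function(p) {
  dplyr::case_when(is.na(p) ~ "ns", p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "ns")
}

#' Pairwise group comparisons of morphometric / density parameters
#'
#' Runs a two-sample t-test for every parameter and pair of groups and
#' reports the Table-1-style star level (* p<0.05, ** p<0.01, *** p<0.001)
#' together with which group has the higher mean. The default variant is
#' the pooled-variance Student test; Welch and paired variants are
#' available. Groups with fewer than two values are skipped and logged.
#'
#' @param data Long-format tibble.
#' @param value Name of the value column.
#' @param group Name of the grouping column.
#' @param parameter Optional name of a parameter column; comparisons run
#'   per parameter.
#' @param variant `"student"`, `"welch"`, or `"paired"` (paired requires
#'   equal group sizes in matching order).
#' @param pairs Optional list of 2-vectors restricting the group pairs.
#' @param p_adjust Optional p-adjustment method across all comparisons
#'   (e.g. `"BH"`); off (`"none"`) by default, matching raw-p reporting.
#' @return Tibble of class `itf_comparisons`: `parameter`, `group1`,
#'   `group2`, group means/SDs/sizes, `statistic`, `df`, `p`, `stars`,
#'   `higher_group`.
#' @export
compare_groups <- function(data, value, group, parameter = NULL,
                           variant = c("student", "welch", "paired"),
                           pairs = NULL, p_adjust = "none") {
  variant <- match.arg(variant)
  dat <- data
  dat$.value <- dat[[value]]
  dat$.group <- as.character(dat[[group]])
  dat$.param <- if (is.null(parameter)) "value" else
    as.character(dat[[parameter]])

  out <- list()
  for (pm in unique(dat$.param)) {
    d <- dat[dat$.param == pm & !is.na(dat$.value), ]
    gl <- unique(d$.group)
    pr <- pairs %||% utils::combn(gl, 2, simplify = FALSE)
    for (gp in pr) {
      x <- d$.value[d$.group == gp[1]]
      y <- d$.value[d$.group == gp[2]]
      if (length(x) < 2L || length(y) < 2L) {
        warn(sprintf("Skipping %s: %s vs %s (fewer than 2 values).",
                     pm, gp[1], gp[2]))
        next
      }
      tt <- switch(variant,
                   student = t.test(x, y, var.equal = TRUE),
                   welch = t.test(x, y),
                   paired = t.test(x, y, paired = TRUE))
      out[[length(out) + 1L]] <- tibble(
        parameter = pm, group1 = gp[1], group2 = gp[2],
        mean1 = mean(x), sd1 = sd(x), n1 = length(x),
        mean2 = mean(y), sd2 = sd(y), n2 = length(y),
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value,
        higher_group = if (mean(x) >= mean(y)) gp[1] else gp[2])
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res)) {
    if (!identical(p_adjust, "none")) {
      res$p <- p.adjust(res$p, method = p_adjust)
    }
    res$stars <- star_level(res$p)
  } else {
    res$stars <- character()
  }
  class(res) <- c("itf_comparisons", class(res))
  res
}

#' Table-1-style significance matrix
#'
#' One row per parameter, one column per tissue pair; each cell shows the
#' abbreviation of the higher group followed by the star level
#' (e.g. `"ITF*"`), or stays blank for non-significant comparisons.
#'
#' @param comparisons An [compare_groups()] result.
#' @param abbrev Named map from group label to printed abbreviation
#'   (defaults to the labels themselves).
#' @return A tibble, parameters x pairs.
#' @export
build_comparison_matrix <- function(comparisons, abbrev = NULL) {
  cmp <- as_tibble(comparisons)
  if (!nrow(cmp)) return(tibble(parameter = character()))
  ab <- function(g) {
    if (is.null(abbrev)) g else unname(abbrev[g])
  }
  cmp <- cmp %>%
    mutate(pair = paste(ab(.data$group1), "vs", ab(.data$group2)),
           cell = ifelse(.data$stars == "ns", "",
                         paste0(ab(.data$higher_group), .data$stars)))
  tidyr::pivot_wider(cmp[, c("parameter", "pair", "cell")],
                     names_from = "pair", values_from = "cell",
                     values_fill = "")
}

#' Per-group means and standard deviations
#'
#' @param data Long-format tibble.
#' @param value,group,parameter Column names as in [compare_groups()].
#' @return Tibble: `parameter`, `group`, `n`, `mean`, `sd` (SD is missing
#'   for singleton groups).
#' @export
summarize_parameters <- function(data, value, group, parameter = NULL) {
  dat <- data
  dat$.value <- dat[[value]]
  dat$.group <- as.character(dat[[group]])
  dat$.param <- if (is.null(parameter)) "value" else
    as.character(dat[[parameter]])
  dat %>%
    filter(!is.na(.data$.value)) %>%
    group_by(parameter = .data$.param, group = .data$.group) %>%
    summarise(n = dplyr::n(), mean = mean(.data$.value),
              sd = if (dplyr::n() > 1L) sd(.data$.value) else NA_real_,
              .groups = "drop")
}
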