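test_that("category assignment follows the configured bands", {
  tiles <- tibble::tibble(tumor_fraction = c(0.5, 1.0, 0.0, 0.8, 0.95,
                                             0.05, 0.3, 0.71))
  out <- assign_categories(tiles)
  expect_equal(out$category,
               c("ITF", "tumor", "target_tissue", "unassigned", "tumor",
                 "target_tissue", "ITF", "unassigned"))
})

test_that("every tile gets exactly one category over the whole range", {
  tiles <- tibble::tibble(tumor_fraction = seq(0, 1, by = 0.01))
  out <- assign_categories(tiles)
  expect_true(all(out$category %in% c("tumor", "target_tissue", "ITF",
                                      "unassigned")))
  expect_equal(nrow(out), 101L)
})

test_that("overlapping bands are a configuration error", {
  tiles <- tibble::tibble(tumor_fraction = 0.5)
  expect_error(assign_categories(tiles, t_hi = 0.6, itf_width = 0.2),
               class = "itf_configuration_error")
  expect_error(assign_categories(tiles, t_lo = 0.4, itf_width = 0.2),
               class = "itf_configuration_error")
})

test_that("the pooled t-test matches the textbook closed form", {
  d <- tibble::tibble(value = c(1:5, 2:6),
                      tissue = rep(c("A", "B"), each = 5))
  cmp <- compare_groups(d, value = "value", group = "tissue")
  # closed form: means 3 and 4, pooled variance 2.5, se = 1
  expect_equal(cmp$statistic, -1, tolerance = 1e-9)
  expect_equal(cmp$df, 8, tolerance = 1e-12)
  expect_equal(cmp$p, 2 * pt(-1, 8), tolerance = 1e-9)
  expect_equal(round(cmp$p, 4), 0.3466)
  expect_equal(cmp$stars, "ns")
  expect_equal(cmp$higher_group, "B")
})

test_that("identical groups give t = 0, p = 1 and no stars", {
  d <- tibble::tibble(value = rep(c(1, 2, 3), 2),
                      g = rep(c("A", "B"), each = 3))
  cmp <- compare_groups(d, value = "value", group = "g")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p, 1)
  expect_equal(cmp$stars, "ns")
})

test_that("star levels map p-values monotonically", {
  expect_equal(itfprofiler:::star_level(c(0.06, 0.04, 0.004, 0.0004, NA)),
               c("ns", "*", "**", "***", "ns"))
})

test_that("undersized groups are skipped with a warning", {
  d <- tibble::tibble(value = c(1, 2, 3, 4), g = c("A", "A", "A", "B"))
  expect_warning(cmp <- compare_groups(d, value = "value", group = "g"),
                 "fewer than 2")
  expect_equal(nrow(cmp), 0L)
})

test_that("welch and paired variants agree with stats::t.test", {
  withr::with_seed(3, {
    d <- tibble::tibble(value = c(rnorm(6), rnorm(6, 1)),
                        g = rep(c("A", "B"), each = 6))
  })
  x <- d$value[d$g == "A"]; y <- d$value[d$g == "B"]
  w <- compare_groups(d, value = "value", group = "g", variant = "welch")
  expect_equal(w$p, t.test(x, y)$p.value)
  pr <- compare_groups(d, value = "value", group = "g", variant = "paired")
  expect_equal(pr$p, t.test(x, y, paired = TRUE)$p.value)
})

test_that("the comparison matrix renders Table-1-style cells", {
  cmp <- tibble::tibble(parameter = c("density", "density", "roundness"),
                        group1 = c("tumor", "tumor", "tumor"),
                        group2 = c("ITF", "target_tissue", "ITF"),
                        p = c(0.03, 0.2, 0.004),
                        higher_group = c("ITF", "tumor", "tumor"))
  cmp$stars <- itfprofiler:::star_level(cmp$p)
  m <- build_comparison_matrix(cmp, abbrev = c(tumor = "T", ITF = "ITF",
                                               target_tissue = "TT"))
  expect_equal(m[["T vs ITF"]][m$parameter == "density"], "ITF*")
  expect_equal(m[["T vs TT"]][m$parameter == "density"], "")
  expect_equal(m[["T vs ITF"]][m$parameter == "roundness"], "T**")
  expect_equal(dim(m), c(2L, 3L))
})

test_that("parameter summaries match direct mean/SD computation", {
  withr::with_seed(8, {
    d <- tibble::tibble(value = rnorm(30), g = rep(c("A", "B", "C"), 10),
                        param = rep(c("area", "width"), 15))
  })
  s <- summarize_parameters(d, value = "value", group = "g",
                            parameter = "param")
  row <- s[s$parameter == "area" & s$group == "A", ]
  ref <- d$value[d$param == "area" & d$g == "A"]
  expect_equal(row$mean, mean(ref))
  expect_equal(row$sd, sd(ref))
  expect_equal(row$n, length(ref))
  single <- summarize_parameters(tibble::tibble(value = 5, g = "A"),
                                 value = "value", group = "g")
  expect_true(is.na(single$sd))
  const <- summarize_parameters(tibble::tibble(value = c(2, 2), g = "A"),
                                value = "value", group = "g")
  expect_equal(const$sd, 0)
})
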