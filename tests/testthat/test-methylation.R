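test_that("beta is the exact intensity ratio with printed endpoints", {
  M <- matrix(c(5, 0, 7, 3), 2, 2)
  U <- matrix(c(5, 2, 0, 9), 2, 2)
  b <- compute_beta(M, U)$beta
  expect_identical(b[1, 1], 0.5)     # M = U
  expect_identical(b[2, 1], 0)       # M = 0 -> no methylation
  expect_identical(b[1, 2], 1)       # U = 0 -> completely methylated
  expect_equal(b[2, 2], 3 / 12)
  expect_error(compute_beta(matrix(-1), matrix(1)),
               class = "itf_value_error")
  # zero total intensity is missing, not an error
  z <- compute_beta(matrix(0), matrix(0))
  expect_true(z$missing[1, 1])
})

test_that("greedycut removes nothing from clean data and whole bad probes", {
  dp <- matrix(0, 10, 4, dimnames = list(paste0("p", 1:10), paste0("s", 1:4)))
  gc <- greedycut_filter(dp)
  expect_equal(gc$kept_probes, paste0("p", 1:10))
  expect_equal(gc$removed_samples, character())
  dp["p3", ] <- 0.9
  gc <- greedycut_filter(dp)
  expect_equal(gc$removed_probes, "p3")
  expect_equal(gc$removed_samples, character())
  expect_error(greedycut_filter(dp, p_threshold = 0),
               class = "itf_parameter_error")
})

test_that("greedycut agrees with a step-by-step oracle on random matrices", {
  for (s in 1:5) {
    withr::with_seed(s, {
      dp <- matrix(runif(20 * 6), 20, 6)
    })
    fail <- dp >= 0.3
    oracle <- oracle_greedycut(fail, max_frac = 0.2)
    gc <- greedycut_filter(dp, p_threshold = 0.3, max_fail_frac = 0.2)
    expect_equal(gc$kept_probes, as.character(oracle$rows))
    expect_equal(gc$kept_samples, as.character(oracle$cols))
  }
})

test_that("blacklist removal is set arithmetic with per-list logs", {
  probes <- sprintf("cg%05d", 1:100)
  out <- remove_blacklisted(probes, snp_list = probes[1:10],
                            crossreactive_list = probes[8:12])
  expect_equal(length(out$kept), 88L)
  expect_equal(out$n_snp, 10L)
  expect_equal(out$n_crossreactive, 5L)
  id <- remove_blacklisted(probes)
  expect_equal(id$kept, probes)
})

test_that("type2-quantile mapping matches type I quantiles on the sample grid", {
  withr::with_seed(7, {
    n1 <- 400; n2 <- 1500
    b1 <- rbeta(n1, 0.5, 0.5)
    b2 <- 0.5 + 0.7 * (rbeta(n2, 0.5, 0.5) - 0.5)  # attenuated type II
    b <- matrix(c(b1, b2), ncol = 1)
  })
  types <- rep(c("I", "II"), c(400, 1500))
  out <- normalize_beta(b, types, method = "type2-quantile")
  v2 <- out$beta[types == "II", 1]
  grid <- (seq_along(v2) - 0.5) / length(v2)
  expect_lt(max(abs(quantile(v2, grid, type = 5) -
                      quantile(b[types == "I", 1], grid, type = 7))), 1e-6)
  expect_identical(normalize_beta(b, types, method = "none")$beta, b)
  expect_error(normalize_beta(b, types, method = "bmiq"),
               class = "itf_parameter_error")
})

test_that("normalisation shrinks planted type-II attenuation", {
  p <- meth_sim_params(n_probes = 6000, n_pairs = 4, n_dm = 0,
                       type2_attenuation = 0.25, seed = 31)
  sim <- simulate_methylation(p)
  bm <- compute_beta(sim$M, sim$U)
  types <- sim$probes$probe_type
  norm <- normalize_beta(bm, types, method = "type2-quantile")
  # planted betas before attenuation: regenerate the un-attenuated sim
  p0 <- meth_sim_params(n_probes = 6000, n_pairs = 4, n_dm = 0,
                        type2_attenuation = 0, seed = 31)
  b_true <- compute_beta(simulate_methylation(p0)$M,
                         simulate_methylation(p0)$U)$beta
  ii <- types == "II"
  err_before <- mean(abs(bm$beta[ii, ] - b_true[ii, ]))
  err_after <- mean(abs(norm$beta[ii, ] - b_true[ii, ]))
  expect_lt(err_after, err_before)
})

test_that("identical groups give zero effects and p = 1", {
  withr::with_seed(2, {
    b <- matrix(runif(50 * 4), 50, 4)
  })
  beta <- cbind(b, b)
  rownames(beta) <- paste0("cg", 1:50)
  colnames(beta) <- c(paste0("LM_", 1:4), paste0("P_", 1:4))
  samples <- tibble::tibble(sample = colnames(beta),
                            group = rep(c("LM", "P"), each = 4),
                            pair_id = rep(1:4, 2))
  fit <- test_dm(beta, samples, design = "paired", group_a = "LM",
                 group_b = "P")
  res <- tidy(fit)
  expect_true(all(res$delta_beta == 0))
  expect_true(all(res$p == 1))
  expect_false(any(res$significant))
  expect_false(any(res$degenerate))
})

test_that("the paired test equals a per-probe paired t-test", {
  sim <- simulate_methylation(meth_sim_params(n_probes = 50, n_pairs = 5,
                                              n_dm = 5, seed = 12))
  bm <- compute_beta(sim$M, sim$U)
  fit <- test_dm(bm, sim$samples, design = "paired", group_a = "LM",
                 group_b = "P")
  res <- tidy(fit)
  for (i in c(1, 17, 42)) {
    a <- bm$beta[i, sim$samples$group == "LM"]
    b <- bm$beta[i, sim$samples$group == "P"]
    tt <- t.test(a, b, paired = TRUE)
    expect_equal(res$statistic[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
    expect_equal(res$delta_beta[i], mean(a) - mean(b), tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the brute-force formula", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  brute <- rev(cummin(rev(pmin(p * 4 / seq_along(p), 1))))
  expect_equal(brute, rep(0.04, 4))
  expect_equal(p.adjust(p, "BH"), brute)
})

test_that("degenerate zero-variance probes are flagged", {
  beta <- rbind(a = c(0.8, 0.8, 0.8, 0.2, 0.2, 0.2),
                b = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  colnames(beta) <- c(paste0("LM_", 1:3), paste0("P_", 1:3))
  samples <- tibble::tibble(sample = colnames(beta),
                            group = rep(c("LM", "P"), each = 3),
                            pair_id = rep(1:3, 2))
  res <- tidy(test_dm(beta, samples, design = "paired"))
  expect_true(res$degenerate[1])
  expect_false(res$degenerate[2])
  expect_equal(res$p[2], 1)
})

test_that("context boundaries follow the 2 kb / 4 kb convention", {
  islands <- tibble::tibble(chr = "chr1", start = 10000, end = 11000)
  probes <- tibble::tibble(
    probe_id = paste0("cg", 1:7),
    chr = c(rep("chr1", 6), "chr2"),
    pos = c(10500, 11000 + 1999, 11000 + 2000, 11000 + 2001,
            11000 + 4000, 11000 + 4001, 10500))
  out <- annotate_context(probes, islands)
  expect_equal(out$context[1:6],
               c("Island", "Shore", "Shore", "Shelf", "Shelf", "open sea"))
  expect_true(is.na(out$context[7]))   # chromosome mismatch -> unannotated
  # upstream side is symmetric
  up <- annotate_context(tibble::tibble(probe_id = "x", chr = "chr1",
                                        pos = 10000 - 2000), islands)
  expect_equal(up$context, "Shore")
})

test_that("gene regions join from the supplied model", {
  islands <- tibble::tibble(chr = "chr1", start = 100, end = 200)
  probes <- tibble::tibble(probe_id = c("a", "b"), chr = "chr1",
                           pos = c(150, 5000))
  gm <- tibble::tibble(probe_id = "a", gene = "TP53",
                       gene_region = "TSS200")
  out <- annotate_context(probes, islands, gene_model = gm)
  expect_equal(out$gene_region, c("TSS200", "Intergenic"))
})

test_that("signature clustering separates planted groups deterministically", {
  sim <- simulate_methylation(meth_sim_params(n_probes = 3000, n_pairs = 5,
                                              n_dm = 200, delta_beta = 0.4,
                                              seed = 19))
  bm <- compute_beta(sim$M, sim$U)
  fit <- test_dm(bm, sim$samples, design = "paired", group_a = "LM",
                 group_b = "P")
  sig <- suppressWarnings(build_signature(fit, bm, k = 200))
  expect_gt(length(sig$probes), 50)
  # the two top-level column clusters equal the true groups
  groups <- stats::cutree(sig$col_hclust, k = 2)
  truth <- sim$samples$group[match(names(groups), sim$samples$sample)]
  expect_equal(length(unique(paste(groups, truth))), 2L)
  sig2 <- suppressWarnings(build_signature(fit, bm, k = 200))
  expect_identical(sig$row_order, sig2$row_order)
  expect_identical(sig$col_order, sig2$col_order)
  empty <- build_signature(fit, bm, k = 0)
  expect_equal(length(empty$probes), 0L)
  expect_null(empty$row_hclust)
})

test_that("PCA separates planted groups and reports bounded variance", {
  sim <- simulate_methylation(meth_sim_params(n_probes = 3000, n_pairs = 5,
                                              n_dm = 200, delta_beta = 0.4,
                                              seed = 19))
  bm <- compute_beta(sim$M, sim$U)
  pca <- pca_beta(bm)
  sc <- tidy(pca)
  grp <- sim$samples$group[match(sc$sample, sim$samples$sample)]
  # silhouette of the two groups on PC1 must be positive
  sil <- function(x, g) {
    ga <- x[g == "LM"]; gb <- x[g == "P"]
    s <- vapply(seq_along(x), function(i) {
      own <- if (g[i] == "LM") ga else gb
      oth <- if (g[i] == "LM") gb else ga
      a <- mean(abs(x[i] - own[own != x[i]]))
      b <- mean(abs(x[i] - oth))
      (b - a) / max(a, b)
    }, numeric(1))
    mean(s)
  }
  expect_gt(sil(sc$PC1, grp), 0)
  expect_lte(sum(pca$var_explained_pct), 100 + 1e-8)
  # identical samples give identical coordinates
  two <- matrix(rep(runif(100), 2), ncol = 2)
  expect_error(pca_beta(two[, 1, drop = FALSE]), class = "itf_value_error")
  pc2 <- pca_beta(two)
  expect_lt(max(abs(pc2$scores$PC1)), 1e-8)
})
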