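test_that("DE-category proportions and chi-square match hand computation", {
  expr <- labelled_expression()
  gene_set <- expr$gene_id
  # categories ordered up-in-MQ, up-in-VQ, ns
  ot <- deg_overlap_test(gene_set, expr, c("MQ", "VQ"),
                         expected = c(0.106, 0.158, 0.736))
  expect_equal(ot$observed$n, c(6L, 14L, 24L))
  expect_equal(100 * ot$observed$proportion, c(13.6364, 31.8182, 54.5455),
               tolerance = 1e-4)
  # hand: sum((O - E)^2 / E) with E = 44 * (0.106, 0.158, 0.736)
  E <- 44 * c(0.106, 0.158, 0.736)
  expect_equal(ot$statistic, sum((c(6, 14, 24) - E)^2 / E), tolerance = 1e-10)
  expect_equal(ot$df, 2)
  expect_lt(ot$p, 0.01)
})

test_that("matching observed and expected proportions give a null statistic", {
  expr <- labelled_expression(n_up_mq = 5, n_dn_mq = 10, n_ns = 35)
  ot <- deg_overlap_test(expr$gene_id, expr, c("MQ", "VQ"),
                         expected = c(0.1, 0.2, 0.7))
  expect_equal(ot$statistic, 0, tolerance = 1e-12)
  expect_equal(ot$p, 1)
})

test_that("uniformly drawn gene sets are not spuriously enriched", {
  withr::local_seed(123)
  expr <- labelled_expression(n_up_mq = 40, n_dn_mq = 60, n_ns = 300)
  ps <- vapply(1:40, function(i) {
    deg_overlap_test(sample(expr$gene_id, 60), expr, c("VQ", "MQ"))$p
  }, 0)
  expect_lte(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps), 0.3)
})

test_that("robust-gene by DEG association detects planted dependence", {
  expr <- labelled_expression(n_up_mq = 30, n_dn_mq = 0, n_ns = 70)
  # set = exactly the DE genes -> maximal association
  rt <- robust_deg_test(expr$gene_id[1:30], expr)
  expect_equal(rt$prop_de_in_set, 1)
  expect_equal(rt$prop_de_outside, 0)
  expect_lt(rt$p, 1e-10)
  expect_equal(rt$df, 1)
})

test_that("HKG selection keeps non-DE genes above median expression", {
  expr <- labelled_expression(n_up_mq = 3, n_dn_mq = 2, n_ns = 5)
  # expressions 1..10, median 5.5; non-DE genes are g006..g010 (expr 6..10)
  gr <- tidyr::expand_grid(gene_id = expr$gene_id,
                           region_class = "exon", sample_id = "s1") |>
    dplyr::mutate(mean_level = 0.1, total_reads = 100L, n_sites = 2L)
  prof <- deg_group_profiles(gr, expr)
  hkg <- prof$groups$gene_id[prof$groups$group == "HKG"]
  expect_setequal(hkg, sprintf("g%03d", 6:10))
})

test_that("a singleton DEG group reports that gene's own methylation", {
  expr <- labelled_expression(n_up_mq = 1, n_dn_mq = 0, n_ns = 9)
  gr <- tibble::tibble(gene_id = expr$gene_id[1:3],
                       region_class = "exon", sample_id = "s1",
                       mean_level = c(0.42, 0.1, 0.2),
                       total_reads = 100L, n_sites = 1L)
  prof <- deg_group_profiles(gr, expr)
  up <- prof$per_sample[prof$per_sample$group == "up_MQ_VQ_vs_MQ", ]
  expect_equal(up$mean_level, 0.42)
  expect_equal(up$n_genes, 1L)
})

test_that("planted methylation-expression coupling orders DEG group means", {
  st <- small_study(seed = 55, n_genes = 150, n_cpg_total = 9000,
                    coupling = TRUE, coupling_target = "up_MQ_VQ",
                    coupling_exon_shift = -0.05, coupling_flank3_shift = 0.01)
  ann <- annotated_matrix(st)
  gr <- aggregate_gene_region(ann)
  prof <- deg_group_profiles(gr, st$expression)
  cmp <- prof$per_sample |>
    dplyr::filter(group %in% c("up_MQ_VQ_vs_MQ", "HKG"),
                  region_class == "exon") |>
    tidyr::pivot_wider(id_cols = sample_id, names_from = group,
                       values_from = mean_level)
  expect_true(all(cmp$up_MQ_VQ_vs_MQ < cmp$HKG))
})

test_that("Spearman correlations equal the rank formula and find planted signal", {
  # toy set of 6 gene pairs, no ties: rho from the rank-difference formula
  gr <- tibble::tibble(gene_id = paste0("g", 1:6), region_class = "exon",
                       sample_id = "s1",
                       mean_level = c(0.12, 0.55, 0.31, 0.08, 0.44, 0.27),
                       total_reads = 100L, n_sites = 1L)
  expr <- tibble::tibble(gene_id = paste0("g", 1:6), sample_id = "s1",
                         expression = c(3.2, 9.1, 4.4, 1.0, 6.8, 8.0))
  ec <- expression_correlation(gr, expr)
  d <- rank(gr$mean_level) - rank(expr$expression)
  expect_equal(ec$rho, 1 - 6 * sum(d^2) / (6 * (6^2 - 1)), tolerance = 1e-10)
  # identical ranks -> rho = 1
  expr2 <- dplyr::mutate(expr, expression = rank(gr$mean_level))
  expect_equal(expression_correlation(gr, expr2)$rho, 1)
  expect_error(expression_correlation(gr[1:2, ], expr), ">= 3 genes")
})

test_that("the methylation GLM drops a constant variable to a reduced model", {
  expr <- labelled_expression(n_up_mq = 0, n_dn_mq = 0, n_ns = 12)
  gr <- tidyr::expand_grid(gene_id = expr$gene_id,
                           region_class = c("exon", "intron"),
                           sample_id = "s1") |>
    dplyr::mutate(mean_level = runif(dplyr::n(), 0.05, 0.2),
                  total_reads = 200L, n_sites = 3L)
  fit <- fit_methylation_glm(gr, expr, "DE")
  expect_true(fit$degenerate)
  expect_false(any(grepl("var", tidy(fit)$term)))
  expect_error(glm_variable_contrast(fit), "degenerate")
})

test_that("GLM predictions are valid proportions over the whole grid", {
  st <- small_study()
  ann <- annotated_matrix(st)
  gr <- aggregate_gene_region(ann)
  fit <- fit_methylation_glm(gr, st$expression, "DE")
  grid <- predict_methylation_grid(fit)
  expect_true(all(grid$predicted >= 0 & grid$predicted <= 1))
  expect_equal(nrow(grid), 4 * 2 * 19)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  g <- glance(fit)
  expect_equal(g$family, "quasibinomial")
  expect_equal(g$method, "fixed")
})

test_that("the random-intercept fit agrees with the absorbed fit on the DE contrast", {
  st <- small_study(seed = 71, n_genes = 80, n_cpg_total = 5000)
  ann <- annotated_matrix(st)
  gr <- aggregate_gene_region(ann)
  f1 <- fit_methylation_glm(gr, st$expression, "DE", method = "fixed")
  f2 <- suppressWarnings(
    fit_methylation_glm(gr, st$expression, "DE", method = "glmer"))
  c1 <- glm_variable_contrast(f1, "exon", se = "model")
  c2 <- glm_variable_contrast(f2, "exon")
  expect_equal(c1$estimate, c2$estimate, tolerance = 0.05)
})

test_that("PCA separates a distinct sample and matches an eigen oracle", {
  # two identical samples plus one distinct
  lv <- cbind(a = c(0.1, 0.2, 0.3, 0.4, 0.5),
              b = c(0.1, 0.2, 0.3, 0.4, 0.5),
              c = c(0.9, 0.8, 0.1, 0.2, 0.9))
  m <- tidyr::expand_grid(i = 1:5, sample_id = colnames(lv)) |>
    dplyr::mutate(site = paste0("c:", i, ":+"), chrom = "c", pos = i,
                  strand = "+", level = lv[cbind(i, match(sample_id, colnames(lv)))])
  pc <- pca_top_variable(m, n_top = 5)
  sc <- pc$scores
  expect_equal(sc$PC1[sc$sample_id == "a"], sc$PC1[sc$sample_id == "b"],
               tolerance = 1e-10)
  expect_gt(abs(sc$PC1[sc$sample_id == "c"] - sc$PC1[sc$sample_id == "a"]), 0.1)
  expect_lte(sum(pc$var_explained), 100 + 1e-8)
  expect_true(all(diff(pc$var_explained) <= 1e-8))

  # eigen oracle on a 5-site x 4-sample toy: scores = centred data projected
  # onto covariance eigenvectors
  withr::local_seed(2)
  lv4 <- matrix(runif(20), 5, 4, dimnames = list(NULL, letters[1:4]))
  m4 <- tidyr::expand_grid(i = 1:5, sample_id = letters[1:4]) |>
    dplyr::mutate(site = paste0("c:", i, ":+"), chrom = "c", pos = i,
                  strand = "+",
                  level = lv4[cbind(i, match(sample_id, letters[1:4]))])
  pc4 <- pca_top_variable(m4, n_top = 5)
  X <- scale(t(lv4), center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(X))
  scores_oracle <- X %*% eig$vectors
  got <- as.matrix(pc4$scores[, paste0("PC", 1:4)])
  for (k in 1:3) {
    expect_equal(abs(got[, k]), abs(scores_oracle[, k]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_equal(pc4$var_explained[1:3],
               100 * eig$values[1:3] / sum(eig$values), tolerance = 1e-6)
})

test_that("effect sizes are bounded and rank-invariant under monotone maps", {
  st <- small_study()
  ann <- annotated_matrix(st)
  vp <- suppressWarnings(
    variance_partition(ann, st$methylomes$samples, n_top = 1e6))
  expect_true(all(vp$eta_sq >= 0 & vp$eta_sq <= 1))
  ann2 <- dplyr::mutate(ann, level = level^3)  # monotone transform
  vp2 <- suppressWarnings(
    variance_partition(ann2, st$methylomes$samples, n_top = 1e6))
  expect_equal(vp$statistic[vp$factor == "region_class"],
               vp2$statistic[vp2$factor == "region_class"], tolerance = 1e-10)
})
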