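# long matrix from wide count/coverage matrices (sites x samples)
matrix_from_counts <- function(cm, cov) {
  rows <- tidyr::expand_grid(i = seq_len(nrow(cm)), j = seq_len(ncol(cm)))
  tibble::tibble(chrom = "c", pos = rows$i, strand = "+",
                 site = paste0("c:", rows$i, ":+"),
                 sample_id = colnames(cm)[rows$j],
                 count_meth = cm[as.matrix(rows)],
                 coverage = cov[as.matrix(rows)],
                 level = cm[as.matrix(rows)] / cov[as.matrix(rows)])
}

test_that("identical groups give a null test; complete separation a maximal one", {
  cm <- rbind(c(5L, 6L, 4L, 5L, 6L, 4L),     # identical group profiles
              c(30L, 30L, 30L, 0L, 0L, 0L))  # complete separation
  cov <- rbind(rep(20L, 6), rep(30L, 6))
  colnames(cm) <- colnames(cov) <- paste0("s", 1:6)
  m <- matrix_from_counts(cm, cov)
  res <- test_differential(m, paste0("s", 1:3), paste0("s", 4:6), min_cov = 10)
  r1 <- res[res$site == "c:1:+", ]
  expect_equal(r1$mean_diff, 0)
  expect_equal(r1$stat, 0, tolerance = 1e-12)
  expect_equal(r1$p, 1)
  expect_false(r1$is_dms)
  r2 <- res[res$site == "c:2:+", ]
  expect_equal(r2$mean_diff, 1)
  expect_true(r2$is_dms)
  expect_equal(r2$direction, "hyper_in_A")
})

test_that("DMS calls respect both the effect and FDR thresholds", {
  # site 1: huge coverage, pooled diff 0.249 -> significant but below effect bar
  # site 2: diff 0.40, clearly significant -> DMS
  cm <- rbind(c(549L, 549L, 549L, 300L, 300L, 300L),
              c(65L, 65L, 65L, 25L, 25L, 25L))
  cov <- rbind(matrix(1000L, 1, 6), matrix(100L, 1, 6))
  colnames(cm) <- colnames(cov) <- paste0("s", 1:6)
  m <- matrix_from_counts(cm, cov)
  res <- test_differential(m, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(res$mean_diff[res$site == "c:1:+"], 0.249)
  expect_lt(res$q[res$site == "c:1:+"], 0.001)
  expect_false(res$is_dms[res$site == "c:1:+"])
  expect_equal(res$mean_diff[res$site == "c:2:+"], 0.40)
  expect_true(res$is_dms[res$site == "c:2:+"])
  expect_true(all(res$is_dms == (abs(res$mean_diff) >= 0.25 & res$q < 0.05)))
})

test_that("swapping group labels negates the effect and preserves the p-value", {
  st <- small_study()
  m <- call_study(st$methylomes$coverage, st$methylomes$samples)
  ga <- paste0("FW_c", 1:3)
  gb <- paste0("MQ_c", 1:3)
  r1 <- test_differential(m, ga, gb)
  r2 <- test_differential(m, gb, ga)
  expect_equal(r1$mean_diff, -r2$mean_diff)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$is_dms, r2$is_dms)
})

test_that("sites below the coverage floor in any of the six samples are excluded", {
  st <- small_study()
  m <- call_study(st$methylomes$coverage, st$methylomes$samples)
  ga <- paste0("FW_c", 1:3)
  gb <- paste0("MQ_c", 1:3)
  res <- test_differential(m, ga, gb, min_cov = 10)
  deep <- m |>
    dplyr::filter(sample_id %in% c(ga, gb)) |>
    dplyr::group_by(site) |>
    dplyr::summarise(ok = all(coverage >= 10) & dplyr::n() == 6)
  expect_setequal(res$site, deep$site[deep$ok])
})

test_that("the LR p-value ranks like Fisher's exact test on pooled tables", {
  withr::local_seed(99)
  n <- 100
  nA <- sample(30:120, n, replace = TRUE)
  nB <- sample(30:120, n, replace = TRUE)
  mA <- rbinom(n, nA, runif(n, 0.05, 0.6))
  mB <- rbinom(n, nB, runif(n, 0.05, 0.6))
  lr <- methylcaste:::lr_binom_test(mA, nA, mB, nB)
  fisher_p <- vapply(seq_len(n), function(i) {
    fisher.test(matrix(c(mA[i], nA[i] - mA[i], mB[i], nB[i] - mB[i]), 2))$p.value
  }, 0)
  expect_gt(cor(lr$p, fisher_p, method = "spearman"), 0.95)
})

test_that("DMS counts are monotone in the thresholds", {
  st <- small_study(seed = 13, n_planted_dms = 30, coverage_mean = 25)
  m <- call_study(st$methylomes$coverage, st$methylomes$samples)
  ga <- paste0("FW_c", 1:3)
  gb <- paste0("MQ_c", 1:3)
  n_dms <- function(dt, qt) sum(test_differential(m, ga, gb,
                                                  diff_threshold = dt,
                                                  q_threshold = qt)$is_dms)
  expect_true(n_dms(0.10, 0.05) >= n_dms(0.25, 0.05))
  expect_true(n_dms(0.25, 0.05) >= n_dms(0.40, 0.05))
  expect_true(n_dms(0.25, 0.05) >= n_dms(0.25, 0.01))
})

test_that("unique DMS, phenotype sets and DMGs deduplicate correctly", {
  res <- tibble::tibble(
    site = c("x", "x", "y", "z"),
    comparison = c("VQ_vs_MQ", "FW_vs_MQ", "FW_vs_VQ", "VQ_vs_MK"),
    is_dms = c(TRUE, TRUE, TRUE, FALSE),
    direction = c("hyper_in_A", "hyper_in_A", "hypo_in_A", "hyper_in_A"))
  ann <- tibble::tibble(site = c("x", "y", "z"),
                        region_class = c("exon", "flank5", "intron"),
                        gene_id = c("g1", "g2", "g3"))
  dms <- classify_dms(res, ann)
  # x is hypo in MQ via two comparisons: counted once
  expect_equal(nrow(dms$unique_dms), 2)
  mq_hypo <- dms$phenotype_sets[dms$phenotype_sets$phenotype == "MQ" &
                                  dms$phenotype_sets$direction == "hypo", ]
  expect_equal(mq_hypo$site, "x")
  expect_equal(unname(dms$pair_matrix["MQ", "VQ"]), 1L)  # x: hyper VQ, hypo MQ
  expect_equal(unname(dms$pair_matrix["MQ", "FW"]), 1L)
  # y is in a flank: not a DMG; x in exon of g1 is
  expect_equal(dms$dmg$gene_id, "g1")
  # accounting: every unique DMS appears in >= 1 phenotype set
  expect_true(all(dms$unique_dms$site %in% dms$phenotype_sets$site))
  expect_gte(sum(dms$phenotype_counts$n_unique), nrow(dms$unique_dms))

  none <- classify_dms(dplyr::mutate(res, is_dms = FALSE), ann)
  expect_equal(nrow(none$unique_dms), 0)
  expect_true(all(none$pair_matrix == 0))
  expect_equal(nrow(none$dmg), 0)
})

test_that("region enrichment reproduces the hand-computed 2x2 chi-square", {
  # DMS: 100 sites, 10 in the region; background: 200 sites, 11 in-region
  # -> 2x2 table (10, 90 / 1, 99), chi-square 7.792 without correction
  bg <- tibble::tibble(site = paste0("s", 1:200),
                       region_class = rep(c("exon", "intergenic"),
                                          c(11, 189)))
  res <- tibble::tibble(site = paste0("s", c(1:10, 12:101)),
                        comparison = "VQ_vs_MQ", is_dms = TRUE,
                        direction = "hyper_in_A")
  en <- region_enrichment(classify_dms(res), bg)
  exon_row <- en[en$region_class == "exon" & en$phenotype == "VQ", ]
  expect_equal(exon_row$statistic,
               200 * (10 * 99 - 90 * 1)^2 / (100 * 100 * 11 * 189),
               tolerance = 1e-10)
  expect_equal(exon_row$prop_dms, 0.1)
  expect_equal(exon_row$prop_background, 11 / 200)
})

test_that("complete exon concentration of DMS is overwhelmingly significant", {
  bg <- tibble::tibble(site = paste0("s", 1:2000),
                       region_class = rep(c("exon", "intergenic"),
                                          c(60, 1940)))
  res <- tibble::tibble(site = paste0("s", 1:40), comparison = "VQ_vs_MQ",
                        is_dms = TRUE, direction = "hyper_in_A")
  en <- region_enrichment(classify_dms(res), bg)
  expect_true(all(en$q[en$region_class == "exon"] < 1e-10))
})

test_that("uniformly drawn DMS show no systematic region enrichment", {
  withr::local_seed(8)
  st <- small_study()
  ann <- annotated_matrix(st)
  bg <- dplyr::distinct(ann, site, region_class)
  fracs <- vapply(1:10, function(i) {
    picked <- sample(bg$site, 120)
    res <- tibble::tibble(site = picked, comparison = "VQ_vs_MQ",
                          is_dms = TRUE, direction = "hyper_in_A")
    en <- region_enrichment(classify_dms(res), bg)
    mean(en$q < 0.05)
  }, 0)
  expect_lte(mean(fracs), 0.05)
})

test_that("the bootstrap null is deterministic under a seed and degenerate on identical samples", {
  st <- small_study()
  m <- call_study(st$methylomes$coverage, st$methylomes$samples)
  b1 <- bootstrap_null(m, n_iter = 120, seed = 42)
  b2 <- bootstrap_null(m, n_iter = 120, seed = 42)
  expect_identical(b1$counts, b2$counts)

  one <- m |> dplyr::filter(sample_id == "FW_c1")
  clones <- purrr::map_dfr(paste0("s", 1:6),
                           ~ dplyr::mutate(one, sample_id = .x))
  b0 <- bootstrap_null(clones, n_iter = 100, seed = 1)
  expect_true(all(b0$counts == 0))
  expect_equal(b0$ci95, c(0, 0))
})
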