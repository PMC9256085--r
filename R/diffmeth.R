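# binomial log-likelihood with the 0*log(0) = 0 convention
ll_binom <- function(m, n, p) {
  t1 <- ifelse(m > 0, m * log(p), 0)
  t2 <- ifelse(n - m > 0, (n - m) * log1p(-p), 0)
  t1 + t2
}

# vectorised likelihood-ratio test of two binomial proportions.
# Equivalent to logistic regression of methylation on group membership with
# per-replicate counts: group totals are the sufficient statistics, so the
# two-parameter model fits the two pooled proportions and the null the grand
# pooled proportion. Optional Williams-type correction divides the statistic
# by the 2x2 Williams factor to temper overdispersion.
lr_binom_test <- function(mA, nA, mB, nB, correction = c("none", "williams")) {
  correction <- match.arg(correction)
  pA <- mA / nA
  pB <- mB / nB
  p0 <- (mA + mB) / (nA + nB)
  G <- 2 * (ll_binom(mA, nA, pA) + ll_binom(mB, nB, pB) -
              ll_binom(mA + mB, nA + nB, p0))
  G <- pmax(G, 0)
  if (correction == "williams") {
    N <- nA + nB
    r <- (N / nA + N / nB - 1)
    ctot <- mA + mB
    utot <- N - ctot
    cc <- ifelse(ctot > 0 & utot > 0, (N / ctot + N / utot - 1), 0)
    q <- 1 + r * cc / (6 * N)
    G <- G / q
  }
  list(stat = G, p = pchisq(G, df = 1, lower.tail = FALSE))
}

#' Per-site differential methylation between two replicated groups
#'
#' Sites are first filtered to those with at least `min_cov` reads in every
#' sample of both groups. Each surviving site is tested by a likelihood-ratio
#' test of a two-proportion vs one-proportion binomial model on the
#' per-replicate (methylated, coverage) counts -- the likelihood-ratio
#' statistic of a logistic regression of methylation on group. The effect
#' size is the pooled-proportion difference
#' `sum(meth_A)/sum(cov_A) - sum(meth_B)/sum(cov_B)`; p-values are BH
#' adjusted within the comparison and a site is a differentially methylated
#' site (DMS) when `|mean_diff| >= diff_threshold` and `q < q_threshold`
#' (defaults: 25 percentage points, FDR 0.05).
#'
#' @param matrix Long methylation matrix ([build_matrix()]).
#' @param group_a,group_b Character vectors of sample ids.
#' @param min_cov Per-sample coverage filter (default 10).
#' @param diff_threshold Minimum absolute pooled difference (default 0.25).
#' @param q_threshold FDR cutoff (default 0.05).
#' @param comparison Label recorded for this comparison; defaults to
#'   `"A_vs_B"` built from the group names.
#' @param correction `"none"` (raw binomial likelihood) or `"williams"`.
#' @return Tibble: `site`, `comparison`, `mean_diff`, `stat`, `p`, `q`,
#'   `is_dms`, `direction` (`hyper_in_A` / `hypo_in_A`), group pooled
#'   proportions and coverages.
#' @export
test_differential <- function(matrix, group_a, group_b, min_cov = 10,
                              diff_threshold = 0.25, q_threshold = 0.05,
                              comparison = NULL, correction = "none") {
  assert_cols(matrix, c("site", "sample_id", "count_meth", "coverage"))
  samp <- c(group_a, group_b)
  miss <- setdiff(samp, unique(matrix$sample_id))
  if (length(miss) > 0) abort(sprintf("unknown sample id(s): %s",
                                      paste(miss, collapse = ", ")))
  sub <- matrix %>% filter(.data$sample_id %in% samp)
  cm <- meth_wide(sub, "count_meth")
  cov <- meth_wide(sub, "coverage")
  cov[is.na(cov)] <- 0
  cm[is.na(cm)] <- 0
  res <- dms_test_wide(cm, cov, match(group_a, colnames(cov)),
                       match(group_b, colnames(cov)),
                       min_cov = min_cov, diff_threshold = diff_threshold,
                       q_threshold = q_threshold, correction = correction)
  res$comparison <- comparison %||%
    paste(paste(group_a, collapse = "+"), paste(group_b, collapse = "+"),
          sep = "_vs_")
  res %>% select("site", "comparison", dplyr::everything())
}

# core vectorised test on wide count matrices; used by test_differential and
# the bootstrap (which re-uses the matrices across iterations)
dms_test_wide <- function(cm, cov, idx_a, idx_b, min_cov = 10,
                          diff_threshold = 0.25, q_threshold = 0.05,
                          correction = "none") {
  idx <- c(idx_a, idx_b)
  keep <- rowSums(cov[, idx, drop = FALSE] >= min_cov) == length(idx)
  if (!any(keep)) {
    return(tibble(site = character(), mean_diff = double(), stat = double(),
                  p = double(), q = double(), is_dms = logical(),
                  direction = character(), prop_a = double(),
                  prop_b = double(), cov_a = double(), cov_b = double()))
  }
  mA <- unname(rowSums(cm[keep, idx_a, drop = FALSE]))
  nA <- unname(rowSums(cov[keep, idx_a, drop = FALSE]))
  mB <- unname(rowSums(cm[keep, idx_b, drop = FALSE]))
  nB <- unname(rowSums(cov[keep, idx_b, drop = FALSE]))
  lr <- lr_binom_test(mA, nA, mB, nB, correction = correction)
  q <- p.adjust(lr$p, method = "BH")
  diff <- mA / nA - mB / nB
  tibble(site = rownames(cov)[keep],
         mean_diff = diff, stat = lr$stat, p = lr$p, q = q,
         is_dms = abs(diff) >= diff_threshold & q < q_threshold,
         direction = if_else(diff >= 0, "hyper_in_A", "hypo_in_A"),
         prop_a = mA / nA, prop_b = mB / nB, cov_a = nA, cov_b = nB)
}

#' Run all six pairwise phenotype comparisons
#'
#' @param matrix Long methylation matrix.
#' @param samples Sample sheet (`sample_id`, `phenotype`).
#' @param ... Passed to [test_differential()].
#' @return Bound tibble of the six comparison results, `comparison` =
#'   `"A_vs_B"` in phenotype order FW, VQ, MQ, MK.
#' @export
test_all_pairs <- function(matrix, samples, ...) {
  purrr::map_dfr(phenotype_pairs(), function(p) {
    ga <- samples$sample_id[samples$phenotype == p[1]]
    gb <- samples$sample_id[samples$phenotype == p[2]]
    test_differential(matrix, ga, gb, comparison = pair_label(p[1], p[2]), ...)
  })
}

#' Classify unique DMS, per-phenotype direction sets and DMGs
#'
#' A site is one unique DMS however many pairwise comparisons flag it. In a
#' comparison `A_vs_B`, a site hypermethylated in A is simultaneously
#' hypomethylated in B; per-phenotype hyper/hypo sets collect sites with
#' that direction in at least one comparison. Differentially methylated
#' genes (DMGs) are genes containing at least one DMS within the gene body
#' (exon or intron).
#'
#' @param results Bound pairwise results ([test_all_pairs()] shape) with
#'   `comparison` labels of the form `"A_vs_B"`.
#' @param annotation Optional site annotation (tibble with `site`,
#'   `region_class`, `gene_id`) enabling the DMG map.
#' @return List of class `dms_summary`: `unique_dms`, `phenotype_sets`
#'   (site x phenotype x direction), `phenotype_counts`, `pair_matrix`
#'   (hyper phenotype x hypo phenotype DMS counts), `dmg` and `results`.
#' @export
classify_dms <- function(results, annotation = NULL) {
  assert_cols(results, c("site", "comparison", "is_dms", "direction"))
  dms <- results %>% filter(.data$is_dms)
  pheno <- strsplit(dms$comparison, "_vs_")
  dms <- dms %>%
    mutate(pheno_a = purrr::map_chr(pheno, 1),
           pheno_b = purrr::map_chr(pheno, 2),
           hyper_phenotype = if_else(.data$direction == "hyper_in_A",
                                     .data$pheno_a, .data$pheno_b),
           hypo_phenotype = if_else(.data$direction == "hyper_in_A",
                                    .data$pheno_b, .data$pheno_a))

  unique_dms <- dms %>% distinct(.data$site)
  phenotype_sets <- bind_rows(
    dms %>% transmute(site = .data$site, phenotype = .data$hyper_phenotype,
                      direction = "hyper"),
    dms %>% transmute(site = .data$site, phenotype = .data$hypo_phenotype,
                      direction = "hypo")) %>%
    distinct()
  phenotype_counts <- phenotype_sets %>%
    count(.data$phenotype, .data$direction, name = "n_unique")

  pair_matrix <- matrix(0L, 4, 4, dimnames = list(hypo = PHENOTYPES,
                                                  hyper = PHENOTYPES))
  tab <- dms %>% count(.data$hyper_phenotype, .data$hypo_phenotype)
  pair_matrix[cbind(tab$hypo_phenotype, tab$hyper_phenotype)] <- tab$n

  dmg <- NULL
  if (!is.null(annotation)) {
    assert_cols(annotation, c("site", "region_class", "gene_id"))
    ann <- annotation %>% distinct(.data$site, .data$region_class, .data$gene_id)
    dmg <- phenotype_sets %>%
      inner_join(ann, by = "site") %>%
      filter(.data$region_class %in% c("exon", "intron"),
             !is.na(.data$gene_id)) %>%
      group_by(.data$gene_id) %>%
      summarise(n_dms = n_distinct(.data$site),
                hyper_phenotypes = paste(sort(unique(
                  .data$phenotype[.data$direction == "hyper"])), collapse = ","),
                hypo_phenotypes = paste(sort(unique(
                  .data$phenotype[.data$direction == "hypo"])), collapse = ","),
                .groups = "drop")
  }
  structure(list(unique_dms = unique_dms, phenotype_sets = phenotype_sets,
                 phenotype_counts = phenotype_counts,
                 pair_matrix = pair_matrix, dmg = dmg, results = results),
            class = "dms_summary")
}

#' @exportS3Method base::print
print.dms_summary <- function(x, ...) {
  cat(sprintf("<dms_summary> %d unique DMS", nrow(x$unique_dms)))
  if (!is.null(x$dmg)) cat(sprintf(" in %d DMGs", nrow(x$dmg)))
  cat("\n")
  print(x$pair_matrix)
  invisible(x)
}

#' Region enrichment of DMS against the sequenced background
#'
#' For each phenotype x direction x region cell, a 2x2 chi-square (without
#' continuity correction, df = 1) of DMS membership against region
#' membership over all annotated background CpGs; Fisher's exact test is
#' substituted when an expected cell drops below 1 (noted in `method`).
#' BH adjustment across all cells.
#'
#' @param dms A [classify_dms()] result.
#' @param background Site annotation of all matrix CpGs (`site`,
#'   `region_class`); ambiguous sites excluded.
#' @return Tibble: phenotype, direction, region_class, counts, DMS and
#'   background proportions, statistic, p, q, method.
#' @export
region_enrichment <- function(dms, background) {
  stopifnot(inherits(dms, "dms_summary"))
  assert_cols(background, c("site", "region_class"))
  bg <- background %>%
    distinct(.data$site, .data$region_class) %>%
    filter(.data$region_class != "ambiguous")
  n_bg <- nrow(bg)

  cells <- dms$phenotype_sets %>%
    inner_join(bg, by = "site") %>%
    count(.data$phenotype, .data$direction, .data$region_class,
          name = "n_dms_in_region") %>%
    left_join(dms$phenotype_sets %>% count(.data$phenotype, .data$direction,
                                           name = "n_dms"),
              by = c("phenotype", "direction")) %>%
    left_join(bg %>% count(.data$region_class, name = "n_region"),
              by = "region_class")

  res <- purrr::pmap_dfr(cells, function(phenotype, direction, region_class,
                                         n_dms_in_region, n_dms, n_region) {
    a <- n_dms_in_region
    b <- n_dms - a
    cc <- n_region - a
    d <- n_bg - n_dms - cc
    tab <- matrix(c(a, b, cc, d), 2)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 1)) {
      ft <- fisher.test(tab)
      tibble(phenotype, direction, region_class, n_dms_in_region, n_dms,
             n_region, statistic = NA_real_, p = ft$p.value,
             method = "fisher")
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      tibble(phenotype, direction, region_class, n_dms_in_region, n_dms,
             n_region, statistic = unname(ct$statistic), p = ct$p.value,
             method = "chisq")
    }
  })
  res %>%
    mutate(prop_dms = .data$n_dms_in_region / .data$n_dms,
           prop_background = .data$n_region / n_bg,
           q = p.adjust(.data$p, method = "BH"))
}

#' Randomized-grouping null distribution of DMS counts
#'
#' Repeatedly draws two groups of `group_size` samples from the matrix
#' (default: six distinct samples split 3/3, sampled without replacement;
#' `mode = "with_replacement"` lets the two groups share individuals), runs
#' the differential test at identical thresholds and records the DMS count,
#' yielding percentile confidence intervals against which the observed
#' phenotype-pair counts are flagged (above the 99th / 95th or below the 5th
#' percentile of the null).
#'
#' @param matrix Long methylation matrix.
#' @param n_iter Number of randomized groupings (default 1000; < 100 warns).
#' @param group_size Samples per group (default 3).
#' @param mode `"disjoint"` or `"with_replacement"`.
#' @param min_cov,diff_threshold,q_threshold,correction As
#'   [test_differential()].
#' @param samples Optional sample sheet (`sample_id`, `phenotype`); when
#'   given, observed per-pair DMS counts are computed and flagged against
#'   the null.
#' @param seed Optional integer seed for the randomized groupings.
#' @return List of class `bootstrap_null`: `counts` (length `n_iter`),
#'   `ci95`, `ci99`, and (with `samples`) `observed` with flag columns.
#' @export
bootstrap_null <- function(matrix, n_iter = 1000, group_size = 3,
                           mode = c("disjoint", "with_replacement"),
                           min_cov = 10, diff_threshold = 0.25,
                           q_threshold = 0.05, correction = "none",
                           samples = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (n_iter < 100) warn("n_iter < 100: percentile intervals will be unstable")
  if (!is.null(seed)) set.seed(seed)
  cm <- meth_wide(matrix, "count_meth")
  cov <- meth_wide(matrix, "coverage")
  cov[is.na(cov)] <- 0
  cm[is.na(cm)] <- 0
  n_samp <- ncol(cov)
  if (n_samp < 2 * group_size && mode == "disjoint") {
    abort("need >= 2 * group_size samples for disjoint bootstrap groups")
  }
  counts <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    if (mode == "disjoint") {
      pick <- sample.int(n_samp, 2 * group_size)
      ia <- pick[seq_len(group_size)]
      ib <- pick[group_size + seq_len(group_size)]
    } else {
      ia <- sample.int(n_samp, group_size, replace = TRUE)
      ib <- sample.int(n_samp, group_size, replace = TRUE)
    }
    res <- dms_test_wide(cm, cov, ia, ib, min_cov = min_cov,
                         diff_threshold = diff_threshold,
                         q_threshold = q_threshold, correction = correction)
    counts[i] <- sum(res$is_dms)
  }
  out <- list(counts = counts,
              ci95 = unname(quantile(counts, c(0.025, 0.975))),
              ci99 = unname(quantile(counts, c(0.005, 0.995))),
              n_iter = n_iter, mode = mode)
  if (!is.null(samples)) {
    obs <- purrr::map_dfr(phenotype_pairs(), function(p) {
      ia <- match(samples$sample_id[samples$phenotype == p[1]], colnames(cov))
      ib <- match(samples$sample_id[samples$phenotype == p[2]], colnames(cov))
      res <- dms_test_wide(cm, cov, ia, ib, min_cov = min_cov,
                           diff_threshold = diff_threshold,
                           q_threshold = q_threshold, correction = correction)
      tibble(comparison = pair_label(p[1], p[2]), n_dms = sum(res$is_dms))
    })
    obs <- obs %>%
      mutate(frac_null_below = purrr::map_dbl(.data$n_dms,
                                              ~ mean(counts < .x)),
             in_ci95 = .data$n_dms >= out$ci95[1] & .data$n_dms <= out$ci95[2],
             flag = case_when(.data$frac_null_below > 0.99 ~ "**",
                              .data$frac_null_below > 0.95 ~ "*",
                              .data$frac_null_below < 0.05 ~ "§",
                              TRUE ~ ""))
    out$observed <- obs
  }
  structure(out, class = "bootstrap_null")
}

#' @exportS3Method base::print
print.bootstrap_null <- function(x, ...) {
  cat(sprintf("<bootstrap_null> %d iterations (%s): 95%% CI [%g, %g], 99%% CI [%g, %g]\n",
              x$n_iter, x$mode, x$ci95[1], x$ci95[2], x$ci99[1], x$ci99[2]))
  if (!is.null(x$observed)) print(x$observed)
  invisible(x)
}
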