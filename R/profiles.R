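#' Region-class methylation summary with omnibus and pairwise tests
#'
#' Computes per-CpG means across samples first (one observation per CpG, so
#' region comparisons are not pseudo-replicated across samples), then a
#' Kruskal-Wallis rank-sum test across region classes on these means and
#' two-sided pairwise Wilcoxon rank-sum tests with Benjamini-Hochberg
#' adjustment. Per-sample per-class means and standard errors are returned
#' alongside. Ambiguous sites are excluded; classes with fewer than two
#' sites are excluded with a warning.
#'
#' @param annotated Annotated methylation matrix (long; [annotate_sites()]).
#' @return List of class `region_summary`: `per_sample` (class x sample mean,
#'   se, n_sites), `per_class` (cross-sample mean of per-CpG means, se,
#'   n_sites), `omnibus` (KW statistic, df, p) and `pairwise` (tibble of
#'   class pairs with BH-adjusted Wilcoxon p).
#' @export
region_summary <- function(annotated) {
  assert_cols(annotated, c("site", "sample_id", "level", "region_class"))
  dat <- annotated %>% filter(.data$region_class != "ambiguous")
  small <- dat %>%
    distinct(.data$site, .data$region_class) %>%
    count(.data$region_class) %>%
    filter(.data$n < 2)
  if (nrow(small) > 0) {
    warn(sprintf("excluding region class(es) with < 2 sites: %s",
                 paste(small$region_class, collapse = ", ")))
    dat <- dat %>% filter(!.data$region_class %in% small$region_class)
  }
  if (n_distinct(dat$region_class) < 2) {
    abort("region_summary needs >= 2 region classes")
  }

  per_sample <- dat %>%
    group_by(.data$region_class, .data$sample_id) %>%
    summarise(mean_level = mean(.data$level),
              se = sd(.data$level) / sqrt(n()),
              n_sites = n(), .groups = "drop")

  site_means <- dat %>%
    group_by(.data$site, .data$region_class) %>%
    summarise(mean_level = mean(.data$level), .groups = "drop")
  per_class <- site_means %>%
    group_by(.data$region_class) %>%
    summarise(se = sd(.data$mean_level) / sqrt(n()),
              mean_level = mean(.data$mean_level),
              n_sites = n(), .groups = "drop") %>%
    select("region_class", "mean_level", "se", "n_sites")

  kw <- kruskal.test(site_means$mean_level,
                     factor(site_means$region_class))
  classes <- sort(unique(site_means$region_class))
  pw <- purrr::map_dfr(combn(classes, 2, simplify = FALSE), function(p) {
    w <- suppressWarnings(wilcox.test(
      site_means$mean_level[site_means$region_class == p[1]],
      site_means$mean_level[site_means$region_class == p[2]]))
    tibble(class_a = p[1], class_b = p[2], p = w$p.value)
  }) %>%
    mutate(q = p.adjust(.data$p, method = "BH"))

  structure(list(per_sample = per_sample, per_class = per_class,
                 omnibus = tibble(statistic = unname(kw$statistic),
                                  df = unname(kw$parameter),
                                  p = kw$p.value),
                 pairwise = pw),
            class = "region_summary")
}

#' @exportS3Method base::print
print.region_summary <- function(x, ...) {
  cat("<region_summary>\n")
  print(x$per_class)
  cat(sprintf("Kruskal-Wallis chi-squared = %.4g, df = %d, p = %.3g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p))
  invisible(x)
}

#' Meta-gene methylation profile
#'
#' Mean methylation per sample along the gene body (exon and intron element
#' ranks, 5' to 3', ranks beyond `rank_cap` pooled into a terminal "last"
#' category) and outward through the 1 kb flank bins (5'-flank bins are
#' reported as negative positions -1, -2, ... counted away from the gene;
#' 3'-flank bins as positive).
#'
#' @param annotated Annotated methylation matrix.
#' @param rank_cap Pool exon/intron ranks beyond this value (default 10).
#' @return Tibble: `sample_id`, `element` (exon/intron/flank5/flank3),
#'   `position` (signed bin for flanks, rank for gene body), `rank_label`,
#'   `mean_level`, `n_sites`.
#' @export
metagene_profile <- function(annotated, rank_cap = 10) {
  assert_cols(annotated, c("sample_id", "level", "region_class"))
  body <- annotated %>%
    filter(.data$region_class %in% c("exon", "intron"),
           !is.na(.data$element_rank)) %>%
    mutate(element = .data$region_class,
           position = as.integer(pmin(.data$element_rank, rank_cap + 1L)),
           rank_label = if_else(.data$element_rank > rank_cap, "last",
                                as.character(.data$element_rank)))
  flank <- annotated %>%
    filter(.data$region_class %in% c("flank5", "flank3"),
           !is.na(.data$flank_bin)) %>%
    mutate(element = .data$region_class,
           position = if_else(.data$region_class == "flank5",
                              -as.integer(.data$flank_bin),
                              as.integer(.data$flank_bin)),
           rank_label = as.character(.data$position))
  bind_rows(body, flank) %>%
    group_by(.data$sample_id, .data$element, .data$position,
             .data$rank_label) %>%
    summarise(mean_level = mean(.data$level), n_sites = n(),
              .groups = "drop") %>%
    arrange(.data$sample_id, .data$element, .data$position)
}

#' Robustness census of methylation calls
#'
#' Counts, per CpG, in how many of the N samples it is flagged methylated,
#' tabulates the proportion of CpGs at each count within each region class,
#' and lists the robustly methylated genes: genes containing at least one
#' CpG methylated in all samples.
#'
#' @param annotated Annotated methylation matrix with `methylated` flags.
#' @return List of class `robustness_census`: `per_site` (site, region,
#'   gene, n_methylated_samples), `per_class` (region x count proportions
#'   over counts 0..N) and `robust_genes` (character vector).
#' @export
robustness_census <- function(annotated) {
  assert_cols(annotated, c("site", "sample_id", "methylated", "region_class"))
  n_samples <- n_distinct(annotated$sample_id)
  per_site <- annotated %>%
    group_by(.data$site, .data$region_class, .data$gene_id) %>%
    summarise(n_methylated_samples = sum(.data$methylated), .groups = "drop")
  per_class <- per_site %>%
    filter(.data$region_class != "ambiguous") %>%
    count(.data$region_class,
          n_methylated_samples = factor(.data$n_methylated_samples,
                                        levels = 0:n_samples)) %>%
    tidyr::complete(.data$region_class, .data$n_methylated_samples,
                    fill = list(n = 0L)) %>%
    group_by(.data$region_class) %>%
    mutate(proportion = .data$n / sum(.data$n),
           n_methylated_samples = as.integer(as.character(.data$n_methylated_samples))) %>%
    ungroup()
  robust_genes <- per_site %>%
    filter(.data$n_methylated_samples == n_samples, !is.na(.data$gene_id),
           .data$region_class %in% c("exon", "intron")) %>%
    pull(.data$gene_id) %>% unique() %>% sort()
  structure(list(per_site = per_site, per_class = per_class,
                 robust_genes = robust_genes, n_samples = n_samples),
            class = "robustness_census")
}

#' @exportS3Method base::print
print.robustness_census <- function(x, ...) {
  cat(sprintf("<robustness_census> %d sites, %d samples, %d robust genes\n",
              nrow(x$per_site), x$n_samples, length(x$robust_genes)))
  invisible(x)
}

#' Aggregate methylation per gene, feature type and sample
#'
#' Average methylation level over a gene's sites of each feature type (exon,
#' intron, 5'-flank, 3'-flank) per sample, each site weighted equally, with
#' the summed read coverage kept as a regression weight. Gene x region cells
#' without sites are absent.
#'
#' @param annotated Annotated methylation matrix.
#' @return Tibble `gene_id`, `region_class`, `sample_id`, `mean_level`,
#'   `total_reads`, `n_sites`.
#' @export
aggregate_gene_region <- function(annotated) {
  assert_cols(annotated, c("gene_id", "region_class", "sample_id",
                           "level", "coverage"))
  annotated %>%
    filter(.data$region_class %in% GENE_REGIONS, !is.na(.data$gene_id)) %>%
    group_by(.data$gene_id, .data$region_class, .data$sample_id) %>%
    summarise(mean_level = mean(.data$level),
              total_reads = sum(.data$coverage),
              n_sites = n(), .groups = "drop")
}

#' Between-sample correlation of methylation levels
#'
#' Pearson correlation between all sample pairs on per-site methylation
#' levels, optionally restricted to one region class (e.g. `"exon"` for
#' coding-only correlations).
#'
#' @param matrix Methylation matrix (annotated if `region_class` is used).
#' @param region_class Optional single region class to restrict to.
#' @return Symmetric correlation matrix, samples x samples.
#' @export
sample_correlations <- function(matrix, region_class = NULL) {
  assert_cols(matrix, c("site", "sample_id", "level"))
  if (!is.null(region_class)) {
    assert_cols(matrix, "region_class")
    matrix <- matrix %>% filter(.data$region_class %in% .env$region_class)
  }
  cor(meth_wide(matrix, "level"), use = "pairwise.complete.obs",
      method = "pearson")
}
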