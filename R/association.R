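# per-gene DE label table (one row per gene) from a long expression table
gene_expression_table <- function(expression) {
  assert_cols(expression, c("gene_id", "expression"))
  expression %>%
    group_by(.data$gene_id) %>%
    summarise(expression = mean(.data$expression),
              across(any_of(c("isoform_count")), first),
              across(any_of("as_flag"), first),
              across(dplyr::starts_with("de_"), first),
              .groups = "drop")
}

#' Differential-expression category overlap of a gene set
#'
#' Compares the observed counts of up/down/non-significant DE labels (for
#' one phenotype pair) within a gene set against the genome-wide label
#' proportions by a Pearson chi-square goodness-of-fit test (df = 2). Used
#' to ask whether, e.g., genes hypomethylated in mature queens are enriched
#' for differential expression. Falls back to an exact multinomial test when
#' an expected count drops below 1.
#'
#' @param gene_set Character vector of gene ids (subset of the expression
#'   universe).
#' @param expression Expression table (long or per-gene) with `de_` columns.
#' @param pair Phenotype pair, e.g. `c("VQ", "MQ")`, naming the DE label
#'   column `de_VQ_vs_MQ`.
#' @param expected Optional expected proportions, named
#'   `c(up_a, up_b, ns)`; defaults to the genome-wide proportions in
#'   `expression`.
#' @return List of class `overlap_test`: `observed` tibble (category, n,
#'   proportion), `expected` proportions, `statistic`, `df`, `p`, `method`.
#' @export
deg_overlap_test <- function(gene_set, expression, pair,
                             expected = NULL) {
  genes <- gene_expression_table(expression)
  # the label column may be stored under either phenotype order
  col <- paste0("de_", pair_label(pair[1], pair[2]))
  if (!col %in% names(genes)) {
    col <- paste0("de_", pair_label(pair[2], pair[1]))
  }
  assert_cols(genes, col, "expression table")
  miss <- setdiff(gene_set, genes$gene_id)
  if (length(miss) > 0) {
    abort(sprintf("gene_set contains %d id(s) absent from the expression universe",
                  length(miss)))
  }
  cats <- c(paste0("up_in_", pair[1]), paste0("up_in_", pair[2]), "ns")
  obs_lab <- factor(genes[[col]][genes$gene_id %in% gene_set], levels = cats)
  obs <- as.integer(table(obs_lab))
  if (is.null(expected)) {
    expected <- as.numeric(table(factor(genes[[col]], levels = cats))) /
      nrow(genes)
  }
  n <- sum(obs)
  exp_counts <- n * expected
  if (any(exp_counts < 1)) {
    # exact multinomial by Monte Carlo through chisq.test
    ct <- chisq.test(obs, p = expected, simulate.p.value = TRUE, B = 10000)
    method <- "exact_multinomial_mc"
    stat <- unname(ct$statistic); pval <- ct$p.value; df <- NA_integer_
  } else {
    ct <- suppressWarnings(chisq.test(obs, p = expected))
    method <- "chisq_gof"
    stat <- unname(ct$statistic); pval <- ct$p.value
    df <- unname(ct$parameter)
  }
  structure(list(observed = tibble(category = cats, n = obs,
                                   proportion = obs / sum(obs)),
                 expected = setNames(expected, cats),
                 statistic = stat, df = df, p = pval, method = method,
                 n = n),
            class = "overlap_test")
}

#' @exportS3Method base::print
print.overlap_test <- function(x, ...) {
  print(x$observed)
  cat(sprintf("chi-squared = %.4g, df = %s, p = %.3g (%s)\n",
              x$statistic, format(x$df), x$p, x$method))
  invisible(x)
}

#' Robust-gene by DEG association (2x2 chi-square)
#'
#' Tests whether genes in a set (e.g. robustly methylated genes) are more
#' often differentially expressed in at least one phenotype pair than the
#' remaining genes; chi-square on the 2x2 table without continuity
#' correction.
#'
#' @param gene_set Character vector of gene ids.
#' @param expression Expression table with `de_` columns.
#' @return Tibble: proportions DE inside/outside the set, statistic, df, p.
#' @export
robust_deg_test <- function(gene_set, expression) {
  genes <- gene_expression_table(expression)
  de_any <- genes %>%
    mutate(is_de = dplyr::if_any(dplyr::starts_with("de_"), ~ .x != "ns"),
           in_set = .data$gene_id %in% gene_set)
  tab <- table(in_set = de_any$in_set, is_de = de_any$is_de)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(prop_de_in_set = mean(de_any$is_de[de_any$in_set]),
         prop_de_outside = mean(de_any$is_de[!de_any$in_set]),
         statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value)
}

#' Methylation signatures of DEG groups
#'
#' Mean methylation per DEG group x gene region x sample. Groups are the
#' up/down sets of each phenotype pair, the pooled DEG set, and
#' house-keeping genes (HKG: non-differentially expressed genes with
#' expression above the median). Cross-sample standard deviations summarise
#' the stability of each signature across phenotypes.
#'
#' @param gene_region [aggregate_gene_region()] output.
#' @param expression Expression table with `de_` columns.
#' @return List of class `deg_profiles`: `per_sample` (group x region x
#'   sample mean), `summary` (group x region cross-sample mean and sd,
#'   `n_genes`), `groups` (gene membership).
#' @export
deg_group_profiles <- function(gene_region, expression) {
  assert_cols(gene_region, c("gene_id", "region_class", "sample_id",
                             "mean_level"))
  genes <- gene_expression_table(expression)
  groups <- list()
  for (p in phenotype_pairs()) {
    col <- paste0("de_", pair_label(p[1], p[2]))
    for (ph in p) {
      nm <- paste0("up_", ph, "_", pair_label(p[1], p[2]))
      ids <- genes$gene_id[genes[[col]] == paste0("up_in_", ph)]
      if (length(ids) > 0) groups[[nm]] <- ids
    }
  }
  is_de <- genes %>%
    mutate(is_de = dplyr::if_any(dplyr::starts_with("de_"), ~ .x != "ns"))
  groups[["DEG"]] <- is_de$gene_id[is_de$is_de]
  hkg <- is_de %>%
    filter(!.data$is_de, .data$expression > median(genes$expression))
  groups[["HKG"]] <- hkg$gene_id
  empty <- names(groups)[lengths(groups) == 0]
  if (length(empty) > 0) {
    warn(sprintf("empty DEG group(s) omitted: %s", paste(empty, collapse = ", ")))
    groups <- groups[lengths(groups) > 0]
  }

  membership <- purrr::imap_dfr(groups, ~ tibble(group = .y, gene_id = .x))
  per_sample <- membership %>%
    inner_join(gene_region, by = "gene_id",
               relationship = "many-to-many") %>%
    group_by(.data$group, .data$region_class, .data$sample_id) %>%
    summarise(mean_level = mean(.data$mean_level),
              n_genes = n_distinct(.data$gene_id), .groups = "drop")
  summary <- per_sample %>%
    group_by(.data$group, .data$region_class) %>%
    summarise(mean_level_all = mean(.data$mean_level),
              sd_across_samples = sd(.data$mean_level),
              n_genes = first(.data$n_genes), .groups = "drop")
  structure(list(per_sample = per_sample, summary = summary,
                 groups = membership),
            class = "deg_profiles")
}

#' @exportS3Method base::print
print.deg_profiles <- function(x, ...) {
  cat(sprintf("<deg_profiles> %d groups x %d regions\n",
              n_distinct(x$summary$group), n_distinct(x$summary$region_class)))
  invisible(x)
}

#' Per-sample Spearman correlation of coding methylation and expression
#'
#' For each sample, the Spearman rank correlation between per-gene mean exon
#' methylation and the gene's expression in that sample, with BH adjustment
#' across samples.
#'
#' @param gene_region [aggregate_gene_region()] output (exon rows used).
#' @param expression Long expression table (`gene_id`, `sample_id`,
#'   `expression`).
#' @return Tibble: `sample_id`, `rho`, `p`, `q`, `n_genes`.
#' @export
expression_correlation <- function(gene_region, expression) {
  assert_cols(expression, c("gene_id", "sample_id", "expression"))
  dat <- gene_region %>%
    filter(.data$region_class == "exon") %>%
    inner_join(expression %>% select("gene_id", "sample_id", "expression"),
               by = c("gene_id", "sample_id"))
  if (n_distinct(dat$gene_id) < 3) {
    abort("expression_correlation needs >= 3 genes with exon methylation")
  }
  dat %>%
    group_by(.data$sample_id) %>%
    summarise({
      ct <- suppressWarnings(cor.test(.data$mean_level, .data$expression,
                                      method = "spearman"))
      tibble(rho = unname(ct$estimate), p = ct$p.value, n_genes = n())
    }, .groups = "drop") %>%
    mutate(q = p.adjust(.data$p, method = "BH"))
}
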