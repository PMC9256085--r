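#' PCA of the most variable CpG sites
#'
#' Ranks sites by their across-sample variance of methylation level, keeps
#' the `n_top` most variable, and runs a principal component analysis on the
#' samples x sites matrix, centred per site and not scaled.
#'
#' @param matrix Long methylation matrix.
#' @param n_top Number of most-variable sites (default 1000; capped to the
#'   available sites with a warning).
#' @param samples Optional sample sheet; its `phenotype`/`colony` columns
#'   are joined onto the scores.
#' @return Object of class `meth_pca`: `scores` tibble (`sample_id`, PCs,
#'   any sample metadata), `var_explained` (percent per component),
#'   `sites` used, and the underlying `prcomp` fit.
#' @export
pca_top_variable <- function(matrix, n_top = 1000, samples = NULL) {
  assert_cols(matrix, c("site", "sample_id", "level"))
  lv <- meth_wide(matrix, "level")
  v <- apply(lv, 1, var)
  if (n_top > nrow(lv)) {
    warn(sprintf("n_top = %d exceeds the %d available sites; using all",
                 n_top, nrow(lv)))
    n_top <- nrow(lv)
  }
  top <- order(v, decreasing = TRUE)[seq_len(n_top)]
  fit <- prcomp(t(lv[top, , drop = FALSE]), center = TRUE, scale. = FALSE)
  scores <- as_tibble(fit$x, rownames = "sample_id")
  if (!is.null(samples)) {
    scores <- scores %>%
      left_join(samples %>% select(any_of(c("sample_id", "phenotype",
                                            "colony"))),
                by = "sample_id")
  }
  structure(list(scores = scores,
                 var_explained = 100 * fit$sdev^2 / sum(fit$sdev^2),
                 sites = rownames(lv)[top], fit = fit, n_top = n_top),
            class = "meth_pca")
}

#' @exportS3Method base::print
print.meth_pca <- function(x, ...) {
  cat(sprintf("<meth_pca> %d sites, PC1 %.1f%%, PC2 %.1f%%\n", x$n_top,
              x$var_explained[1], x$var_explained[2]))
  invisible(x)
}

#' @export
tidy.meth_pca <- function(x, ...) x$scores

#' @export
glance.meth_pca <- function(x, ...) {
  tibble(n_top = x$n_top,
         pc1_var = x$var_explained[1], pc2_var = x$var_explained[2])
}

#' Kruskal-Wallis variance partition over study factors
#'
#' Among the `n_top` most variable sites, tests the effect of each factor
#' (colony, phenotype, genomic region by default) on methylation level with
#' a Kruskal-Wallis rank-sum test on the long site x sample observations,
#' and reports the rank eta-squared effect size
#' `eta2_H = (H - k + 1) / (n - k)`.
#'
#' @param annotated Annotated methylation matrix.
#' @param samples Sample sheet with `colony` and `phenotype`.
#' @param n_top Number of most-variable sites (default 10000).
#' @param factors Factors to test.
#' @return Tibble: `factor`, `statistic`, `df`, `p`, `eta_sq`.
#' @export
variance_partition <- function(annotated, samples, n_top = 10000,
                               factors = c("colony", "phenotype",
                                           "region_class")) {
  assert_cols(annotated, c("site", "sample_id", "level"))
  lv <- meth_wide(annotated, "level")
  v <- apply(lv, 1, var)
  if (n_top > nrow(lv)) {
    warn(sprintf("n_top = %d exceeds the %d available sites; using all",
                 n_top, nrow(lv)))
    n_top <- nrow(lv)
  }
  top_sites <- rownames(lv)[order(v, decreasing = TRUE)[seq_len(n_top)]]
  dat <- annotated %>%
    filter(.data$site %in% top_sites) %>%
    left_join(samples %>% select(any_of(c("sample_id", "colony",
                                          "phenotype"))),
              by = "sample_id")
  if ("region_class" %in% factors) {
    dat <- dat %>% filter(.data$region_class != "ambiguous")
  }
  purrr::map_dfr(factors, function(f) {
    assert_cols(dat, f, "variance_partition data")
    g <- factor(dat[[f]])
    kw <- kruskal.test(dat$level, g)
    k <- nlevels(g)
    n <- length(g)
    tibble(factor = f, statistic = unname(kw$statistic),
           df = unname(kw$parameter), p = kw$p.value,
           eta_sq = max(0, (unname(kw$statistic) - k + 1) / (n - k)))
  })
}
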