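#' Weighted binomial regression of methylation on expression
#'
#' Fits the gene-region methylation model
#' `methylation ~ log10(expression + 0.001) * variable * region` with
#' per-sample intercepts, on the per gene x region x sample aggregates:
#' the response is the successes/failures pair
#' `round(mean_level * total_reads)` / remainder, so each observation is
#' weighted by its summed read coverage. `variable` is one of the gene-level
#' factors `DE` (differentially expressed in at least one phenotype pair),
#' `transcripts` (isoform count, continuous) or `AS` (caste-biased exon
#' usage). Region enters as a factor with exon as the reference level.
#'
#' Samples can be handled as absorbed fixed intercepts (`method = "fixed"`,
#' default) or as a random intercept via `lme4::glmer`
#' (`method = "glmer"`). Default inference is quasi-likelihood
#' (`family = "quasibinomial"`): the dispersion is estimated from the
#' Pearson residuals, which keeps Wald statistics honest when gene-level
#' counts are overdispersed relative to binomial, as RRBS aggregates are;
#' `family = "binomial"` gives the raw binomial fit. The choice is recorded
#' in the fit metadata.
#'
#' @param gene_region [aggregate_gene_region()] output.
#' @param expression Long expression table with `de_` label columns,
#'   `isoform_count`, `as_flag`.
#' @param variable `"DE"`, `"transcripts"` or `"AS"`.
#' @param method `"fixed"` or `"glmer"`.
#' @param family `"quasibinomial"` or `"binomial"` (glmer is always
#'   binomial).
#' @return Object of class `meth_glm` with the fitted model, data and
#'   metadata; see [tidy.meth_glm()], [glance.meth_glm()],
#'   [glm_variable_contrast()] and [predict_methylation_grid()].
#' @export
fit_methylation_glm <- function(gene_region, expression,
                                variable = c("DE", "transcripts", "AS"),
                                method = c("fixed", "glmer"),
                                family = c("quasibinomial", "binomial")) {
  variable <- match.arg(variable)
  method <- match.arg(method)
  family <- match.arg(family)
  assert_cols(gene_region, c("gene_id", "region_class", "sample_id",
                             "mean_level", "total_reads"))
  genes <- gene_expression_table(expression)
  var_col <- switch(variable,
    DE = genes %>%
      mutate(var = factor(if_else(dplyr::if_any(dplyr::starts_with("de_"),
                                                ~ .x != "ns"), "DE", "non-DE"),
                          levels = c("non-DE", "DE"))) %>%
      select("gene_id", "var"),
    transcripts = genes %>%
      mutate(var = as.numeric(.data$isoform_count)) %>%
      select("gene_id", "var"),
    AS = genes %>%
      mutate(var = factor(.data$as_flag, levels = c("non-AS", "AS"))) %>%
      select("gene_id", "var"))

  expr_long <- if ("sample_id" %in% names(expression)) {
    expression %>% select("gene_id", "sample_id", "expression")
  } else {
    abort("expression table must be long by sample (gene_id, sample_id, expression)")
  }
  dat <- gene_region %>%
    inner_join(var_col, by = "gene_id") %>%
    inner_join(expr_long, by = c("gene_id", "sample_id")) %>%
    mutate(log_expr = log10(.data$expression + 0.001),
           region = factor(.data$region_class, levels = GENE_REGIONS),
           sample_id = factor(.data$sample_id),
           successes = round(.data$mean_level * .data$total_reads),
           failures = .data$total_reads - .data$successes)

  degenerate <- (is.factor(dat$var) && n_distinct(dat$var) < 2) ||
    (is.numeric(dat$var) && var(dat$var) == 0)
  rhs <- if (degenerate) "log_expr * region" else "log_expr * var * region"
  one_sample <- nlevels(dat$sample_id) < 2

  if (method == "fixed") {
    form <- as.formula(paste("cbind(successes, failures) ~", rhs,
                             if (!one_sample) "+ sample_id" else ""))
    fam <- if (family == "quasibinomial") quasibinomial() else binomial()
    fit <- glm(form, family = fam, data = dat)
    if (!fit$converged) abort("binomial GLM did not converge")
  } else {
    if (family == "quasibinomial") {
      warn("glmer supports binomial only; fitting family = binomial")
      family <- "binomial"
    }
    if (one_sample) abort("random-intercept fit needs >= 2 samples")
    form <- as.formula(paste("cbind(successes, failures) ~", rhs,
                             "+ (1 | sample_id)"))
    fit <- lme4::glmer(form, family = binomial(), data = dat)
  }
  structure(list(fit = fit, data = dat, variable = variable,
                 method = method, family = family, degenerate = degenerate,
                 formula = form),
            class = "meth_glm")
}

#' @exportS3Method base::print
print.meth_glm <- function(x, ...) {
  cat(sprintf("<meth_glm> variable = %s, method = %s, family = %s, n = %d\n",
              x$variable, x$method, x$family, nrow(x$data)))
  invisible(x)
}

coef_table <- function(x) {
  if (x$method == "fixed") {
    s <- summary(x$fit)$coefficients
  } else {
    s <- coef(summary(x$fit))
  }
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3],
         p.value = if (ncol(s) >= 4) s[, 4] else
           2 * pnorm(-abs(s[, 3])))
}

#' Tidy coefficients of a methylation GLM
#'
#' @param x A `meth_glm`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `std.error`, `statistic`, `p.value`
#'   (logit scale), sample intercepts excluded.
#' @export
tidy.meth_glm <- function(x, ...) {
  coef_table(x) %>% filter(!grepl("^sample_id", .data$term))
}

#' One-line model summary of a methylation GLM
#'
#' @param x A `meth_glm`.
#' @param ... Unused.
#' @return Tibble with observation count, deviance, dispersion and metadata.
#' @export
glance.meth_glm <- function(x, ...) {
  disp <- if (x$method == "fixed") summary(x$fit)$dispersion else NA_real_
  dev <- if (x$method == "fixed") x$fit$deviance else
    as.numeric(lme4::REMLcrit(x$fit) %||% stats::deviance(x$fit))
  tibble(nobs = nrow(x$data), deviance = dev, dispersion = disp,
         variable = x$variable, method = x$method, family = x$family)
}

# model-matrix rows for prediction at new covariate values (fixed method
# uses the first sample's intercept; differences cancel it)
glm_row <- function(x, newdata) {
  trm <- stats::delete.response(stats::terms(x$fit))
  xlev <- if (x$method == "fixed") x$fit$xlevels else NULL
  model.matrix(trm, newdata, xlev = xlev)
}

#' Contrast of the gene-level variable within one region
#'
#' Estimates, on the logit scale, the difference in predicted methylation
#' between the two levels of the model's variable (or per unit for a
#' continuous variable) within a region, at a given expression percentile;
#' Wald standard error and normal CI from the coefficient covariance.
#'
#' @param x A `meth_glm` (non-degenerate).
#' @param region One of exon, intron, flank5, flank3.
#' @param at_percentile Expression percentile at which to evaluate (default
#'   0.5).
#' @param level CI level (default 0.95).
#' @param se `"cluster"` (default for the fixed-intercept fit):
#'   cluster-robust covariance with genes as clusters, acknowledging that a
#'   gene's observations across samples and regions are correlated;
#'   `"model"`: the model-based covariance (always used for `glmer` fits).
#' @return Tibble: `region`, `at_log_expr`, `estimate`, `std.error`, `z`,
#'   `conf.low`, `conf.high`, `p.value`.
#' @export
glm_variable_contrast <- function(x, region = "exon", at_percentile = 0.5,
                                  level = 0.95,
                                  se = c("cluster", "model")) {
  stopifnot(inherits(x, "meth_glm"))
  se <- match.arg(se)
  if (x$degenerate) abort("model was fitted without the variable (degenerate design)")
  le <- quantile(x$data$log_expr, at_percentile, names = FALSE)
  base <- tibble(log_expr = le,
                 region = factor(region, levels = GENE_REGIONS),
                 sample_id = factor(levels(x$data$sample_id)[1],
                                    levels = levels(x$data$sample_id)))
  if (is.factor(x$data$var)) {
    lv <- levels(x$data$var)
    nd0 <- base %>% mutate(var = factor(lv[1], levels = lv))
    nd1 <- base %>% mutate(var = factor(lv[2], levels = lv))
  } else {
    v0 <- median(x$data$var)
    nd0 <- base %>% mutate(var = v0)
    nd1 <- base %>% mutate(var = v0 + 1)
  }
  L <- glm_row(x, nd1) - glm_row(x, nd0)
  beta <- if (x$method == "fixed") coef(x$fit) else lme4::fixef(x$fit)
  V <- if (x$method == "fixed" && se == "cluster") {
    sandwich::vcovCL(x$fit, cluster = x$data$gene_id)
  } else {
    as.matrix(vcov(x$fit))
  }
  keep <- intersect(colnames(L), names(beta))
  est <- drop(L[, keep, drop = FALSE] %*% beta[keep])
  se <- sqrt(drop(L[, keep, drop = FALSE] %*% V[keep, keep] %*%
                    t(L[, keep, drop = FALSE])))
  zq <- qnorm(1 - (1 - level) / 2)
  tibble(region = region, at_log_expr = le, estimate = est, std.error = se,
         z = est / se, conf.low = est - zq * se, conf.high = est + zq * se,
         p.value = 2 * pnorm(-abs(est / se)))
}

#' Predicted methylation over an expression-percentile grid
#'
#' Response-scale predictions per region and variable level across
#' expression percentiles, averaged over the per-sample intercepts, for
#' effect-display plots.
#'
#' @param x A `meth_glm`.
#' @param percentiles Expression percentiles (default 19-point grid).
#' @return Tibble: `region`, `var`, `percentile`, `log_expr`, `predicted`
#'   (in `[0, 1]`).
#' @export
predict_methylation_grid <- function(x, percentiles = seq(0.05, 0.95, 0.05)) {
  stopifnot(inherits(x, "meth_glm"))
  le <- quantile(x$data$log_expr, percentiles, names = FALSE)
  var_vals <- if (x$degenerate) list(NULL) else if (is.factor(x$data$var)) {
    as.list(levels(x$data$var))
  } else {
    as.list(quantile(x$data$var, c(0.25, 0.75), names = FALSE))
  }
  grid <- tidyr::expand_grid(
    region = factor(GENE_REGIONS, levels = GENE_REGIONS),
    vi = seq_along(var_vals),
    pi = seq_along(percentiles))
  samples <- levels(x$data$sample_id)
  out <- grid %>%
    mutate(log_expr = le[.data$pi], percentile = percentiles[.data$pi])
  if (!x$degenerate) {
    out$var <- if (is.factor(x$data$var)) {
      factor(unlist(var_vals)[out$vi], levels = levels(x$data$var))
    } else as.numeric(unlist(var_vals)[out$vi])
  }
  preds <- purrr::map(samples, function(s) {
    nd <- out %>% mutate(sample_id = factor(s, levels = samples))
    if (x$method == "fixed") {
      predict(x$fit, newdata = nd, type = "response")
    } else {
      predict(x$fit, newdata = nd, type = "response")
    }
  })
  out %>%
    mutate(predicted = rowMeans(do.call(cbind, preds))) %>%
    mutate(var = if (x$degenerate) NA else .data$var) %>%
    select("region", "var", "percentile", "log_expr", "predicted")
}
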