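#' Estimate bisulfite non-conversion from unmethylated spike-in controls
#'
#' The non-conversion rate is the fraction of spike-in cytosines that escaped
#' conversion, `spikein_meth / (spikein_meth + spikein_unmeth)`; it sets the
#' error floor against which genomic methylation is called. Samples fail QC
#' when the rate reaches `qc_threshold` (default 5%); a stricter reporting
#' flag marks the 2% bar that well-converted libraries meet.
#'
#' @param samples Sample-sheet tibble with `sample_id`, `spikein_meth`,
#'   `spikein_unmeth`.
#' @param qc_threshold QC cutoff on the rate (default 0.05).
#' @param strict_threshold Stricter reporting cutoff (default 0.02).
#' @return Input tibble plus `nonconversion_rate`, `qc_pass`, `strict_pass`.
#' @export
estimate_nonconversion <- function(samples, qc_threshold = 0.05,
                                   strict_threshold = 0.02) {
  assert_cols(samples, c("sample_id", "spikein_meth", "spikein_unmeth"))
  total <- samples$spikein_meth + samples$spikein_unmeth
  if (any(total == 0)) {
    abort(sprintf("sample %s has zero spike-in reads; non-conversion undefined",
                  samples$sample_id[total == 0][1]))
  }
  samples %>%
    mutate(nonconversion_rate = .data$spikein_meth /
             (.data$spikein_meth + .data$spikein_unmeth),
           qc_pass = .data$nonconversion_rate < qc_threshold,
           strict_pass = .data$nonconversion_rate < strict_threshold)
}

#' Call per-CpG methylation against the non-conversion floor
#'
#' A site's methylated read count is compared with what non-conversion error
#' alone would produce: the p-value is the upper binomial tail
#' `P(X >= count_meth | n = coverage, p = rate)` (one-sided, since true
#' methylation can only inflate non-converted counts). P-values are
#' Benjamini-Hochberg adjusted across all tested sites of the sample and a
#' site is flagged methylated when `q < alpha`; everything else is counted as
#' non-methylated. Sites below `min_coverage` are dropped as unsequenced,
#' not called unmethylated.
#'
#' @param records Coverage tibble for one sample ([read_coverage()] shape).
#' @param rate The sample's non-conversion rate in `[0, 1)`.
#' @param alpha FDR level for the methylated flag (default 0.05).
#' @param min_coverage Minimum reads for a site to be tested (default 5).
#' @return Filtered tibble plus columns `p`, `q`, `methylated`.
#' @export
call_methylation <- function(records, rate, alpha = 0.05, min_coverage = 5) {
  assert_cols(records, c("count_meth", "coverage"))
  if (rate < 0 || rate >= 1) abort("non-conversion rate must lie in [0, 1)")
  out <- records %>% filter(.data$coverage >= min_coverage)
  p <- pbinom(out$count_meth - 1L, out$coverage, rate, lower.tail = FALSE)
  out %>%
    mutate(p = p,
           q = p.adjust(p, method = "BH"),
           methylated = .data$q < alpha)
}

#' Assemble the cross-sample methylation matrix
#'
#' Restricts the study to the largest common ground: exactly the CpGs covered
#' by at least `min_coverage` reads in every sample. Per-sample sequenced-site
#' counts and the intersection size are recorded as attributes (retrievable
#' with [matrix_summary()]).
#'
#' @param calls Long tibble of per-sample calls: [call_methylation()] output
#'   rows for all samples, with a `sample_id` column and site coordinates.
#' @param min_coverage Minimum coverage required in every sample (default 5).
#' @return Long tibble (class `meth_matrix`) with one row per retained site
#'   and sample: `site`, `chrom`, `pos`, `strand`, `sample_id`, `count_meth`,
#'   `coverage`, `level`, `methylated` (if present in `calls`).
#' @export
build_matrix <- function(calls, min_coverage = 5) {
  assert_cols(calls, c("sample_id", "chrom", "pos", "strand",
                       "count_meth", "coverage"))
  n_samples <- n_distinct(calls$sample_id)
  if (n_samples < 2) abort("need >= 2 samples to build a matrix")
  calls <- calls %>%
    mutate(site = site_key(.data$chrom, .data$pos, .data$strand)) %>%
    filter(.data$coverage >= min_coverage)

  per_sample <- calls %>% count(.data$sample_id, name = "n_sequenced")
  common <- calls %>%
    count(.data$site) %>%
    filter(.data$n == n_samples) %>%
    pull(.data$site)
  if (length(common) == 0) {
    abort(paste0("empty CpG intersection across samples at min_coverage = ",
                 min_coverage, "; per-sample sequenced sites: ",
                 paste(sprintf("%s=%d", per_sample$sample_id,
                               per_sample$n_sequenced), collapse = ", ")))
  }
  out <- calls %>%
    filter(.data$site %in% common) %>%
    mutate(level = .data$count_meth / .data$coverage) %>%
    arrange(.data$chrom, .data$pos, .data$strand, .data$sample_id)
  attr(out, "per_sample_sequenced") <- per_sample
  attr(out, "n_sites") <- length(common)
  attr(out, "n_samples") <- n_samples
  class(out) <- c("meth_matrix", class(out))
  out
}

#' Summary of a methylation matrix
#'
#' @param matrix A [build_matrix()] result.
#' @return Tibble: per-sample sequenced-site counts, intersection size and
#'   the intersection as a percentage of the union-wide maximum per sample.
#' @export
matrix_summary <- function(matrix) {
  ps <- attr(matrix, "per_sample_sequenced")
  ps %>%
    mutate(n_intersection = attr(matrix, "n_sites"),
           pct_of_sequenced = 100 * .data$n_intersection / .data$n_sequenced)
}

#' One-call pipeline from coverage tables to the methylation matrix
#'
#' Runs [estimate_nonconversion()], per-sample [call_methylation()] and
#' [build_matrix()] over a long coverage tibble.
#'
#' @param coverage Long tibble of all samples' coverage records with a
#'   `sample_id` column.
#' @param samples Sample sheet with spike-in counts.
#' @param min_coverage,alpha,qc_threshold See the stage functions.
#' @return A `meth_matrix`; samples failing spike-in QC are dropped with a
#'   warning.
#' @export
call_study <- function(coverage, samples, min_coverage = 5, alpha = 0.05,
                       qc_threshold = 0.05) {
  nc <- estimate_nonconversion(samples, qc_threshold = qc_threshold)
  if (any(!nc$qc_pass)) {
    warn(sprintf("dropping %d sample(s) failing non-conversion QC: %s",
                 sum(!nc$qc_pass),
                 paste(nc$sample_id[!nc$qc_pass], collapse = ", ")))
    nc <- nc %>% filter(.data$qc_pass)
  }
  calls <- purrr::map(nc$sample_id, function(sid) {
    call_methylation(coverage %>% filter(.data$sample_id == sid),
                     rate = nc$nonconversion_rate[nc$sample_id == sid],
                     alpha = alpha, min_coverage = min_coverage)
  }) %>% bind_rows()
  build_matrix(calls, min_coverage = min_coverage)
}
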