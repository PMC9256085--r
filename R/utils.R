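# shared internal helpers

PHENOTYPES <- c("FW", "VQ", "MQ", "MK")
REGION_CLASSES <- c("exon", "intron", "flank5", "flank3", "repeat", "intergenic")
GENE_REGIONS <- c("exon", "intron", "flank5", "flank3")

# the 6 ordered phenotype pairs, alphabetical within the fixed phenotype order
phenotype_pairs <- function() {
  combn(PHENOTYPES, 2, simplify = FALSE)
}

pair_label <- function(a, b) paste(a, b, sep = "_vs_")

clamp <- function(x, lo = 0.001, hi = 0.999) pmin(pmax(x, lo), hi)

site_key <- function(chrom, pos, strand) paste(chrom, pos, strand, sep = ":")

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

# long (site x sample) tibble -> sites-by-samples matrix of `value`
meth_wide <- function(tbl, value, fill = NA_real_) {
  assert_cols(tbl, c("site", "sample_id", value), "methylation table")
  sites <- unique(tbl$site)
  samples <- unique(tbl$sample_id)
  m <- matrix(fill, nrow = length(sites), ncol = length(samples),
              dimnames = list(sites, samples))
  m[cbind(match(tbl$site, sites), match(tbl$sample_id, samples))] <- tbl[[value]]
  m
}

# deterministic child seed for stage `k` under master seed `seed`; stays < 2^31
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k)
}
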