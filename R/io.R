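#' Read a Bismark-style coverage file
#'
#' Parses the six-column per-cytosine coverage format written by
#' `bismark_methylation_extractor --bedGraph` (chrom, start, end, methylation
#' percentage, count methylated, count unmethylated). The percentage column is
#' ignored and the methylation level recomputed from the two counts, which are
#' the authoritative record.
#'
#' Bismark emits two closely related dialects that differ by one base: the
#' `.cov` file is 1-based with `start == end` per CpG, while the bedGraph is
#' 0-based half-open. By default positions are taken from the start column
#' read as 1-based; set `zero_based = TRUE` for bedGraph input, in which case
#' 1 is added to the start coordinate.
#'
#' @param path Path to a coverage file (plain text, tab or space separated).
#' @param zero_based Logical; treat the start column as 0-based (bedGraph
#'   dialect). Default `FALSE` (Bismark `.cov` dialect).
#' @param strand Strand to record for all sites in the file; coverage files do
#'   not carry strand, so this defaults to `"*"` (unknown).
#' @return A tibble with columns `chrom`, `pos` (1-based), `strand`,
#'   `count_meth`, `count_unmeth`, `coverage` and `level`
#'   (`count_meth / coverage`). One row per input line; an empty file yields a
#'   zero-row tibble.
#' @export
read_coverage <- function(path, zero_based = FALSE, strand = "*") {
  if (!file.exists(path)) abort(sprintf("coverage file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), pos = integer(), strand = character(),
                  count_meth = integer(), count_unmeth = integer(),
                  coverage = integer(), level = double()))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 6)) {
    bad <- which(nf != 6)[1]
    abort(sprintf("malformed coverage line %d in %s: expected 6 fields, found %d",
                  bad, path, nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 6, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  cm <- suppressWarnings(as.integer(m[, 5]))
  cu <- suppressWarnings(as.integer(m[, 6]))
  bad <- which(is.na(start) | is.na(cm) | is.na(cu))
  if (length(bad) > 0) {
    abort(sprintf("malformed coverage line %d in %s: non-numeric coordinate or count",
                  bad[1], path))
  }
  if (any(cm < 0 | cu < 0)) {
    abort(sprintf("negative read count at coverage line %d in %s",
                  which(cm < 0 | cu < 0)[1], path))
  }
  pos <- if (zero_based) start + 1L else start
  if (any(pos < 1)) {
    abort(sprintf("non-positive position at coverage line %d in %s",
                  which(pos < 1)[1], path))
  }
  cov <- cm + cu
  if (any(cov < 1)) {
    abort(sprintf("zero-coverage record at coverage line %d in %s",
                  which(cov < 1)[1], path))
  }
  tibble(chrom = m[, 1], pos = pos, strand = strand,
         count_meth = cm, count_unmeth = cu,
         coverage = cov, level = cm / cov)
}

#' Write a coverage table back to the Bismark dialect
#'
#' Inverse of [read_coverage()]: counts and positions round-trip exactly; the
#' percentage column is recomputed from the counts.
#'
#' @param tbl Tibble with columns `chrom`, `pos`, `count_meth`, `count_unmeth`.
#' @param path Output path.
#' @param zero_based Write bedGraph-style 0-based start coordinates.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(tbl, path, zero_based = FALSE) {
  assert_cols(tbl, c("chrom", "pos", "count_meth", "count_unmeth"))
  start <- if (zero_based) tbl$pos - 1L else tbl$pos
  out <- data.frame(tbl$chrom, start, tbl$pos,
                    100 * tbl$count_meth / (tbl$count_meth + tbl$count_unmeth),
                    tbl$count_meth, tbl$count_unmeth)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models or repeat intervals from a GFF3 file
#'
#' For `kind = "genes"`, assembles one merged gene model per `gene` feature:
#' exons are collected over all `mRNA` children via their `Parent` attributes
#' and overlapping exon projections are unioned, so a gene's exon list is the
#' flattened transcript union. `transcript_count` is the number of mRNA
#' children. Exons whose parent cannot be resolved are skipped with a warning.
#' For `kind = "repeats"`, every feature row is returned as a flat interval.
#'
#' @param path Path to a GFF3 file.
#' @param kind `"genes"` or `"repeats"`.
#' @return For genes, an object of class `gene_models`: a list with tibbles
#'   `genes` (`gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `transcript_count`, `n_exons`; start/end span the merged exons) and
#'   `exons` (`gene_id`, `chrom`, `strand`, `start`, `end`, `exon_rank` with
#'   rank 1 the 5'-most exon on the gene's strand). For repeats, a tibble
#'   `chrom`, `start`, `end`.
#' @export
read_gff <- function(path, kind = c("genes", "repeats")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("GFF file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  if (kind == "repeats") {
    return(tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr),
                  end = GenomicRanges::end(gr)))
  }
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p) {
    if (length(p) == 0) NA_character_ else p[[1]]
  }, character(1))

  gene_idx <- which(type == "gene")
  mrna_idx <- which(type %in% c("mRNA", "transcript"))
  exon_idx <- which(type == "exon")
  mrna_gene <- setNames(parents[mrna_idx], ids[mrna_idx])

  # map each exon to its gene (exon Parent may be an mRNA or the gene itself)
  exon_parent <- parents[exon_idx]
  exon_gene <- ifelse(exon_parent %in% ids[gene_idx], exon_parent,
                      unname(mrna_gene[exon_parent]))
  unresolved <- is.na(exon_gene)
  if (any(unresolved)) {
    warn(sprintf("skipping %d exon feature(s) without a resolvable gene parent",
                 sum(unresolved)))
    exon_idx <- exon_idx[!unresolved]
    exon_gene <- exon_gene[!unresolved]
  }

  gene_strand <- setNames(as.character(GenomicRanges::strand(gr))[gene_idx],
                          ids[gene_idx])
  gene_chrom <- setNames(as.character(GenomicRanges::seqnames(gr))[gene_idx],
                         ids[gene_idx])

  exon_tbl <- tibble(
    gene_id = exon_gene,
    chrom = as.character(GenomicRanges::seqnames(gr))[exon_idx],
    start = GenomicRanges::start(gr)[exon_idx],
    end = GenomicRanges::end(gr)[exon_idx]
  )
  # union overlapping exon projections within each gene
  exon_tbl <- exon_tbl %>%
    group_by(.data$gene_id, .data$chrom) %>%
    dplyr::reframe({
      r <- IRanges::reduce(IRanges::IRanges(.data$start, .data$end))
      tibble(start = IRanges::start(r), end = IRanges::end(r))
    }) %>%
    ungroup()
  exon_tbl$strand <- unname(gene_strand[exon_tbl$gene_id])
  exon_tbl <- exon_tbl %>%
    arrange(.data$gene_id, .data$start) %>%
    group_by(.data$gene_id) %>%
    mutate(exon_rank = if (first(.data$strand) == "-") rev(row_number())
           else row_number()) %>%
    ungroup()

  tc <- table(factor(unname(mrna_gene), levels = ids[gene_idx]))
  genes <- exon_tbl %>%
    group_by(.data$gene_id) %>%
    summarise(chrom = first(.data$chrom), strand = first(.data$strand),
              start = min(.data$start), end = max(.data$end),
              n_exons = n(), .groups = "drop") %>%
    mutate(transcript_count = pmax(1L, as.integer(tc[.data$gene_id])))
  gene_models(genes, exon_tbl)
}

#' Construct a gene-models object from tidy tibbles
#'
#' @param genes Tibble with `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `transcript_count`.
#' @param exons Tibble with `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `exon_rank` (1 = 5'-most on the gene strand); intervals must be
#'   non-overlapping within a gene.
#' @return A `gene_models` object (list of the two tibbles).
#' @export
gene_models <- function(genes, exons) {
  assert_cols(genes, c("gene_id", "chrom", "strand", "start", "end"))
  assert_cols(exons, c("gene_id", "chrom", "start", "end"))
  structure(list(genes = as_tibble(genes), exons = as_tibble(exons)),
            class = "gene_models")
}

#' @exportS3Method base::print
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes, %d merged exons\n",
              nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

#' Read a sample sheet
#'
#' The sheet is a TSV with header columns `sample_id`, `phenotype`, `colony`,
#' `coverage_path`, `spikein_meth`, `spikein_unmeth`. Phenotypes must be one
#' of FW (female worker), VQ (virgin queen), MQ (mature queen), MK (mature
#' king).
#'
#' @param path Path to the TSV.
#' @return Tibble with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) abort(sprintf("sample sheet not found: %s", path))
  df <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE))
  assert_cols(df, c("sample_id", "phenotype", "colony",
                    "spikein_meth", "spikein_unmeth"), "sample sheet")
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    abort(sprintf("duplicate sample_id in sample sheet: %s",
                  df$sample_id[duplicated(df$sample_id)][1]))
  }
  bad <- setdiff(unique(df$phenotype), PHENOTYPES)
  if (length(bad) > 0) {
    abort(sprintf("unknown phenotype label(s): %s (allowed: %s)",
                  paste(bad, collapse = ", "),
                  paste(PHENOTYPES, collapse = ", ")))
  }
  if (any(df$spikein_meth < 0 | df$spikein_unmeth < 0)) {
    abort("spike-in counts must be non-negative")
  }
  if (any(df$spikein_meth + df$spikein_unmeth == 0)) {
    abort(sprintf("sample %s has zero spike-in reads; non-conversion undefined",
                  df$sample_id[df$spikein_meth + df$spikein_unmeth == 0][1]))
  }
  df
}

#' Read a per-gene expression table
#'
#' A TSV with columns `gene_id`, `sample_id` (or `phenotype`), `expression`,
#' `isoform_count`, `as_flag`, plus one differential-expression label column
#' `de_<A>_vs_<B>` per phenotype pair with values `up_in_<A>`, `up_in_<B>` or
#' `ns`.
#'
#' @param path Path to the TSV.
#' @return Tibble, validated: `expression >= 0`, all six pair label columns
#'   present, labels restricted to the allowed set.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(sprintf("expression table not found: %s", path))
  df <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE))
  assert_cols(df, c("gene_id", "expression", "isoform_count", "as_flag"),
              "expression table")
  validate_expression(df)
}

validate_expression <- function(df) {
  if (any(df$expression < 0)) abort("expression must be non-negative")
  if (any(df$isoform_count < 1)) abort("isoform_count must be >= 1")
  if (!all(df$as_flag %in% c("AS", "non-AS"))) {
    abort("as_flag must be 'AS' or 'non-AS'")
  }
  for (p in phenotype_pairs()) {
    col <- paste0("de_", pair_label(p[1], p[2]))
    if (!col %in% names(df)) {
      abort(sprintf("expression table is missing DE label column %s", col))
    }
    ok <- df[[col]] %in% c(paste0("up_in_", p[1]), paste0("up_in_", p[2]), "ns")
    if (!all(ok)) {
      abort(sprintf("invalid DE label '%s' in column %s",
                    df[[col]][!ok][1], col))
    }
  }
  df
}

#' Write a tibble as a TSV with header
#'
#' Plain-text writer used for all pipeline outputs.
#'
#' @param tbl A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_output <- function(tbl, path) {
  write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
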