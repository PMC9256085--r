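#' Build an interval index of genomic feature classes
#'
#' Derives, per gene, the merged exon set, introns (inter-exon gaps), and
#' 10 kb 5'- and 3'-flanks attached to the gene span (first to last exon)
#' with orientation taken from the gene's strand; repeats are indexed as
#' given. Exon and intron element ranks are counted 5' to 3' on the gene's
#' strand (rank 1 = 5'-most). Flanks are truncated at position 1 (and at
#' scaffold ends when `scaffolds` is supplied).
#'
#' @param genes A [gene_models()] object.
#' @param repeats Optional tibble of repeat intervals (`chrom`, `start`,
#'   `end`).
#' @param flank_size Flank length in bp (default 10000).
#' @param scaffolds Optional tibble (`chrom`, `length`) for edge truncation.
#' @return Object of class `feature_index` holding `GRanges` per feature
#'   class.
#' @export
build_feature_index <- function(genes, repeats = NULL, flank_size = 10000,
                                scaffolds = NULL) {
  stopifnot(inherits(genes, "gene_models"))
  ex <- genes$exons
  exon_gr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end),
                                    gene_id = ex$gene_id,
                                    element_rank = as.integer(ex$exon_rank))

  introns <- ex %>%
    arrange(.data$gene_id, .data$start) %>%
    group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    dplyr::reframe({
      s <- .data$start
      e <- .data$end
      k <- length(s)
      if (k < 2) tibble(start = integer(0), end = integer(0), idx = integer(0))
      else tibble(start = e[-k] + 1L, end = s[-1] - 1L, idx = seq_len(k - 1L))
    }) %>%
    filter(.data$end >= .data$start) %>%
    group_by(.data$gene_id) %>%
    mutate(element_rank = if (n() == 0) integer(0) else
      if_else(.data$strand == "-",
              as.integer(max(.data$idx) - .data$idx + 1L),
              as.integer(.data$idx))) %>%
    ungroup()
  intron_gr <- GenomicRanges::GRanges(
    introns$chrom, IRanges::IRanges(introns$start, introns$end),
    gene_id = introns$gene_id, element_rank = introns$element_rank)

  g <- genes$genes
  cap <- if (!is.null(scaffolds)) {
    setNames(scaffolds$length, scaffolds$chrom)[g$chrom]
  } else rep(Inf, nrow(g))
  up <- tibble(chrom = g$chrom,
               start = pmax(1L, g$start - as.integer(flank_size)),
               end = g$start - 1L, gene_id = g$gene_id, boundary = g$start,
               class = if_else(g$strand == "+", "flank5", "flank3"))
  dn <- tibble(chrom = g$chrom, start = g$end + 1L,
               end = as.integer(pmin(g$end + flank_size, cap)),
               gene_id = g$gene_id, boundary = g$end,
               class = if_else(g$strand == "+", "flank3", "flank5"))
  fl <- bind_rows(up, dn) %>% filter(.data$end >= .data$start)
  flank_gr <- function(cls) {
    f <- fl %>% filter(.data$class == cls)
    GenomicRanges::GRanges(f$chrom, IRanges::IRanges(f$start, f$end),
                           gene_id = f$gene_id, boundary = f$boundary)
  }

  repeat_gr <- if (!is.null(repeats) && nrow(repeats) > 0) {
    GenomicRanges::GRanges(repeats$chrom,
                           IRanges::IRanges(repeats$start, repeats$end))
  } else GenomicRanges::GRanges()

  structure(list(exon = exon_gr, intron = intron_gr,
                 flank5 = flank_gr("flank5"), flank3 = flank_gr("flank3"),
                 "repeat" = repeat_gr,
                 genes = g, flank_size = flank_size),
            class = "feature_index")
}

#' @exportS3Method base::print
print.feature_index <- function(x, ...) {
  cat(sprintf("<feature_index> %d genes | exons %d, introns %d, flanks %d+%d, repeats %d\n",
              nrow(x$genes), length(x$exon), length(x$intron),
              length(x$flank5), length(x$flank3), length(x$`repeat`)))
  invisible(x)
}

# overlap hits of point sites against one feature GRanges, as a tibble
feature_hits <- function(pos_gr, fgr, cols = character()) {
  h <- GenomicRanges::findOverlaps(pos_gr, fgr)
  out <- tibble(site_idx = S4Vectors::queryHits(h))
  for (cl in cols) {
    out[[cl]] <- S4Vectors::mcols(fgr)[[cl]][S4Vectors::subjectHits(h)]
  }
  out
}

#' Classify sites into exactly one genomic region class
#'
#' Applies the precedence exon > intron > flank > repeat > intergenic with an
#' ambiguity rule: a site is `ambiguous` when two different genes imply
#' conflicting genic classes (exon of one, intron of another) or when 5'- and
#' 3'-flanks of different genes both apply; ambiguous sites are excluded from
#' region-level analyses downstream. A repeat overlapping a genic or flank
#' class yields that class; sites touching nothing are intergenic. Flank
#' sites get `flank_bin = ceiling(distance_from_gene_boundary / 1000)` (1 kb
#' bins counted outward); exon/intron sites get the element's 5'-to-3' rank.
#' Where a site falls in the same class of several genes the nearest /
#' lexicographically first gene is reported.
#'
#' @param x Tibble with `chrom`, `pos`, `strand` columns, e.g. a
#'   `meth_matrix`.
#' @param index A [build_feature_index()].
#' @param drop_ambiguous Remove ambiguous sites from the result (default
#'   FALSE; they carry `region_class == "ambiguous"`).
#' @return `x` plus `region_class`, `gene_id`, `element_rank`, `flank_bin`.
#' @export
annotate_sites <- function(x, index, drop_ambiguous = FALSE) {
  stopifnot(inherits(index, "feature_index"))
  assert_cols(x, c("chrom", "pos", "strand"))
  if (!"site" %in% names(x)) {
    x <- x %>% mutate(site = site_key(.data$chrom, .data$pos, .data$strand))
  }
  sites <- x %>% distinct(.data$site, .data$chrom, .data$pos)
  known <- unique(c(as.character(GenomicRanges::seqnames(index$exon)),
                    index$genes$chrom,
                    as.character(GenomicRanges::seqnames(index$`repeat`))))
  unknown <- setdiff(unique(sites$chrom), known)
  if (length(unknown) > 0) {
    warn(sprintf("%d site(s) on scaffold(s) absent from the annotation (%s); classed intergenic",
                 sum(sites$chrom %in% unknown),
                 paste(head(unknown, 3), collapse = ", ")))
  }
  pos_gr <- GenomicRanges::GRanges(sites$chrom,
                                   IRanges::IRanges(sites$pos, width = 1))

  genic <- bind_rows(
    feature_hits(pos_gr, index$exon, c("gene_id", "element_rank")) %>%
      mutate(class = "exon"),
    feature_hits(pos_gr, index$intron, c("gene_id", "element_rank")) %>%
      mutate(class = "intron"))
  empty_res <- tibble(site_idx = integer(), ambiguous = logical(),
                      class = character(), gene_id = character(),
                      element_rank = integer(), flank_bin = integer())
  genic_res <- if (nrow(genic) == 0) empty_res else genic %>%
    arrange(.data$site_idx, .data$gene_id) %>%
    group_by(.data$site_idx) %>%
    summarise(ambiguous = n_distinct(.data$class) > 1,
              class = first(.data$class),
              gene_id = first(.data$gene_id),
              element_rank = first(.data$element_rank),
              .groups = "drop")

  flank <- bind_rows(
    feature_hits(pos_gr, index$flank5, c("gene_id", "boundary")) %>%
      mutate(class = "flank5"),
    feature_hits(pos_gr, index$flank3, c("gene_id", "boundary")) %>%
      mutate(class = "flank3")) %>%
    mutate(dist = abs(sites$pos[.data$site_idx] - .data$boundary))
  flank_res <- if (nrow(flank) == 0) empty_res else flank %>%
    group_by(.data$site_idx) %>%
    summarise(ambiguous = n_distinct(.data$class) > 1,
              class = .data$class[which.min(.data$dist)],
              gene_id = .data$gene_id[which.min(.data$dist)],
              flank_bin = as.integer(ceiling(min(.data$dist) / 1000)),
              .groups = "drop") %>%
    mutate(flank_bin = pmax(1L, .data$flank_bin))

  rep_idx <- unique(feature_hits(pos_gr, index$`repeat`)$site_idx)

  ann <- tibble(site_idx = seq_len(nrow(sites)),
                region_class = "intergenic",
                gene_id = NA_character_, element_rank = NA_integer_,
                flank_bin = NA_integer_)
  ann$region_class[rep_idx] <- "repeat"
  if (nrow(flank_res) > 0) {
    i <- flank_res$site_idx
    ann$region_class[i] <- if_else(flank_res$ambiguous, "ambiguous",
                                   flank_res$class)
    ann$gene_id[i] <- if_else(flank_res$ambiguous, NA_character_,
                              flank_res$gene_id)
    ann$flank_bin[i] <- if_else(flank_res$ambiguous, NA_integer_,
                                flank_res$flank_bin)
  }
  if (nrow(genic_res) > 0) {
    i <- genic_res$site_idx
    ann$region_class[i] <- if_else(genic_res$ambiguous, "ambiguous",
                                   genic_res$class)
    ann$gene_id[i] <- if_else(genic_res$ambiguous, NA_character_,
                              genic_res$gene_id)
    ann$element_rank[i] <- if_else(genic_res$ambiguous, NA_integer_,
                                   as.integer(genic_res$element_rank))
    ann$flank_bin[i] <- NA_integer_
  }

  site_ann <- sites %>%
    mutate(region_class = ann$region_class, gene_id = ann$gene_id,
           element_rank = ann$element_rank, flank_bin = ann$flank_bin) %>%
    select(-"chrom", -"pos")
  out <- x %>%
    select(-any_of(c("region_class", "gene_id", "element_rank", "flank_bin"))) %>%
    left_join(site_ann, by = "site")
  if (drop_ambiguous) out <- out %>% filter(.data$region_class != "ambiguous")
  # keep meth_matrix attributes through the join
  for (a in c("per_sample_sequenced", "n_sites", "n_samples")) {
    if (!is.null(attr(x, a))) attr(out, a) <- attr(x, a)
  }
  if (inherits(x, "meth_matrix") && !inherits(out, "meth_matrix")) {
    class(out) <- c("meth_matrix", class(out))
  }
  out
}
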