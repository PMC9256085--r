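# shared fixture builders; everything is generated in code at test time

# small complete synthetic study, cached per (seed, extra args) within a session
studies_cache <- new.env(parent = emptyenv())
small_study <- function(seed = 11, ...) {
  key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (!is.null(studies_cache[[key]])) return(studies_cache[[key]])
  args <- utils::modifyList(list(seed = seed, n_genes = 60,
                                 n_cpg_total = 6000), list(...))
  st <- simulate_study(do.call(sim_config, args))
  studies_cache[[key]] <- st
  st
}

# called + annotated matrix for a study
annotated_matrix <- function(st) {
  m <- call_study(st$methylomes$coverage, st$methylomes$samples)
  idx <- build_feature_index(st$annotation$genes, st$annotation$repeats,
                             scaffolds = st$annotation$scaffolds)
  annotate_sites(m, idx)
}

# hand-built two-gene toy annotation:
#  gA: + strand, exons 1100-1200 and 1401-1500 (intron 1201-1400)
#  gB: - strand, exons 10000-10200 and 10500-20000 (span 10000-20000)
toy_genes <- function(flank = 1000) {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "s1", strand = c("+", "-"),
    start = c(1100L, 10000L), end = c(1500L, 20000L),
    transcript_count = c(1L, 2L))
  exons <- tibble::tibble(
    gene_id = c("gA", "gA", "gB", "gB"), chrom = "s1",
    strand = c("+", "+", "-", "-"),
    start = c(1100L, 1401L, 10000L, 10500L),
    end = c(1200L, 1500L, 10200L, 20000L),
    exon_rank = c(1L, 2L, 2L, 1L))
  gene_models(genes, exons)
}

# brute-force site classifier over explicit interval tables; independent of
# the GenomicRanges-backed implementation
brute_classify <- function(pos, chrom, gm, repeats, flank_size) {
  hits_g <- list()
  for (i in seq_len(nrow(gm$exons))) {
    e <- gm$exons[i, ]
    if (e$chrom == chrom && pos >= e$start && pos <= e$end) {
      hits_g[[length(hits_g) + 1]] <- list(class = "exon", gene = e$gene_id)
    }
  }
  by_gene <- split(gm$exons, gm$exons$gene_id)
  for (gid in names(by_gene)) {
    ex <- by_gene[[gid]][order(by_gene[[gid]]$start), ]
    if (nrow(ex) > 1 && ex$chrom[1] == chrom) {
      for (k in seq_len(nrow(ex) - 1)) {
        if (pos > ex$end[k] && pos < ex$start[k + 1]) {
          hits_g[[length(hits_g) + 1]] <- list(class = "intron", gene = gid)
        }
      }
    }
  }
  if (length(hits_g) > 0) {
    cls <- unique(vapply(hits_g, `[[`, "", "class"))
    if (length(cls) > 1) return("ambiguous")
    return(cls)
  }
  hits_f <- character()
  for (i in seq_len(nrow(gm$genes))) {
    g <- gm$genes[i, ]
    if (g$chrom != chrom) next
    up <- pos >= g$start - flank_size && pos <= g$start - 1
    dn <- pos >= g$end + 1 && pos <= g$end + flank_size
    if (up) hits_f <- c(hits_f, if (g$strand == "+") "flank5" else "flank3")
    if (dn) hits_f <- c(hits_f, if (g$strand == "+") "flank3" else "flank5")
  }
  if (length(hits_f) > 0) {
    if (length(unique(hits_f)) > 1) return("ambiguous")
    return(hits_f[1])
  }
  if (!is.null(repeats) && nrow(repeats) > 0) {
    for (i in seq_len(nrow(repeats))) {
      r <- repeats[i, ]
      if (r$chrom == chrom && pos >= r$start && pos <= r$end) return("repeat")
    }
  }
  "intergenic"
}

# brute-force Benjamini-Hochberg step-up, straight from the definition
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  cummin_rev <- Inf
  for (i in n:1) {
    cummin_rev <- min(cummin_rev, p[o[i]] * n / i)
    adj[o[i]] <- min(1, cummin_rev)
  }
  adj
}

sites_tbl <- function(pos, chrom = "s1", strand = "+") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), strand = strand)
}

# expression table realising given DE label counts for one pair, all other
# pairs non-significant
labelled_expression <- function(n_up_mq = 6, n_dn_mq = 14, n_ns = 24,
                                n_extra_ns = 0, pair = c("VQ", "MQ")) {
  n <- n_up_mq + n_dn_mq + n_ns + n_extra_ns
  lab <- rep(c(paste0("up_in_", pair[2]), paste0("up_in_", pair[1]), "ns"),
             c(n_up_mq, n_dn_mq, n_ns + n_extra_ns))
  tbl <- tibble::tibble(gene_id = sprintf("g%03d", seq_len(n)),
                        sample_id = "s1", phenotype = "FW",
                        expression = seq_len(n), isoform_count = 1L,
                        as_flag = "non-AS")
  for (p in list(c("FW", "VQ"), c("FW", "MQ"), c("FW", "MK"), c("VQ", "MQ"),
                 c("VQ", "MK"), c("MQ", "MK"))) {
    tbl[[paste0("de_", p[1], "_vs_", p[2])]] <- "ns"
  }
  tbl[[paste0("de_", pair[1], "_vs_", pair[2])]] <- lab
  tbl
}
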