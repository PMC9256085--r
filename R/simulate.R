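#' Configuration for the synthetic RRBS study generator
#'
#' Bundles and validates every tunable of the in-silico study: genome layout,
#' CpG placement, read-count model, bisulfite non-conversion, region-class
#' baseline methylation, the 3'-rising gene-body gradient, colony- and
#' phenotype-level random effects, planted differentially methylated sites
#' (DMS) and the planted expression structure. Defaults emulate a 4-phenotype
#' (FW, VQ, MQ, MK) by 3-colony fat-body RRBS design: region baselines fall
#' off as exon 0.10 >> intron 0.04 > flank 0.025 > repeat 0.022 > intergenic
#' 0.017, methylation rises along the gene body, colony variation (logit-scale
#' sd 0.5) dominates phenotype variation (sd 0.1), and the non-conversion
#' error floor is 1% per sample (all real samples passed a 2% QC bar).
#'
#' @param seed Integer master seed; fully determines all generator output.
#' @param n_scaffolds,n_genes Genome layout size.
#' @param exons_per_gene,exon_len,intron_len Integer ranges `c(min, max)`.
#' @param flank_size Flank length in bp attached up- and downstream of each
#'   gene span (default 10000).
#' @param n_cpg_total Total CpG sites to scatter over the genome.
#' @param cpg_class_weights Named target fractions of CpGs per region class;
#'   every class must receive at least 1%. RRBS-like enrichment near genes is
#'   expressed by the default genic skew.
#' @param coverage_mean,coverage_dispersion Negative-binomial read-coverage
#'   mean and size parameter per site and sample.
#' @param nonconversion_rate Per-sample bisulfite non-conversion error in
#'   `[0, 0.05]`; scalar or one value per sample.
#' @param spikein_total Unmethylated spike-in reads sequenced per sample.
#' @param baseline Named per-region-class baseline methylation probabilities
#'   (`exon`, `intron`, `repeat`, `flank`, `intergenic`).
#' @param gradient_slope Additive increase in exon/intron baseline per
#'   element rank (3' gradient), probability scale per rank.
#' @param colony_sd,phenotype_sd Standard deviations of site-specific
#'   logit-scale random effects shared by all samples of a colony /
#'   phenotype.
#' @param colony_mean_sd,phenotype_mean_sd Standard deviations of global
#'   (genome-wide) logit-scale offsets, one draw per colony / phenotype;
#'   model the overall per-colony methylation differences seen in real
#'   replicated designs, on top of the site-specific effects.
#' @param n_planted_dms Planted DMS per phenotype pair (default 0: null
#'   design).
#' @param dms_effect Percentage-point methylation shift of a planted DMS
#'   (probability scale, default 0.40).
#' @param beta_dispersion Beta-binomial overdispersion `rho` in `[0, 1)`;
#'   0 gives pure binomial counts.
#' @param n_colonies Colonies per phenotype (default 3).
#' @param n_repeats,repeat_len Repeat-interval count and length range.
#' @param de_fraction_up,de_fraction_down Per-pair fractions of genes up in
#'   the first / second phenotype of the pair (defaults 0.106 / 0.158, the
#'   genome-wide DEG proportions of the emulated study).
#' @param as_fraction Fraction of multi-transcript genes flagged as
#'   alternatively spliced.
#' @param expression_meanlog,expression_sdlog,expression_noise_sd,de_fold
#'   Log-normal expression model: per-gene base level, per-sample
#'   multiplicative noise, and the fold change applied to planted DEGs.
#' @param coupling Logical; couple methylation to the planted DE labels.
#' @param coupling_exon_shift,coupling_flank3_shift Baseline shifts applied
#'   to coupled genes' exon and 3'-flank sites when `coupling = TRUE`.
#' @param coupling_target `"any_de"` (all genes DE in at least one pair) or
#'   `"up_MQ_VQ"` (genes over-expressed in MQ relative to VQ).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 4L,
                       n_genes = 120L,
                       exons_per_gene = c(3L, 8L),
                       exon_len = c(120L, 400L),
                       intron_len = c(200L, 1200L),
                       flank_size = 10000L,
                       n_cpg_total = 20000L,
                       cpg_class_weights = c(exon = 0.30, intron = 0.20,
                                             flank5 = 0.15, flank3 = 0.15,
                                             "repeat" = 0.10, intergenic = 0.10),
                       coverage_mean = 12,
                       coverage_dispersion = 5,
                       nonconversion_rate = 0.01,
                       spikein_total = 100000L,
                       baseline = c(exon = 0.10, intron = 0.04,
                                    "repeat" = 0.022, flank = 0.025,
                                    intergenic = 0.017),
                       gradient_slope = 0.015,
                       colony_sd = 0.5,
                       phenotype_sd = 0.1,
                       colony_mean_sd = 0.15,
                       phenotype_mean_sd = 0.05,
                       n_planted_dms = 0L,
                       dms_effect = 0.40,
                       beta_dispersion = 0.02,
                       n_colonies = 3L,
                       n_repeats = 150L,
                       repeat_len = c(500L, 3000L),
                       de_fraction_up = 0.106,
                       de_fraction_down = 0.158,
                       as_fraction = 0.15,
                       expression_meanlog = 3,
                       expression_sdlog = 1.2,
                       expression_noise_sd = 0.2,
                       de_fold = 2,
                       coupling = FALSE,
                       coupling_exon_shift = -0.05,
                       coupling_flank3_shift = 0.01,
                       coupling_target = c("any_de", "up_MQ_VQ")) {
  coupling_target <- match.arg(coupling_target)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  n_samples <- 4L * cfg$n_colonies
  if (length(cfg$nonconversion_rate) == 1) {
    cfg$nonconversion_rate <- rep(cfg$nonconversion_rate, n_samples)
  }
  if (length(cfg$nonconversion_rate) != n_samples) {
    abort("nonconversion_rate must be scalar or one value per sample")
  }
  if (any(cfg$nonconversion_rate < 0 | cfg$nonconversion_rate > 0.05)) {
    abort("nonconversion_rate must lie in [0, 0.05]")
  }
  if (any(cfg$baseline < 0 | cfg$baseline > 1)) {
    abort("baseline methylation probabilities must lie in [0, 1]")
  }
  need <- c("exon", "intron", "repeat", "flank", "intergenic")
  if (!all(need %in% names(cfg$baseline))) {
    abort(sprintf("baseline must name classes: %s", paste(need, collapse = ", ")))
  }
  if (abs(sum(cfg$cpg_class_weights) - 1) > 1e-8) {
    abort("cpg_class_weights must sum to 1")
  }
  if (any(cfg$cpg_class_weights < 0.01)) {
    abort("every region class must receive at least 1% of CpGs")
  }
  if (cfg$beta_dispersion < 0 || cfg$beta_dispersion >= 1) {
    abort("beta_dispersion must lie in [0, 1)")
  }
  if (cfg$dms_effect < 0 || cfg$dms_effect > 1) abort("dms_effect in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' The 4-phenotype by n-colony sample design of a configuration
#'
#' @param config A [sim_config()].
#' @return Tibble `sample_id`, `phenotype`, `colony`, 4 x `n_colonies` rows.
#' @export
study_design <- function(config) {
  colonies <- paste0("c", seq_len(config$n_colonies))
  tidyr::expand_grid(phenotype = PHENOTYPES, colony = colonies) %>%
    mutate(sample_id = paste(.data$phenotype, .data$colony, sep = "_"),
           .before = 1)
}

# draw integers uniformly from an inclusive range given as c(min, max)
draw_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Simulate a genome annotation and CpG site map
#'
#' Lays out non-overlapping genes (with merged exon models and derivable
#' introns) along scaffolds, separated by 10 kb flanks, repeat intervals and
#' intergenic padding, then scatters CpG sites over the region classes with
#' the configured class weights (an RRBS-like genic enrichment by default).
#' Every site is born with a known region class, gene assignment, element
#' rank, flank bin and true baseline methylation (region baseline plus the
#' rank-wise 3' gradient within gene bodies).
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_annotation`: list with `genes` (a
#'   [gene_models()] object), `repeats`, `sites` (the per-CpG truth),
#'   `scaffolds` and the `config`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 1L))
  n_genes <- config$n_genes
  scaf_of_gene <- sort(rep_len(seq_len(config$n_scaffolds), n_genes))

  genes <- vector("list", n_genes)
  exons <- vector("list", n_genes)
  repeats <- list()
  intergenic <- list()
  cursor <- setNames(rep(1L, config$n_scaffolds),
                     paste0("scaf", seq_len(config$n_scaffolds)))
  rep_budget <- config$n_repeats
  rep_per_slot <- ceiling(config$n_repeats / n_genes)

  for (i in seq_len(n_genes)) {
    scaf <- paste0("scaf", scaf_of_gene[i])
    gid <- sprintf("g%04d", i)
    pos <- cursor[scaf]

    # intergenic pad, optional repeats, second pad -- all outside flanks
    pad1 <- draw_range(1, c(2000L, 5000L))
    intergenic[[length(intergenic) + 1]] <-
      tibble(chrom = scaf, start = pos, end = pos + pad1 - 1L)
    pos <- pos + pad1
    k_rep <- min(rep_per_slot, rep_budget)
    if (k_rep > 0) {
      for (r in seq_len(k_rep)) {
        rl <- draw_range(1, config$repeat_len)
        repeats[[length(repeats) + 1]] <-
          tibble(chrom = scaf, start = pos, end = pos + rl - 1L)
        pos <- pos + rl + 200L
      }
      rep_budget <- rep_budget - k_rep
    }
    pad2 <- draw_range(1, c(2000L, 5000L))
    intergenic[[length(intergenic) + 1]] <-
      tibble(chrom = scaf, start = pos, end = pos + pad2 - 1L)
    pos <- pos + pad2

    # upstream flank, then the gene body
    pos <- pos + config$flank_size
    strand <- sample(c("+", "-"), 1)
    n_ex <- draw_range(1, config$exons_per_gene)
    ex_len <- draw_range(n_ex, config$exon_len)
    in_len <- if (n_ex > 1) draw_range(n_ex - 1, config$intron_len) else integer(0)
    starts <- integer(n_ex)
    ends <- integer(n_ex)
    p <- pos
    for (e in seq_len(n_ex)) {
      starts[e] <- p
      ends[e] <- p + ex_len[e] - 1L
      p <- ends[e] + 1L + if (e < n_ex) in_len[e] else 0L
    }
    rank <- if (strand == "-") rev(seq_len(n_ex)) else seq_len(n_ex)
    exons[[i]] <- tibble(gene_id = gid, chrom = scaf, strand = strand,
                         start = starts, end = ends, exon_rank = rank)
    genes[[i]] <- tibble(gene_id = gid, chrom = scaf, strand = strand,
                         start = starts[1], end = ends[n_ex],
                         transcript_count = 1L + stats::rpois(1, 0.8),
                         n_exons = n_ex)
    cursor[scaf] <- ends[n_ex] + config$flank_size + 1L
  }
  # trailing intergenic pad per scaffold
  scaffolds <- tibble(chrom = names(cursor),
                      length = unname(cursor) + 5000L)
  for (s in seq_len(nrow(scaffolds))) {
    intergenic[[length(intergenic) + 1]] <-
      tibble(chrom = scaffolds$chrom[s], start = cursor[s] + 1L,
             end = scaffolds$length[s])
  }

  gene_tbl <- bind_rows(genes)
  exon_tbl <- bind_rows(exons)
  repeat_tbl <- bind_rows(repeats)
  intergenic_tbl <- bind_rows(intergenic)
  gm <- gene_models(gene_tbl, exon_tbl)

  sites <- place_cpg_sites(gm, repeat_tbl, intergenic_tbl, config)
  structure(list(genes = gm, repeats = repeat_tbl, sites = sites,
                 scaffolds = scaffolds, config = config),
            class = "sim_annotation")
}

# scatter CpGs into disjoint per-class interval sets; returns truth tibble
place_cpg_sites <- function(gm, repeat_tbl, intergenic_tbl, config) {
  exon_iv <- gm$exons %>%
    mutate(region_class = "exon", element_rank = .data$exon_rank) %>%
    select("chrom", "start", "end", "region_class",
           "gene_id", "element_rank")

  intron_iv <- gm$exons %>%
    arrange(.data$gene_id, .data$start) %>%
    group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    dplyr::reframe({
      s <- .data$start
      e <- .data$end
      k <- length(s)
      if (k < 2) tibble(start = integer(0), end = integer(0), idx = integer(0))
      else tibble(start = e[-k] + 1L, end = s[-1] - 1L, idx = seq_len(k - 1))
    }) %>%
    filter(.data$end >= .data$start) %>%
    mutate(element_rank = if_else(.data$strand == "-",
                                  as.integer(max(.data$idx) - .data$idx + 1L),
                                  as.integer(.data$idx)),
           .by = "gene_id") %>%
    mutate(region_class = "intron") %>%
    select("chrom", "start", "end", "region_class", "gene_id", "element_rank")

  fl <- gm$genes %>%
    mutate(up_start = .data$start - config$flank_size, up_end = .data$start - 1L,
           dn_start = .data$end + 1L, dn_end = .data$end + config$flank_size)
  flank_iv <- bind_rows(
    fl %>% mutate(region_class = if_else(.data$strand == "+", "flank5", "flank3"),
                  start = .data$up_start, end = .data$up_end),
    fl %>% mutate(region_class = if_else(.data$strand == "+", "flank3", "flank5"),
                  start = .data$dn_start, end = .data$dn_end)
  ) %>%
    mutate(element_rank = NA_integer_) %>%
    select("chrom", "start", "end", "region_class", "gene_id", "element_rank")

  other_iv <- bind_rows(
    repeat_tbl %>% mutate(region_class = "repeat"),
    intergenic_tbl %>% mutate(region_class = "intergenic")
  ) %>%
    mutate(gene_id = NA_character_, element_rank = NA_integer_) %>%
    select("chrom", "start", "end", "region_class", "gene_id", "element_rank")

  ivs <- bind_rows(exon_iv, intron_iv, flank_iv, other_iv) %>%
    mutate(width = .data$end - .data$start + 1L) %>%
    filter(.data$width > 0)

  picked <- ivs %>%
    group_by(.data$region_class) %>%
    dplyr::group_map(function(df, key) {
      cls <- key$region_class[[1]]
      target <- round(config$cpg_class_weights[[cls]] * config$n_cpg_total)
      # oversample, then unique positions
      idx <- sample.int(nrow(df), 3 * target, replace = TRUE,
                        prob = df$width)
      pos <- df$start[idx] +
        floor(runif(length(idx)) * df$width[idx])
      keep <- !duplicated(paste(df$chrom[idx], pos))
      keep_n <- min(target, sum(keep))
      sel <- which(keep)[seq_len(keep_n)]
      tibble(chrom = df$chrom[idx[sel]], pos = as.integer(pos[sel]),
             region_class = cls, gene_id = df$gene_id[idx[sel]],
             element_rank = df$element_rank[idx[sel]])
    }) %>%
    bind_rows()

  gene_span <- gm$genes %>% select("gene_id", g_start = "start",
                                   g_end = "end", g_strand = "strand")
  # flank gene/bin assignment: nearest gene boundary, 1 kb bins outward
  flank_sites <- picked %>%
    filter(.data$region_class %in% c("flank5", "flank3"))
  if (nrow(flank_sites) > 0) {
    fl_lookup <- bind_rows(
      fl %>% transmute(chrom = .data$chrom, start = .data$up_start,
                       end = .data$up_end, gene_id = .data$gene_id,
                       boundary = .data$start, side = "up",
                       g_strand = .data$strand),
      fl %>% transmute(chrom = .data$chrom, start = .data$dn_start,
                       end = .data$dn_end, gene_id = .data$gene_id,
                       boundary = .data$end, side = "dn",
                       g_strand = .data$strand)
    )
    site_gr <- GenomicRanges::GRanges(flank_sites$chrom,
                                      IRanges::IRanges(flank_sites$pos, width = 1))
    fl_gr <- GenomicRanges::GRanges(fl_lookup$chrom,
                                    IRanges::IRanges(fl_lookup$start, fl_lookup$end))
    ov <- GenomicRanges::findOverlaps(site_gr, fl_gr, select = "first")
    dist <- abs(flank_sites$pos - fl_lookup$boundary[ov])
    flank_sites$gene_id <- fl_lookup$gene_id[ov]
    flank_sites$flank_bin <- pmax(1L, as.integer(ceiling(dist / 1000)))
  } else {
    flank_sites$flank_bin <- integer(0)
  }
  sites <- bind_rows(
    picked %>% filter(!.data$region_class %in% c("flank5", "flank3")) %>%
      mutate(flank_bin = NA_integer_),
    flank_sites
  )

  base <- config$baseline
  cls_base <- c(exon = base[["exon"]], intron = base[["intron"]],
                flank5 = base[["flank"]], flank3 = base[["flank"]],
                "repeat" = base[["repeat"]], intergenic = base[["intergenic"]])
  sites %>%
    mutate(strand = sample(c("+", "-"), n(), replace = TRUE),
           baseline = unname(cls_base[.data$region_class]) +
             if_else(.data$region_class %in% c("exon", "intron"),
                     config$gradient_slope * (dplyr::coalesce(.data$element_rank, 1L) - 1L),
                     0),
           baseline = pmin(.data$baseline, 0.999),
           site = site_key(.data$chrom, .data$pos, .data$strand)) %>%
    arrange(.data$chrom, .data$pos) %>%
    select("site", "chrom", "pos", "strand", "region_class", "gene_id",
           "element_rank", "flank_bin", "baseline")
}

#' Simulate an expression table with planted DE/AS structure
#'
#' Per-gene log-normal expression with per-sample noise; differential
#' expression labels drawn independently per phenotype pair at the configured
#' up/down fractions, realised as fold changes on the affected phenotype's
#' samples; isoform counts taken from the annotation's transcript counts; AS
#' flags restricted to multi-transcript genes.
#'
#' @param annotation A [simulate_annotation()] result.
#' @param config The same [sim_config()].
#' @return Tibble, long by sample: `gene_id`, `sample_id`, `phenotype`,
#'   `expression`, plus gene-level `isoform_count`, `as_flag` and the six
#'   `de_<A>_vs_<B>` label columns.
#' @export
simulate_expression <- function(annotation, config = annotation$config) {
  set.seed(child_seed(config$seed, 2L))
  genes <- annotation$genes$genes
  design <- study_design(config)
  n_g <- nrow(genes)

  de <- purrr::list_cbind(purrr::map(phenotype_pairs(), function(p) {
    lab <- sample(c(paste0("up_in_", p[1]), paste0("up_in_", p[2]), "ns"),
                  n_g, replace = TRUE,
                  prob = c(config$de_fraction_up, config$de_fraction_down,
                           1 - config$de_fraction_up - config$de_fraction_down))
    tibble::as_tibble_col(lab, paste0("de_", pair_label(p[1], p[2])))
  }))

  gene_tbl <- tibble(
    gene_id = genes$gene_id,
    isoform_count = genes$transcript_count,
    as_flag = if_else(genes$transcript_count >= 2 &
                        runif(n_g) < config$as_fraction, "AS", "non-AS"),
    base_expr = rlnorm(n_g, config$expression_meanlog, config$expression_sdlog)
  ) %>% dplyr::bind_cols(de)

  # realise DE labels as phenotype-level fold changes
  fold <- matrix(1, nrow = n_g, ncol = 4, dimnames = list(NULL, PHENOTYPES))
  for (p in phenotype_pairs()) {
    lab <- gene_tbl[[paste0("de_", pair_label(p[1], p[2]))]]
    upA <- lab == paste0("up_in_", p[1])
    upB <- lab == paste0("up_in_", p[2])
    fold[upA, p[1]] <- fold[upA, p[1]] * sqrt(config$de_fold)
    fold[upA, p[2]] <- fold[upA, p[2]] / sqrt(config$de_fold)
    fold[upB, p[2]] <- fold[upB, p[2]] * sqrt(config$de_fold)
    fold[upB, p[1]] <- fold[upB, p[1]] / sqrt(config$de_fold)
  }

  out <- tidyr::expand_grid(gene_tbl, design) %>%
    mutate(expression = .data$base_expr *
             fold[cbind(rep(seq_len(n_g), each = nrow(design)),
                        match(.data$phenotype, PHENOTYPES))] *
             exp(rnorm(n(), 0, config$expression_noise_sd))) %>%
    select("gene_id", "sample_id", "phenotype", "expression",
           "isoform_count", "as_flag", dplyr::starts_with("de_"))
  out
}

# per-gene-region baseline shifts implied by the coupling settings
coupling_effects <- function(expression, config) {
  if (!isTRUE(config$coupling)) return(NULL)
  gene_lab <- expression %>% distinct(.data$gene_id,
                                      across(dplyr::starts_with("de_")))
  target <- switch(config$coupling_target,
    any_de = gene_lab %>%
      filter(dplyr::if_any(dplyr::starts_with("de_"), ~ .x != "ns")),
    up_MQ_VQ = gene_lab %>% filter(.data$de_VQ_vs_MQ == "up_in_MQ"))
  if (nrow(target) == 0) return(NULL)
  bind_rows(
    tibble(gene_id = target$gene_id, region_class = "exon",
           shift = config$coupling_exon_shift),
    tibble(gene_id = target$gene_id, region_class = "flank3",
           shift = config$coupling_flank3_shift)
  )
}

#' Simulate the 12 methylomes, spike-ins and planted-DMS truth
#'
#' For each sample and CpG, coverage is negative-binomial and the methylated
#' read count is beta-binomial with mean
#' `plogis(qlogis(baseline) + colony_effect + phenotype_effect)`, shifted by
#' the planted DMS effect where applicable, then pushed through the sample's
#' non-conversion floor: `p_obs = p + (1 - p) * nonconversion`. Colony and
#' phenotype effects are site-specific Gaussian draws shared by all samples
#' of the same colony / phenotype, which is what makes colony structure
#' dominate phenotype structure downstream. Planted DMS shift one phenotype
#' of one pair by `dms_effect` percentage points (upward unless the clamp at
#' 0.999 forbids it); planted sites are guaranteed coverage >= 1 in every
#' sample.
#'
#' @param annotation A [simulate_annotation()] result.
#' @param config The same [sim_config()].
#' @param gene_effects Optional tibble (`gene_id`, `region_class`, `shift`)
#'   of baseline adjustments, e.g. from expression coupling.
#' @return List of class `sim_methylomes`: `samples` (sample sheet with
#'   spike-in counts), `coverage` (long tibble of per-site per-sample read
#'   counts in coverage-file form), `truth_sites` (per-CpG truth), and
#'   `truth_dms` (planted DMS: `site`, `pair`, `target_phenotype`,
#'   `direction`, `effect`).
#' @export
simulate_methylomes <- function(annotation, config = annotation$config,
                                gene_effects = NULL) {
  set.seed(child_seed(config$seed, 3L))
  design <- study_design(config)
  sites <- annotation$sites
  S <- nrow(sites)

  base <- sites$baseline
  if (!is.null(gene_effects)) {
    adj <- sites %>%
      select("site", "gene_id", "region_class") %>%
      left_join(gene_effects, by = c("gene_id", "region_class"))
    base <- clamp(base + dplyr::coalesce(adj$shift, 0), 0, 0.999)
  }

  colonies <- unique(design$colony)
  col_eff <- matrix(rnorm(S * length(colonies), 0, config$colony_sd),
                    nrow = S, dimnames = list(NULL, colonies))
  phe_eff <- matrix(rnorm(S * 4, 0, config$phenotype_sd),
                    nrow = S, dimnames = list(NULL, PHENOTYPES))
  col_mean <- setNames(rnorm(length(colonies), 0, config$colony_mean_sd),
                       colonies)
  phe_mean <- setNames(rnorm(4, 0, config$phenotype_mean_sd), PHENOTYPES)

  # plant DMS: distinct sites across pairs, one target phenotype each
  truth_dms <- tibble(site = character(), pair = character(),
                      target_phenotype = character(),
                      direction = character(), effect = double())
  if (config$n_planted_dms > 0) {
    pool <- sample.int(S)
    taken <- 0
    rows <- list()
    for (p in phenotype_pairs()) {
      idx <- pool[taken + seq_len(config$n_planted_dms)]
      taken <- taken + config$n_planted_dms
      target <- sample(p, length(idx), replace = TRUE)
      up_ok <- base[idx] + config$dms_effect <= 0.999
      rows[[length(rows) + 1]] <- tibble(
        site = sites$site[idx], site_idx = idx,
        pair = pair_label(p[1], p[2]),
        target_phenotype = target,
        direction = if_else(up_ok, "hyper", "hypo"),
        effect = config$dms_effect)
    }
    truth_dms <- bind_rows(rows)
  }

  nc <- setNames(config$nonconversion_rate, design$sample_id)
  rho <- config$beta_dispersion

  per_sample <- purrr::map(seq_len(nrow(design)), function(j) {
    sid <- design$sample_id[j]
    p_true <- plogis(qlogis(base) + col_eff[, design$colony[j]] +
                       phe_eff[, design$phenotype[j]] +
                       col_mean[[design$colony[j]]] +
                       phe_mean[[design$phenotype[j]]])
    if (nrow(truth_dms) > 0) {
      mine <- truth_dms[truth_dms$target_phenotype == design$phenotype[j], ]
      if (nrow(mine) > 0) {
        shift <- if_else(mine$direction == "hyper", mine$effect, -mine$effect)
        p_true[mine$site_idx] <- clamp(p_true[mine$site_idx] + shift)
      }
    }
    if (rho > 0) {
      inner <- p_true > 0 & p_true < 1
      a <- p_true * (1 - rho) / rho
      b <- (1 - p_true) * (1 - rho) / rho
      p_bb <- p_true
      p_bb[inner] <- rbeta(sum(inner), a[inner], b[inner])
    } else {
      p_bb <- p_true
    }
    p_obs <- p_bb + (1 - p_bb) * nc[[sid]]
    cov <- rnbinom(S, mu = config$coverage_mean,
                   size = config$coverage_dispersion)
    if (nrow(truth_dms) > 0) cov[truth_dms$site_idx] <- pmax(cov[truth_dms$site_idx], 1L)
    keep <- cov >= 1
    cm <- rbinom(sum(keep), cov[keep], p_obs[keep])
    tibble(sample_id = sid,
           site = sites$site[keep], chrom = sites$chrom[keep],
           pos = sites$pos[keep], strand = sites$strand[keep],
           count_meth = cm, count_unmeth = cov[keep] - cm,
           coverage = cov[keep], level = cm / cov[keep])
  })
  coverage <- bind_rows(per_sample)

  spike_meth <- rbinom(nrow(design), config$spikein_total, nc[design$sample_id])
  samples <- design %>%
    mutate(spikein_meth = spike_meth,
           spikein_unmeth = config$spikein_total - spike_meth)

  structure(list(samples = samples, coverage = coverage,
                 truth_sites = sites,
                 truth_dms = truth_dms %>% select(-any_of("site_idx")),
                 config = config),
            class = "sim_methylomes")
}

#' Generate a complete synthetic study, optionally writing it to disk
#'
#' Orchestrates [simulate_annotation()], [simulate_expression()] (whose DE
#' labels drive methylation coupling when enabled) and
#' [simulate_methylomes()]. When `dir` is given, the study is written in the
#' exact formats the readers consume: one Bismark-dialect coverage file per
#' sample, GFF3 gene and repeat annotations, a sample sheet, an expression
#' TSV, and the truth tables.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory (created if missing).
#' @return List of class `sim_study`: `annotation`, `expression`,
#'   `methylomes`, plus file `paths` when written.
#' @export
simulate_study <- function(config, dir = NULL) {
  annotation <- simulate_annotation(config)
  expression <- simulate_expression(annotation, config)
  methylomes <- simulate_methylomes(annotation, config,
                                    gene_effects = coupling_effects(expression, config))
  out <- structure(list(annotation = annotation, expression = expression,
                        methylomes = methylomes, config = config),
                   class = "sim_study")
  if (!is.null(dir)) {
    out$paths <- write_sim_study(out, dir)
  }
  out
}

write_sim_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- study$annotation
  meth <- study$methylomes

  gff_path <- file.path(dir, "genes.gff3")
  write_genes_gff3(ann$genes, ann$scaffolds, gff_path)
  rep_path <- file.path(dir, "repeats.gff3")
  write_repeats_gff3(ann$repeats, rep_path)

  cov_paths <- setNames(
    file.path(dir, paste0(meth$samples$sample_id, ".cov")),
    meth$samples$sample_id)
  for (sid in meth$samples$sample_id) {
    write_coverage(meth$coverage %>% filter(.data$sample_id == sid), cov_paths[[sid]])
  }
  sheet <- meth$samples %>%
    mutate(coverage_path = basename(unname(cov_paths[.data$sample_id])))
  sheet_path <- file.path(dir, "samples.tsv")
  write_tsv_output(sheet, sheet_path)
  expr_path <- file.path(dir, "expression.tsv")
  write_tsv_output(study$expression, expr_path)
  write_tsv_output(meth$truth_sites, file.path(dir, "truth_sites.tsv"))
  write_tsv_output(meth$truth_dms, file.path(dir, "truth_dms.tsv"))
  list(genes_gff = gff_path, repeats_gff = rep_path, coverage = cov_paths,
       sample_sheet = sheet_path, expression = expr_path)
}

# minimal GFF3 emitters for the synthetic study (gene/mRNA/exon hierarchy)
write_genes_gff3 <- function(gm, scaffolds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (s in seq_len(nrow(scaffolds))) {
    writeLines(sprintf("##sequence-region %s 1 %d",
                       scaffolds$chrom[s], scaffolds$length[s]), con)
  }
  g <- gm$genes
  ex <- gm$exons %>% arrange(.data$gene_id, .data$start)
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    writeLines(sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom[i], g$start[i], g$end[i], g$strand[i], gid), con)
    for (t in seq_len(g$transcript_count[i])) {
      tid <- sprintf("%s.t%d", gid, t)
      writeLines(sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         g$chrom[i], g$start[i], g$end[i], g$strand[i],
                         tid, gid), con)
      exi <- ex[ex$gene_id == gid, ]
      writeLines(sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         exi$chrom, exi$start, exi$end, exi$strand,
                         tid, seq_len(nrow(exi)), tid), con)
    }
  }
  invisible(path)
}

write_repeats_gff3 <- function(repeats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(repeats) > 0) {
    writeLines(sprintf("%s\tsim\tdispersed_repeat\t%d\t%d\t.\t.\t.\tID=rep%d",
                       repeats$chrom, repeats$start, repeats$end,
                       seq_len(nrow(repeats))), con)
  }
  invisible(path)
}
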