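test_that("flank orientation follows gene strand", {
  gm <- toy_genes()
  idx <- build_feature_index(gm, flank_size = 10000)
  # gB is a minus-strand gene spanning 10000-20000: its 5'-flank lies downstream
  f5 <- idx$flank5[idx$flank5$gene_id == "gB"]
  expect_equal(GenomicRanges::start(f5), 20001)
  expect_equal(GenomicRanges::end(f5), 30000)
  f3 <- idx$flank3[idx$flank3$gene_id == "gB"]
  expect_equal(c(GenomicRanges::start(f3), GenomicRanges::end(f3)),
               c(1, 9999)) # truncated at position 1 (10000 - 10000 < 1)
})

test_that("introns are the inter-exon gaps with 5'-to-3' ranks", {
  gm <- gene_models(
    tibble::tibble(gene_id = "g", chrom = "s1", strand = "+",
                   start = 100L, end = 500L, transcript_count = 1L),
    tibble::tibble(gene_id = "g", chrom = "s1", strand = "+",
                   start = c(100L, 401L), end = c(200L, 500L),
                   exon_rank = c(1L, 2L)))
  idx <- build_feature_index(gm)
  expect_equal(GenomicRanges::start(idx$intron), 201)
  expect_equal(GenomicRanges::end(idx$intron), 400)
  expect_equal(idx$intron$element_rank, 1L)
})

test_that("classification applies precedence and the ambiguity rule", {
  # gA: + strand exons 1100-1200, 1401-1500; gB: - strand span 10000-20000
  gm <- toy_genes()
  reps <- tibble::tibble(chrom = "s1", start = c(1150L, 5000L),
                         end = c(2400L, 6000L))
  idx <- build_feature_index(gm, reps, flank_size = 1000)
  ann <- annotate_sites(
    sites_tbl(c(1150,    # exon gA (and repeat underneath -> exon wins)
                1300,    # intron gA (repeat underneath -> intron wins)
                5500,    # repeat beyond all flanks
                1700,    # 200 bp downstream of gA: flank3 bin 1 over repeat
                4000,    # nothing: intergenic
                10300,   # intron gB (between its exons 10200 and 10500)
                20500)), # 500 bp past gB end: gB 5'-flank (minus strand)
    idx)
  expect_equal(ann$region_class,
               c("exon", "intron", "repeat", "flank3", "intergenic",
                 "intron", "flank5"))
  expect_equal(ann$gene_id[1], "gA")
  expect_equal(ann$element_rank[2], 1L)
  expect_equal(ann$flank_bin[4], 1L)
})

test_that("conflicting genic classes from different genes are ambiguous", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "s1",
                          strand = "+", start = c(100L, 150L),
                          end = c(1000L, 1200L),
                          transcript_count = 1L)
  exons <- tibble::tibble(
    gene_id = c("g1", "g1", "g2"), chrom = "s1", strand = "+",
    start = c(100L, 800L, 150L), end = c(300L, 1000L, 1200L),
    exon_rank = c(1L, 2L, 1L))
  idx <- build_feature_index(gene_models(genes, exons), flank_size = 500)
  ann <- annotate_sites(sites_tbl(c(500, 200)), idx)
  # 500: intron of g1 but exon of g2 -> ambiguous; 200: exon of both -> exon
  expect_equal(ann$region_class, c("ambiguous", "exon"))
  expect_equal(nrow(annotate_sites(sites_tbl(500), idx,
                                   drop_ambiguous = TRUE)), 0)
})

test_that("overlapping 5'- and 3'-flanks of different genes are ambiguous", {
  genes <- tibble::tibble(gene_id = c("gL", "gR"), chrom = "s1",
                          strand = "+", start = c(100L, 3000L),
                          end = c(1000L, 4000L), transcript_count = 1L)
  exons <- tibble::tibble(gene_id = c("gL", "gR"), chrom = "s1",
                          strand = "+", start = c(100L, 3000L),
                          end = c(1000L, 4000L), exon_rank = 1L)
  idx <- build_feature_index(gene_models(genes, exons), flank_size = 10000)
  ann <- annotate_sites(sites_tbl(2000), idx) # flank3 of gL, flank5 of gR
  expect_equal(ann$region_class, "ambiguous")
})

test_that("flank bins count 1 kb steps outward from the gene boundary", {
  gm <- toy_genes()
  idx <- build_feature_index(gm, flank_size = 10000)
  # 2500 bp downstream of gA (+ strand, end 1500) -> flank3, bin 3
  ann <- annotate_sites(sites_tbl(4000), idx)
  expect_equal(ann$region_class, "flank3")
  expect_equal(ann$flank_bin, 3L)
  # exact multiples fall in the inner bin: distance 1000 -> bin 1
  expect_equal(annotate_sites(sites_tbl(2500), idx)$flank_bin, 1L)
})

test_that("classification agrees with an exhaustive brute-force scan", {
  withr::local_seed(77)
  st <- small_study()
  gm <- st$annotation$genes
  reps <- st$annotation$repeats
  idx <- build_feature_index(gm, reps, flank_size = st$config$flank_size)
  pos <- sort(sample(1:150000, 400))
  ann <- annotate_sites(sites_tbl(pos, chrom = "scaf1"), idx)
  expected <- vapply(pos, brute_classify, "", chrom = "scaf1", gm = gm,
                     repeats = reps, flank_size = st$config$flank_size)
  expect_equal(ann$region_class, expected)
})

test_that("every matrix site gets exactly one class and the partition is complete", {
  st <- small_study()
  ann <- annotated_matrix(st)
  per_site <- dplyr::distinct(ann, site, region_class)
  expect_equal(nrow(per_site), dplyr::n_distinct(ann$site))
  expect_true(all(per_site$region_class %in%
                    c("exon", "intron", "flank5", "flank3", "repeat",
                      "intergenic", "ambiguous")))
  # simulated truth is recovered exactly (the generator plants no ambiguity)
  cmp <- dplyr::inner_join(per_site,
                           dplyr::select(st$annotation$sites, site,
                                         truth = region_class),
                           by = "site")
  expect_equal(cmp$region_class, cmp$truth)
})

test_that("mirroring the genome swaps flank classes but preserves counts", {
  st <- small_study()
  gm <- st$annotation$genes
  L <- max(st$annotation$scaffolds$length) + 1L
  idx <- build_feature_index(gm, st$annotation$repeats,
                             flank_size = st$config$flank_size)
  sites <- st$annotation$sites
  ann <- annotate_sites(sites_tbl(sites$pos, chrom = sites$chrom), idx)

  flip <- function(s, e) list(start = L - e, end = L - s)
  g2 <- gm$genes |>
    dplyr::mutate(s2 = L - end, e2 = L - start,
                  start = s2, end = e2,
                  strand = ifelse(strand == "+", "-", "+")) |>
    dplyr::select(-s2, -e2)
  e2 <- gm$exons |>
    dplyr::mutate(s2 = L - end, e2 = L - start, start = s2, end = e2,
                  strand = ifelse(strand == "+", "-", "+")) |>
    dplyr::select(-s2, -e2)
  r2 <- st$annotation$repeats |>
    dplyr::mutate(s2 = L - end, e2 = L - start, start = s2, end = e2) |>
    dplyr::select(-s2, -e2)
  idx2 <- build_feature_index(gene_models(g2, e2), r2,
                              flank_size = st$config$flank_size)
  ann2 <- annotate_sites(sites_tbl(L - sites$pos, chrom = sites$chrom), idx2)
  t1 <- table(ann$region_class)
  t2 <- table(ann2$region_class)
  expect_equal(unname(t1[c("exon", "intron", "repeat", "intergenic")]),
               unname(t2[c("exon", "intron", "repeat", "intergenic")]))
  expect_equal(unname(t1["flank5"]), unname(t2["flank5"]))
  expect_equal(unname(t1["flank3"]), unname(t2["flank3"]))
})
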