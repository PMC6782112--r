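make_toy_genome <- function(seqs) {
  g <- Biostrings::DNAStringSet(toupper(seqs))
  names(g) <- names(seqs)
  g
}

test_that("CG counting is exact, case-insensitive and ambiguity-safe", {
  g <- make_toy_genome(c(chrA = "ACGCGT", chrB = "ATTTAT", chrC = "acgNcgCg"))
  expect_equal(count_cg_sites(g, "chrA", 0, 6), 2L)
  expect_equal(count_cg_sites(g, "chrB", 0, 6), 0L)   # no C at all
  expect_equal(count_cg_sites(g, "chrC", 0, 8), 3L)   # lowercase counts, N never matches
  expect_equal(count_cg_sites(g, "chrA", 1, 3), 1L)   # [1,3) = "CG"
  expect_equal(count_cg_sites(g, "chrA", -5, 100), 2L) # clamped to the chromosome
  expect_error(count_cg_sites(g, "chrZ", 0, 5), "unknown chromosome")

  set.seed(9)
  chrom <- paste(sample(c("A", "C", "G", "T", "N"), 10000,
                        replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
                 collapse = "")
  g2 <- make_toy_genome(c(rand = chrom))
  expect_equal(count_cg_sites(g2, "rand", 0, 10000), brute_force_cg(chrom))
  for (i in 1:10) {
    lo <- sample(0:9000, 1); hi <- lo + sample(10:900, 1)
    expect_equal(count_cg_sites(g2, "rand", lo, hi),
                 brute_force_cg(substr(chrom, lo + 1, hi)))
  }
})

test_that("transcript scores match hand computation on a planted fixture", {
  # chromosome of 60 bp: CGs planted at known 0-based positions
  seq <- paste(rep("A", 60), collapse = "")
  substr(seq, 11, 12) <- "CG"  # pos 10
  substr(seq, 21, 22) <- "CG"  # pos 20
  substr(seq, 41, 42) <- "CG"  # pos 40
  g <- make_toy_genome(c(chr1 = seq))
  tx <- data.frame(gene_id = c("g1", "g1", "g2"),
                   transcript_id = c("t1", "t2", "t3"),
                   chrom = "chr1",
                   start = c(15L, 15L, 52L), end = c(30L, 45L, 55L),
                   strand = c("+", "+", "-"), stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L, 44L), count = c(2L, 1L, 1L))
  sc <- score_transcripts(sites, tx, g, flank = 10)
  # t1 bin [5,40): CGs at 10,20 -> cg=2; sites at 10 (count 2) and 20 -> hmc=3
  # t2 bin [5,55): all three CGs, all three sites; t3 bin [42,60): no CG
  expect_equal(sc$cg_sites, c(2L, 3L, 0L))
  expect_equal(sc$hmc_sites, c(3L, 4L, 1L))
  expect_equal(sc$ratio, c(3 / 2, 4 / 3, NA))
  expect_true(sc$cg_undefined[3])

  # boundary convention: a site exactly at bin end is excluded
  tx_edge <- data.frame(gene_id = "e", transcript_id = "te", chrom = "chr1",
                        start = 10L, end = 15L, strand = "+",
                        stringsAsFactors = FALSE)
  sc_edge <- score_transcripts(data.frame(chrom = "chr1", pos = c(10L, 20L),
                                          count = 1L),
                               tx_edge, g, flank = 0)
  expect_equal(sc_edge$hmc_sites, 1L)  # pos 10 in [10,15), pos 20 out

  # sites on unknown chromosomes are skipped with a warning
  expect_warning(
    sc_skip <- score_transcripts(rbind(sites,
                                       data.frame(chrom = "chrX", pos = 1L,
                                                  count = 1L)),
                                 tx, g, flank = 10),
    "unknown"
  )
  expect_equal(attr(sc_skip, "n_sites_skipped"), 1L)
})

test_that("gene scores sum isoform ratios and report undefined genes", {
  tx_scores <- data.frame(
    gene_id = c("a", "b", "b", "c"),
    transcript_id = c("a1", "b1", "b2", "c1"),
    hmc_sites = c(3L, 1L, 2L, 0L),
    cg_sites = c(30L, 10L, 40L, 0L),
    ratio = c(0.1, 0.1, 0.05, NA),
    cg_undefined = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  gs <- score_genes(tx_scores)
  expect_equal(gs$score[gs$gene_id == "a"], 0.1)
  expect_equal(gs$score[gs$gene_id == "b"], 0.15)
  expect_false("c" %in% gs$gene_id)
  expect_equal(attr(gs, "excluded_genes"), "c")
})

test_that("scores are linear in counts and invariant to order and site splitting", {
  fx <- simulate_hmc_fixture(seed = 5, genes_per_set = 8, chrom_length = 30000L)
  sc <- score_transcripts(fx$sites, fx$transcripts, fx$genome)
  gs <- score_genes(sc)

  doubled <- transform(fx$sites, count = count * 2L)
  gs2 <- score_genes(score_transcripts(doubled, fx$transcripts, fx$genome))
  expect_equal(gs2$score, 2 * gs$score)

  shuffled <- fx$transcripts[sample(nrow(fx$transcripts)), ]
  gs3 <- score_genes(score_transcripts(fx$sites, shuffled, fx$genome))
  expect_equal(gs3[order(gs3$gene_id), "score"], gs[order(gs$gene_id), "score"])

  # splitting a count-k site into k unit records changes nothing
  k_site <- fx$sites[1, ]
  split_sites <- rbind(fx$sites[-1, ],
                       k_site[rep(1, 3), ][, ])
  split_sites$count[(nrow(split_sites) - 2):nrow(split_sites)] <- 1L
  orig <- fx$sites; orig$count[1] <- 3L
  gs_orig <- score_genes(score_transcripts(orig, fx$transcripts, fx$genome))
  gs_split <- score_genes(score_transcripts(split_sites, fx$transcripts, fx$genome))
  expect_equal(gs_split$score, gs_orig$score)
})

test_that("gene-set comparison detects planted enrichment and handles nulls", {
  fx <- simulate_hmc_fixture(seed = 41, genes_per_set = 30, chrom_length = 90000L)
  gs <- score_genes(score_transcripts(fx$sites, fx$transcripts, fx$genome))
  cmp <- compare_gene_sets(gs, fx$sets)
  expect_setequal(names(cmp$ecdf),
                  c("lineage_specific", "hesc_specific", "background", "total"))
  lin_vs_bg <- cmp$tests[cmp$tests$set1 == "background" &
                           cmp$tests$set2 == "lineage_specific" |
                         cmp$tests$set1 == "lineage_specific" &
                           cmp$tests$set2 == "background", ]
  expect_lt(lin_vs_bg$p_value, 0.01)

  # the 2x set's ECDF is right-shifted: lower CDF at the pooled median
  med <- median(gs$score)
  expect_lt(cmp$ecdf$lineage_specific(med), cmp$ecdf$background(med))
  # "total" lies between the component sets
  expect_gte(cmp$ecdf$total(med), cmp$ecdf$lineage_specific(med))
  expect_lte(cmp$ecdf$total(med), cmp$ecdf$background(med))

  # identical sets: no shift
  same <- data.frame(gene_id = rep(gs$gene_id, 2),
                     set = rep(c("s1", "s2"), each = nrow(gs)))
  cmp_same <- compare_gene_sets(gs, same, add_total = FALSE)
  expect_gt(min(cmp_same$tests$p_value), 0.99)

  one <- data.frame(gene_id = gs$gene_id[1], set = "lonely")
  expect_error(compare_gene_sets(gs, one), "insufficient")
})

test_that("fixture files round-trip through the readers", {
  dir <- withr::local_tempdir()
  fx <- simulate_hmc_fixture(seed = 3, genes_per_set = 5, chrom_length = 20000L,
                             out_dir = dir)
  genome <- read_genome_fasta(fx$paths$genome)
  sites <- read_hmc_sites(fx$paths$sites)
  tx <- read_transcript_table(fx$paths$transcripts)
  sets <- read_gene_sets(fx$paths$sets)
  expect_equal(as.character(genome), as.character(fx$genome))
  expect_equal(sites, fx$sites)
  expect_equal(tx, fx$transcripts, ignore_attr = TRUE)
  expect_equal(sets, fx$sets)
  expect_warning(score_transcripts(sites, tx, genome), regexp = NA)

  tx1 <- read_transcript_table(fx$paths$transcripts, coords = "1based")
  expect_equal(tx1$start, fx$transcripts$start - 1L)
})
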