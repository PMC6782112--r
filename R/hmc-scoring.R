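#' Read a genome FASTA
#'
#' Loads a (small) genome as a `Biostrings::DNAStringSet`, uppercased so that
#' dinucleotide counting is case-insensitive.
#'
#' @param path FASTA path.
#' @return `DNAStringSet` named by chromosome.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  Biostrings::DNAStringSet(toupper(as.character(genome)))
}

#' Read 5-hmC sites from a BED3+1 file
#'
#' Expects `chrom`, `start`, `end` (0-based half-open, `end = start + 1`) and
#' a fourth column with the detected event count at the site (defaults to 1
#' when absent).
#'
#' @param path BED path (no header).
#' @return `data.frame` with `chrom`, `pos` (0-based), `count`.
#' @export
read_hmc_sites <- function(path) {
  if (!file.exists(path)) stop("sites BED not found: ", path)
  bed <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("BED needs at least chrom, start, end")
  sites <- data.frame(chrom = as.character(bed[[1]]),
                      pos = as.integer(bed[[2]]),
                      count = if (ncol(bed) >= 4) as.integer(bed[[4]]) else 1L,
                      stringsAsFactors = FALSE)
  if (any(sites$pos < 0)) stop("negative site position")
  if (any(sites$count <= 0)) stop("site counts must be positive")
  sites
}

#' Read a transcript annotation table
#'
#' Tab-separated with header columns `gene_id`, `transcript_id`, `chrom`,
#' `start`, `end`, `strand`. Coordinates are interpreted as 0-based half-open
#' by default; `coords = "1based"` converts closed 1-based intervals
#' (start-1, end kept) and records the conversion in an attribute.
#'
#' @param path TSV path.
#' @param coords `"0based"` (default) or `"1based"`.
#' @return `data.frame` of transcript models.
#' @export
read_transcript_table <- function(path, coords = c("0based", "1based")) {
  coords <- match.arg(coords)
  if (!file.exists(path)) stop("transcript table not found: ", path)
  tx <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(need, names(tx))
  if (length(missing_cols) > 0) {
    stop("transcript table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (coords == "1based") tx$start <- tx$start - 1L
  if (any(tx$start >= tx$end)) stop("transcript with start >= end")
  attr(tx, "coords") <- "0-based half-open"
  tx
}

#' Read gene-set assignments
#'
#' Tab-separated with header columns `gene_id` and `set`.
#'
#' @param path TSV path.
#' @return `data.frame` with `gene_id`, `set`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("gene-set table not found: ", path)
  sets <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "set") %in% names(sets))) {
    stop("gene-set table needs columns gene_id, set")
  }
  sets
}

#' Count CG dinucleotides in a genomic interval
#'
#' Number of occurrences of the dinucleotide CG on the forward strand of
#' `[start, end)` (0-based half-open), case-insensitive; ambiguous bases
#' never match. CG is its own reverse complement at the dinucleotide level,
#' so forward-strand counting covers both strands' CpG context.
#'
#' @param genome `DNAStringSet` from [read_genome_fasta()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval (clamped to the chromosome).
#' @return Integer count.
#' @export
count_cg_sites <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- length(genome[[chrom]])
  start <- max(0L, as.integer(start))
  end <- min(len, as.integer(end))
  if (end - start < 2) return(0L)
  Biostrings::countPattern("CG",
                           Biostrings::subseq(genome[[chrom]], start + 1L, end),
                           fixed = TRUE)
}

#' Score transcripts by CG-normalized 5-hmC density
#'
#' For each transcript the bin is the gene body extended by `flank` bp on
#' both sides, `[start - flank, end + flank)`, clamped to the chromosome
#' (strand carried but ignored: the bin is symmetric). The transcript score
#' is the total 5-hmC site count in the bin divided by the number of CG
#' dinucleotides in the same bin. Bin boundaries are start-inclusive,
#' end-exclusive. Sites on chromosomes absent from the genome are skipped
#' with a warning and counted in the `n_sites_skipped` attribute.
#'
#' @param sites Sites `data.frame` from [read_hmc_sites()].
#' @param transcripts Transcript `data.frame` from [read_transcript_table()].
#' @param genome `DNAStringSet` from [read_genome_fasta()].
#' @param flank Flank size in bp (default 1000).
#' @return `data.frame` with `gene_id`, `transcript_id`, `hmc_sites`,
#'   `cg_sites`, `ratio` (`NA` and `cg_undefined = TRUE` when the bin has no
#'   CG sites).
#' @export
score_transcripts <- function(sites, transcripts, genome, flank = 1000) {
  known <- sites$chrom %in% names(genome)
  n_skipped <- sum(!known)
  if (n_skipped > 0) {
    warning(n_skipped, " site(s) on unknown chromosome(s) skipped: ",
            paste(unique(sites$chrom[!known]), collapse = ", "))
    sites <- sites[known, , drop = FALSE]
  }
  chrom_len <- setNames(Biostrings::width(genome), names(genome))
  bin_start <- pmax(0L, transcripts$start - as.integer(flank))
  bin_end <- pmin(chrom_len[transcripts$chrom], transcripts$end + as.integer(flank))

  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos + 1L, width = 1L))
  bin_gr <- GenomicRanges::GRanges(transcripts$chrom,
                                   IRanges::IRanges(bin_start + 1L, bin_end))
  hits <- GenomicRanges::findOverlaps(site_gr, bin_gr)
  hmc <- rep(0L, nrow(transcripts))
  if (length(hits) > 0) {
    tot <- tapply(sites$count[S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits), sum)
    hmc[as.integer(names(tot))] <- as.integer(tot)
  }
  cg <- vapply(seq_len(nrow(transcripts)), function(i) {
    count_cg_sites(genome, transcripts$chrom[i], bin_start[i], bin_end[i])
  }, integer(1))
  out <- data.frame(
    gene_id = transcripts$gene_id,
    transcript_id = transcripts$transcript_id,
    hmc_sites = hmc,
    cg_sites = cg,
    ratio = ifelse(cg > 0, hmc / cg, NA_real_),
    cg_undefined = cg == 0,
    stringsAsFactors = FALSE
  )
  attr(out, "n_sites_skipped") <- n_skipped
  out
}

#' Aggregate transcript scores to gene scores
#'
#' The 5-hmC level of a gene is the sum of its isoforms' CG-normalized
#' ratios (shared regions deliberately count once per isoform). Genes whose
#' isoforms all have undefined ratios (no CG sites) are excluded and listed
#' in the `excluded_genes` attribute.
#'
#' @param tx_scores Output of [score_transcripts()].
#' @return `data.frame` with `gene_id`, `hmc_sites`, `cg_sites`, `score`.
#' @export
score_genes <- function(tx_scores) {
  defined <- tx_scores[!tx_scores$cg_undefined, , drop = FALSE]
  excluded <- setdiff(unique(tx_scores$gene_id), unique(defined$gene_id))
  if (nrow(defined) == 0) {
    out <- data.frame(gene_id = character(0), hmc_sites = integer(0),
                      cg_sites = integer(0), score = numeric(0))
  } else {
    agg <- aggregate(defined[, c("hmc_sites", "cg_sites", "ratio")],
                     by = list(gene_id = defined$gene_id), FUN = sum)
    names(agg)[names(agg) == "ratio"] <- "score"
    out <- agg[order(agg$gene_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "excluded_genes") <- excluded
  out
}

#' Compare gene-set distributions of 5-hmC scores
#'
#' Builds the empirical CDF of gene scores per set and runs a pairwise
#' Mann-Whitney U test ([mannwhitney_u()]) for every set pair. The set named
#' `"total"`, when present, means all provided genes (including members of
#' the other sets) and is added automatically when absent.
#'
#' @param gene_scores `data.frame` from [score_genes()].
#' @param sets `data.frame` with `gene_id`, `set` (a gene may appear in
#'   several sets). Genes without a score are ignored.
#' @param add_total Add a `"total"` set covering all scored genes (default
#'   TRUE when no set of that name is supplied).
#' @return List with `ecdf` (named list of `stats::ecdf` functions), `values`
#'   (named list of score vectors) and `tests` (`data.frame` of pairwise U
#'   results).
#' @export
compare_gene_sets <- function(gene_scores, sets, add_total = TRUE) {
  score_of <- setNames(gene_scores$score, gene_scores$gene_id)
  groups <- split(sets$gene_id, sets$set)
  values <- lapply(groups, function(g) unname(score_of[intersect(g, names(score_of))]))
  if (add_total && !"total" %in% names(values)) {
    values$total <- unname(score_of)
  }
  small <- names(values)[vapply(values, length, integer(1)) < 2]
  if (length(small) > 0) {
    stop("insufficient data: gene set(s) with < 2 scored genes: ",
         paste(small, collapse = ", "))
  }
  set_names <- names(values)
  combos <- utils::combn(set_names, 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
    s1 <- combos[1, i]; s2 <- combos[2, i]
    res <- mannwhitney_u(values[[s1]], values[[s2]])
    data.frame(set1 = s1, set2 = s2, U = res$statistic,
               p_value = res$p_value, p_label = res$p_label,
               n1 = res$n1, n2 = res$n2, stringsAsFactors = FALSE)
  }))
  list(ecdf = lapply(values, ecdf), values = values, tests = tests)
}
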