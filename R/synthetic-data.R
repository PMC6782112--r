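#' Simulation configuration
#'
#' Bundles the generative parameters for the synthetic FUCCI track generator.
#' The generative model mirrors the analysis assumptions: shifted G1
#' (G1 = c + G1*) with G1* drawn from a continuous-Poisson analogue
#' Gamma(shape = mu, rate = 1) so that var(G1*) = mean(G1*) = mu, an
#' exponential WNT link mu = exp(beta0 + beta1 * AXIN2), sister pairs that
#' share one G1* draw (plus small jitter) except for a fraction `p_asym` of
#' independently drawing pairs, approximate total-cycle conservation via a
#' truncated-normal total cycle (inducing the inverse G1 vs S/G2/M
#' correlation), and quantization of all times to the imaging frame grid.
#'
#' @param seed Integer master seed; per-condition substreams are derived from
#'   it, so output is byte-identical under a fixed seed and config.
#' @param conditions `data.frame` with `label`, `axin2_level`, `n_cells`
#'   (default [default_study_conditions()]).
#' @param c_shift_hours Shift constant c (default 4 h, the lower edge of the
#'   observed G1 range).
#' @param beta0,beta1 WNT-link coefficients (defaults 3.2 and -6380).
#' @param total_cycle_mean_h,total_cycle_sd_h Total-cycle normal parameters
#'   (defaults 34 h and 4 h, centered in the observed 20-40 h S/G2/M range
#'   plus a short G1).
#' @param p_asym Fraction of sister pairs with independent G1 draws
#'   (default 0.25).
#' @param asym_jitter_sd_h SD of within-shared-pair jitter (default 0.25 h).
#' @param early_g1_one_frame_prob Probability that the no-color early-G1
#'   window lasts one frame instead of zero (default 0.2; it is sub-frame in
#'   most cells).
#' @param frame_interval_minutes Imaging frame interval (default 10 min).
#' @param movie_span_h Movie length (default 48 h); events past the end are
#'   censored.
#' @return List of class `g1dist_sim_config`. Warns when a condition's
#'   expected total G1 approaches the total-cycle mean.
#' @export
sim_config <- function(seed = 1L,
                       conditions = default_study_conditions(),
                       c_shift_hours = 4,
                       beta0 = 3.2,
                       beta1 = -6380,
                       total_cycle_mean_h = 34,
                       total_cycle_sd_h = 4,
                       p_asym = 0.25,
                       asym_jitter_sd_h = 0.25,
                       early_g1_one_frame_prob = 0.2,
                       frame_interval_minutes = 10,
                       movie_span_h = 48) {
  stopifnot(total_cycle_sd_h >= 0, asym_jitter_sd_h >= 0,
            p_asym >= 0, p_asym <= 1, c_shift_hours >= 0,
            frame_interval_minutes > 0, movie_span_h > 0,
            early_g1_one_frame_prob >= 0, early_g1_one_frame_prob <= 1)
  cfg <- list(seed = as.integer(seed), conditions = conditions,
              c_shift_hours = c_shift_hours, beta0 = beta0, beta1 = beta1,
              total_cycle_mean_h = total_cycle_mean_h,
              total_cycle_sd_h = total_cycle_sd_h,
              p_asym = p_asym, asym_jitter_sd_h = asym_jitter_sd_h,
              early_g1_one_frame_prob = early_g1_one_frame_prob,
              frame_interval_minutes = frame_interval_minutes,
              movie_span_h = movie_span_h)
  mu <- exp(beta0 + beta1 * conditions$axin2_level)
  if (any(mu + c_shift_hours >= total_cycle_mean_h)) {
    warning("expected G1 (mu + c_shift) reaches the total-cycle mean for condition(s): ",
            paste(conditions$label[mu + c_shift_hours >= total_cycle_mean_h],
                  collapse = ", "))
  }
  class(cfg) <- "g1dist_sim_config"
  cfg
}

#' Default study conditions
#'
#' The condition panels of the study design, with the published per-panel
#' sample sizes: a low-WNT medium (mTeSR1), a high-WNT medium (E8), three
#' WNT3A doses on top of mTeSR1, and three iPSC lines (one neurogenic with
#' long G1, two with short G1). AXIN2 levels (relative to GAPDH, order 1e-4)
#' are calibrated once so that the exponential link with beta0 = 3.2,
#' beta1 = -6380 reproduces the qualitative mean-G1 ordering of the panels.
#'
#' @return `data.frame` with `label`, `axin2_level`, `n_cells`.
#' @export
default_study_conditions <- function() {
  data.frame(
    label = c("mtesr1", "e8", "wnt3a_10", "wnt3a_20", "wnt3a_100",
              "hipsc1", "hipsc2", "hipsc3"),
    axin2_level = c(3.60e-4, 6.10e-4, 3.85e-4, 4.10e-4, 6.10e-4,
                    3.40e-4, 5.60e-4, 5.30e-4),
    n_cells = c(114L, 112L, 42L, 48L, 104L, 100L, 120L, 108L),
    stringsAsFactors = FALSE
  )
}

# Deterministic substream seed below 2^31, derived from the master seed and a
# stage/condition label.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(as.numeric(seed)) %% 1e5 * 10007 + h * 101 + 17) %% 2147483647)
}

#' Simulate one population of FUCCI tracks
#'
#' Cells are emitted as sister pairs (plus one unpaired cell when `n_cells`
#' is odd). With probability `1 - p_asym` both sisters share a single
#' G1* ~ Gamma(shape = mu, rate = 1) draw, each perturbed by
#' Normal(0, `asym_jitter_sd_h`); otherwise the sisters draw independently.
#' G1 = c + G1*; the total cycle T ~ Normal(mean, sd) truncated below at
#' G1 + 1 h gives S/G2/M = T - G1. All times are rounded to the frame grid
#' and emitted as color-event frames, so [derive_phase_lengths()] recovers
#' them; events past the movie end are missing (censored).
#'
#' @param config [sim_config()] output.
#' @param condition One-row slice of `config$conditions` (or a list with
#'   `label`, `axin2_level`, `n_cells`).
#' @return Track `data.frame` in the [track_columns()] layout.
#' @export
simulate_population <- function(config, condition) {
  set.seed(substream_seed(config$seed, paste0("pop:", condition$label)))
  n <- as.integer(condition$n_cells)
  mu <- exp(config$beta0 + config$beta1 * condition$axin2_level)
  n_pairs <- n %/% 2L
  unpaired <- n %% 2L == 1L

  shared <- runif(n_pairs) >= config$p_asym
  common <- rgamma(n_pairs, shape = mu, rate = 1)
  draw_a <- ifelse(shared,
                   common + rnorm(n_pairs, 0, config$asym_jitter_sd_h),
                   rgamma(n_pairs, shape = mu, rate = 1))
  draw_b <- ifelse(shared,
                   common + rnorm(n_pairs, 0, config$asym_jitter_sd_h),
                   rgamma(n_pairs, shape = mu, rate = 1))
  g1star <- c(rbind(draw_a, draw_b))
  if (unpaired) g1star <- c(g1star, rgamma(1, shape = mu, rate = 1))
  g1star <- pmax(g1star, 0)
  g1 <- config$c_shift_hours + g1star

  m <- config$total_cycle_mean_h; s <- config$total_cycle_sd_h
  lower <- pnorm((g1 + 1 - m) / max(s, 1e-12))
  total <- m + s * qnorm(runif(n, lower, 1))
  sg2m <- total - g1

  fph <- 60 / config$frame_interval_minutes
  max_frame <- as.integer(round(config$movie_span_h * fph))
  birth_span_h <- max(0, config$movie_span_h - 24)
  division <- as.integer(floor(runif(n, 0, birth_span_h * fph + 1)))
  division <- pmin(division, max_frame)
  early <- rbinom(n, 1L, config$early_g1_one_frame_prob)
  g1_frames <- as.integer(round(g1 * fph))
  sg2m_frames <- pmax(1L, as.integer(round(sg2m * fph)))

  censor <- function(f) ifelse(f > max_frame, NA_integer_, as.integer(f))

  pair_idx <- c(rbind(seq_len(n_pairs), seq_len(n_pairs)))
  if (unpaired) pair_idx <- c(pair_idx, n_pairs + 1L)
  cell_id <- sprintf("%s_c%04d", condition$label, seq_len(n))
  lineage_id <- sprintf("%s_l%04d", condition$label, pair_idx)
  sister_id <- rep(NA_character_, n)
  if (n_pairs > 0) {
    a_rows <- seq(1L, 2L * n_pairs, by = 2L)
    sister_id[a_rows] <- cell_id[a_rows + 1L]
    sister_id[a_rows + 1L] <- cell_id[a_rows]
  }
  # sisters share the division event
  a_rows <- if (n_pairs > 0) seq(1L, 2L * n_pairs, by = 2L) else integer(0)
  division[a_rows + 1L] <- division[a_rows]
  red_on <- division + early
  green_on <- red_on + g1_frames
  red_off <- green_on
  green_off <- red_off + sg2m_frames

  data.frame(
    cell_id = cell_id,
    lineage_id = lineage_id,
    parent_id = NA_character_,
    sister_id = sister_id,
    condition = condition$label,
    frame_interval_minutes = config$frame_interval_minutes,
    division_frame = censor(division),
    red_on_frame = censor(red_on),
    red_off_frame = censor(red_off),
    green_on_frame = censor(green_on),
    green_off_frame = censor(green_off),
    stringsAsFactors = FALSE
  )
}

#' Simulate every condition of a configuration
#'
#' Runs [simulate_population()] for each row of `config$conditions` and
#' binds the tracks.
#'
#' @param config [sim_config()] output.
#' @return List with `tracks` (combined track `data.frame`) and `conditions`
#'   (the condition table used).
#' @export
simulate_study <- function(config) {
  tracks <- do.call(rbind, lapply(seq_len(nrow(config$conditions)), function(i) {
    simulate_population(config, config$conditions[i, ])
  }))
  rownames(tracks) <- NULL
  list(tracks = tracks, conditions = config$conditions)
}

#' Simulate a WNT3A dose-response series
#'
#' Maps each dose to an AXIN2 level through a linear map (AXIN2 rises
#' linearly with the added WNT3A below saturation), then simulates one
#' population per dose. Defaults follow the published design: doses 0, 10,
#' 20, 100 ng/ml with 114, 42, 48 and 104 cells.
#'
#' @param config [sim_config()] output (its `conditions` field is ignored).
#' @param doses WNT3A doses in ng/ml.
#' @param n_per_dose Cells per dose.
#' @param axin2_intercept,axin2_slope Linear dose-to-AXIN2 map; the slope
#'   must be positive.
#' @return List with `conditions` (`label`, `dose`, `axin2_level`,
#'   `n_cells`) and `tracks`.
#' @export
simulate_dose_series <- function(config,
                                 doses = c(0, 10, 20, 100),
                                 n_per_dose = c(114L, 42L, 48L, 104L),
                                 axin2_intercept = 3.6e-4,
                                 axin2_slope = 2.5e-6) {
  if (axin2_slope <= 0) stop("dose-to-AXIN2 slope must be positive")
  if (length(doses) != length(n_per_dose)) stop("doses and n_per_dose lengths differ")
  conditions <- data.frame(
    label = sprintf("dose_%g", doses),
    dose = doses,
    axin2_level = axin2_intercept + axin2_slope * doses,
    n_cells = as.integer(n_per_dose),
    stringsAsFactors = FALSE
  )
  tracks <- do.call(rbind, lapply(seq_len(nrow(conditions)), function(i) {
    simulate_population(config, conditions[i, ])
  }))
  rownames(tracks) <- NULL
  list(conditions = conditions, tracks = tracks)
}

#' Simulate a toy 5-hmC fixture
#'
#' Builds a small random genome, plants non-overlapping genes (alternating
#' one- and two-isoform models) assigned to three sets, and places unit-count
#' 5-hmC sites at CG dinucleotides inside each gene's body ± flank with a
#' per-set Bernoulli rate (`site_prob` times the set's multiplier). Gene
#' slots are padded so that neighbouring bins never overlap, making every
#' gene's expected score `site_prob * multiplier` per isoform.
#'
#' @param seed Integer seed (byte-identical output under a fixed seed).
#' @param n_chrom Number of chromosomes (default 3).
#' @param chrom_length Chromosome length in bp (default 150000).
#' @param genes_per_set Genes per set (default 50).
#' @param gene_length Gene body length in bp (default 800).
#' @param flank Flank used for the bins (default 1000).
#' @param site_prob Background probability that a CG carries a site
#'   (default 0.1).
#' @param set_multipliers Named per-set density multipliers (defaults:
#'   `lineage_specific` 2, `hesc_specific` 2, `background` 1).
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `sites.bed` (BED3+1), `transcripts.tsv`, `gene_sets.tsv`.
#' @return List with `genome` (`DNAStringSet`), `sites`, `transcripts`,
#'   `sets` (data frames), and `paths` when files were written.
#' @export
simulate_hmc_fixture <- function(seed = 1L,
                                 n_chrom = 3L,
                                 chrom_length = 150000L,
                                 genes_per_set = 50L,
                                 gene_length = 800L,
                                 flank = 1000L,
                                 site_prob = 0.1,
                                 set_multipliers = c(lineage_specific = 2,
                                                     hesc_specific = 2,
                                                     background = 1),
                                 out_dir = NULL) {
  set.seed(substream_seed(seed, "hmc_fixture"))
  set_names <- names(set_multipliers)
  n_genes <- genes_per_set * length(set_names)
  slot <- gene_length + 2L * flank + 200L
  per_chrom <- chrom_length %/% slot
  if (per_chrom * n_chrom < n_genes) {
    stop("genome too small for requested genes: fits ", per_chrom * n_chrom,
         ", need ", n_genes)
  }
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
          collapse = "")
  }, character(1)))
  names(genome) <- chroms

  gene_set <- rep(set_names, each = genes_per_set)
  # interleave sets across slots so no set is confined to one chromosome
  ord <- order(rep(seq_len(genes_per_set), times = length(set_names)))
  gene_set <- gene_set[ord]
  gene_id <- sprintf("g%03d", seq_len(n_genes))
  slot_idx <- seq_len(n_genes) - 1L
  chrom <- chroms[slot_idx %/% per_chrom + 1L]
  start <- (slot_idx %% per_chrom) * slot + flank + 100L
  end <- start + gene_length

  tx_list <- lapply(seq_len(n_genes), function(i) {
    tx <- data.frame(gene_id = gene_id[i],
                     transcript_id = paste0(gene_id[i], "_t1"),
                     chrom = chrom[i], start = start[i], end = end[i],
                     strand = if (i %% 2L == 0L) "-" else "+",
                     stringsAsFactors = FALSE)
    if (i %% 2L == 0L) {  # every other gene gets a shorter second isoform
      tx <- rbind(tx, data.frame(gene_id = gene_id[i],
                                 transcript_id = paste0(gene_id[i], "_t2"),
                                 chrom = chrom[i],
                                 start = start[i] + gene_length %/% 4L,
                                 end = end[i], strand = tx$strand[1],
                                 stringsAsFactors = FALSE))
    }
    tx
  })
  transcripts <- do.call(rbind, tx_list)
  rownames(transcripts) <- NULL

  seqs <- as.character(genome)
  site_list <- lapply(seq_len(n_genes), function(i) {
    bin_lo <- start[i] - flank
    bin_hi <- end[i] + flank
    sub <- substr(seqs[[chrom[i]]], bin_lo + 1L, bin_hi)
    cg_pos <- gregexpr("CG", sub, fixed = TRUE)[[1]]
    if (cg_pos[1] == -1L) return(NULL)
    pos0 <- bin_lo + as.integer(cg_pos) - 1L
    rate <- min(1, site_prob * set_multipliers[[gene_set[i]]])
    keep <- runif(length(pos0)) < rate
    if (!any(keep)) return(NULL)
    data.frame(chrom = chrom[i], pos = pos0[keep], count = 1L,
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_list)
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL

  sets <- data.frame(gene_id = gene_id, set = gene_set, stringsAsFactors = FALSE)
  out <- list(genome = genome, sites = sites, transcripts = transcripts,
              sets = sets)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- list(
      genome = file.path(out_dir, "genome.fa"),
      sites = file.path(out_dir, "sites.bed"),
      transcripts = file.path(out_dir, "transcripts.tsv"),
      sets = file.path(out_dir, "gene_sets.tsv")
    )
    Biostrings::writeXStringSet(genome, paths$genome, width = 80L)
    write.table(data.frame(sites$chrom, sites$pos, sites$pos + 1L, sites$count),
                paths$sites, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write.table(transcripts, paths$transcripts, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(sets, paths$sets, sep = "\t", quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  out
}
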