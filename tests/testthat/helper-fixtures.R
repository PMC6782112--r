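# Small in-code fixtures shared across test files.

# A hand-built two-sister track table (frames at 10-min intervals).
make_sister_tracks <- function() {
  data.frame(
    cell_id = c("A", "B"),
    lineage_id = c("L1", "L1"),
    parent_id = c(NA_character_, NA_character_),
    sister_id = c("B", "A"),
    condition = c("ctrl", "ctrl"),
    frame_interval_minutes = c(10, 10),
    division_frame = c(100L, 100L),
    red_on_frame = c(100L, 101L),
    red_off_frame = c(146L, 150L),
    green_on_frame = c(136L, 137L),
    green_off_frame = c(326L, 340L),
    stringsAsFactors = FALSE
  )
}

# Minimal records table with uncensored G1 for sister-pair tests.
make_records <- function(g1, sister_of = NULL, censored = NULL) {
  n <- length(g1)
  ids <- sprintf("c%02d", seq_len(n))
  sister <- if (is.null(sister_of)) rep(NA_character_, n) else ids[sister_of]
  if (is.null(censored)) censored <- rep(FALSE, n)
  data.frame(
    cell_id = ids, lineage_id = ids, sister_id = sister, condition = "x",
    frame_interval_minutes = 10, g1_hours = g1, sg2m_hours = NA_real_,
    early_g1_minutes = 0, g1_censored = censored, sg2m_censored = TRUE,
    early_g1_censored = FALSE, stringsAsFactors = FALSE
  )
}

# Per-cell data frame (condition, axin2, g1_hours) from a simulated dose
# series, for model-fit tests.
dose_series_cells <- function(seed, ...) {
  cfg <- sim_config(seed = seed)
  ds <- simulate_dose_series(cfg, ...)
  rec <- derive_phase_lengths(ds$tracks)
  rec <- rec[!rec$g1_censored, ]
  ax <- setNames(ds$conditions$axin2_level, ds$conditions$label)
  data.frame(condition = rec$condition, axin2 = unname(ax[rec$condition]),
             g1_hours = rec$g1_hours, stringsAsFactors = FALSE)
}
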