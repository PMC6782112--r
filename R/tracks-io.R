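#' Column layout of a FUCCI track table
#'
#' One row per tracked cell. Frame indices are 0-based; an event "on at frame
#' k" means the first frame at which the color is visible. Missing events
#' (unobserved because the movie ended, or never scored) are encoded by an
#' empty field by default.
#'
#' @return Character vector of required column names, in canonical order.
#' @export
track_columns <- function() {
  c("cell_id", "lineage_id", "parent_id", "sister_id", "condition",
    "frame_interval_minutes", "division_frame", "red_on_frame",
    "red_off_frame", "green_on_frame", "green_off_frame")
}

frame_cols <- function() {
  c("division_frame", "red_on_frame", "red_off_frame",
    "green_on_frame", "green_off_frame")
}

#' Read a FUCCI track table
#'
#' Reads a TSV/CSV of per-cell FUCCI color-event frames, validates frame
#' ordering invariants and sister-link symmetry, and returns a data frame of
#' tracks (one `PhaseTrack` per row, row order preserved).
#'
#' @param path Path to a delimited text file with a header containing all of
#'   [track_columns()].
#' @param sep Field separator. Default `NULL` chooses `","` for `.csv` files
#'   and tab otherwise.
#' @param na Sentinel string marking a missing (censored/unobserved) event.
#' @return A `data.frame` with the columns of [track_columns()]; identifier
#'   columns are character, frame columns integer (`NA` = missing event).
#' @export
read_track_table <- function(path, sep = NULL, na = "") {
  if (!file.exists(path)) stop("track table not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.table(path, header = TRUE, sep = sep, na.strings = na,
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "")
  missing_cols <- setdiff(track_columns(), names(raw))
  if (length(missing_cols) > 0) {
    stop("track table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tracks <- raw[, track_columns()]
  tracks$frame_interval_minutes <- as.numeric(tracks$frame_interval_minutes)
  for (col in frame_cols()) {
    v <- tracks[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & (is.na(num) | num != round(num))
    if (any(bad)) {
      stop("non-integer frame index in column '", col, "' for cell(s): ",
           paste(tracks$cell_id[bad], collapse = ", "))
    }
    tracks[[col]] <- as.integer(num)
  }
  validate_tracks(tracks)
  tracks
}

#' Validate a track table
#'
#' Checks the `PhaseTrack` invariants: positive frame interval, non-negative
#' frames, event ordering (`division <= red_on <= green_on`,
#' `red_off <= green_off` where both ends are observed) and symmetry of the
#' sister relation. Called by [read_track_table()]; exported so simulated or
#' hand-built tables can be checked too.
#'
#' @param tracks A track `data.frame` as returned by [read_track_table()].
#' @return `tracks`, invisibly, if valid; otherwise an error naming the
#'   offending cell(s).
#' @export
validate_tracks <- function(tracks) {
  if (any(duplicated(tracks$cell_id))) {
    stop("duplicated cell_id: ",
         paste(unique(tracks$cell_id[duplicated(tracks$cell_id)]), collapse = ", "))
  }
  if (any(!is.finite(tracks$frame_interval_minutes) |
          tracks$frame_interval_minutes <= 0)) {
    stop("frame_interval_minutes must be > 0")
  }
  for (col in frame_cols()) {
    bad <- !is.na(tracks[[col]]) & tracks[[col]] < 0L
    if (any(bad)) {
      stop("negative frame index in '", col, "' for cell(s): ",
           paste(tracks$cell_id[bad], collapse = ", "))
    }
  }
  check_order <- function(a, b, what) {
    bad <- !is.na(tracks[[a]]) & !is.na(tracks[[b]]) & tracks[[a]] > tracks[[b]]
    if (any(bad)) {
      stop("event order violation (", what, ") for cell(s): ",
           paste(tracks$cell_id[bad], collapse = ", "))
    }
  }
  check_order("division_frame", "red_on_frame", "division <= red on")
  check_order("red_on_frame", "green_on_frame", "red on <= green on")
  check_order("red_off_frame", "green_off_frame", "red off <= green off")

  has_sister <- !is.na(tracks$sister_id) & tracks$sister_id != ""
  if (any(has_sister)) {
    idx <- match(tracks$sister_id[has_sister], tracks$cell_id)
    if (anyNA(idx)) {
      stop("sister_id points to a missing cell for cell(s): ",
           paste(tracks$cell_id[has_sister][is.na(idx)], collapse = ", "))
    }
    back <- tracks$sister_id[idx]
    bad <- is.na(back) | back != tracks$cell_id[has_sister]
    if (any(bad)) {
      stop("asymmetric sister link for cell(s): ",
           paste(tracks$cell_id[has_sister][bad], collapse = ", "))
    }
  }
  invisible(tracks)
}

#' Write a track table
#'
#' TSV with the fixed column order of [track_columns()]; missing events are
#' written as the `na` sentinel. `read_track_table(write_track_table(x))`
#' round-trips losslessly.
#'
#' @param tracks A track `data.frame`.
#' @param path Output path.
#' @param na Sentinel used for missing events.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(tracks, path, na = "") {
  write.table(tracks[, track_columns()], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = na)
  invisible(path)
}

#' Derive absolute phase lengths from color-event frames
#'
#' Converts FUCCI event frames into per-cell phase lengths:
#' G1 runs from red-on to green-on, S/G2/M from red-off to green-off, and
#' early G1 (the no-color window, sub-frame in most cells) from division to
#' red-on. A phase whose defining events are not both observed is marked
#' censored and its length left `NA`; downstream distribution operations use
#' only uncensored lengths. Early G1 is reported in minutes and never added
#' to `g1_hours` (G1 is defined to start at red-on).
#'
#' @param tracks A validated track `data.frame`.
#' @return A `data.frame` of cell-cycle records with columns `cell_id`,
#'   `lineage_id`, `sister_id`, `condition`, `frame_interval_minutes`,
#'   `g1_hours`, `sg2m_hours`, `early_g1_minutes`, and logical censoring flags
#'   `g1_censored`, `sg2m_censored`, `early_g1_censored`.
#' @export
derive_phase_lengths <- function(tracks) {
  validate_tracks(tracks)
  dt <- tracks$frame_interval_minutes
  g1_frames <- tracks$green_on_frame - tracks$red_on_frame
  sg2m_frames <- tracks$green_off_frame - tracks$red_off_frame
  early_frames <- tracks$red_on_frame - tracks$division_frame
  neg <- function(x) !is.na(x) & x < 0
  if (any(neg(g1_frames) | neg(sg2m_frames) | neg(early_frames))) {
    bad <- neg(g1_frames) | neg(sg2m_frames) | neg(early_frames)
    stop("negative phase length for cell(s): ",
         paste(tracks$cell_id[bad], collapse = ", "))
  }
  data.frame(
    cell_id = tracks$cell_id,
    lineage_id = tracks$lineage_id,
    sister_id = tracks$sister_id,
    condition = tracks$condition,
    frame_interval_minutes = dt,
    g1_hours = g1_frames * dt / 60,
    sg2m_hours = sg2m_frames * dt / 60,
    early_g1_minutes = early_frames * dt,
    g1_censored = is.na(g1_frames),
    sg2m_censored = is.na(sg2m_frames),
    early_g1_censored = is.na(early_frames),
    stringsAsFactors = FALSE
  )
}

record_columns <- function() {
  c("cell_id", "lineage_id", "sister_id", "condition",
    "frame_interval_minutes", "g1_hours", "sg2m_hours", "early_g1_minutes",
    "g1_censored", "sg2m_censored", "early_g1_censored")
}

#' Write cell-cycle records
#'
#' TSV with fixed column order; see [derive_phase_lengths()] for the schema.
#'
#' @param records Record `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  write.table(records[, intersect(record_columns(), names(records))], path,
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read cell-cycle records written by [write_records()]
#'
#' @param path Path to a records TSV.
#' @return Record `data.frame`.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("records file not found: ", path)
  rec <- read.table(path, header = TRUE, sep = "\t", na.strings = "",
                    stringsAsFactors = FALSE, quote = "")
  for (col in c("g1_censored", "sg2m_censored", "early_g1_censored")) {
    if (col %in% names(rec)) rec[[col]] <- as.logical(rec[[col]])
  }
  rec
}
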