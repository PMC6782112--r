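#' Pair sister cells and compute the G1 asymmetry ratio
#'
#' Builds one row per unordered sister pair from the `sister_id` links of a
#' records table and computes the asymmetry ratio
#' \eqn{|G1_a - G1_b| / ((G1_a + G1_b)/2)}, i.e. the absolute sister G1
#' difference divided by the sisters' mean G1. Pairs in which either sister
#' has a censored G1 are dropped and counted in the `n_dropped_censored`
#' attribute.
#'
#' @param records Records `data.frame` from [derive_phase_lengths()] with
#'   symmetric `sister_id` links.
#' @return `data.frame` with `cell_a`, `cell_b`, `g1_a`, `g1_b`,
#'   `delta_ratio`; attribute `n_dropped_censored` counts pairs lost to
#'   censoring. `delta_ratio` lies in `[0, 2)` and is 0 iff the sisters'
#'   G1 lengths are equal.
#' @export
pair_and_score <- function(records) {
  has_sister <- !is.na(records$sister_id) & records$sister_id != ""
  linked <- records[has_sister, , drop = FALSE]
  idx <- match(linked$sister_id, records$cell_id)
  if (anyNA(idx)) {
    stop("sister_id points to a missing cell for cell(s): ",
         paste(linked$cell_id[is.na(idx)], collapse = ", "))
  }
  back <- records$sister_id[idx]
  if (any(is.na(back) | back != linked$cell_id)) {
    stop("asymmetric sister link for cell(s): ",
         paste(linked$cell_id[is.na(back) | back != linked$cell_id], collapse = ", "))
  }
  if (any(duplicated(linked$cell_id))) {
    stop("cell paired twice: ",
         paste(unique(linked$cell_id[duplicated(linked$cell_id)]), collapse = ", "))
  }
  # each unordered pair once: keep the member that sorts first
  first <- linked$cell_id < linked$sister_id
  a <- linked[first, , drop = FALSE]
  b_idx <- match(a$sister_id, records$cell_id)
  b <- records[b_idx, , drop = FALSE]
  ok <- !a$g1_censored & !b$g1_censored & !is.na(a$g1_hours) & !is.na(b$g1_hours)
  n_dropped <- sum(!ok)
  a <- a[ok, , drop = FALSE]; b <- b[ok, , drop = FALSE]
  pairs <- data.frame(
    cell_a = a$cell_id, cell_b = b$cell_id,
    g1_a = a$g1_hours, g1_b = b$g1_hours,
    delta_ratio = abs(a$g1_hours - b$g1_hours) / ((a$g1_hours + b$g1_hours) / 2),
    stringsAsFactors = FALSE
  )
  rownames(pairs) <- NULL
  attr(pairs, "n_dropped_censored") <- n_dropped
  pairs
}

#' Classify sister pairs as symmetric or asymmetric
#'
#' A pair is asymmetric when its `delta_ratio` exceeds the cutoff; pairs
#' exactly at the cutoff count as symmetric (the symmetric class is closed at
#' the boundary). The default cutoff 0.2 separates sisters whose G1 lengths
#' differ by more than 20% of their mean.
#'
#' @param pairs Pairs `data.frame` from [pair_and_score()].
#' @param cutoff Dimensionless asymmetry cutoff (default 0.2).
#' @return List with `fraction_symmetric`, `fraction_asymmetric` (summing to
#'   1) and `n_pairs`.
#' @export
classify_pairs <- function(pairs, cutoff = 0.2) {
  if (nrow(pairs) == 0) stop("insufficient data: no sister pairs")
  asym <- mean(pairs$delta_ratio > cutoff)
  list(fraction_symmetric = 1 - asym, fraction_asymmetric = asym,
       n_pairs = nrow(pairs))
}

#' Asymmetric fraction across sliding cutoffs
#'
#' Applies [classify_pairs()] at each cutoff. Cutoffs are sorted and
#' de-duplicated; the resulting asymmetric fraction is non-increasing in the
#' cutoff by construction.
#'
#' @param pairs Pairs `data.frame` from [pair_and_score()].
#' @param cutoffs Vector of dimensionless cutoffs (default 0.1 to 0.5 by 0.1).
#' @return `data.frame` with `cutoff` and `fraction_asymmetric`; attribute
#'   `n_pairs`.
#' @export
sliding_profile <- function(pairs, cutoffs = seq(0.1, 0.5, by = 0.1)) {
  cutoffs <- sort(unique(cutoffs))
  frac <- vapply(cutoffs, function(co) classify_pairs(pairs, co)$fraction_asymmetric,
                 numeric(1))
  out <- data.frame(cutoff = cutoffs, fraction_asymmetric = frac)
  attr(out, "n_pairs") <- nrow(pairs)
  out
}

#' Sister-sister G1 correlation
#'
#' Pearson correlation of G1 lengths across sister pairs. Because each pair
#' is unordered, a naive (a, b) assignment is order-dependent; by default the
#' assignment is randomized once per pair under a fixed seed.
#' `method = "double_entry"` instead enters every pair twice, once in each
#' orientation (symmetrized estimate).
#'
#' @param pairs Pairs `data.frame` from [pair_and_score()].
#' @param method `"randomized"` (default) or `"double_entry"`.
#' @param seed Seed for the randomized orientation.
#' @return List with `r`, `n_pairs`, `method`.
#' @export
sister_correlation <- function(pairs, method = c("randomized", "double_entry"),
                               seed = 1L) {
  method <- match.arg(method)
  if (nrow(pairs) < 3) stop("insufficient data: need at least 3 pairs")
  if (method == "randomized") {
    old <- .Random.seed_exists()
    set.seed(seed)
    swap <- runif(nrow(pairs)) < 0.5
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    x <- ifelse(swap, pairs$g1_b, pairs$g1_a)
    y <- ifelse(swap, pairs$g1_a, pairs$g1_b)
  } else {
    x <- c(pairs$g1_a, pairs$g1_b)
    y <- c(pairs$g1_b, pairs$g1_a)
  }
  if (sd(x) == 0 || sd(y) == 0) stop("undefined correlation: zero variance")
  list(r = cor(x, y), n_pairs = nrow(pairs), method = method)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  } else {
    NULL
  }
}
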