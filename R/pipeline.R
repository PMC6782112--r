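#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> derive -> distribution statistics ->
#' sister asymmetry -> shifted-Poisson model into a write-once output
#' directory with a JSON manifest (versions, seed, config, file hashes).
#' Re-running with the same config and inputs reproduces identical numeric
#' outputs and hashes.
#'
#' The config is a named list (or a YAML file with the same structure):
#' \preformatted{
#' seed: 1
#' out_dir: path/
#' tracks: path/to/tracks.tsv        # either this ...
#' simulate: true                    # ... or simulation from `conditions`
#' conditions: {label: [...], axin2_level: [...], n_cells: [...]}
#' stats: true
#' sisters: true
#' model: true
#' g1_split_hours: 6
#' asym_cutoff: 0.2
#' }
#'
#' @param config Named list or path to a YAML file.
#' @return The manifest (named list), invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(seed = 1L, stats = TRUE, sisters = TRUE, model = TRUE,
                   hmc = FALSE, g1_split_hours = 6, asym_cutoff = 0.2,
                   simulate = is.null(config$tracks))
  config <- utils::modifyList(defaults, config)
  if (is.null(config$out_dir)) stop("config needs an out_dir")
  if (!is.null(config$tracks) && isTRUE(config$simulate)) {
    stop("provide either input tracks or a simulation config, not both")
  }
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  stage <- "input"
  manifest <- list(
    package = "g1dist",
    version = as.character(utils::packageVersion("g1dist")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    files = list()
  )
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    outputs <<- c(outputs, path)
    path
  }
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(e)
      manifest$files <<- as.list(setNames(unname(tools::md5sum(outputs)),
                                          basename(outputs)))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (partial manifest written)", call. = FALSE)
    })
  }

  # --- data -----------------------------------------------------------------
  conditions <- NULL
  tracks <- run_stage("data", {
    if (isTRUE(config$simulate)) {
      cond <- if (is.null(config$conditions)) default_study_conditions()
              else as.data.frame(config$conditions, stringsAsFactors = FALSE)
      cfg_args <- config[intersect(names(config), names(formals(sim_config)))]
      cfg_args$conditions <- cond
      cfg <- do.call(sim_config, cfg_args)
      conditions <- cond
      sim <- simulate_study(cfg)
      emit("tracks.tsv", function(p) write_track_table(sim$tracks, p))
      sim$tracks
    } else {
      tr <- read_track_table(config$tracks)
      conditions <- data.frame(label = unique(tr$condition),
                                stringsAsFactors = FALSE)
      if (!is.null(config$conditions)) {
        conditions <- as.data.frame(config$conditions, stringsAsFactors = FALSE)
      }
      tr
    }
  })
  records <- run_stage("derive", {
    rec <- derive_phase_lengths(tracks)
    emit("records.tsv", function(p) write_records(rec, p))
    rec
  })

  results <- list()

  if (isTRUE(config$stats)) {
    results$stats <- run_stage("stats", {
      by_cond <- split(records, records$condition)
      summaries <- lapply(by_cond, function(r) {
        v <- r$g1_hours[!r$g1_censored]
        if (length(v) >= 2) unclass(summarize_lengths(v)) else NULL
      })
      labels <- names(by_cond)
      tests <- list()
      if (length(labels) >= 2) {
        combos <- utils::combn(labels, 2)
        tests <- lapply(seq_len(ncol(combos)), function(i) {
          a <- by_cond[[combos[1, i]]]; b <- by_cond[[combos[2, i]]]
          va <- a$g1_hours[!a$g1_censored]; vb <- b$g1_hours[!b$g1_censored]
          if (length(va) < 2 || length(vb) < 2) return(NULL)
          ks <- ks_two_sample(va, vb); u <- mannwhitney_u(va, vb)
          list(pair = combos[, i],
               ks = list(D = ks$statistic, p = ks$p_value, p_label = ks$p_label),
               mwu = list(U = u$statistic, p = u$p_value, p_label = u$p_label))
        })
      }
      split6 <- lapply(by_cond, function(r) {
        sp <- split_by_cutoff(r, config$g1_split_hours)
        list(n_below = length(sp$below), n_above = length(sp$above),
             cv_below = if (!is.null(sp$summary_below)) sp$summary_below$cv else NA,
             cv_above = if (!is.null(sp$summary_above)) sp$summary_above$cv else NA)
      })
      st <- list(summaries = summaries, tests = tests, split = split6)
      emit("stats.json", function(p) jsonlite::write_json(st, p, auto_unbox = TRUE,
                                                          digits = NA, pretty = TRUE))
      st
    })
  }

  if (isTRUE(config$sisters)) {
    results$sisters <- run_stage("sisters", {
      by_cond <- split(records, records$condition)
      sis <- lapply(by_cond, function(r) {
        pairs <- pair_and_score(r)
        if (nrow(pairs) == 0) return(NULL)
        prof <- sliding_profile(pairs)
        list(n_pairs = nrow(pairs),
             n_dropped_censored = attr(pairs, "n_dropped_censored"),
             classification = classify_pairs(pairs, config$asym_cutoff),
             profile = prof,
             correlation = if (nrow(pairs) >= 3)
               sister_correlation(pairs, seed = config$seed)$r else NA)
      })
      emit("sisters.json", function(p) jsonlite::write_json(sis, p, auto_unbox = TRUE,
                                                            digits = NA, pretty = TRUE))
      sis
    })
  }

  if (isTRUE(config$model)) {
    results$model <- run_stage("model", {
      axin2 <- setNames(conditions$axin2_level, conditions$label)
      if (is.null(conditions$axin2_level)) {
        stop("model stage needs AXIN2 levels in the condition table")
      }
      ok <- !records$g1_censored
      cells <- data.frame(condition = records$condition[ok],
                          axin2 = unname(axin2[records$condition[ok]]),
                          g1_hours = records$g1_hours[ok])
      c_shift <- pooled_shift(cells$g1_hours)
      model <- fit_wnt_g1_glm(cells, c_shift)
      diag <- model_diagnostics(pmax(cells$g1_hours - c_shift, 0))
      mj <- list(c_shift = model$c_shift, beta0 = model$beta0, beta1 = model$beta1,
                 adj_r2 = model$adj_r2, dispersion_ratio = model$dispersion_ratio,
                 beta2_p = model$beta2_p, lambda_max = diag$lambda_max,
                 meta = model$meta)
      emit("model.json", function(p) jsonlite::write_json(mj, p, auto_unbox = TRUE,
                                                          digits = NA, pretty = TRUE))
      c(mj, list(object = model, diagnostics = diag))
    })
  }

  stage <- "manifest"
  manifest$files <- as.list(setNames(unname(tools::md5sum(outputs)),
                                     basename(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(manifest, list(results = results)))
}
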