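required_cell_columns <- function() {
  c("cell_id", "slide_id", "tile_id", "x_um", "y_um")
}

#' Read / write single-cell tables
#'
#' Cell tables are CSV files with columns `cell_id`, `slide_id`,
#' `tile_id`, `x_um`, `y_um`, one column per marker intensity, and any
#' number of extra columns (`true_phenotype`, `layer`, ...), which are
#' preserved untouched. Intensities round-trip to at least 6 significant
#' digits.
#'
#' @param path file path.
#' @param cells data.frame to write.
#' @return `read_cell_table` returns the data.frame;
#'   `write_cell_table` returns `path` invisibly.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(required_cell_columns(), names(df))
  if (length(miss))
    stop("cell table ", path, " missing required column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("x_um", "y_um")) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) &
                   !is.na(df[[col]]))
    if (length(bad))
      stop("malformed value in column ", col, " at data line ", bad[1],
           " of ", path)
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' @rdname read_cell_table
#' @export
write_cell_table <- function(cells, path) {
  miss <- setdiff(required_cell_columns(), names(cells))
  if (length(miss))
    stop("cell table missing required column(s): ",
         paste(miss, collapse = ", "))
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

provenance_header <- function(manifest) {
  sprintf("# wallplex run %s | config sha %s | seed %d | %s",
          manifest$run_id, manifest$config_hash, manifest$seed,
          format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

write_result_csv <- function(df, path, manifest) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(manifest), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# Stable content hash of the configuration (FNV-1a over the deparse).
config_hash <- function(config) {
  txt <- paste(deparse(config, control = "exact"), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration: simulate a cohort (or take one as given),
#' gate both panels, summarize every slide per layer, detect TLS, run the
#' nearest-neighbor analysis, and compute the cohort statistics. When
#' `output_dir` is given, every table is written as CSV with a provenance
#' header (run id, configuration hash, seed). Re-running the same
#' configuration reproduces identical outputs.
#'
#' @param config a [cohort_config()]; ignored when `cohort` is supplied.
#' @param cohort optional pre-generated `wp_cohort`.
#' @param output_dir optional directory for result CSVs.
#' @param nn_from,nn_to phenotype rules for the nearest-neighbor stage.
#' @param verbose print per-stage progress to stderr.
#' @return Object of class `wp_results`: list with `summary` (slide
#'   summaries), `tls_records`, `tls_stats` (per group),
#'   `fold_changes`, `cd4_cd8` (per slide), `nn_results`,
#'   `nn_comparison`, `intima_pooled`, `manifest`, `config`.
#' @export
run_pipeline <- function(config = default_cohort_config(), cohort = NULL,
                         output_dir = NULL, nn_from = "CD68+CD206-",
                         nn_to = "CD31+CD68-", verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, slide, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed",
           if (!is.na(slide)) paste0(" on slide ", slide) else "",
           ": ", conditionMessage(e), call. = FALSE))
  }
  if (is.null(cohort)) {
    stopifnot(inherits(config, "cohort_config"))
    if (sum(vapply(config$groups, `[[`, numeric(1), "n_slides")) == 0)
      stop("manifest has zero slides")
    say("simulate: generating cohort (seed %d)", config$master_seed)
    cohort <- stage("simulate", NA, generate_cohort(config))
  } else config <- cohort$config
  if (!length(cohort$slides)) stop("manifest has zero slides")
  analysis <- config$analysis
  geometry <- config$geometry

  say("gate/quantify: %d slides", length(cohort$slides))
  sq <- stage("gate", NA, summarize_cohort(cohort, analysis))
  gated <- sq$cells
  summary <- sq$summary

  say("tls: detecting lymphoid structures")
  tls_records <- list()
  for (sl in cohort$slides) {
    det <- stage("tls", sl$slide_id,
                 detect_tls(gated[[sl$slide_id]], geometry, analysis,
                            slide_id = sl$slide_id))
    if (nrow(det$records)) {
      det$records$group <- sl$group
      tls_records[[sl$slide_id]] <- det$records
    }
  }
  tls_records <- if (length(tls_records)) do.call(rbind, tls_records) else
    cbind(detect_tls(gated[[1]][0, ], geometry, analysis,
                     slide_id = NA)$records,
          group = character(0))
  rownames(tls_records) <- NULL
  tls_stats <- list()
  for (g in names(config$groups)) {
    ids <- cohort$manifest$slide_id[cohort$manifest$group == g &
                                      cohort$manifest$adventitia_quantifiable]
    if (length(ids))
      tls_stats[[g]] <- tls_group_stats(tls_records, ids)
  }

  say("neighbors: %s -> %s", nn_from, nn_to)
  nn <- lapply(cohort$slides, function(sl) {
    r <- stage("neighbors", sl$slide_id,
               median_min_distance(gated[[sl$slide_id]], geometry,
                                   from = nn_from, to = nn_to,
                                   min_count = analysis$nn_min_count))
    r$group <- sl$group
    r
  })
  nn_results <- do.call(rbind, nn)
  rownames(nn_results) <- NULL
  nn_comparison <- if (length(unique(nn_results$group)) >= 2L)
    cohort_nn_comparison(nn_results) else NULL

  say("stats: fold changes and per-slide ratios")
  groups <- names(config$groups)
  fold_changes <- NULL
  if (all(c("non_dilated", "dilated") %in% groups)) {
    fc <- function(ph) group_fold_change(summary, ph, "adventitia",
                                         "non_dilated", "dilated")
    fold_changes <- data.frame(
      phenotype = c("lymphocyte", "b_cell", "macrophage_all"),
      layer = "adventitia", groups = "dilated/non_dilated",
      fold_change = c(fc("lymphocyte"), fc("b_cell"), fc("macrophage_all")),
      stringsAsFactors = FALSE)
  }
  cd4_cd8 <- do.call(rbind, lapply(cohort$slides, function(sl) {
    s <- summary[summary$slide_id == sl$slide_id, ]
    ratio <- if (sl$quantifiable)
      suppressWarnings(cd4_cd8_ratio(s, "adventitia")) else NA_real_
    data.frame(slide_id = sl$slide_id, group = sl$group,
               cd4_cd8_adventitia = ratio, stringsAsFactors = FALSE)
  }))
  rownames(cd4_cd8) <- NULL
  # pooled intima composition across all slides and groups
  intima <- summary[summary$layer == "intima", ]
  pool <- function(ph) {
    r <- intima[intima$phenotype == ph, ]
    sum(r$count, na.rm = TRUE)
  }
  tot_intima <- sum(intima$total_cells[intima$phenotype == "immune"])
  intima_pooled <- data.frame(
    phenotype = c("immune", "m1_macrophage"),
    count = c(pool("immune"), pool("m1_macrophage")),
    total = tot_intima,
    fraction = c(pool("immune"), pool("m1_macrophage")) / tot_intima,
    stringsAsFactors = FALSE)

  manifest <- list(run_id = sprintf("run_%d", config$master_seed),
                   config_hash = config_hash(config),
                   seed = config$master_seed,
                   n_slides = length(cohort$slides))
  out <- structure(list(summary = summary, tls_records = tls_records,
                        tls_stats = tls_stats, fold_changes = fold_changes,
                        cd4_cd8 = cd4_cd8, nn_results = nn_results,
                        nn_comparison = nn_comparison,
                        intima_pooled = intima_pooled,
                        manifest = manifest, config = config),
                   class = "wp_results")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_csv(summary, file.path(output_dir, "slide_summary.csv"),
                     manifest)
    write_result_csv(tls_records, file.path(output_dir, "tls_records.csv"),
                     manifest)
    write_result_csv(nn_results, file.path(output_dir, "nn_results.csv"),
                     manifest)
    write_result_csv(cd4_cd8, file.path(output_dir, "cd4_cd8.csv"),
                     manifest)
    if (!is.null(fold_changes))
      write_result_csv(fold_changes,
                       file.path(output_dir, "fold_changes.csv"), manifest)
  }
  out
}

#' @export
print.wp_results <- function(x, ...) {
  cat("<wp_results> ", x$manifest$n_slides, " slides, run ",
      x$manifest$run_id, " (config ", x$manifest$config_hash, ")\n",
      sep = "")
  if (!is.null(x$fold_changes)) {
    cat("  adventitial fold changes (dilated / non-dilated, group medians of % of all cells):\n")
    for (i in seq_len(nrow(x$fold_changes)))
      cat(sprintf("    %-15s %.2fx\n", x$fold_changes$phenotype[i],
                  x$fold_changes$fold_change[i]))
  }
  for (g in names(x$tls_stats)) {
    ts <- x$tls_stats[[g]]
    cat(sprintf("  TLS [%s]: prevalence %.2f, %.2f per positive slide, mean distance to media %.0f um\n",
                g, ts$prevalence,
                ifelse(is.na(ts$mean_per_positive_slide), 0,
                       ts$mean_per_positive_slide),
                ifelse(is.na(ts$mean_distance_um), NA,
                       ts$mean_distance_um)))
  }
  if (!is.null(x$nn_comparison) &&
      inherits(x$nn_comparison, "group_comparison"))
    cat(sprintf("  NN comparison (Kruskal-Wallis): H = %.3f, p = %.3f\n",
                x$nn_comparison$statistic, x$nn_comparison$p))
  invisible(x)
}
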