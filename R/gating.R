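#' Adaptive threshold for a gradually expressed marker
#'
#' CD45RO and MMP9 have no separated positive population, so they cannot be
#' gated with a fixed valley threshold. Instead, cells matching a
#' negative-control rule (by default: negative for every non-gradual
#' lineage marker of the panel, i.e. non-immune cells) define a negative
#' population, and the threshold is a high quantile (nearest-rank) of that
#' population's intensity: cells above it are called positive.
#'
#' @param cells cell table with one intensity column per marker.
#' @param marker gradual marker name (an intensity column of `cells`).
#' @param negative_population logical vector selecting the negative-control
#'   cells, or `NULL` to use the default rule via `panel` and `thresholds`
#'   (all non-gradual panel markers below their fixed thresholds).
#' @param quantile_p quantile of the negative population (default 0.995).
#' @param panel,thresholds used only when `negative_population` is `NULL`.
#' @param min_negative minimum negative-population size; below it an error
#'   instructs the caller to use a fixed fallback threshold from
#'   configuration.
#' @return Threshold value (numeric scalar).
#' @examples
#' cells <- data.frame(CD45RO = 1:100)
#' compute_gradual_threshold(cells, "CD45RO", rep(TRUE, 100),
#'                           quantile_p = 0.95, min_negative = 50)
#' @export
compute_gradual_threshold <- function(cells, marker,
                                      negative_population = NULL,
                                      quantile_p = 0.995,
                                      panel = NULL, thresholds = NULL,
                                      min_negative = 50L) {
  if (!marker %in% names(cells)) stop("missing marker column: ", marker)
  if (is.null(negative_population)) {
    stopifnot(inherits(panel, "marker_panel"), !is.null(thresholds))
    lineage <- setdiff(panel$markers, panel$gradual_markers)
    negative_population <- rep(TRUE, nrow(cells))
    for (m in lineage)
      negative_population <- negative_population &
        cells[[m]] <= thresholds[[m]]
  }
  v <- cells[[marker]][negative_population]
  if (length(v) < min_negative)
    stop("only ", length(v), " negative-control cells for ", marker,
         " (need >= ", min_negative,
         "); use a fixed fallback threshold from configuration")
  unname(stats::quantile(v, quantile_p, type = 1))  # nearest-rank
}

#' Fixed and adaptive thresholds for a panel
#'
#' Bimodal markers get the fixed configuration threshold; gradual markers
#' get per-slide adaptive thresholds from [compute_gradual_threshold()].
#'
#' @param cells cell table of one slide.
#' @param panel a [marker_panel()].
#' @param analysis an [analysis_config()].
#' @return Named numeric vector of per-marker thresholds.
#' @export
default_thresholds <- function(cells, panel, analysis = analysis_config()) {
  stopifnot(inherits(panel, "marker_panel"))
  thr <- setNames(rep(analysis$fixed_threshold, length(panel$markers)),
                  panel$markers)
  for (m in panel$gradual_markers)
    thr[[m]] <- compute_gradual_threshold(
      cells, m, quantile_p = analysis$gradual_quantile,
      panel = panel, thresholds = thr)
  thr
}

#' Binarize marker intensities against thresholds
#'
#' Strictly-greater-than comparison: an intensity exactly equal to its
#' threshold is negative (deterministic tie-break).
#'
#' @param cells cell table with intensity columns.
#' @param thresholds named numeric vector; every requested marker needs a
#'   threshold and an intensity column, otherwise an error is raised.
#' @param markers markers to binarize (default: names of `thresholds`).
#' @return Logical matrix (cells x markers).
#' @export
binarize_markers <- function(cells, thresholds, markers = names(thresholds)) {
  miss <- setdiff(markers, names(cells))
  if (length(miss)) stop("missing marker value(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(markers, names(thresholds))
  if (length(miss)) stop("missing threshold(s): ",
                         paste(miss, collapse = ", "))
  out <- vapply(markers, function(m) cells[[m]] > thresholds[[m]],
                logical(nrow(cells)))
  if (nrow(cells) == 1L) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, markers))
  out
}

#' Gate a panel: assign each cell its most specific phenotype
#'
#' Rules are evaluated in panel order (most specific first); the first rule
#' whose required-positive and required-negative markers all match wins.
#' Cells positive for a mutually exclusive lineage-marker pair (e.g.
#' CD3 and CD20) are labeled `"ambiguous"` (segmentation doublets) and
#' excluded from phenotype counts downstream; cells matching no rule are
#' `"other"`. Rules requiring a masked marker (e.g. FoxP3 in a post-mortem
#' group) are skipped entirely.
#'
#' @param cells cell table with intensity columns for every panel marker.
#' @param panel a [marker_panel()].
#' @param thresholds named per-marker thresholds (see
#'   [default_thresholds()]); computed from `cells` when `NULL`.
#' @param masked_markers markers treated as unavailable.
#' @param analysis an [analysis_config()] (used when `thresholds` is NULL).
#' @return `cells` with added columns `phenotype` (leaf label) and one
#'   logical `<marker>_pos` column per (unmasked) panel marker.
#' @examples
#' pan <- panel_adaptive()
#' cells <- data.frame(CD3 = c(100, 100, 1), CD8 = c(1, 100, 1),
#'                     CD20 = 1, CD1c = 1, FoxP3 = 1, CD45RO = 1)
#' thr <- setNames(rep(15, 6), pan$markers)
#' gate_panel(cells, pan, thr)$phenotype
#' @export
gate_panel <- function(cells, panel, thresholds = NULL,
                       masked_markers = character(),
                       analysis = analysis_config()) {
  stopifnot(inherits(panel, "marker_panel"))
  if (is.null(thresholds))
    thresholds <- default_thresholds(cells, panel, analysis)
  markers <- setdiff(panel$markers, masked_markers)
  pos <- binarize_markers(cells, thresholds, markers)
  n <- nrow(cells)
  lab <- rep("other", n)
  assigned <- rep(FALSE, n)
  # segmentation doublets: mutually exclusive lineage markers both positive
  ambiguous <- rep(FALSE, n)
  for (pair in panel$exclusive_pairs) {
    if (all(pair %in% markers))
      ambiguous <- ambiguous | (pos[, pair[1]] & pos[, pair[2]])
  }
  lab[ambiguous] <- "ambiguous"
  assigned <- ambiguous
  for (r in panel$rules) {
    if (any(c(r$pos, r$neg) %in% masked_markers)) next
    m <- !assigned
    for (mk in r$pos) m <- m & pos[, mk]
    for (mk in r$neg) m <- m & !pos[, mk]
    lab[m] <- r$label
    assigned <- assigned | m
  }
  out <- cells
  out$phenotype <- lab
  for (mk in markers) out[[paste0(mk, "_pos")]] <- pos[, mk]
  attr(out, "panel") <- panel$name
  attr(out, "masked_markers") <- masked_markers
  out
}

#' Gate both panels on a slide
#'
#' Convenience wrapper: gates the adaptive and innate panels on the same
#' cell table (emulating serial sections of one slide), returning one table
#' with `phenotype_adaptive`, `phenotype_innate` and all positivity
#' columns.
#'
#' @inheritParams gate_panel
#' @param panels list of [marker_panel()]s.
#' @return Gated cell table.
#' @export
gate_slide <- function(cells, panels = list(panel_adaptive(), panel_innate()),
                       masked_markers = character(),
                       analysis = analysis_config()) {
  out <- cells
  for (pan in panels) {
    g <- gate_panel(cells, pan, masked_markers =
                      intersect(masked_markers, pan$markers),
                    analysis = analysis)
    out[[paste0("phenotype_", pan$name)]] <- g$phenotype
    for (cl in grep("_pos$", names(g), value = TRUE)) out[[cl]] <- g[[cl]]
  }
  out
}
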