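# Grid-indexed nearest-neighbor distances: for each query point the
# distance to the nearest reference point. Expanding-ring search over a
# bucket grid; exact (verified against the O(n^2) brute force).
grid_nn_dist <- function(qx, qy, rx, ry, cell = NULL) {
  nq <- length(qx); nr <- length(rx)
  if (nq == 0L) return(numeric(0))
  if (nr == 0L) return(rep(Inf, nq))
  if (is.null(cell)) {
    span <- max(max(rx) - min(rx), max(ry) - min(ry), 1)
    cell <- max(span / max(1, ceiling(sqrt(nr))), 1e-9)
  }
  gx <- floor(rx / cell); gy <- floor(ry / cell)
  buckets <- split(seq_len(nr), paste(gx, gy))
  out <- numeric(nq)
  for (i in seq_len(nq)) {
    cgx <- floor(qx[i] / cell); cgy <- floor(qy[i] / cell)
    best <- Inf
    ring <- 0L
    repeat {
      # scan ring at Chebyshev distance `ring` from the query bucket
      found_any <- FALSE
      bx <- seq.int(cgx - ring, cgx + ring)
      cand <- integer(0)
      if (ring == 0L) {
        b <- buckets[[paste(cgx, cgy)]]
        if (!is.null(b)) cand <- b
      } else {
        for (xx in bx) {
          for (yy in c(cgy - ring, cgy + ring)) {
            b <- buckets[[paste(xx, yy)]]
            if (!is.null(b)) cand <- c(cand, b)
          }
        }
        for (yy in seq.int(cgy - ring + 1L, cgy + ring - 1L)) {
          for (xx in c(cgx - ring, cgx + ring)) {
            b <- buckets[[paste(xx, yy)]]
            if (!is.null(b)) cand <- c(cand, b)
          }
        }
      }
      if (length(cand)) {
        d <- sqrt((rx[cand] - qx[i])^2 + (ry[cand] - qy[i])^2)
        best <- min(best, min(d))
      }
      # a point in a farther ring can still be closer than `best`
      # (bucket geometry), so expand until ring lower bound exceeds best
      if (is.finite(best) && (ring * cell) > best) break
      ring <- ring + 1L
      if (ring > 4L + ceiling(max(
        abs(cgx - floor(min(rx) / cell)), abs(cgx - floor(max(rx) / cell)),
        abs(cgy - floor(min(ry) / cell)), abs(cgy - floor(max(ry) / cell))))) {
        break  # scanned past every occupied bucket
      }
    }
    out[i] <- best
  }
  out
}

#' Median minimal distance between two phenotypes on a slide
#'
#' For every cell matching `from` the Euclidean distance to its nearest
#' cell matching `to` is found, and the per-slide median of those minimal
#' distances is returned. All tiles of the slide are merged before the
#' computation, so nearest neighbors are found across tile borders. Slides
#' with fewer than `min_count` cells of either phenotype are excluded
#' (flagged, not dropped silently) because of the high sampling error.
#' Defaults follow the M1-like macrophage (CD68+CD206-) to endothelium
#' (CD31+CD68-) analysis in the media and adventitia.
#'
#' @param cells gated cell table of one slide (positions plus `*_pos`
#'   positivity columns).
#' @param geometry a [layer_geometry()] used to restrict to `layers` and
#'   drop excluded-region cells.
#' @param from,to phenotype selectors: either a rule string like
#'   `"CD68+CD206-"` or a function of the cell table returning a logical
#'   vector.
#' @param layers layers included (default media + adventitia).
#' @param min_count exclusion threshold (default 150 cells per phenotype).
#' @return A one-row `data.frame`: slide_id, from, to, n_from, n_to,
#'   median_min_distance_um, excluded, reason.
#' @examples
#' cells <- data.frame(cell_id = c("a", "b"), slide_id = "s",
#'                     x_um = c(0, 3), y_um = c(0, 4),
#'                     CD68_pos = c(TRUE, FALSE), CD206_pos = FALSE,
#'                     CD31_pos = c(FALSE, TRUE))
#' g <- layer_geometry(100, 1, 50, 49)
#' median_min_distance(cells, g, layers = c("intima", "media",
#'                     "adventitia"), min_count = 1)
#' @export
median_min_distance <- function(cells, geometry,
                                from = "CD68+CD206-", to = "CD31+CD68-",
                                layers = c("media", "adventitia"),
                                min_count = 150) {
  sel_layer <- assign_layer(cells$x_um, cells$y_um, geometry) %in% layers
  fsel <- phenotype_selector(from)(cells) & sel_layer
  tsel <- phenotype_selector(to)(cells) & sel_layer
  n_from <- sum(fsel); n_to <- sum(tsel)
  from_lab <- if (is.character(from)) from else "custom"
  to_lab <- if (is.character(to)) to else "custom"
  excluded <- n_from < min_count || n_to < min_count
  med <- NA_real_
  if (!excluded) {
    d <- grid_nn_dist(cells$x_um[fsel], cells$y_um[fsel],
                      cells$x_um[tsel], cells$y_um[tsel])
    med <- stats::median(d)
  }
  data.frame(slide_id = if (!is.null(cells$slide_id) && nrow(cells))
               cells$slide_id[1] else NA_character_,
             from = from_lab, to = to_lab, n_from = n_from, n_to = n_to,
             median_min_distance_um = med, excluded = excluded,
             reason = if (excluded)
               sprintf("fewer than %d cells of one phenotype", min_count)
             else "", stringsAsFactors = FALSE)
}

# Parse "CD68+CD206-" style rule strings into selector functions over the
# gated positivity columns; phenotype labels of the shipped panels are
# also accepted.
phenotype_selector <- function(rule) {
  if (is.function(rule)) return(rule)
  stopifnot(is.character(rule), length(rule) == 1L)
  labels <- unlist(lapply(list(panel_adaptive(), panel_innate()),
                          function(p) vapply(p$rules, `[[`, character(1),
                                             "label")))
  if (rule %in% labels) {
    return(function(cells) {
      hit <- rep(FALSE, nrow(cells))
      for (cl in c("phenotype_adaptive", "phenotype_innate", "phenotype"))
        if (cl %in% names(cells)) hit <- hit | cells[[cl]] == rule
      hit
    })
  }
  toks <- regmatches(rule, gregexpr("[A-Za-z0-9]+[+-]", rule))[[1]]
  if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(rule))
    stop("cannot parse phenotype rule: ", rule)
  function(cells) {
    sel <- rep(TRUE, nrow(cells))
    for (tk in toks) {
      m <- sub("[+-]$", "", tk)
      col <- paste0(m, "_pos")
      if (!col %in% names(cells)) stop("no positivity column for ", m)
      sel <- sel & (if (endsWith(tk, "+")) cells[[col]] else !cells[[col]])
    }
    sel
  }
}

#' Compare per-slide nearest-neighbor medians across groups
#'
#' Kruskal-Wallis test across cohort groups on the per-slide median
#' minimal distances, after dropping excluded slides.
#'
#' @param results combined data.frame of [median_min_distance()] rows with
#'   a `group` column.
#' @param min_slides minimum non-excluded slides required per group.
#' @return A `group_comparison` (see [kruskal_wallis_pairwise()]) or, when
#'   some group has too few usable slides, a list with `computable =
#'   FALSE` and the per-group counts.
#' @export
cohort_nn_comparison <- function(results, min_slides = 2L) {
  ok <- results[!results$excluded & !is.na(results$median_min_distance_um), ]
  counts <- table(factor(ok$group, levels = unique(results$group)))
  if (any(counts < min_slides)) {
    return(list(computable = FALSE, n_per_group = as.list(counts),
                reason = "a group has too few non-excluded slides"))
  }
  kruskal_wallis_pairwise(split(ok$median_min_distance_um, ok$group))
}
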