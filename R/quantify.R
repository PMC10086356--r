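#' Summarize one slide per layer and phenotype
#'
#' Assigns every cell to a tissue layer, drops cells in excluded
#' blood/background regions, and tabulates count, fraction-of-all-cells
#' and density (cells/mm^2) per layer for every leaf phenotype of the
#' gated panels plus a set of derived populations computed from marker
#' positivity: `helper_t_all` (all CD3+CD8- cells, i.e. helper incl.
#' memory/regulatory leaves), `cytotoxic_t_all`, `t_cell_all`,
#' `lymphocyte` (CD3+ or CD20+), `macrophage_all` (CD68+), and `immune`
#' (any immune lineage label in either panel). Ambiguous doublets count
#' toward totals but toward no phenotype. Phenotypes whose gating rule
#' needs a masked marker are reported as missing (`NA`), not zero.
#'
#' @param cells gated cell table (see [gate_slide()]) with `x_um`, `y_um`.
#' @param geometry a [layer_geometry()].
#' @param slide_id,group identifiers copied into the output.
#' @param masked_markers markers unavailable on this slide.
#' @param quantifiable_layers layers where quantitative composition
#'   analysis is valid (the adventitia of dissected aortas is excluded by
#'   passing `c("intima","media")`).
#' @param panels list of [marker_panel()]s that were gated.
#' @return A `slide_summary` data.frame, one row per layer x phenotype:
#'   columns slide_id, group, layer, area_mm2, total_cells, phenotype,
#'   count, fraction, density, quantifiable.
#' @export
summarize_slide <- function(cells, geometry, slide_id = cells$slide_id[1],
                            group = NA_character_,
                            masked_markers = character(),
                            quantifiable_layers = c("intima", "media",
                                                    "adventitia"),
                            panels = list(panel_adaptive(), panel_innate())) {
  stopifnot(inherits(geometry, "layer_geometry"))
  areas <- layer_areas(geometry)
  if (nrow(cells)) {
    layer <- assign_layer(cells$x_um, cells$y_um, geometry)
  } else layer <- character(0)
  keep <- layer %in% names(areas)
  cells <- cells[keep, , drop = FALSE]
  layer <- layer[keep]

  masked_labels <- character(0)
  for (pan in panels) {
    for (r in pan$rules)
      if (any(c(r$pos, r$neg) %in% masked_markers))
        masked_labels <- c(masked_labels, r$label)
  }

  derived <- function(idx) {
    has <- function(cl) if (cl %in% names(cells))
      cells[[cl]][idx] else rep(FALSE, sum(idx))
    amb_ad <- if ("phenotype_adaptive" %in% names(cells))
      cells$phenotype_adaptive[idx] == "ambiguous" else rep(FALSE, sum(idx))
    amb_in <- if ("phenotype_innate" %in% names(cells))
      cells$phenotype_innate[idx] == "ambiguous" else rep(FALSE, sum(idx))
    imm <- rep(FALSE, sum(idx))
    for (cl in c("phenotype_adaptive", "phenotype_innate"))
      if (cl %in% names(cells))
        imm <- imm | cells[[cl]][idx] %in% immune_labels()
    c(helper_t_all = sum(has("CD3_pos") & !has("CD8_pos") & !amb_ad),
      cytotoxic_t_all = sum(has("CD3_pos") & has("CD8_pos") & !amb_ad),
      t_cell_all = sum(has("CD3_pos") & !amb_ad),
      lymphocyte = sum((has("CD3_pos") | has("CD20_pos")) & !amb_ad),
      macrophage_all = sum(has("CD68_pos") & !amb_in),
      immune = sum(imm))
  }

  rows <- list()
  for (ly in names(areas)) {
    idx <- layer == ly
    tot <- sum(idx)
    counts <- c()
    for (pan in panels) {
      cl <- paste0("phenotype_", pan$name)
      if (!cl %in% names(cells)) next
      labs <- c(vapply(pan$rules, `[[`, character(1), "label"),
                "other", "ambiguous")
      cnt <- as.numeric(table(factor(cells[[cl]][idx], levels = labs)))
      names(cnt) <- labs
      cnt[labs %in% masked_labels] <- NA_real_
      names(cnt) <- paste0(labs, ".", pan$name)
      counts <- c(counts, cnt)
    }
    counts <- c(counts, derived(idx))
    phen <- sub("\\.(adaptive|innate)$", "", names(counts))
    rows[[ly]] <- data.frame(
      slide_id = slide_id, group = group, layer = ly,
      area_mm2 = unname(areas[[ly]]), total_cells = tot,
      phenotype = phen,
      panel = ifelse(grepl("\\.adaptive$", names(counts)), "adaptive",
                     ifelse(grepl("\\.innate$", names(counts)), "innate",
                            "derived")),
      count = unname(counts),
      fraction = if (tot > 0) unname(counts) / tot else NA_real_,
      density = unname(counts) / unname(areas[[ly]]),
      quantifiable = ly %in% quantifiable_layers,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("slide_summary", class(out))
  out
}

#' Gate and summarize every slide of a cohort
#'
#' @param cohort a `wp_cohort` from [generate_cohort()], or a list of
#'   slides with `cells`, `slide_id`, `group`, `quantifiable`,
#'   `markers_masked` fields.
#' @param analysis an [analysis_config()].
#' @return List with `cells` (named list of gated cell tables) and
#'   `summary` (combined `slide_summary` data.frame).
#' @export
summarize_cohort <- function(cohort, analysis = NULL) {
  geometry <- cohort$config$geometry
  if (is.null(analysis))
    analysis <- if (!is.null(cohort$config)) cohort$config$analysis
                else analysis_config()
  gated <- list()
  summaries <- list()
  for (sl in cohort$slides) {
    g <- gate_slide(sl$cells, masked_markers = sl$markers_masked,
                    analysis = analysis)
    gated[[sl$slide_id]] <- g
    ql <- if (isTRUE(sl$quantifiable)) c("intima", "media", "adventitia")
          else c("intima", "media")
    summaries[[sl$slide_id]] <- summarize_slide(
      g, geometry, slide_id = sl$slide_id, group = sl$group,
      masked_markers = sl$markers_masked, quantifiable_layers = ql)
  }
  list(cells = gated, summary = do.call(rbind, summaries))
}

#' Fold change between two groups
#'
#' Ratio of the group medians of a per-slide measure (group B over
#' group A), matching median-based cohort reporting. Slides whose layer is
#' flagged non-quantifiable, and missing (masked) values, are excluded.
#'
#' @param summary combined `slide_summary` data.frame with a `group`
#'   column.
#' @param phenotype,layer which population and layer to compare.
#' @param group_a,group_b group names; the result is B over A.
#' @param measure `"fraction"` (fraction of all cells; default, matching
#'   "% of all cells" reporting) or `"density"`.
#' @return Numeric ratio; `Inf` with a warning when the group-A median is
#'   zero and group B's is not.
#' @export
group_fold_change <- function(summary, phenotype, layer, group_a, group_b,
                              measure = c("fraction", "density")) {
  measure <- match.arg(measure)
  pick <- function(grp) {
    r <- summary[summary$group == grp & summary$layer == layer &
                   summary$phenotype == phenotype & summary$quantifiable, ]
    v <- r[[measure]]
    v[!is.na(v)]
  }
  va <- pick(group_a); vb <- pick(group_b)
  if (!length(va) || !length(vb))
    stop("no quantifiable slides for one of the groups")
  ma <- stats::median(va); mb <- stats::median(vb)
  if (ma == 0) {
    if (mb == 0) return(1)
    warning("denominator group median is zero; fold change infinite")
    return(Inf)
  }
  mb / ma
}

#' CD4/CD8 ratio of a slide layer
#'
#' Helper T cells (all CD3+CD8- cells) over cytotoxic T cells (CD3+CD8+)
#' in one layer of one slide summary.
#'
#' @param summary a `slide_summary` for one slide.
#' @param layer layer name.
#' @return Ratio; 0 when there are no helper T cells; `NA` with a warning
#'   when there are no cytotoxic T cells.
#' @export
cd4_cd8_ratio <- function(summary, layer = "adventitia") {
  r <- summary[summary$layer == layer, ]
  h <- r$count[r$phenotype == "helper_t_all"]
  c8 <- r$count[r$phenotype == "cytotoxic_t_all"]
  if (!length(h) || !length(c8) || is.na(h) || is.na(c8))
    stop("summary lacks helper_t_all/cytotoxic_t_all counts for ", layer)
  if (c8 == 0) {
    warning("no cytotoxic T cells in ", layer, "; CD4/CD8 ratio undefined")
    return(NA_real_)
  }
  h / c8
}
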