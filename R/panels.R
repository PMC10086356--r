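#' Marker panel with ordered phenotype gating rules
#'
#' A `marker_panel` holds the marker list of one 8-color mIHC panel together
#' with its ordered boolean phenotype rules. Each rule names the markers a
#' cell must be positive for and the markers it must be negative for; rules
#' are evaluated in order and the first (most specific) match wins, so child
#' phenotypes (e.g. regulatory T cell, CD3+CD8-FoxP3+) must precede their
#' parents (helper T cell, CD3+CD8-).
#'
#' @param name panel name, e.g. `"adaptive"` or `"innate"`.
#' @param markers character vector of marker names measured by the panel.
#' @param rules list of rules; each a list with elements `label`,
#'   `pos` (character vector of required-positive markers), `neg`
#'   (required-negative markers), and optional `parent` (label of the
#'   parent phenotype) and `immune` (logical; default `TRUE`).
#' @param gradual_markers subset of `markers` whose expression is gradual
#'   (no separated positive mode) and must be thresholded against a
#'   negative-control cell population rather than a fixed gate.
#' @param exclusive_pairs list of length-2 character vectors of mutually
#'   exclusive lineage markers; a cell positive for both members of a pair
#'   is labeled `"ambiguous"` (segmentation doublet) and excluded from
#'   phenotype counts.
#'
#' @return An object of class `marker_panel`.
#' @seealso [panel_adaptive()], [panel_innate()], [gate_panel()]
#' @export
marker_panel <- function(name, markers, rules, gradual_markers = character(),
                         exclusive_pairs = list()) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(markers), length(markers) >= 1L,
            is.list(rules), length(rules) >= 1L)
  labels <- vapply(rules, function(r) r$label, character(1))
  if (anyDuplicated(labels))
    stop("duplicate phenotype labels in panel '", name, "'")
  for (r in rules) {
    used <- c(r$pos, r$neg)
    bad <- setdiff(used, markers)
    if (length(bad))
      stop("rule '", r$label, "' uses markers not in panel: ",
           paste(bad, collapse = ", "))
    if (!is.null(r$parent)) {
      pr <- rules[[match(r$parent, labels)]]
      if (is.null(pr)) stop("rule '", r$label, "' has unknown parent '",
                            r$parent, "'")
      # a child may only add constraints to its parent
      if (!all(pr$pos %in% r$pos) || !all(pr$neg %in% r$neg))
        stop("rule '", r$label, "' does not refine its parent '",
             r$parent, "'")
    }
  }
  if (!all(gradual_markers %in% markers))
    stop("gradual_markers must be panel markers")
  rules <- lapply(rules, function(r) {
    if (is.null(r$immune)) r$immune <- TRUE
    r
  })
  structure(list(name = name, markers = markers, rules = rules,
                 gradual_markers = gradual_markers,
                 exclusive_pairs = exclusive_pairs),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel> ", x$name, ": ", paste(x$markers, collapse = ", "),
      "\n", sep = "")
  for (r in x$rules) {
    cat(sprintf("  %-22s %s%s\n", r$label,
                paste0(r$pos, "+", collapse = " "),
                if (length(r$neg)) paste0(" ", paste0(r$neg, "-",
                                                      collapse = " ")) else ""))
  }
  invisible(x)
}

#' Adaptive immune cell panel (lymphocytes and dendritic cells)
#'
#' Eight-color panel for T-cell subsets, B cells and type-2 classical
#' dendritic cells: CD3, CD8, CD20, CD1c, FoxP3, CD45RO (plus DAPI and
#' elastin autofluorescence, which carry no phenotype information and are
#' not modeled). CD45RO is a gradual marker. CD3/CD20 are treated as
#' mutually exclusive lineage markers.
#'
#' Leaf phenotypes, in gating order: regulatory T cell (CD3+CD8-FoxP3+),
#' memory helper T cell (CD3+CD8-CD45RO+), helper T cell (CD3+CD8-),
#' cytotoxic T cell (CD3+CD8+), cDC2 (CD1c+CD20-), B cell (CD20+).
#'
#' @return A [marker_panel()].
#' @export
panel_adaptive <- function() {
  marker_panel(
    name = "adaptive",
    markers = c("CD3", "CD8", "CD20", "CD1c", "FoxP3", "CD45RO"),
    rules = list(
      list(label = "regulatory_t", pos = c("CD3", "FoxP3"), neg = "CD8",
           parent = "helper_t"),
      list(label = "memory_helper_t", pos = c("CD3", "CD45RO"), neg = "CD8",
           parent = "helper_t"),
      list(label = "helper_t", pos = "CD3", neg = "CD8", parent = "t_cell"),
      list(label = "cytotoxic_t", pos = c("CD3", "CD8"), neg = character(),
           parent = "t_cell"),
      list(label = "t_cell", pos = "CD3", neg = character()),
      list(label = "cdc2", pos = "CD1c", neg = "CD20"),
      list(label = "b_cell", pos = "CD20", neg = character())
    ),
    gradual_markers = "CD45RO",
    exclusive_pairs = list(c("CD3", "CD20"))
  )
}

#' Innate immune cell panel (myeloid cells and vascularization)
#'
#' Eight-color panel for macrophages and their polarization, neutrophils,
#' endothelium and MMP9 expression: CD68, CD206, CD15, CD31, MMP9, GM-CSF
#' (GM-CSF is a qualitative readout and carries no phenotype rule). MMP9 is
#' a gradual marker. CD68/CD15 are mutually exclusive lineage markers.
#'
#' Leaf phenotypes, in gating order: M1-like macrophage (CD68+CD206-),
#' M2-like macrophage (CD68+CD206+), neutrophil (CD15+), endothelium
#' (CD31+, not immune), MMP9+ cell (MMP9+CD15-, not an immune lineage).
#'
#' @return A [marker_panel()].
#' @export
panel_innate <- function() {
  marker_panel(
    name = "innate",
    markers = c("CD68", "CD206", "CD15", "CD31", "MMP9"),
    rules = list(
      list(label = "m1_macrophage", pos = "CD68", neg = "CD206",
           parent = "macrophage"),
      list(label = "m2_macrophage", pos = c("CD68", "CD206"),
           neg = character(), parent = "macrophage"),
      list(label = "macrophage", pos = "CD68", neg = character()),
      list(label = "neutrophil", pos = "CD15", neg = character()),
      list(label = "endothelium", pos = "CD31", neg = character(),
           immune = FALSE),
      list(label = "mmp9_cell", pos = "MMP9", neg = "CD15", immune = FALSE)
    ),
    gradual_markers = "MMP9",
    exclusive_pairs = list(c("CD68", "CD15"))
  )
}

#' Phenotype labels counted as immune cells
#'
#' The union over both default panels of phenotype labels that represent an
#' immune lineage (T-cell subsets, B cells, cDC2, macrophages, neutrophils).
#' Endothelium and MMP9 positivity are not immune lineages.
#'
#' @return Character vector of labels.
#' @export
immune_labels <- function() {
  c("regulatory_t", "memory_helper_t", "helper_t", "cytotoxic_t", "t_cell",
    "cdc2", "b_cell", "m1_macrophage", "m2_macrophage", "macrophage",
    "neutrophil")
}
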