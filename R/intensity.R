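#' Per-marker intensity model
#'
#' Marker intensities are modeled as log-normal, with separate parameters
#' for the marker-positive and marker-negative cell populations. Bimodal
#' lineage markers get well-separated populations; the gradual markers
#' CD45RO and MMP9 get deliberately overlapping populations, reproducing
#' the absence of a clearly separated positive mode that motivates
#' thresholding them against a negative-control cell population.
#'
#' @param markers marker names to parameterize.
#' @param gradual subset of `markers` given the overlapping (gradual)
#'   parameters.
#' @param bimodal_neg,bimodal_pos,gradual_neg,gradual_pos length-2 numeric
#'   vectors `c(meanlog, sdlog)` of the log-normal parameters.
#' @return Named list (class `intensity_model`), one element per marker with
#'   fields `neg` and `pos`.
#' @export
intensity_model <- function(markers,
                            gradual = character(),
                            bimodal_neg = c(0.7, 0.5),
                            bimodal_pos = c(4.6, 0.35),
                            gradual_neg = c(1.5, 0.5),
                            gradual_pos = c(3.2, 0.5)) {
  stopifnot(all(gradual %in% markers))
  out <- lapply(markers, function(m) {
    if (m %in% gradual) list(neg = gradual_neg, pos = gradual_pos)
    else list(neg = bimodal_neg, pos = bimodal_pos)
  })
  names(out) <- markers
  class(out) <- "intensity_model"
  out
}

#' Default intensity model for both shipped panels
#' @return An [intensity_model()] covering all markers of
#'   [panel_adaptive()] and [panel_innate()].
#' @export
default_intensity_model <- function() {
  intensity_model(
    markers = c("CD3", "CD8", "CD20", "CD1c", "FoxP3", "CD45RO",
                "CD68", "CD206", "CD15", "CD31", "MMP9"),
    gradual = c("CD45RO", "MMP9"))
}

# Markers each true phenotype expresses, across both panels.
phenotype_marker_map <- function() {
  list(
    helper_t        = "CD3",
    memory_helper_t = c("CD3", "CD45RO"),
    regulatory_t    = c("CD3", "FoxP3"),
    cytotoxic_t     = c("CD3", "CD8"),
    b_cell          = "CD20",
    cdc2            = "CD1c",
    m1_macrophage   = "CD68",
    m2_macrophage   = c("CD68", "CD206"),
    neutrophil      = "CD15",
    endothelium     = "CD31",
    other           = character()
  )
}

#' Sample marker intensities for cells of known phenotype
#'
#' For each cell, markers its true phenotype expresses are drawn from the
#' marker's positive log-normal population and all other markers from the
#' negative population. Independent marker statuses that are not part of a
#' lineage definition (MMP9 positivity) can be injected via
#' `extra_positive`.
#'
#' @param phenotypes character vector of true phenotype labels (one per
#'   cell); must be names of the internal phenotype–marker map (see
#'   [generate_slide()]).
#' @param model an [intensity_model()]; every requested marker must be
#'   parameterized, otherwise an error is raised.
#' @param markers markers to sample; default all markers in `model`.
#' @param extra_positive optional logical matrix (cells x markers, named
#'   columns) forcing additional markers positive per cell.
#' @return Numeric matrix (cells x markers) of strictly positive
#'   intensities.
#' @export
sample_intensities <- function(phenotypes, model,
                               markers = names(model),
                               extra_positive = NULL) {
  stopifnot(inherits(model, "intensity_model"))
  unknown <- setdiff(markers, names(model))
  if (length(unknown))
    stop("unknown marker(s): ", paste(unknown, collapse = ", "))
  pmap <- phenotype_marker_map()
  bad <- setdiff(unique(phenotypes), names(pmap))
  if (length(bad))
    stop("unknown phenotype(s): ", paste(bad, collapse = ", "))
  n <- length(phenotypes)
  out <- matrix(0, nrow = n, ncol = length(markers),
                dimnames = list(NULL, markers))
  for (m in markers) {
    pos <- vapply(pmap[phenotypes], function(mm) m %in% mm, logical(1))
    if (!is.null(extra_positive) && m %in% colnames(extra_positive))
      pos <- pos | extra_positive[, m]
    pars <- model[[m]]
    ml <- ifelse(pos, pars$pos[1], pars$neg[1])
    sl <- ifelse(pos, pars$pos[2], pars$neg[2])
    out[, m] <- stats::rlnorm(n, meanlog = ml, sdlog = sl)
  }
  out
}
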