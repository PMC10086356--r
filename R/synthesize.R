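#' TLS planting parameters
#'
#' Parameters of the planted tertiary lymphoid structures: per-slide
#' prevalence, count distribution on positive slides (1 + Poisson(lambda)),
#' disk geometry and composition, and the distribution of the offset
#' between TLS centroid and the media/adventitia boundary. Each structure
#' is built from three concentric shells emulating the organization of a
#' real TLS: a very dense germinal-center focus of proliferating B cells
#' (radius `gc_spot_radius_um`), a B-cell mantle out to `core_radius_um`,
#' and a T-cell ring out to `rim_radius_um`.
#'
#' @param prevalence fraction of slides carrying at least one TLS, in [0,1].
#' @param count_lambda Poisson rate; a positive slide carries
#'   `1 + Poisson(count_lambda)` TLS (mean `1 + count_lambda`).
#' @param gc_spot_radius_um radius of the germinal-center focus.
#' @param n_b_gc B cells inside the germinal-center focus (part of `n_b`).
#' @param core_radius_um outer radius of the B-cell zone (focus + mantle).
#' @param rim_radius_um outer radius of the T-cell ring; must exceed
#'   `core_radius_um`.
#' @param n_b,n_t numbers of planted B and T cells per TLS.
#' @param t_helper_frac fraction of planted T cells that are helper
#'   (CD3+CD8-) rather than cytotoxic.
#' @param helper_memory_frac fraction of planted helper T cells of the
#'   memory (CD45RO+) subtype.
#' @param offset_mean_um,offset_sd_um normal distribution of the centroid
#'   offset from the media/adventitia boundary, truncated so the disk fits
#'   inside the adventitia.
#' @return List of class `tls_config`.
#' @export
tls_config <- function(prevalence = 0, count_lambda = 1.6,
                       gc_spot_radius_um = 12, n_b_gc = 20,
                       core_radius_um = 30, rim_radius_um = 58,
                       n_b = 45, n_t = 60, t_helper_frac = 0.72,
                       helper_memory_frac = 0.49,
                       offset_mean_um = 242, offset_sd_um = 40) {
  if (prevalence < 0 || prevalence > 1)
    stop("invalid config: tls.prevalence must be in [0, 1]")
  if (rim_radius_um <= core_radius_um ||
      core_radius_um <= gc_spot_radius_um)
    stop("invalid config: tls radii must increase gc_spot < core < rim")
  if (n_b < 1 || n_t < 1)
    stop("invalid config: tls.n_b and tls.n_t must be >= 1")
  if (n_b_gc < 0 || n_b_gc > n_b)
    stop("invalid config: tls.n_b_gc must be in [0, n_b]")
  structure(list(prevalence = prevalence, count_lambda = count_lambda,
                 gc_spot_radius_um = gc_spot_radius_um, n_b_gc = n_b_gc,
                 core_radius_um = core_radius_um,
                 rim_radius_um = rim_radius_um, n_b = n_b, n_t = n_t,
                 t_helper_frac = t_helper_frac,
                 helper_memory_frac = helper_memory_frac,
                 offset_mean_um = offset_mean_um,
                 offset_sd_um = offset_sd_um),
            class = "tls_config")
}

#' Per-group generator parameters
#'
#' @param name group name.
#' @param n_slides number of slides (>= 0).
#' @param densities named list with elements `intima`, `media`,
#'   `adventitia`; each a named numeric vector of per-phenotype cell
#'   densities (cells/mm^2), all >= 0.
#' @param tls a [tls_config()].
#' @param markers_masked markers not analyzable in this group (e.g. FoxP3
#'   in a post-mortem group); gating rules requiring them are skipped and
#'   the corresponding phenotypes reported as missing.
#' @param adventitia_quantifiable `FALSE` when the adventitia is too
#'   disrupted for quantitative composition analysis (dissection group);
#'   such slides are excluded from adventitial group summaries.
#' @return List of class `group_config`.
#' @export
group_config <- function(name, n_slides, densities, tls = tls_config(),
                         markers_masked = character(),
                         adventitia_quantifiable = TRUE) {
  if (n_slides < 0) stop("invalid config: n_slides must be >= 0")
  for (layer in c("intima", "media", "adventitia")) {
    d <- densities[[layer]]
    if (is.null(d)) stop("invalid config: densities$", layer, " missing")
    if (any(d < 0)) stop("invalid config: densities$", layer,
                         " has negative density")
    bad <- setdiff(names(d), names(phenotype_marker_map()))
    if (length(bad)) stop("invalid config: unknown phenotype(s) in densities$",
                          layer, ": ", paste(bad, collapse = ", "))
  }
  stopifnot(inherits(tls, "tls_config"))
  structure(list(name = name, n_slides = n_slides, densities = densities,
                 tls = tls, markers_masked = markers_masked,
                 adventitia_quantifiable = adventitia_quantifiable),
            class = "group_config")
}

#' Analysis parameters
#'
#' Tunable parameters shared by gating, TLS detection and nearest-neighbor
#' analysis. Defaults: gradual-marker quantile 0.995 (bounds the
#' false-positive rate at 0.5% by construction); contact radius 12 µm
#' (about one lymphocyte diameter, so "physically touching" cell centers);
#' minimum infiltrate size 20 cells; 5 nearest neighbors and a 0.7
#' segregation threshold for B/T zone calling; germinal-center rule: a
#' 15 µm disk with >= 2-fold the component's median local density and at
#' most 20% T cells (a germinal center is a compact proliferating focus,
#' so the probe must be small enough not to average it away against the
#' surrounding B mantle); 150-cell minimum per phenotype for
#' nearest-neighbor inclusion; fixed gate threshold 15 for bimodal
#' markers.
#'
#' @param gradual_quantile quantile of the negative-control population used
#'   to threshold gradual markers.
#' @param contact_radius_um maximum center distance of touching cells.
#' @param min_infiltrate_cells minimum lymphoid infiltrate size.
#' @param k_neighbors neighbors used for zone segregation scores.
#' @param zone_segregation_threshold minimum per-class segregation score.
#' @param gc_radius_um,gc_fold,gc_max_t germinal-center disk radius,
#'   density fold and maximum T fraction.
#' @param nn_min_count minimum per-phenotype cell count per slide for the
#'   nearest-neighbor analysis (>= 1).
#' @param fixed_threshold fixed intensity gate for bimodal markers.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(gradual_quantile = 0.995, contact_radius_um = 12,
                            min_infiltrate_cells = 20, k_neighbors = 5,
                            zone_segregation_threshold = 0.7,
                            gc_radius_um = 15, gc_fold = 2, gc_max_t = 0.2,
                            nn_min_count = 150, fixed_threshold = 15) {
  if (nn_min_count < 1) stop("invalid config: nn_min_count must be >= 1")
  if (gradual_quantile <= 0 || gradual_quantile >= 1)
    stop("invalid config: gradual_quantile must be in (0, 1)")
  structure(as.list(environment()), class = "analysis_config")
}

#' Cohort generator configuration
#'
#' @param groups named list of [group_config()]s.
#' @param geometry a [layer_geometry()] shared by all slides.
#' @param intensity an [intensity_model()].
#' @param analysis an [analysis_config()].
#' @param mmp9_rate probability that any cell is MMP9-positive
#'   (independent of lineage; equal across groups).
#' @param blood_cell_density nuisance cell density inside excluded blood
#'   regions (cells/mm^2).
#' @param endo_cluster_size,endo_cluster_radius_um endothelial cells are
#'   placed as vasa-vasorum-like clusters of this size and radius instead
#'   of uniformly.
#' @param master_seed integer master seed; per-slide child seeds are
#'   derived deterministically from it.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(groups, geometry = default_geometry(),
                          intensity = default_intensity_model(),
                          analysis = analysis_config(),
                          mmp9_rate = 0.05, blood_cell_density = 1500,
                          endo_cluster_size = 8,
                          endo_cluster_radius_um = 20,
                          master_seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("invalid config: groups must be a named list")
  for (g in groups) stopifnot(inherits(g, "group_config"))
  stopifnot(inherits(geometry, "layer_geometry"),
            inherits(intensity, "intensity_model"),
            inherits(analysis, "analysis_config"))
  if (mmp9_rate < 0 || mmp9_rate > 1)
    stop("invalid config: mmp9_rate must be in [0, 1]")
  structure(list(groups = groups, geometry = geometry,
                 intensity = intensity, analysis = analysis,
                 mmp9_rate = mmp9_rate,
                 blood_cell_density = blood_cell_density,
                 endo_cluster_size = endo_cluster_size,
                 endo_cluster_radius_um = endo_cluster_radius_um,
                 master_seed = as.integer(master_seed)),
            class = "cohort_config")
}

# Deterministic child seed per slide, kept inside 32-bit integer range.
child_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 48271 +
                as.numeric(index) * 1299721) %% 2147483629 + 1)
}

#' Default calibrated cohort configuration
#'
#' The shipped study conditions: 8 non-dilated, 15 dilated and 4 dissection
#' slides of about 2e4 cells each. Per-layer per-phenotype densities and
#' TLS parameters are calibrated by construction so the full pipeline
#' recovers the cohort-level composition statistics the package targets
#' (adventitial lymphocyte and B-cell enrichment in dilated aortas, helper
#' T fraction, CD4/CD8 ratios, macrophage enrichment, TLS prevalence,
#' count and distance to the media, and the low intima immune fraction);
#' see the methods vignette for the closed-form calibration, including the
#' compensation of background adventitial B/T densities for the cells
#' contributed by planted TLS.
#'
#' @param master_seed integer master seed.
#' @return A [cohort_config()].
#' @export
default_cohort_config <- function(master_seed = 1L) {
  dens <- function(helper_t = 0, memory_helper_t = 0, regulatory_t = 0,
                   cytotoxic_t = 0, b_cell = 0, cdc2 = 0, m1_macrophage = 0,
                   m2_macrophage = 0, neutrophil = 0, endothelium = 0,
                   other = 0) {
    c(helper_t = helper_t, memory_helper_t = memory_helper_t,
      regulatory_t = regulatory_t, cytotoxic_t = cytotoxic_t,
      b_cell = b_cell, cdc2 = cdc2, m1_macrophage = m1_macrophage,
      m2_macrophage = m2_macrophage, neutrophil = neutrophil,
      endothelium = endothelium, other = other)
  }
  # intima identical across groups: 8.1% immune, M1-like 4.6% of all cells
  intima <- dens(helper_t = 15, memory_helper_t = 8, cytotoxic_t = 11.5,
                 b_cell = 4.6, cdc2 = 6.9, m1_macrophage = 105.8,
                 m2_macrophage = 23, neutrophil = 11.5, endothelium = 23,
                 other = 2090.7)
  media <- function(m1, m2, other) {
    dens(helper_t = 10, memory_helper_t = 5, cytotoxic_t = 5, b_cell = 1,
         m1_macrophage = m1, m2_macrophage = m2, neutrophil = 3,
         endothelium = 40, other = other)
  }
  adv_nd <- dens(helper_t = 60, memory_helper_t = 26.9, cytotoxic_t = 47.8,
                 b_cell = 5, cdc2 = 8, m1_macrophage = 45,
                 m2_macrophage = 80, neutrophil = 12.5, endothelium = 62.5,
                 other = 2152.3)
  adv_dil <- dens(helper_t = 147.8, memory_helper_t = 142.1,
                  regulatory_t = 9.8, cytotoxic_t = 118.7, b_cell = 113,
                  cdc2 = 20, m1_macrophage = 63.6, m2_macrophage = 140,
                  neutrophil = 12.5, endothelium = 62.5, other = 1670)
  cohort_config(
    groups = list(
      non_dilated = group_config(
        name = "non_dilated", n_slides = 8,
        densities = list(intima = intima, media = media(25, 10, 2101),
                         adventitia = adv_nd),
        tls = tls_config(prevalence = 0),
        markers_masked = "FoxP3"),
      dilated = group_config(
        name = "dilated", n_slides = 15,
        densities = list(intima = intima, media = media(40, 15, 2086),
                         adventitia = adv_dil),
        tls = tls_config(prevalence = 0.5)),
      dissection = group_config(
        name = "dissection", n_slides = 4,
        densities = list(intima = intima, media = media(60, 20, 2061),
                         adventitia = adv_dil),
        tls = tls_config(prevalence = 0.75),
        adventitia_quantifiable = FALSE)
    ),
    master_seed = master_seed)
}

# Uniform points in a layer band, rejecting excluded regions.
sample_in_band <- function(n, geometry, y0, y1) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(16L, 2L * (n - length(xs)))
    x <- stats::runif(m, 0, geometry$width_um)
    y <- stats::runif(m, y0, y1)
    keep <- rep(TRUE, m)
    for (ex in geometry$excluded)
      keep <- keep & !point_in_polygon(x, y, ex$poly)
    xs <- c(xs, x[keep]); ys <- c(ys, y[keep])
  }
  cbind(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

# Uniform points in a disk / annulus.
sample_in_annulus <- function(n, cx, cy, r0, r1) {
  r <- sqrt(stats::runif(n, r0^2, r1^2))
  a <- stats::runif(n, 0, 2 * pi)
  cbind(x = cx + r * cos(a), y = cy + r * sin(a))
}

#' Plant tertiary lymphoid structures into a slide
#'
#' Adds `n_tls` TLS to a cell table: each is a disk in the adventitia at a
#' sampled offset from the media/adventitia boundary, with a dense B-cell
#' core (germinal-center proxy) and a helper-dominated T-cell rim. Member
#' spacing within the disk is far below the contact radius, so every
#' planted structure forms a single contact-connected component.
#'
#' @param cells slide cell table (possibly empty) as built by
#'   [generate_slide()].
#' @param geometry a [layer_geometry()].
#' @param tls a [tls_config()].
#' @param n_tls number of structures to plant.
#' @param slide_id slide identifier used for member cell ids.
#' @param max_tries resampling attempts for a disk that does not fit inside
#'   the adventitia or that overlaps an already-placed structure.
#' @return List with `cells` (augmented table) and `tls` (list of planted
#'   ground-truth records: member ids, centroid, offset, counts,
#'   `has_germinal_center = TRUE`).
#' @export
place_tls <- function(cells, geometry, tls, n_tls, slide_id = "s",
                      max_tries = 200L) {
  stopifnot(inherits(geometry, "layer_geometry"), inherits(tls, "tls_config"))
  if (n_tls == 0L) return(list(cells = cells, tls = list()))
  rim <- tls$rim_radius_um
  margin <- 5
  y_lo <- geometry$y_media_adventitia
  if (geometry$adventitia_um < 2 * (rim + margin))
    stop("geometry error: adventitia too thin for TLS of rim radius ", rim)
  centers <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n_tls)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      off <- stats::rnorm(1, tls$offset_mean_um, tls$offset_sd_um)
      if (off < rim + margin || off > geometry$adventitia_um - rim - margin)
        next
      cx <- stats::runif(1, rim + margin, geometry$width_um - rim - margin)
      cy <- y_lo + off
      if (nrow(centers) &&
          any(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) <
                2 * rim + 40))
        next
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place TLS ", i, " inside the adventitia after ",
                  max_tries, " tries")
    centers <- rbind(centers, c(cx, cy))
  }
  records <- vector("list", n_tls)
  new_cells <- vector("list", n_tls)
  n0 <- nrow(cells)
  next_id <- n0
  for (i in seq_len(n_tls)) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    core <- rbind(
      sample_in_annulus(tls$n_b_gc, cx, cy, 0, tls$gc_spot_radius_um),
      sample_in_annulus(tls$n_b - tls$n_b_gc, cx, cy,
                        tls$gc_spot_radius_um, tls$core_radius_um))
    rimp <- sample_in_annulus(tls$n_t, cx, cy, tls$core_radius_um, rim)
    n_help <- round(tls$n_t * tls$t_helper_frac)
    n_mem <- round(n_help * tls$helper_memory_frac)
    t_phen <- c(rep("memory_helper_t", n_mem),
                rep("helper_t", n_help - n_mem),
                rep("cytotoxic_t", tls$n_t - n_help))
    phen <- c(rep("b_cell", tls$n_b), t_phen)
    xy <- rbind(core, rimp)
    ids <- sprintf("%s_c%06d", slide_id, next_id + seq_len(nrow(xy)))
    next_id <- next_id + nrow(xy)
    new_cells[[i]] <- data.frame(cell_id = ids, x_um = xy[, 1],
                                 y_um = xy[, 2], true_phenotype = phen,
                                 true_layer = "adventitia",
                                 tls_id = sprintf("%s_tls%d", slide_id, i),
                                 stringsAsFactors = FALSE)
    records[[i]] <- list(tls_id = sprintf("%s_tls%d", slide_id, i),
                         member_ids = ids, centroid = c(cx, cy),
                         offset_um = cy - y_lo, n_b = tls$n_b,
                         n_t = tls$n_t, has_germinal_center = TRUE)
  }
  add <- do.call(rbind, new_cells)
  if (n0 == 0L && !nrow(cells)) cells_out <- add
  else {
    if (is.null(cells$tls_id)) cells$tls_id <- NA_character_
    cells_out <- rbind(cells, add)
  }
  list(cells = cells_out, tls = records)
}

#' Generate one synthetic slide
#'
#' Places cells of each phenotype as a homogeneous Poisson process within
#' each layer band (excluding blood/background polygons) at the configured
#' densities, with endothelium instead placed as small vasa-vasorum-like
#' clusters; plants TLS in the adventitia; adds nuisance cells inside
#' excluded blood regions; and draws per-marker log-normal intensities for
#' every cell. The caller controls the RNG state (see [generate_cohort()]
#' for seeded cohorts).
#'
#' @param group a [group_config()].
#' @param config a [cohort_config()] (geometry, intensity model, rates).
#' @param slide_id slide identifier.
#' @param tls_positive force this slide to carry (`TRUE`) or lack
#'   (`FALSE`) TLS; `NULL` (default) draws a Bernoulli with the group's
#'   TLS prevalence. [generate_cohort()] passes this flag to realize the
#'   prevalence as an exact fraction of each group's slides.
#' @return List with `cells` (data.frame: cell_id, slide_id, group,
#'   tile_id, x_um, y_um, one intensity column per marker, true_phenotype,
#'   true_layer, tls_id) and `truth` (list with planted `tls` records and
#'   the per-compartment cell counts).
#' @export
generate_slide <- function(group, config, slide_id = "s1",
                           tls_positive = NULL) {
  stopifnot(inherits(group, "group_config"), inherits(config, "cohort_config"))
  geometry <- config$geometry
  areas <- layer_areas(geometry)  # validates > 0
  bands <- layer_bands(geometry)
  parts <- list()
  for (layer in names(bands)) {
    d <- group$densities[[layer]]
    d <- d[d > 0]
    b <- bands[[layer]]
    for (phen in names(d)) {
      if (phen == "endothelium") {
        sz <- config$endo_cluster_size
        n_cl <- stats::rpois(1, areas[[layer]] * d[[phen]] / sz)
        if (n_cl == 0L) next
        ctr <- sample_in_band(n_cl, geometry, b[1] + config$endo_cluster_radius_um,
                              b[2] - config$endo_cluster_radius_um)
        xy <- do.call(rbind, lapply(seq_len(n_cl), function(i)
          sample_in_annulus(sz, ctr[i, 1], ctr[i, 2], 0,
                            config$endo_cluster_radius_um)))
      } else {
        n <- stats::rpois(1, areas[[layer]] * d[[phen]])
        if (n == 0L) next
        xy <- sample_in_band(n, geometry, b[1], b[2])
      }
      parts[[length(parts) + 1L]] <-
        data.frame(cell_id = NA_character_, x_um = xy[, 1], y_um = xy[, 2],
                   true_phenotype = phen, true_layer = layer,
                   tls_id = NA_character_, stringsAsFactors = FALSE)
    }
  }
  cells <- if (length(parts)) do.call(rbind, parts) else
    data.frame(cell_id = character(0), x_um = numeric(0), y_um = numeric(0),
               true_phenotype = character(0), true_layer = character(0),
               tls_id = character(0), stringsAsFactors = FALSE)
  cells$cell_id <- if (nrow(cells))
    sprintf("%s_c%06d", slide_id, seq_len(nrow(cells))) else character(0)
  # TLS
  if (is.null(tls_positive))
    tls_positive <- stats::runif(1) < group$tls$prevalence
  n_tls <- if (tls_positive)
    1L + stats::rpois(1, group$tls$count_lambda) else 0L
  pl <- place_tls(cells, geometry, group$tls, n_tls, slide_id = slide_id)
  cells <- pl$cells
  # nuisance cells inside excluded blood regions
  blood_mix <- c(other = 0.7, neutrophil = 0.1, helper_t = 0.1,
                 cytotoxic_t = 0.05, b_cell = 0.05)
  for (ex in geometry$excluded) {
    if (ex$label != "blood" || config$blood_cell_density <= 0) next
    a_mm2 <- polygon_area(ex$poly) / 1e6
    nb <- stats::rpois(1, a_mm2 * config$blood_cell_density)
    if (nb == 0L) next
    bb <- apply(ex$poly, 2, range)
    xs <- numeric(0); ys <- numeric(0)
    while (length(xs) < nb) {
      m <- 2L * max(8L, nb - length(xs))
      x <- stats::runif(m, bb[1, 1], bb[2, 1])
      y <- stats::runif(m, bb[1, 2], bb[2, 2])
      keep <- point_in_polygon(x, y, ex$poly)
      xs <- c(xs, x[keep]); ys <- c(ys, y[keep])
    }
    phen <- sample(names(blood_mix), nb, replace = TRUE, prob = blood_mix)
    cells <- rbind(cells, data.frame(
      cell_id = sprintf("%s_x%06d", slide_id, seq_len(nb)),
      x_um = xs[seq_len(nb)], y_um = ys[seq_len(nb)], true_phenotype = phen,
      true_layer = ex$label, tls_id = NA_character_,
      stringsAsFactors = FALSE))
  }
  # intensities
  markers <- names(config$intensity)
  if (nrow(cells)) {
    extra <- NULL
    if ("MMP9" %in% markers && config$mmp9_rate > 0) {
      extra <- matrix(stats::runif(nrow(cells)) < config$mmp9_rate, ncol = 1,
                      dimnames = list(NULL, "MMP9"))
    }
    inten <- sample_intensities(cells$true_phenotype, config$intensity,
                                markers = markers, extra_positive = extra)
  } else {
    inten <- matrix(numeric(0), nrow = 0, ncol = length(markers),
                    dimnames = list(NULL, markers))
  }
  tile <- if (nrow(cells))
    sprintf("t%02d_%02d", pmin(floor(cells$x_um / 500), 1e4),
            pmin(floor(cells$y_um / 500), 1e4)) else character(0)
  out <- data.frame(cell_id = cells$cell_id,
                    slide_id = rep(slide_id, nrow(cells)),
                    group = rep(group$name, nrow(cells)), tile_id = tile,
                    x_um = cells$x_um, y_um = cells$y_um,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(inten))
  out$true_phenotype <- cells$true_phenotype
  out$true_layer <- cells$true_layer
  out$tls_id <- cells$tls_id
  rownames(out) <- NULL
  list(cells = out,
       truth = list(tls = pl$tls,
                    n_layer = table(cells$true_layer)))
}

#' Generate a seeded synthetic cohort
#'
#' One slide per configured group slot, each generated under a child seed
#' derived deterministically from the master seed, so an identical
#' configuration yields a bit-identical cohort. TLS prevalence is
#' realized as an exact fraction of each group's slides
#' (`round(prevalence * n_slides)` randomly chosen slides carry TLS):
#' the prevalence emulates a realized cohort property, not a
#' superpopulation rate.
#'
#' @param config a [cohort_config()].
#' @return Object of class `wp_cohort`: list with `slides` (each holding
#'   `cells`, `truth`, `slide_id`, `group`, `quantifiable`,
#'   `markers_masked`), `config`, and a `manifest` data.frame.
#' @examples
#' cfg <- default_cohort_config(master_seed = 7)
#' cfg$groups$non_dilated$n_slides <- 1
#' cfg$groups$dilated$n_slides <- 1
#' cfg$groups$dissection$n_slides <- 0
#' coh <- generate_cohort(cfg)
#' coh
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  slides <- list()
  idx <- 0L
  gi <- 0L
  for (g in config$groups) {
    gi <- gi + 1L
    n_pos <- round(g$tls$prevalence * g$n_slides)
    set.seed(child_seed(config$master_seed, 1000000L + gi))
    pos_slides <- sample(seq_len(g$n_slides), n_pos)
    for (i in seq_len(g$n_slides)) {
      idx <- idx + 1L
      slide_id <- sprintf("%s_%02d", g$name, i)
      set.seed(child_seed(config$master_seed, idx))
      sl <- generate_slide(g, config, slide_id = slide_id,
                           tls_positive = i %in% pos_slides)
      slides[[slide_id]] <- list(cells = sl$cells, truth = sl$truth,
                                 slide_id = slide_id, group = g$name,
                                 quantifiable = g$adventitia_quantifiable,
                                 markers_masked = g$markers_masked)
    }
  }
  manifest <- data.frame(
    slide_id = vapply(slides, `[[`, character(1), "slide_id"),
    group = vapply(slides, `[[`, character(1), "group"),
    n_cells = vapply(slides, function(s) nrow(s$cells), integer(1)),
    n_tls_planted = vapply(slides, function(s) length(s$truth$tls),
                           integer(1)),
    adventitia_quantifiable = vapply(slides, `[[`, logical(1),
                                     "quantifiable"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(slides = slides, config = config, manifest = manifest),
            class = "wp_cohort")
}

#' @export
print.wp_cohort <- function(x, ...) {
  cat("<wp_cohort> ", length(x$slides), " slide(s), ",
      sum(x$manifest$n_cells), " cells, master_seed ",
      x$config$master_seed, "\n", sep = "")
  if (nrow(x$manifest)) {
    tab <- table(x$manifest$group)
    cat("  groups: ",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}
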