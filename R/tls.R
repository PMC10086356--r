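# Grid-bucket index: all pairs of points within distance r.
# Bucket side = r, so candidate pairs live in adjacent buckets; each
# unordered bucket pair is visited once via the half-neighborhood key
# offsets. Returns a 2-column matrix of indices (i < j). Tested against
# the all-pairs O(n^2) comparison.
radius_pairs <- function(x, y, r) {
  n <- length(x)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  gx <- as.integer(floor(x / r)); gy <- as.integer(floor(y / r))
  gx <- gx - min(gx); gy <- gy - min(gy)
  K <- max(gy) + 2L  # +2 so gy+1 never wraps into the next column
  key <- gx * K + gy
  ord <- order(key)
  ks <- key[ord]
  r2 <- r * r
  out <- list()
  for (off in c(0L, 1L, K - 1L, K, K + 1L)) {
    target <- key + off
    lo <- findInterval(target - 0.5, ks) + 1L
    hi <- findInterval(target + 0.5, ks)
    valid <- which(hi >= lo)
    if (!length(valid)) next
    reps <- hi[valid] - lo[valid] + 1L
    ii <- rep.int(valid, reps)
    jj <- ord[sequence(reps, from = lo[valid])]
    if (off == 0L) {
      keep <- ii < jj
      ii <- ii[keep]; jj <- jj[keep]
    }
    if (!length(ii)) next
    sel <- (x[ii] - x[jj])^2 + (y[ii] - y[jj])^2 <= r2
    if (any(sel))
      out[[length(out) + 1L]] <- cbind(ii[sel], jj[sel])
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  m <- do.call(rbind, out)
  cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
}

#' Build the cell-contact graph
#'
#' Undirected graph over lymphocytes with an edge whenever two cell
#' centers are at most `contact_radius_um` apart ("physically touching":
#' about one lymphocyte diameter). No self-loops; symmetric by
#' construction.
#'
#' @param cells cell table with `x_um`, `y_um` (typically the T and B
#'   lymphocytes of one slide layer).
#' @param contact_radius_um maximum center distance for an edge.
#' @return An [igraph::graph] with one vertex per row of `cells` (vertex
#'   attribute `name` = `cell_id` when present).
#' @export
build_contact_graph <- function(cells, contact_radius_um = 12) {
  n <- nrow(cells)
  pairs <- radius_pairs(cells$x_um, cells$y_um, contact_radius_um)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(pairs))
    g <- igraph::add_edges(g, t(pairs))
  if (!is.null(cells$cell_id))
    g <- igraph::set_vertex_attr(g, "name", value = cells$cell_id)
  g
}

#' Find lymphoid infiltrates
#'
#' Connected components of the contact graph that contain at least one T
#' cell, at least one B cell, and at least `min_cells` members (dense
#' mixed lymphocytic conglomerates). Components are returned in
#' deterministic order (by centroid x, then y).
#'
#' @param graph contact graph from [build_contact_graph()].
#' @param cells the cell table the graph was built over, with a logical
#'   `is_b` column (`TRUE` = B cell, `FALSE` = T cell).
#' @param min_cells minimum component size.
#' @return List of integer vectors (row indices into `cells`).
#' @export
find_lymphoid_infiltrates <- function(graph, cells, min_cells = 20) {
  if (igraph::vcount(graph) == 0L) return(list())
  comp <- igraph::components(graph)
  keep <- which(comp$csize >= min_cells)
  out <- list()
  for (ci in keep) {
    idx <- which(comp$membership == ci)
    if (any(cells$is_b[idx]) && any(!cells$is_b[idx]))
      out[[length(out) + 1L]] <- idx
  }
  if (length(out) > 1L) {
    cx <- vapply(out, function(i) mean(cells$x_um[i]), numeric(1))
    cy <- vapply(out, function(i) mean(cells$y_um[i]), numeric(1))
    out <- out[order(cx, cy)]
  }
  out
}

#' Classify an infiltrate as a tertiary lymphoid structure
#'
#' Computes, for each lineage class, a zone-segregation score: the mean
#' over class members of the fraction of their `k_neighbors` nearest
#' within-component neighbors that share the class. The component `has
#' zones` when both class scores reach the threshold. It `has a germinal
#' center` when some disk of radius `gc_radius_um` centered on a member
#' holds a B-cell density at least `gc_fold` times the component's median
#' local density with a T-cell fraction of at most `gc_max_t`. It is a TLS
#' when it has zones or a germinal center.
#'
#' @param idx integer vector of member row indices.
#' @param cells cell table with `x_um`, `y_um`, `is_b`.
#' @param geometry a [layer_geometry()] for the media distance.
#' @param analysis an [analysis_config()].
#' @param slide_id,tls_id identifiers for the record.
#' @return A one-row `tls_record` data.frame: tls_id, slide_id, n_members,
#'   n_t, n_b, centroid_x_um, centroid_y_um, zone_segregation_t,
#'   zone_segregation_b, has_zones, has_germinal_center, is_tls,
#'   distance_to_media_um.
#' @export
classify_tls <- function(idx, cells, geometry,
                         analysis = analysis_config(),
                         slide_id = NA_character_, tls_id = "tls1") {
  x <- cells$x_um[idx]; y <- cells$y_um[idx]; b <- cells$is_b[idx]
  n <- length(idx)
  k <- min(analysis$k_neighbors, n - 1L)
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  same_frac <- function(members) {
    if (!length(members) || k < 1L) return(NA_real_)
    mean(vapply(members, function(i) {
      nb <- order(d[i, ])[seq_len(k)]
      mean(b[nb] == b[i])
    }, numeric(1)))
  }
  seg_b <- same_frac(which(b))
  seg_t <- same_frac(which(!b))
  has_zones <- isTRUE(seg_b >= analysis$zone_segregation_threshold &&
                        seg_t >= analysis$zone_segregation_threshold)
  # germinal center: candidate disks centered on each member
  r <- analysis$gc_radius_um
  cnt <- integer(n); bcnt <- integer(n)
  for (i in seq_len(n)) {
    inn <- which(d[i, ] <= r)
    cnt[i] <- length(inn) + 1L           # include the center cell
    bcnt[i] <- sum(b[inn]) + as.integer(b[i])
  }
  area <- pi * r^2
  med_local <- stats::median(cnt / area)
  dens_b <- bcnt / area
  t_frac <- (cnt - bcnt) / cnt
  has_gc <- any(dens_b >= analysis$gc_fold * med_local &
                  t_frac <= analysis$gc_max_t)
  cx <- mean(x); cy <- mean(y)
  rec <- data.frame(
    tls_id = tls_id, slide_id = slide_id, n_members = n,
    n_t = sum(!b), n_b = sum(b), centroid_x_um = cx, centroid_y_um = cy,
    zone_segregation_t = seg_t, zone_segregation_b = seg_b,
    has_zones = has_zones, has_germinal_center = has_gc,
    is_tls = has_zones || has_gc,
    distance_to_media_um = tls_media_distance(c(cx, cy), geometry),
    stringsAsFactors = FALSE)
  class(rec) <- c("tls_record", class(rec))
  rec
}

#' Distance from a TLS centroid to the media/adventitia boundary
#'
#' Euclidean distance from a point to the nearest point of the boundary
#' between the media and the adventitia. With the horizontal-band
#' geometry the boundary is the line `y = y_media_adventitia`, clipped to
#' the slide width.
#'
#' @param centroid numeric length-2 `c(x_um, y_um)`.
#' @param geometry a [layer_geometry()].
#' @return Distance in µm (>= 0).
#' @export
tls_media_distance <- function(centroid, geometry) {
  stopifnot(inherits(geometry, "layer_geometry"))
  x <- min(max(centroid[1], 0), geometry$width_um)
  sqrt((centroid[1] - x)^2 + (centroid[2] - geometry$y_media_adventitia)^2)
}

#' Detect lymphoid infiltrates and TLS on one slide
#'
#' Selects the gated T and B lymphocytes of the requested layers, builds
#' the contact graph, extracts mixed infiltrates and classifies each.
#'
#' @param cells gated cell table (needs `phenotype_adaptive`, positions).
#' @param geometry a [layer_geometry()].
#' @param analysis an [analysis_config()].
#' @param layers layers searched for infiltrates (default adventitia).
#' @param slide_id identifier.
#' @return List with `records` (a `tls_record` data.frame, possibly
#'   0-row) and `members` (list of cell-id vectors per record).
#' @export
detect_tls <- function(cells, geometry, analysis = analysis_config(),
                       layers = "adventitia",
                       slide_id = cells$slide_id[1]) {
  layer <- assign_layer(cells$x_um, cells$y_um, geometry)
  t_lab <- c("helper_t", "memory_helper_t", "regulatory_t", "cytotoxic_t",
             "t_cell")
  is_t <- cells$phenotype_adaptive %in% t_lab
  is_b <- cells$phenotype_adaptive == "b_cell"
  sel <- (is_t | is_b) & layer %in% layers
  ly <- cells[sel, c("cell_id", "x_um", "y_um")]
  ly$is_b <- is_b[sel]
  g <- build_contact_graph(ly, analysis$contact_radius_um)
  comps <- find_lymphoid_infiltrates(g, ly, analysis$min_infiltrate_cells)
  recs <- list(); members <- list()
  for (i in seq_along(comps)) {
    recs[[i]] <- classify_tls(comps[[i]], ly, geometry, analysis,
                              slide_id = slide_id,
                              tls_id = sprintf("%s_det%d", slide_id, i))
    members[[i]] <- ly$cell_id[comps[[i]]]
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(tls_id = character(0), slide_id = character(0),
               n_members = integer(0), n_t = integer(0), n_b = integer(0),
               centroid_x_um = numeric(0), centroid_y_um = numeric(0),
               zone_segregation_t = numeric(0),
               zone_segregation_b = numeric(0), has_zones = logical(0),
               has_germinal_center = logical(0), is_tls = logical(0),
               distance_to_media_um = numeric(0), stringsAsFactors = FALSE)
  list(records = records, members = members)
}

#' Cohort-level TLS statistics
#'
#' @param records combined `tls_record` data.frame over the slides of one
#'   group (only `is_tls` structures count).
#' @param slide_ids ids of all quantifiable slides of the group (slides
#'   without any record count toward the denominator).
#' @return List: `prevalence` (fraction of slides with >= 1 TLS),
#'   `mean_per_positive_slide`, `mean_per_slide` (over all slides, the
#'   alternative reading), `mean_distance_um` (mean centroid distance to
#'   the media over all TLS), `n_slides`, `n_tls`. Means are `NA` when no
#'   slide carries a TLS.
#' @export
tls_group_stats <- function(records, slide_ids) {
  stopifnot(length(slide_ids) >= 1L)
  tls <- records[records$is_tls & records$slide_id %in% slide_ids, ,
                 drop = FALSE]
  per_slide <- table(factor(tls$slide_id, levels = slide_ids))
  pos <- per_slide[per_slide > 0]
  list(prevalence = mean(per_slide > 0),
       mean_per_positive_slide = if (length(pos)) mean(pos) else NA_real_,
       mean_per_slide = mean(per_slide),
       mean_distance_um = if (nrow(tls)) mean(tls$distance_to_media_um)
                          else NA_real_,
       n_slides = length(slide_ids), n_tls = nrow(tls))
}
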