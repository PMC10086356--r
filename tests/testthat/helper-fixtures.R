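# Shared fixtures built in code.

# Small geometry without excluded regions.
mini_geometry <- function() layer_geometry(1000, 100, 400, 500)

# Scaled-down cohort configuration for fast end-to-end tests: same layer
# structure and phenotype mix as the default, ~40x fewer cells.
mini_config <- function(master_seed = 1L, n_nd = 2L, n_dil = 2L,
                        n_diss = 0L, tls_prevalence = c(0, 1, 1)) {
  scale <- 1 / 8
  cfg <- default_cohort_config(master_seed = master_seed)
  cfg$geometry <- layer_geometry(800, 150, 1200, 800)
  grps <- cfg$groups
  ns <- c(n_nd, n_dil, n_diss)
  for (i in seq_along(grps)) {
    grps[[i]]$n_slides <- ns[i]
    grps[[i]]$densities <- lapply(grps[[i]]$densities, function(d) d * scale)
    grps[[i]]$tls$prevalence <- tls_prevalence[i]
  }
  cfg$groups <- grps
  cfg
}

# Cell table with prescribed intensities: all markers at `lo` except the
# named ones at `hi`.
cell_with <- function(..., lo = 1, hi = 100) {
  pos <- c(...)
  markers <- names(default_intensity_model())
  v <- setNames(rep(lo, length(markers)), markers)
  v[pos] <- hi
  as.data.frame(as.list(v))
}

flat_thresholds <- function(value = 15) {
  setNames(rep(value, length(names(default_intensity_model()))),
           names(default_intensity_model()))
}

# Deterministic synthetic TLS disk (B core + T ring) around a center.
toy_tls_cells <- function(cx = 500, cy = 1700, n_gc = 20, n_b = 45,
                          n_t = 60, spot_r = 12, core_r = 30, rim_r = 58,
                          seed = 1) {
  set.seed(seed)
  ann <- function(n, r0, r1) {
    th <- runif(n, 0, 2 * pi); r <- sqrt(runif(n, r0^2, r1^2))
    cbind(cx + r * cos(th), cy + r * sin(th))
  }
  xy <- rbind(ann(n_gc, 0, spot_r), ann(n_b - n_gc, spot_r, core_r),
              ann(n_t, core_r, rim_r))
  data.frame(cell_id = sprintf("c%03d", seq_len(nrow(xy))),
             x_um = xy[, 1], y_um = xy[, 2],
             is_b = c(rep(TRUE, n_b), rep(FALSE, n_t)),
             stringsAsFactors = FALSE)
}
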