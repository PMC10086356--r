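#' Recover the headline cohort statistics from a pipeline run
#'
#' Computes, from a [run_pipeline()] result, the cohort-level composition
#' and TLS statistics the synthetic generator is calibrated to: the
#' adventitial lymphocyte / B-cell / macrophage enrichment of dilated over
#' non-dilated aortas (ratios of group medians of per-slide
#' fractions-of-all-cells), the dilated-group median helper-T percentage
#' and the CD4/CD8 ratios, TLS prevalence, mean count per TLS-positive
#' slide and mean distance to the media in the dilated group, and the
#' pooled intima immune and M1-like macrophage percentages.
#'
#' @param results a `wp_results` object from [run_pipeline()].
#' @return Named numeric vector; percentages on the 0-100 scale.
#' @examples
#' \donttest{
#' res <- run_pipeline(default_cohort_config(master_seed = 1))
#' cohort_statistics(res)
#' }
#' @export
cohort_statistics <- function(results) {
  stopifnot(inherits(results, "wp_results"))
  s <- results$summary
  grp_median <- function(grp, ph, layer = "adventitia") {
    v <- s$fraction[s$group == grp & s$layer == layer & s$phenotype == ph &
                      s$quantifiable]
    stats::median(v, na.rm = TRUE)
  }
  fc <- function(ph) results$fold_changes$fold_change[
    results$fold_changes$phenotype == ph]
  ts <- results$tls_stats$dilated
  r <- results$cd4_cd8
  c(lymphocyte_fold_adventitia = fc("lymphocyte"),
    b_cell_fold_adventitia = fc("b_cell"),
    helper_t_pct_adventitia_dilated =
      100 * grp_median("dilated", "helper_t_all"),
    cd4_cd8_dilated = stats::median(
      r$cd4_cd8_adventitia[r$group == "dilated"], na.rm = TRUE),
    cd4_cd8_non_dilated = stats::median(
      r$cd4_cd8_adventitia[r$group == "non_dilated"], na.rm = TRUE),
    tls_prevalence_dilated_pct = 100 * ts$prevalence,
    tls_per_positive_slide = ts$mean_per_positive_slide,
    tls_media_distance_um = ts$mean_distance_um,
    macrophage_fold_adventitia = fc("macrophage_all"),
    intima_immune_pct = 100 * results$intima_pooled$fraction[
      results$intima_pooled$phenotype == "immune"],
    intima_m1_pct = 100 * results$intima_pooled$fraction[
      results$intima_pooled$phenotype == "m1_macrophage"])
}

#' Recover cohort statistics across several master seeds
#'
#' Runs the full default pipeline once per master seed and returns the
#' per-seed statistics plus their across-seed medians — the package's
#' calibration-recovery readout.
#'
#' @param master_seeds integer vector of master seeds.
#' @param config_fn function(seed) returning a [cohort_config()]; default
#'   [default_cohort_config()].
#' @param verbose print one line per seed to stderr.
#' @return List with `per_seed` (seeds x statistics matrix) and `median`
#'   (named vector of across-seed medians, NAs removed).
#' @export
recover_cohort_statistics <- function(master_seeds,
                                      config_fn = default_cohort_config,
                                      verbose = FALSE) {
  per_seed <- t(vapply(master_seeds, function(ms) {
    if (verbose) message("master seed ", ms)
    cohort_statistics(run_pipeline(config_fn(ms)))
  }, FUN.VALUE = numeric(11)))
  rownames(per_seed) <- master_seeds
  list(per_seed = per_seed,
       median = apply(per_seed, 2, stats::median, na.rm = TRUE))
}
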