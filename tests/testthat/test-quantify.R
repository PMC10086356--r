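gated_toy_slide <- function(n = 500, seed = 2) {
  cfg <- mini_config(master_seed = seed, n_nd = 0, n_dil = 1,
                     tls_prevalence = c(0, 0, 0))
  coh <- generate_cohort(cfg)
  sl <- coh$slides[[1]]
  list(cells = gate_slide(sl$cells), geometry = cfg$geometry)
}

test_that("summary counts equal a brute-force recount", {
  gs <- gated_toy_slide()
  s <- summarize_slide(gs$cells, gs$geometry, group = "dilated")
  lay <- assign_layer(gs$cells$x_um, gs$cells$y_um, gs$geometry)
  for (ly in c("intima", "media", "adventitia")) {
    for (ph in c("helper_t", "b_cell", "m1_macrophage", "other")) {
      pan <- if (ph %in% c("m1_macrophage")) "innate" else "adaptive"
      cl <- paste0("phenotype_", pan)
      brute <- sum(gs$cells[[cl]] == ph & lay == ly)
      got <- s$count[s$layer == ly & s$phenotype == ph & s$panel == pan]
      expect_equal(got, brute)
    }
    expect_equal(unique(s$total_cells[s$layer == ly]), sum(lay == ly))
  }
})

test_that("fractions, densities and conservation hold per layer", {
  gs <- gated_toy_slide(seed = 8)
  s <- summarize_slide(gs$cells, gs$geometry)
  for (ly in unique(s$layer)) {
    r <- s[s$layer == ly & s$panel == "adaptive", ]
    expect_equal(sum(r$count, na.rm = TRUE), r$total_cells[1])
    expect_equal(sum(r$fraction, na.rm = TRUE), 1, tolerance = 1e-12)
    expect_equal(r$density, r$count / r$area_mm2)
  }
  # excluded-region cells are in no layer total
  lay <- assign_layer(gs$cells$x_um, gs$cells$y_um, gs$geometry)
  expect_equal(sum(s$total_cells[s$phenotype == "immune"]),
               sum(lay %in% c("intima", "media", "adventitia")))
})

test_that("simple fraction arithmetic on a constructed slide", {
  # 10 helper T among 100 adventitial cells -> fraction 0.10
  geo <- mini_geometry()
  n <- 100
  cells <- data.frame(cell_id = sprintf("c%d", 1:n), slide_id = "s",
                      x_um = runif(n, 0, 1000), y_um = runif(n, 510, 990),
                      phenotype_adaptive = c(rep("helper_t", 10),
                                             rep("other", 90)),
                      CD3_pos = c(rep(TRUE, 10), rep(FALSE, 90)),
                      CD8_pos = FALSE, CD20_pos = FALSE,
                      stringsAsFactors = FALSE)
  s <- summarize_slide(cells, geo, panels = list(panel_adaptive()))
  expect_equal(s$fraction[s$layer == "adventitia" &
                            s$phenotype == "helper_t"], 0.10)
  expect_equal(s$count[s$layer == "adventitia" &
                         s$phenotype == "helper_t_all"], 10)
  # empty slide: counts 0, fractions missing
  s0 <- summarize_slide(cells[0, ], geo, panels = list(panel_adaptive()))
  expect_true(all(s0$count == 0))
  expect_true(all(is.na(s0$fraction)))
})

test_that("masked phenotypes are missing, not zero", {
  gs <- gated_toy_slide(seed = 3)
  cells <- gate_slide(gs$cells, masked_markers = "FoxP3")
  s <- summarize_slide(cells, gs$geometry, masked_markers = "FoxP3")
  expect_true(all(is.na(s$count[s$phenotype == "regulatory_t"])))
  expect_false(anyNA(s$count[s$phenotype == "helper_t"]))
})

fake_summary <- function(fractions, group, phenotype = "b_cell",
                         layer = "adventitia", quantifiable = TRUE) {
  data.frame(slide_id = sprintf("%s_%d", group, seq_along(fractions)),
             group = group, layer = layer, area_mm2 = 1,
             total_cells = 1000, phenotype = phenotype, panel = "adaptive",
             count = fractions * 1000, fraction = fractions,
             density = fractions * 1000, quantifiable = quantifiable,
             stringsAsFactors = FALSE)
}

test_that("fold change is the ratio of group medians", {
  s <- rbind(fake_summary(c(0.02, 0.02, 0.02), "a"),
             fake_summary(c(0.08, 0.08, 0.08), "b"))
  expect_equal(group_fold_change(s, "b_cell", "adventitia", "a", "b"), 4)
  expect_equal(group_fold_change(s, "b_cell", "adventitia", "a", "a"), 1)
  # scale invariance: scaling all counts/densities leaves fractions alone
  s2 <- s; s2$density <- s2$density * 7; s2$count <- s2$count * 7
  expect_equal(group_fold_change(s2, "b_cell", "adventitia", "a", "b"), 4)
  # zero denominator median -> infinite with warning
  s3 <- rbind(fake_summary(c(0, 0), "a"), fake_summary(c(0.1, 0.1), "b"))
  expect_warning(fc <- group_fold_change(s3, "b_cell", "adventitia",
                                         "a", "b"), "infinite")
  expect_identical(fc, Inf)
})

test_that("non-quantifiable slides are excluded from fold changes", {
  s <- rbind(fake_summary(c(0.02, 0.02), "a"),
             fake_summary(c(0.08, 0.08), "b"),
             fake_summary(c(0.8, 0.8), "b", quantifiable = FALSE))
  expect_equal(group_fold_change(s, "b_cell", "adventitia", "a", "b"), 4)
  s_bad <- fake_summary(c(0.1), "a", quantifiable = FALSE)
  expect_error(group_fold_change(rbind(s, s_bad)[
    rbind(s, s_bad)$group == "zzz", , drop = FALSE][0, ],
    "b_cell", "adventitia", "a", "b"), "no quantifiable")
})

test_that("CD4/CD8 ratio handles regular and degenerate counts", {
  mk <- function(h, c8) {
    data.frame(slide_id = "s", group = "g", layer = "adventitia",
               area_mm2 = 1, total_cells = h + c8,
               phenotype = c("helper_t_all", "cytotoxic_t_all"),
               panel = "derived", count = c(h, c8),
               fraction = c(h, c8) / max(1, h + c8),
               density = c(h, c8), quantifiable = TRUE,
               stringsAsFactors = FALSE)
  }
  expect_equal(cd4_cd8_ratio(mk(50, 25)), 2)
  expect_equal(cd4_cd8_ratio(mk(0, 10)), 0)
  expect_warning(r <- cd4_cd8_ratio(mk(10, 0)), "undefined")
  expect_true(is.na(r))
})
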