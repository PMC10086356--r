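test_that("configuration validation names the offending field", {
  expect_error(tls_config(prevalence = 1.2), "tls.prevalence")
  expect_error(analysis_config(nn_min_count = 0), "nn_min_count")
  d <- list(intima = c(other = 10), media = c(other = 10),
            adventitia = c(other = -1))
  expect_error(group_config("g", 1, d), "adventitia.*negative")
  expect_error(group_config("g", -1, list()), "n_slides")
})

test_that("zero-slide groups give an empty cohort", {
  cfg <- mini_config(n_nd = 0, n_dil = 0, n_diss = 0)
  coh <- generate_cohort(cfg)
  expect_length(coh$slides, 0)
  expect_equal(nrow(coh$manifest), 0)
})

test_that("zero densities and zero TLS prevalence give an empty slide", {
  cfg <- mini_config(tls_prevalence = c(0, 0, 0))
  for (i in seq_along(cfg$groups))
    cfg$groups[[i]]$densities <- lapply(cfg$groups[[i]]$densities,
                                        function(d) d * 0)
  cfg$blood_cell_density <- 0
  set.seed(1)
  sl <- generate_slide(cfg$groups$dilated, cfg)
  expect_equal(nrow(sl$cells), 0)
  expect_length(sl$truth$tls, 0)
})

test_that("identical master seed reproduces a bit-identical cohort", {
  cfg <- mini_config(master_seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$slides, b$slides)
  c2 <- generate_cohort(mini_config(master_seed = 43))
  expect_false(identical(a$slides[[1]]$cells, c2$slides[[1]]$cells))
})

test_that("cells of a single phenotype land only in their own layer", {
  cfg <- mini_config()
  g <- cfg$groups$dilated
  g$densities <- list(intima = c(helper_t = 0), media = c(helper_t = 0),
                      adventitia = c(helper_t = 100))
  g$tls$prevalence <- 0
  cfg$blood_cell_density <- 0
  set.seed(7)
  sl <- generate_slide(g, cfg)
  expect_gt(nrow(sl$cells), 0)
  expect_true(all(sl$cells$true_layer == "adventitia"))
  expect_true(all(sl$cells$y_um > cfg$geometry$y_media_adventitia))
})

test_that("per-slide counts are Poisson with mean density x area", {
  cfg <- mini_config()
  g <- cfg$groups$dilated
  d <- 40
  g$densities <- list(intima = c(b_cell = 0), media = c(b_cell = 0),
                      adventitia = c(b_cell = d))
  g$tls$prevalence <- 0
  cfg$blood_cell_density <- 0
  area <- layer_areas(cfg$geometry)[["adventitia"]]
  set.seed(11)
  n <- vapply(1:50, function(i) nrow(generate_slide(g, cfg)$cells),
              numeric(1))
  lambda <- d * area
  # empirical mean within 3 SE of the Poisson mean
  expect_lt(abs(mean(n) - lambda), 3 * sqrt(lambda / 50))
  # chi-square dispersion test not rejected at alpha = 0.01
  disp <- sum((n - mean(n))^2) / mean(n)
  expect_gt(disp, qchisq(0.005, 49))
  expect_lt(disp, qchisq(0.995, 49))
})

test_that("generated cells are conserved across compartments", {
  cfg <- mini_config(master_seed = 5)
  coh <- generate_cohort(cfg)
  for (sl in coh$slides) {
    tab <- table(sl$cells$true_layer)
    expect_equal(sum(tab), nrow(sl$cells))
    n_tls_members <- sum(!is.na(sl$cells$tls_id))
    expect_equal(n_tls_members,
                 sum(vapply(sl$truth$tls,
                            function(t) length(t$member_ids), numeric(1))))
  }
})

test_that("place_tls plants disks at the sampled media offset", {
  geo <- default_geometry()
  tls <- tls_config(prevalence = 1, offset_mean_um = 242,
                    offset_sd_um = 1e-9)
  empty <- data.frame(cell_id = character(0), x_um = numeric(0),
                      y_um = numeric(0), true_phenotype = character(0),
                      true_layer = character(0), tls_id = character(0))
  set.seed(3)
  pl <- place_tls(empty, geo, tls, 1)
  expect_length(pl$tls, 1)
  rec <- pl$tls[[1]]
  expect_equal(rec$offset_um, 242, tolerance = 1e-6)
  # centroid of the planted members is close to the nominal center
  expect_equal(mean(pl$cells$y_um) - geo$y_media_adventitia, 242,
               tolerance = 15)
  expect_gte(rec$n_b, 1)
  expect_gte(rec$n_t, 1)
  expect_gte(length(rec$member_ids), analysis_config()$min_infiltrate_cells)
  # zero TLS leaves the table untouched
  expect_identical(place_tls(empty, geo, tls, 0)$cells, empty)
})

test_that("a TLS that cannot fit the adventitia raises a geometry error", {
  thin <- layer_geometry(1000, 100, 400, 80)
  expect_error(place_tls(data.frame(), thin, tls_config(prevalence = 1), 1),
               "adventitia")
})

test_that("intensities reflect the true phenotype's markers", {
  model <- default_intensity_model()
  set.seed(1)
  m <- sample_intensities(rep("helper_t", 500), model)
  expect_true(all(m > 0))
  # CD3 from the positive population, CD8/CD20 from the negative one
  expect_gt(median(m[, "CD3"]), 10 * median(m[, "CD8"]))
  expect_gt(median(m[, "CD3"]), 10 * median(m[, "CD20"]))
  expect_error(sample_intensities("helper_t", model, markers = "CD99"),
               "unknown marker")
  expect_error(sample_intensities("weird_cell", model), "unknown phenotype")
})

test_that("zero-variance intensity model degenerates to constants", {
  model <- intensity_model(c("CD3", "CD8"),
                           bimodal_neg = c(1, 0), bimodal_pos = c(3, 0))
  m <- sample_intensities(rep("helper_t", 10), model)
  expect_true(all(m[, "CD3"] == exp(3)))
  expect_true(all(m[, "CD8"] == exp(1)))
})

test_that("gradual-marker overlap misclassifies at most the quantile tail", {
  model <- default_intensity_model()
  q <- 0.995
  # closed-form quantile of the negative CD45RO population
  pars <- model$CD45RO$neg
  thr <- qlnorm(q, pars[1], pars[2])
  set.seed(2)
  neg <- rlnorm(2e4, pars[1], pars[2])
  expect_lte(mean(neg > thr), 1 - q + 0.005)
})
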