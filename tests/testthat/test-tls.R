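test_that("contact edges follow the touching radius exactly", {
  cells <- data.frame(cell_id = c("a", "b"), x_um = c(0, 5), y_um = 0)
  expect_equal(igraph::ecount(build_contact_graph(cells, 12)), 1)
  cells$x_um <- c(0, 12.1)
  expect_equal(igraph::ecount(build_contact_graph(cells, 12)), 0)
  cells$x_um <- c(0, 12)  # boundary: touching at exactly the radius
  expect_equal(igraph::ecount(build_contact_graph(cells, 12)), 1)
})

test_that("contact graph equals brute-force all-pairs comparison", {
  set.seed(31)
  n <- 300
  cells <- data.frame(cell_id = sprintf("c%d", 1:n),
                      x_um = runif(n, 0, 400), y_um = runif(n, 0, 300))
  g <- build_contact_graph(cells, 15)
  d <- as.matrix(dist(cbind(cells$x_um, cells$y_um)))
  brute <- which(upper.tri(d) & d <= 15, arr.ind = TRUE)
  el <- igraph::as_edgelist(g, names = FALSE)
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  expect_setequal(key(el), key(brute))
})

test_that("infiltrates require both lineages and the minimum size", {
  # 30 tightly packed T cells, no B: no infiltrate
  g30 <- expand.grid(x = seq(0, 40, 8), y = seq(0, 32, 8))
  cells <- data.frame(cell_id = sprintf("c%d", 1:30), x_um = g30$x[1:30],
                      y_um = g30$y[1:30], is_b = FALSE)
  gr <- build_contact_graph(cells, 12)
  expect_length(find_lymphoid_infiltrates(gr, cells, 20), 0)
  # one B converts it into a single infiltrate
  cells$is_b[1] <- TRUE
  expect_length(find_lymphoid_infiltrates(gr, cells, 20), 1)
  expect_length(find_lymphoid_infiltrates(gr, cells, 31), 0)
})

test_that("planted structures are recovered as single components", {
  geo <- default_geometry()
  an <- analysis_config()
  # 40 B + 40 T in one dense disk: one infiltrate holding all 80 cells
  cells <- toy_tls_cells(n_gc = 15, n_b = 40, n_t = 40, rim_r = 40,
                         seed = 1)
  gr <- build_contact_graph(cells, an$contact_radius_um)
  comps <- find_lymphoid_infiltrates(gr, cells, an$min_infiltrate_cells)
  expect_length(comps, 1)
  expect_length(comps[[1]], 80)
  # two disks farther apart than the contact radius: two infiltrates
  cells2 <- rbind(cells, within(toy_tls_cells(cx = 900, seed = 6),
                                cell_id <- paste0("q", cell_id)))
  gr2 <- build_contact_graph(cells2, an$contact_radius_um)
  expect_length(find_lymphoid_infiltrates(gr2, cells2,
                                          an$min_infiltrate_cells), 2)
})

test_that("B-core/T-rim structures have zones and a germinal center", {
  geo <- default_geometry()
  an <- analysis_config()
  cells <- toy_tls_cells(seed = 2)
  gr <- build_contact_graph(cells, an$contact_radius_um)
  comps <- find_lymphoid_infiltrates(gr, cells, an$min_infiltrate_cells)
  rec <- classify_tls(comps[[1]], cells, geo, an, tls_id = "t1")
  expect_true(rec$has_zones)
  expect_true(rec$has_germinal_center)
  expect_true(rec$is_tls)
  expect_gte(rec$zone_segregation_b, an$zone_segregation_threshold)
  expect_gte(rec$zone_segregation_t, an$zone_segregation_threshold)
})

test_that("well-mixed checkerboards have no zones", {
  geo <- default_geometry()
  an <- analysis_config()
  g <- expand.grid(x = seq(0, 90, 10), y = seq(0, 90, 10))
  cells <- data.frame(cell_id = sprintf("c%d", seq_len(nrow(g))),
                      x_um = g$x + 100, y_um = g$y + 1500,
                      is_b = (g$x / 10 + g$y / 10) %% 2 == 0)
  gr <- build_contact_graph(cells, 15)
  comps <- find_lymphoid_infiltrates(gr, cells, 20)
  rec <- classify_tls(comps[[1]], cells, geo, an)
  expect_lt(rec$zone_segregation_b, an$zone_segregation_threshold)
  expect_lt(rec$zone_segregation_t, an$zone_segregation_threshold)
  expect_false(rec$has_zones)
})

test_that("a minimal two-cell infiltrate is not a TLS", {
  geo <- default_geometry()
  an <- analysis_config()
  cells <- data.frame(cell_id = c("a", "b"), x_um = c(0, 5),
                      y_um = geo$y_media_adventitia + 100,
                      is_b = c(TRUE, FALSE))
  rec <- classify_tls(1:2, cells, geo, an)
  expect_false(rec$has_zones)
  expect_false(rec$has_germinal_center)
  expect_false(rec$is_tls)
})

test_that("media distance matches closed form and a sampling oracle", {
  geo <- default_geometry()
  yb <- geo$y_media_adventitia
  expect_equal(tls_media_distance(c(500, yb + 100), geo), 100)
  expect_equal(tls_media_distance(c(500, yb), geo), 0)
  set.seed(9)
  bx <- seq(0, geo$width_um, length.out = 20001)
  for (i in 1:10) {
    p <- c(runif(1, 0, geo$width_um), runif(1, yb, geo$height_um))
    brute <- min(sqrt((bx - p[1])^2 + (yb - p[2])^2))
    expect_equal(tls_media_distance(p, geo), brute, tolerance = 1e-4)
  }
})

test_that("detection is invariant to cell order and translation", {
  geo <- default_geometry()
  an <- analysis_config()
  cells <- toy_tls_cells(cx = 400, cy = 1600, seed = 12)
  detect1 <- function(tab) {
    gr <- build_contact_graph(tab, an$contact_radius_um)
    comps <- find_lymphoid_infiltrates(gr, tab, an$min_infiltrate_cells)
    classify_tls(comps[[1]], tab, geo, an)
  }
  base <- detect1(cells)
  set.seed(1)
  shuf <- cells[sample(nrow(cells)), ]
  rec <- detect1(shuf)
  expect_equal(rec$n_members, base$n_members)
  expect_equal(rec$zone_segregation_t, base$zone_segregation_t)
  expect_equal(rec$centroid_x_um, base$centroid_x_um)
  # rigid translation moves the centroid but not the classification
  tr <- cells; tr$x_um <- tr$x_um + 321
  rec2 <- detect1(tr)
  expect_equal(rec2$n_members, base$n_members)
  expect_equal(rec2$has_zones, base$has_zones)
  expect_equal(rec2$has_germinal_center, base$has_germinal_center)
  expect_equal(rec2$centroid_x_um, base$centroid_x_um + 321)
})

test_that("growing the contact radius never shrinks components", {
  set.seed(21)
  n <- 150
  cells <- data.frame(cell_id = sprintf("c%d", 1:n),
                      x_um = runif(n, 0, 300), y_um = runif(n, 0, 300),
                      is_b = runif(n) < 0.5)
  sizes <- function(r) {
    g <- build_contact_graph(cells, r)
    sort(igraph::components(g)$csize, decreasing = TRUE)
  }
  for (r in c(8, 12, 20, 30)) {
    a <- sizes(r); b <- sizes(r + 5)
    expect_gte(b[1], a[1])
    expect_lte(length(b), length(a))
  }
})

test_that("group TLS statistics count prevalence and per-slide means", {
  rec <- function(slide, is_tls, d = 100) {
    data.frame(tls_id = "t", slide_id = slide, n_members = 30, n_t = 10,
               n_b = 20, centroid_x_um = 0, centroid_y_um = 0,
               zone_segregation_t = 1, zone_segregation_b = 1,
               has_zones = is_tls, has_germinal_center = FALSE,
               is_tls = is_tls, distance_to_media_um = d,
               stringsAsFactors = FALSE)
  }
  slides <- paste0("s", 1:4)
  empty <- rec("s1", TRUE)[0, ]
  st0 <- tls_group_stats(empty, slides)
  expect_equal(st0$prevalence, 0)
  expect_true(is.na(st0$mean_per_positive_slide))
  recs <- rbind(rec("s1", TRUE, 200), rec("s1", TRUE, 300),
                rec("s2", TRUE, 100), rec("s3", FALSE))
  st <- tls_group_stats(recs, slides)
  expect_equal(st$prevalence, 0.5)
  expect_equal(st$mean_per_positive_slide, 1.5)
  expect_equal(st$mean_per_slide, 0.75)
  expect_equal(st$mean_distance_um, 200)
})
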