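# Shared fixture: a pair table with controllable residuals.
dresd_fixture <- function(n = 30, seed = 1, width = 300, height = 200) {
  geo <- random_geo(n, width = width, height = height, seed = seed)
  dgen <- dps_distances(random_gt(n, 6, A = 5, seed = seed))
  pairs <- build_pairs(geo, dgen)
  fit <- fit_ibd(pairs, "linear")
  list(geo = geo, pairs = build_pairs(geo, dgen, ibd_model = fit))
}

test_that("default distance classes partition pairs half-open with no overlap", {
  fx <- dresd_fixture(seed = 2)
  grid <- grid_from_samples(fx$geo, spacing = 50)
  dr <- suppressWarnings(
    dresd_analysis(fx$pairs, grid, n_iter = 50, seed = 1))
  cls <- glance(dr)
  in_class <- vapply(seq_len(nrow(cls)), function(k) {
    sum(fx$pairs$geo_km >= cls$d_min[k] & fx$pairs$geo_km < cls$d_max[k])
  }, 0)
  expect_equal(cls$n_pairs, in_class)
  # each pair lands in at most one class
  total <- sum(fx$pairs$geo_km >= 20 & fx$pairs$geo_km < 250)
  expect_equal(sum(in_class), total)
  expect_error(
    dresd_analysis(fx$pairs, grid, classes = list(c(20, 90), c(80, 140))),
    "overlap")
})

test_that("all-equal residuals produce no significant point anywhere", {
  fx <- dresd_fixture(seed = 3)
  pairs <- dplyr::mutate(fx$pairs, residual = 0.25)
  grid <- grid_from_samples(fx$geo, spacing = 50)
  dr <- suppressWarnings(dresd_analysis(pairs, grid, n_iter = 100, seed = 2))
  expect_true(all(tidy(dr)$label == "ns"))
})

test_that("a class with fewer than 10 pairs is marked empty, not zero", {
  fx <- dresd_fixture(n = 12, seed = 4)
  grid <- grid_from_samples(fx$geo, spacing = 80)
  expect_warning(
    dr <- dresd_analysis(fx$pairs, grid,
                         classes = list(c(0, 5), c(5, 300)),
                         n_iter = 50, seed = 1),
    "empty")
  cls <- glance(dr)
  expect_equal(cls$status, c("empty", "used"))
  expect_false("0-5" %in% tidy(dr)$class_id)
})

test_that("significance labels imply p <= alpha and match tail direction", {
  fx <- dresd_fixture(seed = 5)
  grid <- grid_from_samples(fx$geo, spacing = 40)
  dr <- suppressWarnings(dresd_analysis(fx$pairs, grid, n_iter = 200, seed = 9))
  fld <- tidy(dr)
  sig <- fld[fld$label != "ns", ]
  if (nrow(sig) > 0) expect_true(all(sig$p <= dr$params$alpha))
  expect_true(all(fld$p >= 0 & fld$p <= 1))
})

test_that("the residual surface is translation-equivariant", {
  fx <- dresd_fixture(seed = 6)
  g1 <- grid_from_samples(fx$geo, spacing = 50)
  shift_geo <- dplyr::mutate(fx$geo, x = x + 1000, y = y - 2000)
  pairs2 <- dplyr::mutate(fx$pairs, mid_x = mid_x + 1000, mid_y = mid_y - 2000)
  g2 <- grid_spec(g1$x0 + 1000, g1$y0 - 2000, g1$spacing, g1$nx, g1$ny)
  d1 <- suppressWarnings(dresd_analysis(fx$pairs, g1, n_iter = 60, seed = 4))
  d2 <- suppressWarnings(dresd_analysis(pairs2, g2, n_iter = 60, seed = 4))
  expect_equal(tidy(d1)$value, tidy(d2)$value, tolerance = 1e-9)
  expect_equal(tidy(d1)$label, tidy(d2)$label)
})

test_that("DResD is reproducible given a seed", {
  fx <- dresd_fixture(seed = 7)
  grid <- grid_from_samples(fx$geo, spacing = 60)
  d1 <- suppressWarnings(dresd_analysis(fx$pairs, grid, n_iter = 80, seed = 11))
  d2 <- suppressWarnings(dresd_analysis(fx$pairs, grid, n_iter = 80, seed = 11))
  expect_identical(tidy(d1), tidy(d2))
})

test_that("strongly significant points are stable under reseeding", {
  # planted structure: cross-cluster pairs carry high residuals near x = 0
  set.seed(8)
  n_half <- 30
  geo <- sample_geo(data.frame(
    sample_id = sprintf("s%02d", 1:(2 * n_half)),
    x = c(rnorm(n_half, -60, 5), rnorm(n_half, 60, 5)),
    y = c(runif(n_half, 0, 150), runif(n_half, 0, 150))))
  side <- rep(c("L", "R"), each = n_half)
  up <- spatgen:::upper_pairs(2 * n_half)
  gen <- matrix(0, 2 * n_half, 2 * n_half,
                dimnames = list(geo$sample_id, geo$sample_id))
  cross <- side[up$i] != side[up$j]
  gen[cbind(up$i, up$j)] <- ifelse(cross, 1, 0) + rnorm(length(up$i), 0, 0.02)
  gen[lower.tri(gen)] <- t(gen)[lower.tri(gen)]
  dgen <- spatgen:::new_dist_matrix(gen, "dps")
  pairs <- build_pairs(geo, dgen, ibd_model = fit_ibd(build_pairs(geo, dgen), "linear"))
  grid <- grid_from_samples(geo, spacing = 20)
  base <- suppressWarnings(
    dresd_analysis(pairs, grid, classes = list(c(80, 140)),
                   n_iter = 1000, seed = 100))
  strong <- tidy(base)$p < 0.01
  skip_if(sum(strong) == 0)
  stable <- vapply(1:10, function(k) {
    d <- suppressWarnings(
      dresd_analysis(pairs, grid, classes = list(c(80, 140)),
                     n_iter = 1000, seed = 200 + k))
    mean(tidy(d)$label[strong] == tidy(base)$label[strong])
  }, 0)
  expect_gte(mean(stable), 0.95)
})
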