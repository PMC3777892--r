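test_that("IDW reproduces hand-computed weights and the coincidence rule", {
  grid <- grid_spec(0, 0, spacing = 1, nx = 5, ny = 1)
  pts <- tibble::tibble(x = c(0, 4), y = c(0, 0), value = c(0, 1))
  f <- idw_interpolate(pts, grid)
  # at (1,0): (0 * 1 + 1 * 1/3) / (1 + 1/3) = 0.25
  expect_equal(f$value[f$x == 1], 0.25, tolerance = 1e-12)
  # grid point coincident with a sample takes that sample's value
  expect_equal(f$value[f$x == 0], 0)
  expect_equal(f$value[f$x == 4], 1)
  # single sample: constant field
  f1 <- idw_interpolate(tibble::tibble(x = 2, y = 0, value = 0.7), grid)
  expect_equal(f1$value, rep(0.7, 5))
  expect_error(idw_interpolate(tibble::tibble(x = numeric(), y = numeric(),
                                              value = numeric()), grid),
               "empty")
})

test_that("interpolated membership columns conserve the row-sum of one", {
  sim <- simulate_dataset(synth_config(n = 60, k = 3, seed = 12))
  grid <- grid_from_samples(sim$geo, spacing = 25)
  pts <- dplyr::bind_cols(sim$geo[c("x", "y")],
                          tibble::as_tibble(as.data.frame(q_matrix(sim$membership))))
  f <- idw_interpolate(pts, grid)
  sums <- rowSums(f[clusters_of(sim$membership)])
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("the field is translation-equivariant", {
  set.seed(5)
  pts <- tibble::tibble(x = runif(20, 0, 100), y = runif(20, 0, 100),
                        value = rnorm(20))
  g1 <- grid_spec(0, 0, 10, 6, 6)
  g2 <- grid_spec(1000, -500, 10, 6, 6)
  f1 <- idw_interpolate(pts, g1)
  f2 <- idw_interpolate(dplyr::mutate(pts, x = x + 1000, y = y - 500), g2)
  expect_equal(f1$value, f2$value, tolerance = 1e-9)
})

test_that("classification recovers planted two-group structure", {
  set.seed(77)
  n <- 60
  west <- tibble::tibble(
    sample_id = sprintf("w%02d", 1:(n / 2)),
    x = rnorm(n / 2, 50, 15), y = rnorm(n / 2, 100, 15))
  east <- tibble::tibble(
    sample_id = sprintf("e%02d", 1:(n / 2)),
    x = rnorm(n / 2, 350, 15), y = rnorm(n / 2, 100, 15))
  geo <- sample_geo(dplyr::bind_rows(west, east))
  q <- membership_matrix(data.frame(
    sample_id = geo$sample_id,
    A = rep(c(0.95, 0.05), each = n / 2),
    B = rep(c(0.05, 0.95), each = n / 2)))
  rc <- classify_ranges(q, geo, grid = grid_from_samples(geo, spacing = 20),
                        n_boot = 200, seed = 42)
  fld <- tidy(rc)
  nearest <- function(cx, cy, grp) {
    sub <- fld[fld$group == grp, ]
    sub$class[which.min((sub$x - cx)^2 + (sub$y - cy)^2)]
  }
  expect_equal(as.character(nearest(50, 100, "A")), "core")
  expect_equal(as.character(nearest(350, 100, "B")), "core")
  expect_equal(as.character(nearest(50, 100, "B")), "outside")
  # coverage fractions sum to one per group
  rep_ <- glance(rc)
  expect_equal(rep_$core + rep_$probable + rep_$outside, c(1, 1))
})

test_that("identical membership rows give the degenerate all-probable field", {
  geo <- random_geo(20, seed = 3)
  q <- membership_matrix(data.frame(sample_id = geo$sample_id,
                                    A = 0.5, B = 0.5))
  expect_warning(rc <- classify_ranges(q, geo, n_boot = 50, seed = 1),
                 "degenerate")
  expect_true(all(tidy(rc)$class == "probable"))
  expect_equal(glance(rc)$probable, c(1, 1))
})

test_that("classification is invariant under group relabelling", {
  sim <- simulate_dataset(synth_config(n = 50, k = 3, seed = 21))
  grid <- grid_from_samples(sim$geo, spacing = 30)
  rc1 <- classify_ranges(sim$membership, sim$geo, grid = grid,
                         n_boot = 100, seed = 7)
  qq <- sim$membership[c("sample_id", "G3", "G1", "G2")]
  q2 <- membership_matrix(as.data.frame(qq))
  rc2 <- classify_ranges(q2, sim$geo, grid = grid, n_boot = 100, seed = 7)
  f1 <- tidy(rc1); f2 <- tidy(rc2)
  for (g in c("G1", "G2", "G3")) {
    expect_equal(f1$class[f1$group == g], f2$class[f2$group == g])
    expect_equal(f1$value[f1$group == g], f2$value[f2$group == g])
  }
})

test_that("shrinking alpha only moves points into 'probable'", {
  sim <- simulate_dataset(synth_config(n = 50, k = 2, seed = 31))
  grid <- grid_from_samples(sim$geo, spacing = 30)
  rc_wide <- classify_ranges(sim$membership, sim$geo, grid = grid,
                             n_boot = 200, alpha = 0.10, seed = 5)
  rc_narrow <- classify_ranges(sim$membership, sim$geo, grid = grid,
                               n_boot = 200, alpha = 0.01, seed = 5)
  wide <- as.character(tidy(rc_wide)$class)
  narrow <- as.character(tidy(rc_narrow)$class)
  moved <- wide != narrow
  expect_true(all(narrow[moved] == "probable"))
})

test_that("classification is bit-reproducible given a seed", {
  sim <- simulate_dataset(synth_config(n = 40, k = 2, seed = 61))
  grid <- grid_from_samples(sim$geo, spacing = 40)
  rc1 <- classify_ranges(sim$membership, sim$geo, grid = grid,
                         n_boot = 80, seed = 123)
  rc2 <- classify_ranges(sim$membership, sim$geo, grid = grid,
                         n_boot = 80, seed = 123)
  expect_identical(tidy(rc1), tidy(rc2))
  rc3 <- classify_ranges(sim$membership, sim$geo, grid = grid,
                         n_boot = 80, seed = 124, resample = "permute")
  expect_false(identical(tidy(rc1)$lower, tidy(rc3)$lower))
})

test_that("classify_ranges validates its inputs", {
  geo <- random_geo(10, seed = 1)
  q <- membership_matrix(data.frame(sample_id = geo$sample_id,
                                    A = runif(10, 0.3, 0.7)) |>
                           dplyr::mutate(B = 1 - A))
  expect_error(classify_ranges(q, geo, n_boot = 10), "n_boot")
  expect_error(classify_ranges(q, geo[1:5, ], n_boot = 50), "coordinates")
})
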