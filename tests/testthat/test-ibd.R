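test_that("a perfectly correlated pair of matrices gives r = 1 and the floor p", {
  geo <- random_geo(5, seed = 4)
  dgeo <- geographic_distances(geo)
  dgen <- unclass(dgeo) * 2 + 1
  diag(dgen) <- 0
  mt <- mantel_test(dgeo, dgen, n_perm = 99, seed = 1)
  expect_equal(mt$statistic, 1, tolerance = 1e-12)
  expect_equal(mt$p_value, 1 / 100)
})

test_that("random-permutation p agrees with exhaustive enumeration at n = 4", {
  set.seed(9)
  m1 <- as.matrix(stats::dist(matrix(runif(8), 4)))
  m2 <- as.matrix(stats::dist(matrix(runif(8), 4)))
  ex <- mantel_test(m1, m2, exhaustive = TRUE)
  expect_equal(ex$n_perm, 23L)
  # exhaustive p is k/24 for integer k and must match the sampling
  # convention (1 + #{>=}) / (1 + n_perm) when all 23 non-identity
  # permutations are drawn
  r_obs <- ex$statistic
  up <- upper.tri(m1)
  perms <- spatgen:::all_permutations(4)
  r_all <- apply(perms, 1, function(p) cor(m1[up], m2[p, p][up]))
  expect_equal(ex$p_value, mean(r_all >= r_obs - 1e-12))
  expect_equal(ex$p_value * 24, round(ex$p_value * 24))
})

test_that("mantel agrees with vegan on statistic and is calibrated on it", {
  skip_if_not_installed("vegan")
  geo <- random_geo(20, seed = 6)
  dgeo <- geographic_distances(geo)
  set.seed(10)
  dgen <- as.matrix(stats::dist(matrix(runif(40), 20)))
  ours <- mantel_test(dgeo, dgen, n_perm = 499, seed = 3)
  ref <- vegan::mantel(stats::as.dist(dgeo), stats::as.dist(dgen),
                       permutations = 499)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  # both permutation p-values estimate the same tail probability
  expect_lt(abs(ours$p_value - ref$signif), 0.12)
})

test_that("a constant matrix yields NA with a warning", {
  m0 <- matrix(1, 4, 4); diag(m0) <- 0
  m0[,] <- 0
  m <- as.matrix(stats::dist(matrix(runif(8), 4)))
  expect_warning(mt <- mantel_test(m0, m, n_perm = 9), "undefined")
  expect_true(is.na(mt$statistic))
})

test_that("the Mantel null p-value is uniform (type-I error near 0.05)", {
  n <- 10
  rejections <- vapply(1:400, function(k) {
    set.seed(5000 + k)
    a <- as.matrix(stats::dist(matrix(runif(2 * n), n)))
    b <- as.matrix(stats::dist(matrix(runif(2 * n), n)))
    mantel_test(a, b, n_perm = 99)$p_value <= 0.05
  }, TRUE)
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})

test_that("noiseless asymptotic-exponential data are recovered exactly", {
  d <- seq(1, 300, length.out = 120)
  pairs <- tibble::tibble(geo_km = d, gen = 1 - 0.8 * exp(-0.05 * d))
  fit <- fit_ibd(pairs, "asymptotic_exp")
  expect_equal(unname(fit$parameters), c(1, 0.8, 0.05), tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # predictions are monotone non-decreasing by the b, c >= 0 constraint
  pr <- predict(fit, seq(0, 500, length.out = 200))
  expect_true(all(diff(pr) >= -1e-12))
})

test_that("linear fits obey least-squares identities", {
  pairs <- tibble::tibble(geo_km = c(1, 2, 3, 4), gen = c(2, 4, 6, 8))
  fit <- fit_ibd(pairs, "linear")
  expect_equal(pairs$gen - predict(fit, pairs$geo_km), rep(0, 4),
               tolerance = 1e-12)
  set.seed(2)
  noisy <- tibble::tibble(geo_km = runif(50, 0, 100),
                          gen = 0.1 + 0.002 * geo_km + rnorm(50, 0, 0.05))
  f2 <- fit_ibd(noisy, "linear")
  expect_equal(sum(noisy$gen - predict(f2, noisy$geo_km)), 0,
               tolerance = 1e-9)
  expect_error(fit_ibd(tibble::tibble(geo_km = rep(3, 5), gen = 1:5)),
               "equal")
})

test_that("build_pairs produces all unordered pairs with correct geometry", {
  geo <- random_geo(6, seed = 44)
  dgen <- dps_distances(random_gt(6, 4, seed = 44))
  pairs <- build_pairs(geo, dgen)
  expect_equal(nrow(pairs), choose(6, 2))
  # midpoint lies on the segment: distance from midpoint to each member
  # is half the pair distance
  g1 <- geo[match(pairs$id_1, geo$sample_id), ]
  half <- sqrt((pairs$mid_x - g1$x)^2 + (pairs$mid_y - g1$y)^2)
  expect_equal(half, pairs$geo_km / 2, tolerance = 1e-9)
  expect_true(all(pairs$bearing >= 0 & pairs$bearing < 180))
  # residuals on the fitted curve are zero for points on the curve
  fit <- fit_ibd(pairs, "linear")
  pr <- build_pairs(geo, dgen, ibd_model = fit)
  on_curve <- abs(pr$gen - predict(fit, pr$geo_km)) < 1e-12
  expect_equal(pr$residual[on_curve], rep(0, sum(on_curve)))
})

test_that("coincident samples give a zero-distance pair at their location", {
  geo <- sample_geo(data.frame(sample_id = c("a", "b"),
                               x = c(10, 10), y = c(20, 20)))
  dgen <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  pairs <- build_pairs(geo, spatgen:::new_dist_matrix(dgen, "dps"))
  expect_equal(pairs$geo_km, 0)
  expect_equal(c(pairs$mid_x, pairs$mid_y), c(10, 20))
})
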