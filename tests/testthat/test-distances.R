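test_that("geographic distances are Euclidean km with metric properties", {
  geo <- sample_geo(data.frame(sample_id = c("a", "b", "c"),
                               x = c(0, 3, 3), y = c(0, 4, 4)))
  d <- geographic_distances(geo)
  expect_equal(d["a", "b"], 5)
  expect_equal(d["b", "c"], 0)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  # triangle inequality on a random fixture
  g2 <- random_geo(12, seed = 8)
  m <- unclass(geographic_distances(g2))
  for (i in 1:12) for (j in 1:12) for (k in 1:12) {
    expect_lte(m[i, j], m[i, k] + m[k, j] + 1e-12)
  }
  expect_error(geographic_distances(
    sample_geo(data.frame(sample_id = "a", x = 1, y = 2)) |>
      dplyr::mutate(x = NA_real_)), "non-finite|missing")
})

test_that("D_LR reproduces the hand-computed one-locus example", {
  # group A holds 9 copies of allele 1 out of 10; group B the mirror image;
  # the focal pair are opposite homozygotes, so with loo off
  # D_LR = log10(0.81/0.01) = log10(81)
  gA <- list(i = c(1, 1), a2 = c(1, 1), a3 = c(1, 1), a4 = c(1, 1), a5 = c(1, 2))
  gB <- list(j = c(2, 2), b2 = c(2, 2), b3 = c(2, 2), b4 = c(2, 2), b5 = c(1, 2))
  genos <- c(lapply(gA, function(p) list(L1 = p)),
             lapply(gB, function(p) list(L1 = p)))
  groups <- setNames(rep(c("A", "B"), each = 5), names(genos))
  gt <- make_gt(genos, groups)
  d <- dlr_distances(gt, loo = FALSE)
  expect_equal(d["i", "j"], log10(81), tolerance = 1e-12)
})

test_that("same-group pairs evaluate to exactly zero", {
  gt <- random_gt(10, 4, A = 6, seed = 13, groups = rep(c("A", "B"), each = 5))
  d <- dlr_distances(gt)
  same <- unclass(d)[1:5, 1:5]
  expect_true(all(same == 0))
  expect_true(all(unclass(d)[6:10, 6:10] == 0))
})

test_that("identical group frequencies give the all-zero D_LR matrix", {
  # two groups containing the same multiset of genotypes, loo off so the
  # frequency pools are literally identical
  genos <- list(a1 = list(L1 = c(1, 2), L2 = c(3, 3)),
                a2 = list(L1 = c(2, 2), L2 = c(1, 3)),
                b1 = list(L1 = c(1, 2), L2 = c(3, 3)),
                b2 = list(L1 = c(2, 2), L2 = c(1, 3)))
  gt <- make_gt(genos, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  d <- dlr_distances(gt, loo = FALSE)
  expect_true(all(unclass(d) == 0))
})

test_that("D_LR equals the brute-force oracle on random small fixtures", {
  for (seed in c(3, 17, 29)) {
    gt <- random_gt(6, 3, A = 4, seed = seed,
                    groups = rep(c("A", "B", "C"), each = 2))
    expect_equal(as_mat(dlr_distances(gt, loo = TRUE)),
                 dlr_oracle(gt, loo = TRUE), tolerance = 1e-12)
    expect_equal(as_mat(dlr_distances(gt, loo = FALSE)),
                 dlr_oracle(gt, loo = FALSE), tolerance = 1e-12)
  }
})

test_that("D_LR handles missing calls by dropping the individual's locus", {
  gt <- random_gt(8, 3, A = 4, seed = 31, groups = rep(c("A", "B"), each = 4))
  tb <- as.data.frame(gt)
  tb$allele_1[tb$sample_id == "s01" & tb$locus == "L2"] <- NA
  tb$allele_2[tb$sample_id == "s01" & tb$locus == "L2"] <- NA
  gt2 <- genotype_table(tb, loci = loci_of(gt))
  expect_equal(as_mat(dlr_distances(gt2)), dlr_oracle(gt2), tolerance = 1e-12)
})

test_that("D_LR preconditions are enforced", {
  gt <- random_gt(4, 2, seed = 1, groups = c("A", "A", "A", "B"))
  expect_error(dlr_distances(gt, loo = TRUE), "leave-one-out")
  gt1 <- random_gt(4, 2, seed = 1, groups = rep("A", 4))
  expect_error(dlr_distances(gt1), ">= 2 groups")
  expect_error(dlr_distances(random_gt(4, 2, seed = 1)), "group label")
})

test_that("D_PS matches hand counts and its bounds", {
  gt <- make_gt(list(s1 = list(L1 = c(1, 2)), s2 = list(L1 = c(2, 3)),
                     s3 = list(L1 = c(1, 2)), s4 = list(L1 = c(4, 5))))
  d <- dps_distances(gt)
  expect_equal(d["s1", "s2"], 0.5)   # one shared allele of two
  expect_equal(d["s1", "s3"], 0)     # identical genotypes
  expect_equal(d["s1", "s4"], 1)     # fully disjoint
  # homozygote vs heterozygote multiset counting
  gt2 <- make_gt(list(a = list(L1 = c(2, 2)), b = list(L1 = c(1, 2))))
  expect_equal(dps_distances(gt2)["a", "b"], 0.5)
  # random fixture stays within [0, 1] and symmetric
  g3 <- random_gt(10, 5, A = 4, seed = 23)
  m <- unclass(dps_distances(g3))
  expect_true(all(m >= -1e-12 & m <= 1 + 1e-12))
  expect_true(isSymmetric(m))
})

test_that("a pair with no shared non-missing locus is NA with a warning", {
  tb <- data.frame(
    sample_id = c("s1", "s1", "s2", "s2", "s3", "s3"),
    locus = rep(c("L1", "L2"), 3),
    allele_1 = c(1, NA, NA, 2, 1, 2),
    allele_2 = c(1, NA, NA, 2, 1, 2))
  gt <- genotype_table(tb)
  expect_warning(d <- dps_distances(gt), "no shared")
  expect_true(is.na(d["s1", "s2"]))
  expect_false(is.na(d["s1", "s3"]))
})

test_that("tidy() on a distance matrix gives the n(n-1)/2 pair rows", {
  g <- random_geo(7, seed = 2)
  td <- tidy(geographic_distances(g))
  expect_equal(nrow(td), choose(7, 2))
  expect_true(all(td$distance >= 0))
})
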