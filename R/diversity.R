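#' Allele frequencies per (group, locus)
#'
#' Counts allele copies among non-missing calls only (locus-wise deletion
#' of missing data) and divides by the gene-copy count `2 * n_locus`.
#'
#' @param gt a [genotype_table()].
#' @param by_group count within each group label (requires labels on every
#'   sample); otherwise the whole table is one group `"all"`.
#' @return tibble `group`, `locus`, `allele`, `count`, `gene_copies`,
#'   `freq`; frequencies sum to 1 within each (group, locus).
#' @export
allele_frequencies <- function(gt, by_group = FALSE) {
  tb <- as_tibble(gt)
  if (by_group) {
    if (any(is.na(tb$group))) abort("by_group = TRUE requires a group label on every sample")
  } else {
    tb$group <- "all"
  }
  long <- tb %>%
    filter(!is.na(.data$allele_1)) %>%
    tidyr::pivot_longer(c("allele_1", "allele_2"), values_to = "allele") %>%
    count(.data$group, .data$locus, .data$allele, name = "count") %>%
    group_by(.data$group, .data$locus) %>%
    mutate(gene_copies = sum(.data$count),
           freq = .data$count / .data$gene_copies) %>%
    ungroup()
  present <- long %>% distinct(.data$group, .data$locus)
  expected <- tidyr::expand_grid(group = unique(tb$group),
                                 locus = loci_of(gt))
  gap <- dplyr::anti_join(expected, present, by = c("group", "locus"))
  if (nrow(gap) > 0) {
    abort(paste0("no non-missing call for group '", gap$group[1],
                 "', locus '", gap$locus[1], "'"))
  }
  long %>% arrange(.data$group, match(.data$locus, loci_of(gt)), .data$allele)
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies, by the hypergeometric rarefaction
#' `A_R = sum_i [1 - C(G - G_i, g) / C(G, g)]` over alleles with copy
#' counts `G_i`, `G = sum G_i` (`C(a, b) = 0` when `a < b`). Standardises
#' allele counts to a common sample size across groups of unequal size.
#'
#' @param counts non-negative allele copy counts.
#' @param g gene copies to rarefy to, `1 <= g <= sum(counts)`.
#' @return `A_R`, between 1 and `length(counts)`.
#' @examples
#' rarefied_richness(c(3, 1), g = 2) # 1.5
#' @export
rarefied_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  total <- sum(counts)
  if (g > total) abort("g exceeds the total number of gene copies")
  if (g < 1) abort("g must be >= 1")
  # lchoose(a, b) is -Inf for a < b, so the ratio term vanishes correctly
  sum(1 - exp(lchoose(total - counts, g) - lchoose(total, g)))
}

# ---- Weir & Cockerham (1984) variance components --------------------------
#
# Per locus and allele, with r populations, n_i individuals genotyped in
# population i, p_i the allele frequency and h_i the observed proportion of
# heterozygotes carrying the allele:
#   a (among populations), b (among individuals within populations),
#   c (within individuals).
# theta = sum(a) / sum(a + b + c); f = 1 - sum(c) / sum(b + c),
# both summed over alleles and loci (multilocus ratio-of-sums).
# With a single population the among-population component drops (a = 0,
# s^2 = 0) and f reduces to the within-population estimator.
wc_components <- function(gt, by_group = FALSE) {
  tb <- as_tibble(gt) %>% filter(!is.na(.data$allele_1))
  if (by_group) {
    if (any(is.na(tb$group))) abort("group labels required")
  } else {
    tb$group <- "all"
  }
  per_locus <- tb %>%
    group_by(.data$locus) %>%
    dplyr::group_map(function(d, key) {
      pops <- split(d, d$group)
      r <- length(pops)
      n_i <- vapply(pops, nrow, 0L)
      alleles <- sort(unique(c(d$allele_1, d$allele_2)))
      nbar <- mean(n_i)
      n_c <- if (r > 1) (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1) else nbar
      comp <- vapply(alleles, function(al) {
        p_i <- vapply(pops, function(pp) {
          (sum(pp$allele_1 == al) + sum(pp$allele_2 == al)) / (2 * nrow(pp))
        }, 0)
        h_i <- vapply(pops, function(pp) {
          mean((pp$allele_1 == al) != (pp$allele_2 == al))
        }, 0)
        pbar <- sum(n_i * p_i) / (r * nbar)
        hbar <- sum(n_i * h_i) / (r * nbar)
        s2 <- if (r > 1) sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar) else 0
        a <- if (r > 1) {
          (nbar / n_c) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
        } else 0
        b <- (nbar / (nbar - 1)) *
          (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
        c_ <- hbar / 2
        c(a = a, b = b, c = c_)
      }, c(a = 0, b = 0, c = 0))
      tibble(locus = key$locus, a = sum(comp["a", ]),
             b = sum(comp["b", ]), c = sum(comp["c", ]))
    }) %>%
    bind_rows()
  per_locus
}

wc_f <- function(components) {
  denom <- sum(components$b + components$c)
  if (denom <= 0) return(NA_real_)
  1 - sum(components$c) / denom
}

wc_theta <- function(components) {
  denom <- sum(components$a + components$b + components$c)
  if (denom <= 0) return(NA_real_)
  sum(components$a) / denom
}

#' Per-locus and multilocus diversity summary
#'
#' Computes, per locus over non-missing calls: observed heterozygosity
#' `H_O`, Nei's unbiased expected heterozygosity
#' `H_Eunb = 2n/(2n-1) * (1 - sum p^2)`, the allele count `N_A`, and
#' rarefied allelic richness `A_R` at `2 * raref_n` gene copies; plus the
#' multilocus inbreeding coefficient `F_IS` with a percentile bootstrap
#' confidence interval obtained by resampling loci with replacement.
#'
#' @param gt a [genotype_table()].
#' @param raref_n rarefaction size in individuals; default = smallest
#'   per-locus count of genotyped individuals.
#' @param fis_mode `"wc"` (Weir & Cockerham's f, the default — the
#'   estimator classic population-genetics software reports as Wright's
#'   F_IS) or `"nei"` (`1 - mean H_O / mean H_Eunb`).
#' @param n_boot bootstrap replicates for the F_IS interval (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed optional integer seed for the bootstrap.
#' @return a `diversity_summary` object; see [tidy.diversity_summary()]
#'   and [glance.diversity_summary()].
#' @export
diversity_summary <- function(gt, raref_n = NULL, fis_mode = c("wc", "nei"),
                              n_boot = 1000, conf = 0.95, seed = NULL) {
  fis_mode <- match.arg(fis_mode)
  tb <- as_tibble(gt) %>% filter(!is.na(.data$allele_1))
  if (length(unique(tb$sample_id)) < 2) abort("need at least 2 individuals")
  freqs <- allele_frequencies(gt, by_group = FALSE)

  per_locus <- tb %>%
    group_by(.data$locus) %>%
    summarise(n = dplyr::n(),
              h_o = mean(.data$allele_1 != .data$allele_2),
              .groups = "drop") %>%
    left_join(
      freqs %>%
        group_by(.data$locus) %>%
        summarise(sum_p2 = sum(.data$freq^2),
                  n_alleles = dplyr::n(), .groups = "drop"),
      by = "locus"
    ) %>%
    mutate(h_e_unb = (2 * .data$n) / (2 * .data$n - 1) * (1 - .data$sum_p2))

  min_n <- min(per_locus$n)
  raref_n <- raref_n %||% min_n
  if (raref_n > min_n) {
    abort(paste0("raref_n = ", raref_n, " exceeds the smallest per-locus ",
                 "sample size (", min_n, " individuals)"))
  }
  g <- 2L * raref_n
  ar <- freqs %>%
    group_by(.data$locus) %>%
    summarise(a_r = rarefied_richness(.data$count, g = g), .groups = "drop")
  per_locus <- per_locus %>%
    left_join(ar, by = "locus") %>%
    mutate(locus = factor(.data$locus, levels = loci_of(gt))) %>%
    arrange(.data$locus) %>%
    mutate(locus = as.character(.data$locus)) %>%
    select("locus", "n", "h_o", "h_e_unb", n_alleles = "n_alleles", a_r = "a_r")

  comp <- wc_components(gt, by_group = FALSE)
  comp <- comp[match(per_locus$locus, comp$locus), ]
  fis_point <- switch(fis_mode,
    wc = wc_f(comp),
    nei = {
      he <- mean(per_locus$h_e_unb)
      if (he <= 0) NA_real_ else 1 - mean(per_locus$h_o) / he
    }
  )
  if (is.na(fis_point)) {
    warn("F_IS undefined (all loci monomorphic); reporting NA")
    fis_ci <- c(NA_real_, NA_real_)
  } else {
    if (!is.null(seed)) set.seed(seed)
    L <- nrow(per_locus)
    boots <- vapply(seq_len(n_boot), function(k) {
      idx <- sample.int(L, L, replace = TRUE)
      switch(fis_mode,
        wc = wc_f(comp[idx, ]),
        nei = {
          he <- mean(per_locus$h_e_unb[idx])
          if (he <= 0) NA_real_ else 1 - mean(per_locus$h_o[idx]) / he
        }
      )
    }, 0)
    boots <- boots[!is.na(boots)]
    lo <- (1 - conf) / 2
    fis_ci <- q_type1(boots, c(lo, 1 - lo))
  }

  structure(
    list(per_locus = per_locus,
         fis = fis_point, fis_ci = fis_ci, fis_mode = fis_mode,
         raref_n = raref_n, conf = conf, n_boot = n_boot),
    class = "diversity_summary"
  )
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat("<diversity_summary> ", nrow(x$per_locus), " loci\n", sep = "")
  cat(sprintf("  mean H_O = %.3f, mean H_Eunb = %.3f, mean N_A = %.2f, mean A_R(%d) = %.2f\n",
              mean(x$per_locus$h_o), mean(x$per_locus$h_e_unb),
              mean(x$per_locus$n_alleles), x$raref_n, mean(x$per_locus$a_r)))
  cat(sprintf("  multilocus F_IS (%s) = %.4f [%0.3f, %0.3f] (%d%% bootstrap over loci)\n",
              x$fis_mode, x$fis, x$fis_ci[1], x$fis_ci[2],
              round(100 * x$conf)))
  invisible(x)
}

#' Per-locus diversity statistics as a tibble
#' @param x a `diversity_summary`.
#' @param ... unused.
#' @return tibble with one row per locus.
#' @export
tidy.diversity_summary <- function(x, ...) x$per_locus

#' One-row multilocus diversity summary
#' @param x a `diversity_summary`.
#' @param ... unused.
#' @return one-row tibble of means and the F_IS estimate with its
#'   bootstrap interval.
#' @export
glance.diversity_summary <- function(x, ...) {
  tibble(
    n_loci = nrow(x$per_locus),
    mean_h_o = mean(x$per_locus$h_o),
    mean_h_e_unb = mean(x$per_locus$h_e_unb),
    mean_n_alleles = mean(x$per_locus$n_alleles),
    mean_a_r = mean(x$per_locus$a_r),
    raref_n = x$raref_n,
    fis = x$fis,
    fis_low = x$fis_ci[1],
    fis_high = x$fis_ci[2],
    fis_mode = x$fis_mode
  )
}

#' Pairwise F_ST between groups
#'
#' Multilocus Weir & Cockerham theta for every pair of group labels,
#' summing variance components over alleles and loci.
#'
#' @param gt a [genotype_table()] with group labels; every group needs
#'   `>= 2` individuals.
#' @return symmetric matrix of theta values, zero diagonal.
#' @export
pairwise_fst <- function(gt) {
  labs <- groups_of(gt)
  if (any(is.na(labs))) abort("pairwise_fst requires a group label on every sample")
  sizes <- table(labs)
  if (any(sizes < 2)) {
    abort(paste0("group with < 2 individuals: ",
                 names(sizes)[sizes < 2][1]))
  }
  gs <- names(sizes)
  if (length(gs) < 2) abort("need >= 2 groups")
  m <- matrix(0, length(gs), length(gs), dimnames = list(gs, gs))
  for (i in seq_along(gs)[-length(gs)]) {
    for (j in (i + 1):length(gs)) {
      sub <- as_tibble(gt) %>% filter(.data$group %in% c(gs[i], gs[j]))
      sub <- genotype_table(sub, loci = intersect(loci_of(gt), unique(sub$locus)))
      th <- wc_theta(wc_components(sub, by_group = TRUE))
      m[i, j] <- m[j, i] <- th
    }
  }
  m
}
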