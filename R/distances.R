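new_dist_matrix <- function(m, kind) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  structure(m, kind = kind, class = c("dist_matrix", "matrix", "array"))
}

#' Kind tag of a distance matrix
#' @param m a `dist_matrix`.
#' @return `"geographic_km"`, `"dlr"` or `"dps"`.
#' @export
dist_kind <- function(m) attr(m, "kind", exact = TRUE)

#' Long pair form of a distance matrix
#'
#' @param x a `dist_matrix`.
#' @param ... unused.
#' @return tibble `id_1`, `id_2`, `distance`, one row per unordered pair
#'   (upper triangle).
#' @export
tidy.dist_matrix <- function(x, ...) {
  n <- nrow(x)
  up <- upper_pairs(n)
  ids <- rownames(x) %||% as.character(seq_len(n))
  tibble(id_1 = ids[up$i], id_2 = ids[up$j],
         distance = x[cbind(up$i, up$j)])
}

#' Pairwise geographic distances (km)
#'
#' Euclidean distances between planar sample coordinates.
#'
#' @param geo a [sample_geo()] tibble.
#' @return symmetric `dist_matrix` (kind `"geographic_km"`), zero diagonal,
#'   dimnames = sample ids.
#' @export
geographic_distances <- function(geo) {
  if (any(is.na(geo$x) | is.na(geo$y))) {
    abort(paste0("missing location for sample '",
                 geo$sample_id[is.na(geo$x) | is.na(geo$y)][1], "'"))
  }
  m <- as.matrix(stats::dist(cbind(geo$x, geo$y)))
  dimnames(m) <- list(geo$sample_id, geo$sample_id)
  new_dist_matrix(m, "geographic_km")
}

#' Genotype likelihood ratio distance (D_LR)
#'
#' For individuals `i`, `j` with source groups `P_i`, `P_j`, computes
#' per-individual log10 genotype likelihoods under Hardy-Weinberg
#' proportions from each group's allele frequencies —
#' `log L(i|P) = sum_loci log10(p_a^2)` for homozygotes and
#' `log10(2 p_a p_b)` for heterozygotes — and
#' `D_LR(i,j) = [ (logL(i|P_i) - logL(i|P_j)) + (logL(j|P_j) - logL(j|P_i)) ] / 2`.
#' The construction is symmetric, may be negative, and evaluates to
#' exactly 0 for pairs from the same group. Built on the assignment
#' index of classic individual-assignment calculators; it resolves
#' fine-scale divergence well where individuals are weakly differentiated.
#'
#' A locus at which an individual has a missing call is dropped from both
#' of that individual's likelihoods. Zero (or unobserved) frequencies are
#' replaced by `zero_sub` (default `1/(G_P + 1)` with `G_P` the group's
#' gene-copy count at the locus, i.e. `1/(2 n_P + 1)`), applied after any
#' leave-one-out adjustment.
#'
#' @param gt a [genotype_table()]. Group labels are taken from `gt` unless
#'   `groups` is given.
#' @param groups optional: a named character vector of labels, or a
#'   [membership_matrix()] whose per-row argmax defines the groups.
#' @param loo leave-one-out: remove an individual's own alleles from its
#'   group's frequencies when evaluating its likelihood in that group
#'   (default `TRUE`; requires every group to have `>= 2` members).
#' @param zero_sub fixed substitute frequency, or `NULL` for the
#'   per-(group, locus) default.
#' @return symmetric `dist_matrix` of kind `"dlr"`; the group labels used
#'   are attached as attribute `"groups"`.
#' @export
dlr_distances <- function(gt, groups = NULL, loo = TRUE, zero_sub = NULL) {
  ids <- samples_of(gt)
  n <- length(ids)
  labs <- resolve_groups(gt, groups)
  labs <- labs[ids]
  if (any(is.na(labs))) abort("every sample needs a group label for D_LR")
  gl <- sort(unique(labs))
  if (length(gl) < 2) abort("D_LR needs >= 2 groups")
  if (loo && any(table(labs) < 2)) {
    abort("leave-one-out requires every group to have >= 2 members")
  }
  G <- length(gl)
  gidx <- match(labs, gl)

  LL <- matrix(0, n, G, dimnames = list(ids, gl))
  tb <- as_tibble(gt)
  for (lc in loci_of(gt)) {
    d <- tb[tb$locus == lc, ]
    d <- d[match(ids, d$sample_id), ]
    ok <- which(!is.na(d$allele_1))
    if (length(ok) == 0) next
    alleles <- sort(unique(c(d$allele_1[ok], d$allele_2[ok])))
    A <- length(alleles)
    i1 <- match(d$allele_1, alleles)
    i2 <- match(d$allele_2, alleles)
    # counts: G x A allele-copy counts among genotyped members of each group
    cnt <- matrix(0, G, A)
    for (k in ok) {
      g <- gidx[k]
      cnt[g, i1[k]] <- cnt[g, i1[k]] + 1
      cnt[g, i2[k]] <- cnt[g, i2[k]] + 1
    }
    copies <- rowSums(cnt)
    m1 <- cnt[, i1[ok], drop = FALSE]        # G x n_ok
    m2 <- cnt[, i2[ok], drop = FALSE]
    cp <- matrix(copies, G, length(ok))
    if (loo) {
      hom <- 1 + (i1[ok] == i2[ok])
      sel <- cbind(gidx[ok], seq_along(ok))
      m1[sel] <- m1[sel] - hom
      m2[sel] <- m2[sel] - hom
      cp[sel] <- cp[sel] - 2
    }
    f1 <- m1 / cp
    f2 <- m2 / cp
    sub <- if (is.null(zero_sub)) 1 / (cp + 1) else zero_sub
    if (!is.matrix(sub)) sub <- matrix(sub, G, length(ok))
    f1 <- ifelse(f1 <= 0, sub, f1)
    f2 <- ifelse(f2 <= 0, sub, f2)
    het <- matrix(i1[ok] != i2[ok], G, length(ok), byrow = TRUE)
    p <- ifelse(het, 2 * f1 * f2, f1 * f1)
    LL[ok, ] <- LL[ok, ] + t(log10(p))
  }

  own <- LL[cbind(seq_len(n), gidx)]
  # d_half[i, j] = logL(i|P_i) - logL(i|P_j)
  d_half <- matrix(own, n, n) - LL[, gidx, drop = FALSE]
  m <- (d_half + t(d_half)) / 2
  diag(m) <- 0
  dimnames(m) <- list(ids, ids)
  out <- new_dist_matrix(m, "dlr")
  attr(out, "groups") <- setNames(labs, ids)
  out
}

resolve_groups <- function(gt, groups) {
  if (is.null(groups)) {
    labs <- groups_of(gt)
  } else if (inherits(groups, "membership_tbl")) {
    labs <- assign_groups(groups)
  } else {
    labs <- groups
    if (is.null(names(labs))) {
      ids <- samples_of(gt)
      if (length(labs) != length(ids)) {
        abort("unnamed `groups` must have one label per sample")
      }
      labs <- setNames(as.character(labs), ids)
    }
  }
  missing_ids <- setdiff(samples_of(gt), names(labs))
  if (length(missing_ids) > 0) {
    abort(paste0("no group label for sample(s): ",
                 paste(head(missing_ids, 3), collapse = ", ")))
  }
  labs
}

#' Proportion-of-shared-alleles distance (D_PS)
#'
#' `D_PS(i, j) = 1 - mean_loci(shared / 2)` where `shared` is the multiset
#' intersection size of the two allele pairs at a locus, averaged over the
#' loci non-missing in both individuals. Values lie in `[0, 1]`; identical
#' genotypes give 0 and fully disjoint ones give 1. A group-free metric,
#' so it resolves within-group pairs where D_LR collapses to 0.
#'
#' @param gt a [genotype_table()].
#' @return symmetric `dist_matrix` of kind `"dps"`; pairs with no shared
#'   non-missing locus are `NA` (with a warning).
#' @export
dps_distances <- function(gt) {
  ids <- samples_of(gt)
  n <- length(ids)
  num <- matrix(0, n, n)
  den <- matrix(0L, n, n)
  tb <- as_tibble(gt)
  for (lc in loci_of(gt)) {
    d <- tb[tb$locus == lc, ]
    d <- d[match(ids, d$sample_id), ]
    a1 <- d$allele_1
    a2 <- d$allele_2
    ok <- !is.na(a1)
    straight <- outer(a1, a1, "==") + outer(a2, a2, "==")
    cross <- outer(a1, a2, "==") + outer(a2, a1, "==")
    shared <- pmax(straight, cross)
    both <- outer(ok, ok, "&")
    shared[!both] <- 0
    num <- num + shared / 2
    den <- den + both
  }
  m <- 1 - num / den
  if (any(den == 0 & row(den) != col(den))) {
    warn("pair(s) with no shared non-missing locus: D_PS is NA there")
  }
  diag(m) <- 0
  dimnames(m) <- list(ids, ids)
  new_dist_matrix(m, "dps")
}
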