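# Independent oracles and fixture builders. Everything here is coded from
# first principles (textbook formulas, literal enumeration), deliberately
# ignoring the package's implementation, so the two routes can disagree.

# Build a genotype_tbl from a wide matrix spec:
# geno[[sample]] = list(locus = c(a, b), ...); NA pair = missing.
make_gt <- function(genos, groups = NULL) {
  rows <- list()
  for (s in names(genos)) {
    for (l in names(genos[[s]])) {
      p <- genos[[s]][[l]]
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = s,
        group = if (is.null(groups)) NA_character_ else groups[[s]],
        locus = l, allele_1 = p[1], allele_2 = p[2])
    }
  }
  genotype_table(do.call(rbind, rows))
}

# Random genotype table: n samples, L loci, A alleles, optional groups.
random_gt <- function(n, L, A = 5, groups = NULL, seed = 1) {
  set.seed(seed)
  df <- expand.grid(sample_id = sprintf("s%02d", seq_len(n)),
                    locus = sprintf("L%d", seq_len(L)),
                    stringsAsFactors = FALSE)
  df$allele_1 <- sample.int(A, nrow(df), replace = TRUE)
  df$allele_2 <- sample.int(A, nrow(df), replace = TRUE)
  if (!is.null(groups)) {
    df$group <- groups[match(df$sample_id, sprintf("s%02d", seq_len(n)))]
  }
  genotype_table(df)
}

# ---- Weir & Cockerham (1984) oracle --------------------------------------
# Literal per-allele variance components a, b, c from the published
# formulas, for r >= 1 populations at one locus. Input: list of
# per-population genotype matrices (rows = individuals, two integer
# columns), missing rows removed beforehand.
wc_oracle_locus <- function(pop_genos) {
  r <- length(pop_genos)
  n_i <- vapply(pop_genos, nrow, 0L)
  alleles <- sort(unique(unlist(pop_genos)))
  nbar <- mean(n_i)
  nc <- if (r > 1) (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1) else nbar
  acc <- c(a = 0, b = 0, c = 0)
  for (al in alleles) {
    p_i <- vapply(pop_genos, function(g) mean(g == al), 0)
    h_i <- vapply(pop_genos, function(g) mean((g[, 1] == al) != (g[, 2] == al)), 0)
    pbar <- sum(n_i * p_i) / (r * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    s2 <- if (r > 1) sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar) else 0
    a <- if (r > 1) {
      (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                       (nbar - 1))
    } else 0
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    acc <- acc + c(a = a, b = b, c = cc)
  }
  acc
}

# Multilocus theta and f over a genotype_tbl, via the oracle components.
wc_oracle <- function(gt, use_groups = TRUE) {
  tb <- as.data.frame(gt)
  tb <- tb[!is.na(tb$allele_1), ]
  if (!use_groups) tb$group <- "all"
  comps <- lapply(split(tb, tb$locus), function(d) {
    pops <- lapply(split(d, d$group), function(p) {
      as.matrix(p[c("allele_1", "allele_2")])
    })
    wc_oracle_locus(pops)
  })
  tot <- Reduce(`+`, comps)
  list(theta = unname(tot["a"] / sum(tot)),
       f = unname(1 - tot["c"] / (tot["b"] + tot["c"])))
}

# ---- naive D_LR oracle ----------------------------------------------------
# Enumerates the likelihood products literally, individual by individual,
# locus by locus, with plain loops. loo and zero substitution as in the
# documented convention (substitute = 1 / (gene copies + 1)).
dlr_oracle <- function(gt, loo = TRUE) {
  tb <- as.data.frame(gt)
  ids <- unique(tb$sample_id)
  grp <- sapply(ids, function(s) tb$group[tb$sample_id == s][1])
  gl <- sort(unique(grp))
  loci <- unique(tb$locus)

  loglik <- function(i, P) {
    total <- 0
    for (l in loci) {
      row_i <- tb[tb$sample_id == i & tb$locus == l, ]
      if (is.na(row_i$allele_1)) next
      members <- ids[grp == P]
      pool <- c()
      for (m in members) {
        rm_ <- tb[tb$sample_id == m & tb$locus == l, ]
        if (!is.na(rm_$allele_1)) pool <- c(pool, rm_$allele_1, rm_$allele_2)
      }
      if (loo && grp[[i]] == P) {
        for (al in c(row_i$allele_1, row_i$allele_2)) {
          pool <- pool[-match(al, pool)]
        }
      }
      fr <- function(al) {
        f <- sum(pool == al) / length(pool)
        if (f <= 0) 1 / (length(pool) + 1) else f
      }
      p <- if (row_i$allele_1 == row_i$allele_2) {
        fr(row_i$allele_1)^2
      } else {
        2 * fr(row_i$allele_1) * fr(row_i$allele_2)
      }
      total <- total + log10(p)
    }
    total
  }
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- loglik(ids[i], grp[[ids[i]]]) - loglik(ids[i], grp[[ids[j]]])
      b <- loglik(ids[j], grp[[ids[j]]]) - loglik(ids[j], grp[[ids[i]]])
      m[i, j] <- m[j, i] <- (a + b) / 2
    }
  }
  m
}

# Strip dist_matrix attributes down to a plain named matrix.
as_mat <- function(m) {
  matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
}

# Canonical row order for comparing genotype tables across dialects.
canon_gt <- function(gt) {
  dplyr::arrange(tibble::as_tibble(gt), sample_id, locus)
}

# Geometry fixture: n points scattered in a box (km).
random_geo <- function(n, width = 300, height = 200, seed = 1) {
  set.seed(seed)
  sample_geo(data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                        x = runif(n, 0, width), y = runif(n, 0, height)))
}
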