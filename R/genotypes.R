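#' Build a genotype table from a data frame
#'
#' The central genotype container is a long tibble with one row per sample
#' x locus, columns `sample_id`, `group` (optional label, `NA` allowed),
#' `locus`, `allele_1`, `allele_2`. Allele labels are positive integers
#' (microsatellite fragment lengths or arbitrary codes); a missing call has
#' `NA` in both allele columns. Pairs are unordered and stored normalised
#' as `allele_1 <= allele_2`.
#'
#' @param df a data frame with columns `sample_id`, `locus`, `allele_1`,
#'   `allele_2` and optionally `group`.
#' @param loci optional character vector fixing locus order; defaults to
#'   order of first appearance.
#' @return a `genotype_tbl`, a tibble subclass carrying the locus order as
#'   an attribute.
#' @examples
#' df <- data.frame(
#'   sample_id = rep(c("s1", "s2"), each = 2),
#'   locus     = rep(c("L1", "L2"), 2),
#'   allele_1  = c(101, 140, 103, 140),
#'   allele_2  = c(103, 144, 101, NA)
#' )
#' genotype_table(df)
#' @export
genotype_table <- function(df, loci = NULL) {
  need <- c("sample_id", "locus", "allele_1", "allele_2")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("genotype table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  gt <- as_tibble(df)
  if (!"group" %in% names(gt)) gt$group <- NA_character_
  gt <- gt %>%
    mutate(
      sample_id = as.character(.data$sample_id),
      group     = as.character(.data$group),
      locus     = as.character(.data$locus),
      allele_1  = as.integer(.data$allele_1),
      allele_2  = as.integer(.data$allele_2)
    ) %>%
    select("sample_id", "group", "locus", "allele_1", "allele_2")

  half <- xor(is.na(gt$allele_1), is.na(gt$allele_2))
  if (any(half)) {
    abort("half-missing calls (one NA allele) are not allowed")
  }
  ok <- !is.na(gt$allele_1)
  if (any(gt$allele_1[ok] <= 0) || any(gt$allele_2[ok] <= 0)) {
    abort("allele labels must be positive integers")
  }
  # normalise unordered pair to (low, high)
  a1 <- pmin(gt$allele_1, gt$allele_2)
  a2 <- pmax(gt$allele_1, gt$allele_2)
  gt$allele_1 <- a1
  gt$allele_2 <- a2

  grp <- gt %>% distinct(.data$sample_id, .data$group)
  if (anyDuplicated(grp$sample_id)) {
    abort("a sample_id maps to more than one group label")
  }
  dup_cell <- gt %>% count(.data$sample_id, .data$locus) %>% filter(n > 1)
  if (nrow(dup_cell) > 0) {
    abort(paste0("duplicate sample x locus cell: ",
                 dup_cell$sample_id[1], " / ", dup_cell$locus[1]))
  }
  loci <- loci %||% unique(gt$locus)
  if (!setequal(loci, unique(gt$locus))) {
    abort("`loci` does not match the loci present in `df`")
  }
  all_na <- gt %>%
    group_by(.data$locus) %>%
    summarise(none = all(is.na(.data$allele_1)), .groups = "drop") %>%
    filter(.data$none)
  if (nrow(all_na) > 0) {
    abort(paste0("locus with no non-missing call: ", all_na$locus[1]))
  }
  new_genotype_tbl(gt, loci)
}

new_genotype_tbl <- function(gt, loci) {
  structure(gt, loci = as.character(loci),
            class = c("genotype_tbl", class(tibble())))
}

#' Locus names of a genotype table, in file order
#' @param gt a `genotype_tbl`.
#' @return character vector of locus names.
#' @export
loci_of <- function(gt) attr(gt, "loci", exact = TRUE) %||% unique(gt$locus)

#' Sample identifiers of a genotype table
#' @param gt a `genotype_tbl`.
#' @return character vector of unique sample ids, in order of appearance.
#' @export
samples_of <- function(gt) unique(gt$sample_id)

#' Per-sample group labels
#' @param gt a `genotype_tbl`.
#' @return named character vector, one label per sample (may be `NA`).
#' @export
groups_of <- function(gt) {
  g <- gt %>% distinct(.data$sample_id, .data$group)
  setNames(g$group, g$sample_id)
}

#' Attach or replace group labels on a genotype table
#'
#' @param gt a `genotype_tbl`.
#' @param groups named character vector (names = sample ids) or unnamed
#'   vector in `samples_of(gt)` order.
#' @return the relabelled `genotype_tbl`.
#' @export
set_groups <- function(gt, groups) {
  ids <- samples_of(gt)
  if (is.null(names(groups))) {
    if (length(groups) != length(ids)) {
      abort("unnamed `groups` must have one label per sample")
    }
    groups <- setNames(as.character(groups), ids)
  }
  missing_ids <- setdiff(ids, names(groups))
  if (length(missing_ids) > 0) {
    abort(paste0("no group label for sample(s): ",
                 paste(head(missing_ids, 3), collapse = ", ")))
  }
  gt$group <- unname(groups[gt$sample_id])
  new_genotype_tbl(gt, loci_of(gt))
}

# ---- readers -------------------------------------------------------------

#' Read multilocus genotypes
#'
#' Reads a genotype file in one of three dialects and returns the
#' normalised long `genotype_tbl`:
#'
#' * `structure2row` — whitespace-delimited, a header line of locus names,
#'   then two rows per individual (`id [group] allele...`), one allele per
#'   locus per row; missing coded `-9`.
#' * `genepop` — title line, locus names (one per line or one
#'   comma-separated line), `Pop` separators, then `id , 003006 ...` with
#'   concatenated 2- or 3-digit allele coding; missing allele coded `00`
#'   or `000`; individuals take the 1-based population index as group
#'   label (`pop_1`, `pop_2`, ...).
#' * `csv_wide` — header `sample_id[,group]`, then two columns per locus
#'   named `<locus>_1`, `<locus>_2`; missing is empty or `0`.
#'
#' @param path file path.
#' @param dialect one of `"structure2row"`, `"genepop"`, `"csv_wide"`.
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(path,
                           dialect = c("structure2row", "genepop", "csv_wide")) {
  dialect <- match.arg(dialect)
  switch(dialect,
    structure2row = read_structure2row(path),
    genepop       = read_genepop(path),
    csv_wide      = read_csv_wide(path)
  )
}

read_structure2row <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) abort("structure2row file too short")
  loci <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  L <- length(loci)
  body <- lines[-1]
  if (length(body) %% 2 != 0) {
    abort("structure2row body must have two rows per individual")
  }
  toks <- strsplit(trimws(body), "\\s+")
  nt <- lengths(toks)
  has_group <- all(nt == L + 2)
  if (!has_group && !all(nt == L + 1)) {
    bad <- which(nt != nt[1])[1] %||% which(nt != L + 1)[1]
    abort(paste0("ragged row in structure2row file at body line ", bad))
  }
  ids <- vapply(toks, `[[`, "", 1L)
  grp <- if (has_group) vapply(toks, `[[`, "", 2L) else rep(NA_character_, length(toks))
  alle <- do.call(rbind, lapply(toks, function(tk) {
    as.integer(tk[(length(tk) - L + 1):length(tk)])
  }))
  odd <- seq(1, nrow(alle), by = 2)
  if (any(ids[odd] != ids[odd + 1])) {
    abort("the two rows of an individual carry different ids")
  }
  if (anyDuplicated(ids[odd])) {
    abort(paste0("duplicate sample id: ", ids[odd][duplicated(ids[odd])][1]))
  }
  a1 <- alle[odd, , drop = FALSE]
  a2 <- alle[odd + 1, , drop = FALSE]
  a1[a1 == -9] <- NA_integer_
  a2[a2 == -9] <- NA_integer_
  df <- tibble(
    sample_id = rep(ids[odd], each = L),
    group     = rep(grp[odd], each = L),
    locus     = rep(loci, length(odd)),
    allele_1  = as.vector(t(a1)),
    allele_2  = as.vector(t(a2))
  )
  genotype_table(df, loci = loci)
}

read_genepop <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4) abort("genepop file too short")
  lines <- lines[nzchar(trimws(lines))]
  body <- lines[-1]  # drop title
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_idx) == 0) abort("genepop file has no Pop line")
  locus_lines <- body[seq_len(pop_idx[1] - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  pop_of <- findInterval(seq_along(body), pop_idx)
  rows <- which(pop_of > 0 & !(seq_along(body) %in% pop_idx))
  recs <- lapply(rows, function(r) {
    parts <- strsplit(body[r], ",")[[1]]
    if (length(parts) < 2) {
      abort(paste0("genepop line ", r + 1, " lacks the 'id ,' separator"))
    }
    id <- trimws(parts[1])
    gcodes <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(gcodes) != L) {
      abort(paste0("ragged genepop record for '", id, "': ",
                   length(gcodes), " genotypes, expected ", L))
    }
    w <- unique(nchar(gcodes))
    if (length(w) != 1 || !(w %in% c(4L, 6L))) {
      abort(paste0("genepop alleles for '", id,
                   "' are not uniformly 2- or 3-digit coded"))
    }
    half <- w / 2
    a1 <- as.integer(substr(gcodes, 1, half))
    a2 <- as.integer(substr(gcodes, half + 1, w))
    a1[a1 == 0] <- NA_integer_
    a2[a2 == 0] <- NA_integer_
    tibble(sample_id = id, group = paste0("pop_", pop_of[r]),
           locus = loci, allele_1 = a1, allele_2 = a2)
  })
  df <- bind_rows(recs)
  if (anyDuplicated(unique(df$sample_id)) ||
      anyDuplicated(df$sample_id[df$locus == loci[1]])) {
    dup <- df$sample_id[df$locus == loci[1]]
    abort(paste0("duplicate sample id: ", dup[duplicated(dup)][1]))
  }
  genotype_table(df, loci = loci)
}

read_csv_wide <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(df)) abort("csv_wide file needs a sample_id column")
  meta <- intersect(c("sample_id", "group"), names(df))
  acols <- setdiff(names(df), meta)
  if (length(acols) %% 2 != 0 ||
      !all(grepl("_[12]$", acols))) {
    abort("csv_wide allele columns must come in <locus>_1 / <locus>_2 pairs")
  }
  loci <- unique(sub("_[12]$", "", acols))
  if (!all(c(paste0(loci, "_1"), paste0(loci, "_2")) %in% acols)) {
    abort("csv_wide allele columns must come in <locus>_1 / <locus>_2 pairs")
  }
  if (anyDuplicated(df$sample_id)) {
    abort(paste0("duplicate sample id: ",
                 df$sample_id[duplicated(df$sample_id)][1]))
  }
  long <- df %>%
    tidyr::pivot_longer(dplyr::all_of(acols),
                        names_to = c("locus", ".value"),
                        names_pattern = "(.*)_([12])$") %>%
    rename(allele_1 = "1", allele_2 = "2") %>%
    mutate(allele_1 = ifelse(.data$allele_1 %in% 0, NA, .data$allele_1),
           allele_2 = ifelse(.data$allele_2 %in% 0, NA, .data$allele_2))
  genotype_table(long, loci = loci)
}

# ---- writers -------------------------------------------------------------

#' Write a genotype table
#'
#' Serialises a `genotype_tbl` in any of the three dialects accepted by
#' [read_genotypes()]; the write -> read round trip is loss-free for allele
#' labels, sample ids, locus names and (where the dialect can carry them)
#' group labels. GenePop output uses 3-digit allele coding and requires
#' allele labels `< 1000`; individuals are grouped into `Pop` blocks by
#' their group label (unlabelled tables form a single block).
#'
#' @param gt a `genotype_tbl`.
#' @param path output file path.
#' @param dialect one of `"structure2row"`, `"genepop"`, `"csv_wide"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path,
                            dialect = c("structure2row", "genepop", "csv_wide")) {
  dialect <- match.arg(dialect)
  loci <- loci_of(gt)
  wide <- genotypes_wide(gt, loci)
  switch(dialect,
    structure2row = {
      has_group <- !all(is.na(wide$group))
      a1 <- as.matrix(wide[paste0(loci, "_1")])
      a2 <- as.matrix(wide[paste0(loci, "_2")])
      a1[is.na(a1)] <- -9; a2[is.na(a2)] <- -9
      rows <- character(2 * nrow(wide))
      for (k in seq_len(nrow(wide))) {
        pre <- if (has_group) paste(wide$sample_id[k], wide$group[k]) else wide$sample_id[k]
        rows[2 * k - 1] <- paste(pre, paste(a1[k, ], collapse = " "))
        rows[2 * k]     <- paste(pre, paste(a2[k, ], collapse = " "))
      }
      writeLines(c(paste(loci, collapse = " "), rows), path)
    },
    genepop = {
      amax <- max(c(wide_alleles(wide, loci), 0), na.rm = TRUE)
      if (amax >= 1000) abort("genepop 3-digit coding requires allele labels < 1000")
      enc <- function(a) ifelse(is.na(a), "000", formatC(a, width = 3, flag = "0"))
      grp <- wide$group
      grp[is.na(grp)] <- "all"
      out <- c("genotypes", loci)
      for (g in unique(grp)) {
        out <- c(out, "Pop")
        sel <- which(grp == g)
        for (k in sel) {
          codes <- paste0(enc(unlist(wide[k, paste0(loci, "_1")])),
                          enc(unlist(wide[k, paste0(loci, "_2")])))
          out <- c(out, paste(wide$sample_id[k], ",", paste(codes, collapse = " ")))
        }
      }
      writeLines(out, path)
    },
    csv_wide = {
      out <- wide
      if (all(is.na(out$group))) out$group <- NULL
      readr::write_csv(out, path, progress = FALSE)
    }
  )
  invisible(path)
}

genotypes_wide <- function(gt, loci = loci_of(gt)) {
  gt %>%
    as_tibble() %>%
    mutate(locus = factor(.data$locus, levels = loci)) %>%
    tidyr::pivot_wider(id_cols = c("sample_id", "group"),
                       names_from = "locus",
                       values_from = c("allele_1", "allele_2"),
                       names_glue = "{locus}_{ifelse(.value == 'allele_1', 1, 2)}") %>%
    select("sample_id", "group",
           dplyr::all_of(as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))))
}

wide_alleles <- function(wide, loci) {
  unlist(wide[c(paste0(loci, "_1"), paste0(loci, "_2"))], use.names = FALSE)
}
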