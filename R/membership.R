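#' Build a membership (admixture Q) matrix
#'
#' Per-individual admixture proportions across `K >= 2` genetic clusters,
#' as produced by an admixture model. Stored as a tibble with a
#' `sample_id` column followed by one numeric column per cluster; rows are
#' renormalised to sum to exactly 1 (a warning is raised when the input
#' deviates by more than `1e-3`, an error when a row sum reaches the
#' 0.9 / 1.1 guard rails or any entry is negative).
#'
#' @param df data frame: `sample_id` plus `K` numeric cluster columns, or
#'   a bare numeric matrix/data frame of proportions (ids generated).
#' @param cluster_names optional names for the cluster columns.
#' @return a `membership_tbl` tibble.
#' @export
membership_matrix <- function(df, cluster_names = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    df <- cbind(sample_id = paste0("ind_", seq_len(nrow(df))), df)
  }
  qcols <- setdiff(names(df), "sample_id")
  if (length(qcols) < 2) abort("membership matrix needs K >= 2 clusters")
  q <- as.matrix(df[qcols])
  storage.mode(q) <- "double"
  if (any(!is.finite(q))) abort("membership entries must be finite")
  if (any(q < 0)) abort("negative membership entries")
  if (any(q > 1 + 1e-6)) abort("membership entries greater than 1")
  rs <- rowSums(q)
  # a row sum at or beyond the 0.9 / 1.1 guard rails indicates a corrupt file
  if (any(rs <= 0.9 + 1e-12 | rs >= 1.1 - 1e-12)) {
    bad <- which(rs <= 0.9 + 1e-12 | rs >= 1.1 - 1e-12)[1]
    abort(paste0("row sum ", signif(rs[bad], 4), " for sample '",
                 df$sample_id[bad], "' outside [0.9, 1.1]: corrupt file?"))
  }
  if (any(abs(rs - 1) > 1e-3)) {
    warn("membership rows deviate from sum 1 by more than 1e-3; renormalising")
  }
  q <- q / rs
  if (!is.null(cluster_names)) {
    if (length(cluster_names) != ncol(q)) abort("wrong number of cluster names")
    colnames(q) <- cluster_names
  } else {
    colnames(q) <- qcols
  }
  ids <- as.character(df$sample_id)
  if (anyDuplicated(ids)) abort("duplicate sample_id in membership matrix")
  out <- as_tibble(as.data.frame(q))
  out <- tibble(sample_id = ids) %>% dplyr::bind_cols(out)
  structure(out, class = c("membership_tbl", class(tibble())))
}

#' Cluster column names of a membership matrix
#' @param q a `membership_tbl`.
#' @return character vector of cluster names.
#' @export
clusters_of <- function(q) setdiff(names(q), "sample_id")

#' Extract the numeric Q matrix
#' @param q a `membership_tbl`.
#' @return numeric matrix, rownames = sample ids.
#' @export
q_matrix <- function(q) {
  m <- as.matrix(as.data.frame(q)[clusters_of(q)])
  rownames(m) <- q$sample_id
  m
}

#' Read a membership matrix
#'
#' `csv` expects a header with `sample_id` (optional) and one column per
#' cluster. `structure_output` parses the "Inferred ancestry of
#' individuals" block of a STRUCTURE main results file: rows of the form
#' `  1 ind_7  (0)  2 :  0.021 0.979`.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"structure_output"`.
#' @return a [membership_matrix()].
#' @export
read_membership <- function(path, dialect = c("csv", "structure_output")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    return(membership_matrix(df))
  }
  lines <- readLines(path)
  start <- grep("Inferred ancestry of individuals", lines, fixed = TRUE)
  if (length(start) == 0) {
    abort("no 'Inferred ancestry of individuals' block in file")
  }
  body <- lines[(start[1] + 1):length(lines)]
  # data rows start with an integer index and contain the ':' separator;
  # this skips the column-header line and stops at the end of the block
  is_row <- grepl("^\\s*[0-9]+\\s+\\S+", body) & grepl(":", body, fixed = TRUE)
  end <- which(!nzchar(trimws(body)) & cumsum(is_row) > 0)
  if (length(end) > 0) is_row[end[1]:length(body)] <- FALSE
  rows <- body[is_row]
  if (length(rows) == 0) abort("empty ancestry block")
  parsed <- lapply(rows, function(ln) {
    halves <- strsplit(ln, ":", fixed = TRUE)[[1]]
    left <- strsplit(trimws(halves[1]), "\\s+")[[1]]
    qv <- as.numeric(strsplit(trimws(halves[2]), "\\s+")[[1]])
    list(id = left[2], q = qv)
  })
  K <- length(parsed[[1]]$q)
  if (any(vapply(parsed, function(p) length(p$q), 0L) != K)) {
    abort("ragged ancestry block: differing number of clusters per row")
  }
  q <- do.call(rbind, lapply(parsed, `[[`, "q"))
  colnames(q) <- paste0("cluster_", seq_len(K))
  df <- data.frame(sample_id = vapply(parsed, `[[`, "", "id"), q,
                   check.names = FALSE)
  membership_matrix(df)
}

#' Hard group labels from a membership matrix
#'
#' Assigns each individual to the cluster with its highest membership
#' coefficient — the convention used to derive discrete genetic groups
#' from an admixture Q matrix.
#'
#' @param q a `membership_tbl`.
#' @return named character vector of cluster names, names = sample ids.
#' @export
assign_groups <- function(q) {
  m <- q_matrix(q)
  setNames(colnames(m)[max.col(m, ties.method = "first")], rownames(m))
}
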