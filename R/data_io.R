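# Readers and writers for the plain-text formats the pipeline exchanges:
# two-column edge-list TSVs, labelled matrix TSVs, and the disease-DAG TSV.
# Canonical on-disk identifiers are strings; in-memory association matrices
# are 0/1 matrices with sorted, unique dimnames.

#' Read a two-column edge list into a binary association matrix
#'
#' Each line holds `row_id<TAB>col_id` (an optional third weight column is
#' ignored for association data). Duplicate edges are collapsed to a single 1
#' with a warning; malformed lines are rejected with their line number.
#'
#' @param path Path to a TSV edge list (no header).
#' @param row_ids,col_ids Optional character vectors fixing the full label
#'   universe (so all-zero rows/columns survive the round trip).
#' @return A 0/1 matrix with sorted unique row and column names.
#' @export
read_edge_list <- function(path, row_ids = NULL, col_ids = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(paste0("empty edge list: ", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad) > 0) {
    abort(sprintf("malformed line %d in %s: expected 2-3 tab-separated fields",
                  bad[1], path))
  }
  edges <- tibble::tibble(
    row = vapply(parts, `[[`, character(1), 1L),
    col = vapply(parts, `[[`, character(1), 2L)
  )
  ndup <- nrow(edges) - nrow(dplyr::distinct(edges))
  if (ndup > 0) {
    warn(sprintf("%d duplicate edge(s) collapsed in %s", ndup, path))
    edges <- dplyr::distinct(edges)
  }
  edges_to_matrix(edges, row_ids, col_ids)
}

# Edge tibble (row, col) -> binary matrix with sorted unique labels.
edges_to_matrix <- function(edges, row_ids = NULL, col_ids = NULL) {
  row_ids <- row_ids %||% sort(unique(edges$row))
  col_ids <- col_ids %||% sort(unique(edges$col))
  missing_r <- setdiff(edges$row, row_ids)
  missing_c <- setdiff(edges$col, col_ids)
  if (length(missing_r) > 0 || length(missing_c) > 0) {
    abort(paste0("edge references unknown identifiers: ",
                 paste(head(c(missing_r, missing_c), 5), collapse = ", ")))
  }
  m <- matrix(0L, length(row_ids), length(col_ids),
              dimnames = list(row_ids, col_ids))
  m[cbind(match(edges$row, row_ids), match(edges$col, col_ids))] <- 1L
  m
}

#' Write a binary association matrix as a two-column edge list
#'
#' @param m A 0/1 matrix with dimnames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(m, path) {
  check_binary_matrix(m, "association matrix")
  idx <- which(m == 1, arr.ind = TRUE)
  df <- data.frame(row = rownames(m)[idx[, 1]], col = colnames(m)[idx[, 2]])
  df <- df[order(df$row, df$col), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a labelled numeric matrix from TSV
#'
#' First row holds column identifiers, first column row identifiers.
#'
#' @param path Path to the TSV.
#' @return A numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' Write a labelled numeric matrix to TSV
#'
#' @param m A matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a disease DAG edge list
#'
#' @param path TSV with two columns, `child<TAB>parent`, no header.
#' @return A tibble with columns `child` and `parent`.
#' @export
read_disease_dag <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(paste0("empty DAG file: ", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0) {
    abort(sprintf("malformed line %d in %s: expected child<TAB>parent",
                  bad[1], path))
  }
  tibble::tibble(
    child = vapply(parts, `[[`, character(1), 1L),
    parent = vapply(parts, `[[`, character(1), 2L)
  )
}

#' Validate a loaded dataset
#'
#' Runs structural checks on the lncRNA-disease (`ld`) and lncRNA-miRNA
#' (`lm`) association matrices and an optional similarity matrix: label
#' consistency across matrices, binary values, symmetry and unit diagonal of
#' the similarity matrix, and isolated nodes.
#'
#' @param ld,lm Binary association matrices (lncRNAs in rows).
#' @param similarity Optional square similarity matrix over diseases (DSS) or
#'   lncRNAs (LFS); which one is inferred from its labels.
#' @return A tibble with columns `check`, `pass` and `detail`.
#' @export
validate_dataset <- function(ld, lm, similarity = NULL) {
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = check, pass = pass, detail = detail)
  }

  add("ld_binary", all(ld %in% c(0, 1)))
  add("lm_binary", all(lm %in% c(0, 1)))
  mism <- union(setdiff(rownames(ld), rownames(lm)),
                setdiff(rownames(lm), rownames(ld)))
  add("lncrna_labels_consistent", length(mism) == 0,
      paste(head(mism, 5), collapse = ", "))
  add("no_duplicate_lncrna_ids", !anyDuplicated(rownames(ld)))
  add("no_duplicate_disease_ids", !anyDuplicated(colnames(ld)))
  add("no_duplicate_mirna_ids", !anyDuplicated(colnames(lm)))

  iso_l <- rownames(ld)[rowSums(ld) + rowSums(lm) == 0]
  iso_d <- colnames(ld)[colSums(ld) == 0]
  iso_m <- colnames(lm)[colSums(lm) == 0]
  add("no_isolated_nodes", length(c(iso_l, iso_d, iso_m)) == 0,
      paste(head(c(iso_l, iso_d, iso_m), 5), collapse = ", "))

  if (!is.null(similarity)) {
    sym <- isTRUE(all.equal(similarity, t(similarity), tolerance = 1e-12,
                            check.attributes = FALSE))
    add("similarity_symmetric", sym)
    add("similarity_bounded",
        all(similarity >= -1e-12 & similarity <= 1 + 1e-12))
    add("similarity_unit_diagonal",
        isTRUE(all.equal(unname(diag(similarity)),
                         rep(1, nrow(similarity)), tolerance = 1e-9)))
  }
  dplyr::bind_rows(checks)
}
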