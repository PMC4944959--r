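#' Read a dense labeled similarity matrix
#'
#' Reads the dense phenotype-network dialect: a UTF-8 TSV whose first row and
#' first column hold the disease identifiers and whose cell (i, j) is the
#' similarity score, `.` as decimal mark. Identifiers are opaque strings and
#' are not validated numerically.
#'
#' @param path file path.
#' @param expect_symmetric when `TRUE` (e.g. for a distributed matrix
#'   documented as symmetric), any asymmetry above `1e-9` is a format error.
#' @return a [phenotype_net()].
#' @export
read_dense_matrix <- function(path, expect_symmetric = FALSE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  ids <- as.character(raw[[1]])
  col_ids <- names(raw)[-1]
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (length(ids) != length(col_ids)) {
    abort(sprintf("Matrix in %s is not square (%d rows, %d columns).",
                  path, length(ids), length(col_ids)))
  }
  if (anyDuplicated(ids) || anyDuplicated(col_ids)) {
    abort(sprintf("Duplicate disease identifiers in %s.", path))
  }
  if (!identical(ids, col_ids)) {
    abort(sprintf("Row and column identifiers disagree in %s.", path))
  }
  if (any(!is.finite(m))) abort(sprintf("Non-numeric cells in %s.", path))
  dimnames(m) <- list(ids, ids)
  if (expect_symmetric && max(abs(m - base::t(m))) > 1e-9) {
    abort(sprintf("Matrix in %s declared symmetric but is not (tolerance 1e-9).",
                  path))
  }
  phenotype_net(m, ids)
}

#' Write the dense similarity matrix dialect
#'
#' @param net a [phenotype_net()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dense_matrix <- function(net, path) {
  stopifnot(inherits(net, "phenotype_net"))
  df <- data.frame(disease = net$disease_ids, net$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pairwise similarity score list
#'
#' Reads the sparse pairwise dialect: a TSV with at least three columns
#' (disease id, disease id, score), optional comment/header lines starting
#' with `#`. The matrix is assembled over the union of identifiers seen;
#' unlisted pairs — including unlisted diagonal self-similarities — default
#' to 0 (absent evidence). A pair listed twice with conflicting scores is an
#' error. Files of this kind may be asymmetric: (A, B) and (B, A) are
#' distinct entries.
#'
#' @param path file path.
#' @return a [phenotype_net()].
#' @export
read_pair_scores <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("No score lines in %s.", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3)) {
    abort(sprintf("Every score line in %s needs >= 3 tab-separated fields.",
                  path))
  }
  a <- vapply(parts, `[[`, "", 1)
  b <- vapply(parts, `[[`, "", 2)
  score <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
  if (any(is.na(score))) abort(sprintf("Non-numeric score in %s.", path))
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    conflicting <- vapply(unique(dup), function(k) {
      length(unique(score[key == k])) > 1
    }, logical(1))
    if (any(conflicting)) {
      abort(sprintf("Conflicting duplicate pair(s) in %s.", path))
    }
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]; score <- score[keep]
  }
  ids <- sort(unique(c(a, b)))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(match(a, ids), match(b, ids))] <- score
  phenotype_net(m, ids)
}

#' Write the pairwise score dialect
#'
#' Writes every nonzero entry as a `disease <TAB> disease <TAB> score` line
#' (zero entries are the dialect's implicit default).
#'
#' @param net a [phenotype_net()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_pair_scores <- function(net, path) {
  stopifnot(inherits(net, "phenotype_net"))
  nz <- which(net$scores != 0, arr.ind = TRUE)
  lines <- sprintf("%s\t%s\t%.15g",
                   net$disease_ids[nz[, 1]], net$disease_ids[nz[, 2]],
                   net$scores[nz])
  writeLines(c("# disease\tdisease\tscore", lines), path)
  invisible(path)
}

#' Read a PPI edge list
#'
#' Reads the interaction dialect: a TSV with two gene-symbol columns and an
#' optional third weight column; lines starting with `#` are skipped. Edges
#' are undirected; duplicates collapse to the maximum weight and self-loops
#' are dropped (with a warning), as in [gene_net()].
#'
#' @param path file path.
#' @return a [gene_net()].
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("No edges in %s.", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    abort(sprintf("Every edge line in %s needs >= 2 tab-separated fields.",
                  path))
  }
  from <- vapply(parts, `[[`, "", 1)
  to <- vapply(parts, `[[`, "", 2)
  weight <- vapply(parts, function(p) {
    if (length(p) >= 3) suppressWarnings(as.numeric(p[[3]])) else 1
  }, numeric(1))
  if (any(is.na(weight))) abort(sprintf("Non-numeric edge weight in %s.", path))
  gene_net(tibble(from = from, to = to, weight = weight))
}

#' Write a PPI edge list
#'
#' @param net a [gene_net()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  edges <- gene_net_edges(net)
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a disease-gene association table
#'
#' Reads a two-column TSV (disease id, gene symbol); lines starting with `#`
#' are skipped and exact duplicate rows are collapsed.
#'
#' @param path file path.
#' @return a tibble with columns `disease`, `gene`.
#' @export
read_associations <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("No associations in %s.", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    abort(sprintf("Every line in %s needs 2 tab-separated fields.", path))
  }
  check_associations(tibble(
    disease = vapply(parts, `[[`, "", 1),
    gene = vapply(parts, `[[`, "", 2)
  ))
}

#' Write a disease-gene association table
#'
#' @param associations tibble with columns `disease`, `gene`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(associations, path) {
  associations <- check_associations(associations)
  utils::write.table(associations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
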