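#' Undirected gene-gene interaction network
#'
#' A `gene_net` wraps an undirected, weighted protein-protein interaction
#' (PPI) graph as a sparse symmetric adjacency matrix over an ordered set of
#' gene symbols. Self-loops are dropped and duplicate edges (in either
#' orientation) are collapsed to their maximum weight. Unweighted edge lists
#' get weight 1.
#'
#' @param edges a data frame with columns `from` and `to` (gene symbols) and
#'   optionally `weight` (positive numeric, default 1).
#' @param gene_ids optional character vector fixing the node set and order;
#'   defaults to the sorted union of symbols in `edges`. Genes listed here but
#'   absent from `edges` become isolated nodes.
#'
#' @return An object of class `gene_net`: a list with `gene_ids`, `adjacency`
#'   (sparse symmetric `dgCMatrix`), and `w_norm` (cache of the
#'   degree-normalized adjacency, filled by [normalize_adjacency()]).
#' @export
gene_net <- function(edges, gene_ids = NULL) {
  edges <- as_tibble(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    abort("`edges` must have columns `from` and `to`.")
  }
  if (!"weight" %in% names(edges)) edges$weight <- 1
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  loops <- edges$from == edges$to
  if (any(loops)) {
    warn(sprintf("Dropping %d self-loop(s).", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  if (is.null(gene_ids)) {
    gene_ids <- sort(unique(c(edges$from, edges$to)))
  } else {
    gene_ids <- as.character(gene_ids)
    if (anyDuplicated(gene_ids)) abort("`gene_ids` must be unique.")
    missing <- setdiff(unique(c(edges$from, edges$to)), gene_ids)
    if (length(missing)) {
      abort(sprintf("Edge gene(s) absent from `gene_ids`: %s",
                    paste(utils::head(missing, 5), collapse = ", ")))
    }
  }
  n <- length(gene_ids)
  i <- match(edges$from, gene_ids)
  j <- match(edges$to, gene_ids)
  # canonical orientation, then collapse duplicates to max weight
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  w <- tapply(edges$weight, key, max)
  pairs <- do.call(rbind, strsplit(names(w), " ", fixed = TRUE))
  lo <- as.integer(pairs[, 1]); hi <- as.integer(pairs[, 2])
  adj <- Matrix::sparseMatrix(
    i = c(lo, hi), j = c(hi, lo), x = c(as.numeric(w), as.numeric(w)),
    dims = c(n, n), dimnames = list(gene_ids, gene_ids)
  )
  structure(
    list(gene_ids = gene_ids, adjacency = adj, w_norm = NULL),
    class = "gene_net"
  )
}

#' @export
print.gene_net <- function(x, ...) {
  cat(sprintf("<gene_net> %d genes, %.0f interactions%s\n",
              length(x$gene_ids), Matrix::nnzero(x$adjacency) / 2,
              if (is.null(x$w_norm)) "" else ", normalized"))
  invisible(x)
}

#' Edges of a gene network as a tibble
#'
#' @param net a [gene_net()].
#' @return a tibble with columns `from`, `to`, `weight`, one row per
#'   undirected edge (canonical orientation `from <= to` by node order).
#' @export
gene_net_edges <- function(net) {
  stopifnot(inherits(net, "gene_net"))
  m <- Matrix::summary(Matrix::triu(net$adjacency))
  tibble(from = net$gene_ids[m$i], to = net$gene_ids[m$j],
         weight = m$x)
}

#' Symmetric degree normalization of the adjacency matrix
#'
#' Computes \eqn{W_{norm} = D^{-1/2} A D^{-1/2}} with `D` the diagonal matrix
#' of (weighted) degrees — the normalization under which label propagation
#' with restart weight `alpha < 1` is a contraction, since the spectral radius
#' of \eqn{W_{norm}} is at most 1. Isolated nodes get zero rows.
#'
#' @param net a [gene_net()].
#' @return the same `gene_net` with the `w_norm` cache filled.
#' @export
normalize_adjacency <- function(net) {
  stopifnot(inherits(net, "gene_net"))
  deg <- Matrix::rowSums(net$adjacency)
  inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  d_half <- Matrix::Diagonal(x = inv_sqrt)
  net$w_norm <- d_half %*% net$adjacency %*% d_half
  dimnames(net$w_norm) <- dimnames(net$adjacency)
  net
}
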