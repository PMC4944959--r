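# Small in-code fixtures shared across test files.

# Labeled square matrix -> phenotype_net with ids D1..Dn.
pn <- function(m, symmetric = NULL) {
  n <- nrow(m)
  dimnames(m) <- list(paste0("D", seq_len(n)), paste0("D", seq_len(n)))
  phenotype_net(m, symmetric = symmetric)
}

# Random asymmetric similarity matrix with diagonal dominating its row/column,
# so every normalization stays in [0, 1] without clipping.
random_simnet <- function(n, seed, symmetric = FALSE) {
  withr::with_seed(seed, {
    m <- matrix(runif(n * n, 0.05, 0.9), n, n)
    if (symmetric) m <- (m + t(m)) / 2
    diag(m) <- 0
    diag(m) <- pmax(apply(m, 1, max), apply(m, 2, max))
    pn(m, symmetric = symmetric)
  })
}

# Erdos-Renyi style gene network with guaranteed edges, genes g1..gn.
random_gnet <- function(n, seed, p_edge = 0.15) {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p_edge)
    el <- igraph::as_edgelist(g, names = FALSE)
    ids <- paste0("g", seq_len(n))
    if (nrow(el) == 0) el <- cbind(1, 2)
    gene_net(tibble::tibble(from = ids[el[, 1]], to = ids[el[, 2]]),
             gene_ids = ids)
  })
}

# Path graph a - b - c - ... as a gene_net.
path_gnet <- function(ids) {
  gene_net(tibble::tibble(from = ids[-length(ids)], to = ids[-1]),
           gene_ids = ids)
}

random_prior <- function(gnet, seed) {
  withr::with_seed(seed, {
    stats::setNames(stats::runif(length(gnet$gene_ids)), gnet$gene_ids)
  })
}
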