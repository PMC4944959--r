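#' Configuration for the synthetic benchmark generator
#'
#' Defines a synthetic study in which the guilt-by-association premise holds
#' by construction: diseases fall into phenotype modules, each module is
#' anchored in a neighborhood of the PPI graph, and a disease's causal genes
#' are drawn from its module's neighborhood — so phenotypically similar
#' diseases map to genes that are close in the PPI network. The defaults
#' describe a moderately sized study: 500 genes, 100 diseases in 10 modules,
#' within-module phenotype similarity centered at 0.6 against a between-module
#' background of 0.1.
#'
#' @param n_genes number of genes (PPI nodes).
#' @param n_diseases number of diseases.
#' @param n_modules number of disease modules; at most `n_diseases`.
#' @param edges_per_node edges added per node during preferential-attachment
#'   growth of the PPI graph.
#' @param within_sim length-2 numeric `(mean, sd)` of within-module
#'   similarity; mean in (0, 1).
#' @param between_sim length-2 numeric `(mean, sd)` of between-module
#'   similarity; mean in (0, 1).
#' @param genes_per_disease integer range `(min, max)` of causal genes per
#'   disease; diseases at the minimum of 1 are monogenic.
#' @param asym_noise standard deviation of directional noise added to the
#'   similarity matrix; 0 (default) gives an exactly symmetric network.
#' @param seed integer seed; the whole study is deterministic given it.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 500L, n_diseases = 100L, n_modules = 10L,
                         edges_per_node = 3L,
                         within_sim = c(0.6, 0.1), between_sim = c(0.1, 0.05),
                         genes_per_disease = c(1L, 3L),
                         asym_noise = 0, seed = 1L) {
  stopifnot(n_genes >= 2, n_diseases >= 1, n_modules >= 1,
            n_modules <= n_diseases, edges_per_node >= 1,
            length(within_sim) == 2, length(between_sim) == 2,
            within_sim[1] > 0, within_sim[1] < 1,
            between_sim[1] > 0, between_sim[1] < 1,
            length(genes_per_disease) == 2,
            genes_per_disease[1] >= 1,
            genes_per_disease[2] >= genes_per_disease[1],
            asym_noise >= 0)
  structure(
    list(n_genes = as.integer(n_genes), n_diseases = as.integer(n_diseases),
         n_modules = as.integer(n_modules),
         edges_per_node = as.integer(edges_per_node),
         within_sim = as.numeric(within_sim),
         between_sim = as.numeric(between_sim),
         genes_per_disease = as.integer(genes_per_disease),
         asym_noise = as.numeric(asym_noise), seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a synthetic PPI network
#'
#' Grows a connected, simple, undirected graph by preferential attachment
#' (each new node attaches to `edges_per_node` existing nodes with probability
#' proportional to degree), reproducing the heavy-tailed degree distribution
#' of curated interactomes. Gene symbols are `g0001`, `g0002`, ...
#'
#' @param cfg a [synth_config()].
#' @return a [gene_net()] with `cfg$n_genes` nodes.
#' @export
gen_ppi <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$edges_per_node >= cfg$n_genes) {
    abort("`edges_per_node` must be smaller than `n_genes`.")
  }
  g <- withr::with_seed(cfg$seed, {
    igraph::sample_pa(cfg$n_genes, m = cfg$edges_per_node, directed = FALSE)
  })
  ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  el <- igraph::as_edgelist(g, names = FALSE)
  gene_net(tibble(from = ids[el[, 1]], to = ids[el[, 2]], weight = 1),
           gene_ids = ids)
}

#' Generate the disease layer of a synthetic study
#'
#' Assigns diseases to phenotype modules, anchors each module at a PPI node,
#' takes the module's gene pool as a breadth-first neighborhood of the anchor,
#' and draws each disease's causal genes from its module pool. Pairwise
#' phenotype similarity is truncated-normal: `within_sim` for same-module
#' pairs, `between_sim` otherwise, clipped to \[0, 1\]. The diagonal
#' self-similarity is set to each disease's row maximum, which keeps the Lin,
#' Sqrt and Tanimoto normalizations inside \[0, 1\] without clipping. With
#' `asym_noise > 0`, independent directional noise is added off the diagonal
#' and the network is flagged asymmetric.
#'
#' @param cfg a [synth_config()].
#' @param ppi a connected [gene_net()], typically from [gen_ppi()].
#' @return a list with `phenonet` (a [phenotype_net()], disease ids `600001`,
#'   `600002`, ...), `associations` (tibble `disease`, `gene`), and `modules`
#'   (tibble `disease`, `module`).
#' @export
gen_disease_model <- function(cfg, ppi) {
  stopifnot(inherits(cfg, "synth_config"), inherits(ppi, "gene_net"))
  g <- igraph::graph_from_adjacency_matrix(ppi$adjacency, mode = "undirected",
                                           weighted = TRUE)
  if (!igraph::is_connected(g)) abort("The PPI network must be connected.")
  n_d <- cfg$n_diseases
  n_m <- cfg$n_modules
  pool_size <- max(cfg$genes_per_disease[2] * 3L,
                   ceiling(cfg$n_genes / n_m))
  if (pool_size > cfg$n_genes) {
    abort("Module gene pool larger than the gene set; increase `n_genes`.")
  }

  withr::with_seed(cfg$seed + 1L, {
    anchors <- sample(ppi$gene_ids, n_m)
    pools <- lapply(anchors, function(a) {
      ord <- igraph::bfs(g, root = a, order = TRUE)$order
      ppi$gene_ids[as.integer(ord)[seq_len(pool_size)]]
    })
    module_of <- sample(rep_len(seq_len(n_m), n_d))
    disease_ids <- sprintf("6%05d", seq_len(n_d))

    k_genes <- sample(seq(cfg$genes_per_disease[1], cfg$genes_per_disease[2]),
                      n_d, replace = TRUE)
    associations <- dplyr::bind_rows(lapply(seq_len(n_d), function(i) {
      tibble(disease = disease_ids[i],
             gene = sample(pools[[module_of[i]]], k_genes[i]))
    }))

    rtrunc <- function(n, mean, sd) pmin(pmax(rnorm(n, mean, sd), 0), 1)
    same <- outer(module_of, module_of, "==")
    s <- matrix(0, n_d, n_d)
    upper <- upper.tri(s)
    vals <- numeric(sum(upper))
    w <- same[upper]
    vals[w] <- rtrunc(sum(w), cfg$within_sim[1], cfg$within_sim[2])
    vals[!w] <- rtrunc(sum(!w), cfg$between_sim[1], cfg$between_sim[2])
    s[upper] <- vals
    s <- s + base::t(s)
    if (cfg$asym_noise > 0) {
      noise <- matrix(rnorm(n_d * n_d, 0, cfg$asym_noise), n_d, n_d)
      diag(noise) <- 0
      s <- pmin(pmax(s + noise, 0), 1)
    }
    diag(s) <- 0
    diag(s) <- pmax(apply(s, 1, max), apply(s, 2, max))
    dimnames(s) <- list(disease_ids, disease_ids)

    list(
      phenonet = phenotype_net(s, disease_ids,
                               symmetric = cfg$asym_noise == 0),
      associations = associations,
      modules = tibble(disease = disease_ids, module = module_of)
    )
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [gen_ppi()] and [gen_disease_model()], and
#' optionally writing the three standard input files (dense similarity matrix,
#' PPI edge list, association table) to a directory so the file-based pipeline
#' can be exercised end to end.
#'
#' @param cfg a [synth_config()].
#' @param dir optional output directory; created if missing.
#' @return a list with `phenonet`, `gnet`, `associations`, `modules`, `config`
#'   and, when `dir` is given, `paths` (named: `phenonet`, `ppi`,
#'   `associations`).
#' @export
simulate_study <- function(cfg = synth_config(), dir = NULL) {
  gnet <- gen_ppi(cfg)
  dm <- gen_disease_model(cfg, gnet)
  out <- list(phenonet = dm$phenonet, gnet = gnet,
              associations = dm$associations, modules = dm$modules,
              config = cfg)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      phenonet = file.path(dir, "phenonet.tsv"),
      ppi = file.path(dir, "ppi_edges.tsv"),
      associations = file.path(dir, "associations.tsv")
    )
    write_dense_matrix(dm$phenonet, paths$phenonet)
    write_edge_list(gnet, paths$ppi)
    write_associations(dm$associations, paths$associations)
    out$paths <- paths
  }
  out
}
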