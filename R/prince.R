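#' Phenotype-informed prior over the gene network
#'
#' Builds the prior knowledge vector `Y` of the PRINCE algorithm for a query
#' disease. Seed genes — genes already known to cause the query disease — get
#' the maximal prior 1. Every other gene that causes at least one *other*
#' disease inherits the calibrated phenotype similarity between that disease
#' and the query, aggregated by maximum over its diseases (the
#' most-phenotypically-similar disease carries the evidence, and the prior
#' stays in \[0, 1\]). Genes with no known disease get 0.
#'
#' For an asymmetric similarity network the direction matters: `form = "row"`
#' reads Sim(query -> d) along the query's row (the -R form), `form = "col"`
#' reads Sim(d -> query) down the query's column (the -C form). `form =
#' "symmetric"` requires a symmetric network; conversely the row/col forms
#' require an asymmetric one.
#'
#' @param query disease identifier, present in `phenonet`.
#' @param associations data frame with columns `disease`, `gene`: the known
#'   disease-gene associations. Genes absent from `gnet` are dropped with a
#'   warning.
#' @param phenonet a [phenotype_net()], already logistic-calibrated.
#' @param gnet a [gene_net()].
#' @param form one of `"symmetric"`, `"row"`, `"col"`.
#' @param seeds character vector of seed genes; defaults to the genes
#'   associated with `query` in `associations`. Pass `character(0)` to build a
#'   similarity-only prior (the monogenic leave-one-out situation).
#' @return a named numeric vector over `gnet$gene_ids`, values in \[0, 1\].
#' @export
build_prior <- function(query, associations, phenonet, gnet,
                        form = c("symmetric", "row", "col"),
                        seeds = NULL) {
  form <- match.arg(form)
  stopifnot(inherits(phenonet, "phenotype_net"), inherits(gnet, "gene_net"))
  if (!query %in% phenonet$disease_ids) {
    abort(sprintf("Query disease '%s' is not in the phenotype network.", query))
  }
  check_form(form, phenonet)
  associations <- check_associations(associations)
  unknown <- setdiff(unique(associations$gene), gnet$gene_ids)
  if (length(unknown)) {
    warn(sprintf("Dropping %d association gene(s) absent from the PPI network.",
                 length(unknown)))
    associations <- associations[!associations$gene %in% unknown, ,
                                 drop = FALSE]
  }
  if (is.null(seeds)) {
    seeds <- associations$gene[associations$disease == query]
  }
  seeds <- intersect(as.character(seeds), gnet$gene_ids)

  sim <- switch(form,
    row = phenonet$scores[query, ],
    col = phenonet$scores[, query],
    symmetric = phenonet$scores[query, ]
  )

  y <- setNames(numeric(length(gnet$gene_ids)), gnet$gene_ids)
  other <- associations[associations$disease != query &
                          associations$disease %in% phenonet$disease_ids, ,
                        drop = FALSE]
  if (nrow(other)) {
    best <- tapply(sim[other$disease], other$gene, max)
    y[names(best)] <- as.numeric(best)
  }
  y[seeds] <- 1
  y
}

check_form <- function(form, phenonet) {
  if (form == "symmetric" && !phenonet$symmetric) {
    abort("form = 'symmetric' requires a symmetric phenotype network; symmetrize() it first.")
  }
  if (form != "symmetric" && phenonet$symmetric) {
    abort(sprintf("form = '%s' reads a direction of an asymmetric network; use form = 'symmetric' for a symmetric one.", form))
  }
  invisible(form)
}

check_associations <- function(associations) {
  associations <- as_tibble(associations)
  if (!all(c("disease", "gene") %in% names(associations))) {
    abort("`associations` must have columns `disease` and `gene`.")
  }
  associations$disease <- as.character(associations$disease)
  associations$gene <- as.character(associations$gene)
  unique(associations[c("disease", "gene")])
}

#' PRINCE label propagation
#'
#' Iterates the propagation update
#' \deqn{F^t = \alpha W_{norm} F^{t-1} + (1-\alpha) Y, \qquad F^1 = Y,}
#' smoothing the prior `Y` over the degree-normalized PPI network so that
#' genes interacting with highly-scored genes are themselves up-weighted
#' (guilt by association). Iteration stops when the L1 difference between
#' successive iterates falls below `tol` or after `max_iter` updates.
#'
#' @param gnet a [gene_net()]; [normalize_adjacency()] is applied if the
#'   normalized form is not cached yet.
#' @param y prior scores: a named numeric vector aligned to `gnet$gene_ids`
#'   (names are checked when present).
#' @param alpha restart weight in (0, 1); default 0.9. Propagation is
#'   insensitive to `alpha` above 0.5.
#' @param tol L1 convergence tolerance, default 1e-9.
#' @param max_iter iteration cap, default 100.
#' @return a tibble with columns `gene`, `prior`, `score`, carrying attributes
#'   `iterations` (updates performed) and `converged` (logical).
#' @seealso [closed_form_propagate()] for the exact fixed point.
#' @export
propagate <- function(gnet, y, alpha = 0.9, tol = 1e-9, max_iter = 100L) {
  stopifnot(inherits(gnet, "gene_net"),
            alpha > 0, alpha < 1, tol > 0, max_iter >= 1)
  y <- align_scores(y, gnet)
  if (is.null(gnet$w_norm)) gnet <- normalize_adjacency(gnet)
  w <- gnet$w_norm
  f <- y
  iterations <- 0L
  converged <- FALSE
  for (t in seq_len(max_iter)) {
    f_new <- as.numeric(alpha * (w %*% f)) + (1 - alpha) * y
    if (!all(is.finite(f_new))) {
      abort("Non-finite values during propagation; is the adjacency normalized?")
    }
    delta <- sum(abs(f_new - f))
    f <- f_new
    iterations <- t
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  out <- tibble(gene = gnet$gene_ids, prior = y, score = f)
  attr(out, "iterations") <- iterations
  attr(out, "converged") <- converged
  out
}

#' Closed-form fixed point of the propagation
#'
#' The PRINCE iteration converges to the solution of the linear system
#' \eqn{(I - \alpha W_{norm}) F = (1-\alpha) Y}, solved here directly. It is
#' exact (up to linear-algebra roundoff) and serves as the reference the
#' iterative scheme is checked against.
#'
#' @inheritParams propagate
#' @return a tibble with columns `gene`, `prior`, `score`.
#' @export
closed_form_propagate <- function(gnet, y, alpha = 0.9) {
  stopifnot(inherits(gnet, "gene_net"), alpha >= 0, alpha < 1)
  y <- align_scores(y, gnet)
  if (is.null(gnet$w_norm)) gnet <- normalize_adjacency(gnet)
  n <- length(y)
  a <- diag(n) - alpha * as.matrix(gnet$w_norm)
  f <- tryCatch(solve(a, (1 - alpha) * y),
                error = function(e) abort("Propagation system is singular."))
  tibble(gene = gnet$gene_ids, prior = y, score = as.numeric(f))
}

align_scores <- function(y, gnet) {
  if (!is.numeric(y)) abort("`y` must be numeric.")
  if (!is.null(names(y))) {
    if (!setequal(names(y), gnet$gene_ids)) {
      abort("Names of `y` do not match the gene network's node set.")
    }
    y <- y[gnet$gene_ids]
  } else if (length(y) != length(gnet$gene_ids)) {
    abort("`y` length does not match the number of genes.")
  }
  unname(y)
}

#' Rank candidate genes for a disease
#'
#' Runs the full prioritization for one query disease: build the
#' phenotype-informed prior, propagate it over the PPI network, restrict to
#' the candidate set, and sort by decreasing score. Seeds are excluded from
#' the candidates. Ties get the pessimistic competition rank (a tied gene is
#' placed after all genes tied with it), so reported ranks never flatter the
#' method.
#'
#' @inheritParams build_prior
#' @param candidates character vector of candidate genes (e.g. a linkage
#'   interval), or `NULL` for all PPI genes minus the seeds.
#' @param alpha,tol,max_iter propagation parameters, see [propagate()].
#' @return a tibble with columns `gene`, `score`, `rank`, sorted by
#'   decreasing score, one row per candidate.
#' @export
prioritize <- function(query, associations, phenonet, gnet,
                       form = c("symmetric", "row", "col"),
                       seeds = NULL, candidates = NULL,
                       alpha = 0.9, tol = 1e-9, max_iter = 100L) {
  form <- match.arg(form)
  y <- build_prior(query, associations, phenonet, gnet, form, seeds)
  if (is.null(seeds)) {
    associations <- check_associations(associations)
    seeds <- intersect(associations$gene[associations$disease == query],
                       gnet$gene_ids)
  }
  seeds <- as.character(seeds)
  if (is.null(candidates)) {
    candidates <- setdiff(gnet$gene_ids, seeds)
  } else {
    candidates <- as.character(candidates)
    bad <- setdiff(candidates, gnet$gene_ids)
    if (length(bad)) {
      abort(sprintf("Candidate gene(s) absent from the PPI network: %s",
                    paste(utils::head(bad, 5), collapse = ", ")))
    }
    candidates <- setdiff(candidates, seeds)
  }
  if (length(candidates) == 0) abort("Empty candidate set.")
  fit <- propagate(gnet, y, alpha = alpha, tol = tol, max_iter = max_iter)
  scores <- setNames(fit$score, fit$gene)[candidates]
  rk <- rank(-scores, ties.method = "max")
  out <- tibble(gene = candidates, score = unname(scores), rank = unname(rk))
  out <- out[order(out$rank, out$gene), , drop = FALSE]
  attr(out, "iterations") <- attr(fit, "iterations")
  attr(out, "converged") <- attr(fit, "converged")
  out
}
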