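#' Leave-one-out cross-validation of a phenotype network
#'
#' Benchmarks a calibrated disease phenotype network as prior knowledge for
#' gene prioritization. Each disease-gene association is removed in turn; the
#' removed gene is the *target*, the disease's remaining genes form the *seed
#' set* (empty for a monogenic disease, so the target must be recovered from
#' phenotype similarity alone), and the target is re-predicted among all PPI
#' genes minus the seeds. The rank of every target is recorded.
#'
#' @param associations data frame with columns `disease`, `gene`. Associations
#'   whose gene is absent from `gnet` or whose disease is absent from
#'   `phenonet` are dropped with a warning; the monogenic/polygenic partition
#'   is computed after this filtering.
#' @param phenonet a [phenotype_net()], already logistic-calibrated.
#' @param gnet a [gene_net()].
#' @param form similarity read direction, see [build_prior()].
#' @param mode `"all"`, `"monogenic"` (diseases with exactly one gene) or
#'   `"polygenic"` (two or more).
#' @param alpha,tol,max_iter propagation parameters, see [propagate()].
#' @return an object of class `phenoprio_loocv`: a list with `records` (tibble
#'   with columns `disease`, `target_gene`, `rank`, `n_candidates`,
#'   `n_disease_genes`) and `params`. Use [tidy()] for the records,
#'   [glance()] or [compute_report()] for summary statistics.
#' @export
loocv <- function(associations, phenonet, gnet,
                  form = c("symmetric", "row", "col"),
                  mode = c("all", "monogenic", "polygenic"),
                  alpha = 0.9, tol = 1e-9, max_iter = 100L) {
  form <- match.arg(form)
  mode <- match.arg(mode)
  stopifnot(inherits(phenonet, "phenotype_net"), inherits(gnet, "gene_net"))
  check_form(form, phenonet)
  associations <- check_associations(associations)

  drop_gene <- !associations$gene %in% gnet$gene_ids
  drop_dis <- !associations$disease %in% phenonet$disease_ids
  if (any(drop_gene | drop_dis)) {
    warn(sprintf(
      "Dropping %d association(s) outside the PPI network or phenotype network.",
      sum(drop_gene | drop_dis)))
    associations <- associations[!(drop_gene | drop_dis), , drop = FALSE]
  }
  if (nrow(associations) == 0) abort("No usable associations left.")

  genes_of <- split(associations$gene, associations$disease)
  n_genes_of <- lengths(genes_of)
  in_scope <- switch(mode,
    all = rep(TRUE, nrow(associations)),
    monogenic = n_genes_of[associations$disease] == 1L,
    polygenic = n_genes_of[associations$disease] >= 2L
  )
  scope <- associations[in_scope, , drop = FALSE]
  if (nrow(scope) == 0) abort(sprintf("No %s associations to validate.", mode))

  if (is.null(gnet$w_norm)) gnet <- normalize_adjacency(gnet)

  records <- purrr::pmap(scope, function(disease, gene) {
    held_out <- associations$disease == disease & associations$gene == gene
    remaining <- associations[!held_out, , drop = FALSE]
    seeds <- remaining$gene[remaining$disease == disease]
    ranked <- prioritize(disease, remaining, phenonet, gnet, form,
                         seeds = seeds, candidates = NULL,
                         alpha = alpha, tol = tol, max_iter = max_iter)
    tibble(disease = disease, target_gene = gene,
           rank = ranked$rank[ranked$gene == gene],
           n_candidates = nrow(ranked),
           n_disease_genes = unname(n_genes_of[disease]))
  })
  records <- dplyr::bind_rows(records)

  structure(
    list(records = records,
         params = list(form = form, mode = mode, alpha = alpha, tol = tol,
                       max_iter = max_iter)),
    class = "phenoprio_loocv"
  )
}

#' @export
print.phenoprio_loocv <- function(x, ...) {
  cat(sprintf("<phenoprio_loocv> %d targets (%s mode, form = %s)\n",
              nrow(x$records), x$params$mode, x$params$form))
  print(compute_report(x$records), ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.phenoprio_loocv <- function(x, ...) x$records

#' @exportS3Method generics::glance
glance.phenoprio_loocv <- function(x, ...) compute_report(x$records)

#' Summary statistics of a cross-validation run
#'
#' Condenses per-target rank records into the standard gene-prioritization
#' metrics:
#' \describe{
#'   \item{mrr_percent}{mean rank ratio — the mean over targets of
#'     `100 * rank / n_candidates`; lower is better.}
#'   \item{top_count}{number of targets ranked first.}
#'   \item{tpr_at_k}{true positive rate at k — percentage of targets ranked in
#'     the top k, for k in `ks` (default 5, 10, 30).}
#' }
#'
#' @param records a tibble of rank records with columns `rank` and
#'   `n_candidates` (as produced by [loocv()] / [tidy()]), or a
#'   `phenoprio_loocv` object.
#' @param ks integer cutoffs for the TPR columns.
#' @return a one-row tibble: `n_targets`, `mrr_percent`, `top_count`, and one
#'   `tpr_at_<k>` column per cutoff.
#' @export
compute_report <- function(records, ks = c(5L, 10L, 30L)) {
  if (inherits(records, "phenoprio_loocv")) records <- records$records
  records <- as_tibble(records)
  if (nrow(records) == 0) abort("No rank records to summarize.")
  stopifnot(all(c("rank", "n_candidates") %in% names(records)),
            all(records$rank >= 1), all(records$rank <= records$n_candidates))
  out <- tibble(
    n_targets = nrow(records),
    mrr_percent = mean(100 * records$rank / records$n_candidates),
    top_count = sum(records$rank == 1L)
  )
  for (k in sort(ks)) {
    out[[paste0("tpr_at_", k)]] <- 100 * mean(records$rank <= k)
  }
  out
}

#' Sweep the logistic steepness parameter
#'
#' The steepness `c` of the logistic calibration is the one free parameter of
#' the pipeline and is tuned by cross-validation: for each value in the grid,
#' the *uncalibrated* network is logistic-transformed with that `c` and the
#' full leave-one-out validation is run. The best `c` maximizes the number of
#' top-ranking genes; ties are broken toward the smallest `|c|` (the least
#' aggressive calibration). The default grid of integers -25..-8 brackets the
#' optima observed across phenotype networks in practice; a 0.1-step
#' refinement around the coarse optimum can be passed explicitly.
#'
#' @param c_grid numeric vector of steepness values to try.
#' @param associations,phenonet,gnet,form,mode,alpha,tol,max_iter as in
#'   [loocv()]; `phenonet` here is the normalized but *not yet* calibrated
#'   network.
#' @return an object of class `phenoprio_sweep`: list with `best_c`, `reports`
#'   (one summary row per `c`), and `runs` (named list of `phenoprio_loocv`
#'   objects). [tidy()] returns the per-`c` reports, [glance()] the best row.
#' @export
sweep_c <- function(c_grid = -25:-8, associations, phenonet, gnet,
                    form = c("symmetric", "row", "col"),
                    mode = c("all", "monogenic", "polygenic"),
                    alpha = 0.9, tol = 1e-9, max_iter = 100L) {
  form <- match.arg(form)
  mode <- match.arg(mode)
  if (length(c_grid) == 0) abort("`c_grid` must be nonempty.")
  runs <- purrr::map(c_grid, function(cc) {
    loocv(associations, logistic_transform(phenonet, cc), gnet,
          form = form, mode = mode, alpha = alpha, tol = tol,
          max_iter = max_iter)
  })
  names(runs) <- format(c_grid, trim = TRUE)
  reports <- dplyr::bind_rows(
    purrr::map2(c_grid, runs, function(cc, run) {
      dplyr::bind_cols(tibble(c = cc), compute_report(run$records))
    })
  )
  ord <- order(-reports$top_count, abs(reports$c), -reports$c)
  best_c <- reports$c[ord[1]]
  structure(list(best_c = best_c, reports = reports, runs = runs),
            class = "phenoprio_sweep")
}

#' @export
print.phenoprio_sweep <- function(x, ...) {
  cat(sprintf("<phenoprio_sweep> %d values of c, best c = %g\n",
              nrow(x$reports), x$best_c))
  print(x$reports, ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.phenoprio_sweep <- function(x, ...) x$reports

#' @exportS3Method generics::glance
glance.phenoprio_sweep <- function(x, ...) {
  x$reports[x$reports$c == x$best_c, , drop = FALSE]
}

#' Concordance of two cross-validation runs
#'
#' Cross-tabulates which targets each of two networks validated — a target is
#' validated when it is ranked first — over the same association list. The
#' off-diagonal cells show what one network recovers that the other misses.
#'
#' @param records_a,records_b rank-record tibbles (or `phenoprio_loocv`
#'   objects) over the identical set of (disease, target gene) pairs.
#' @return a tibble with columns `validated_a`, `validated_b` (logical) and
#'   `n`, four rows summing to the number of targets.
#' @export
compare_networks <- function(records_a, records_b) {
  if (inherits(records_a, "phenoprio_loocv")) records_a <- records_a$records
  if (inherits(records_b, "phenoprio_loocv")) records_b <- records_b$records
  key <- function(r) paste(r$disease, r$target_gene)
  a <- as_tibble(records_a)
  b <- as_tibble(records_b)
  if (!setequal(key(a), key(b)) || nrow(a) != nrow(b)) {
    abort("The two record sets cover different associations.")
  }
  b <- b[match(key(a), key(b)), , drop = FALSE]
  grid <- expand.grid(validated_a = c(FALSE, TRUE),
                      validated_b = c(FALSE, TRUE))
  counts <- mapply(function(va, vb) {
    sum((a$rank == 1L) == va & (b$rank == 1L) == vb)
  }, grid$validated_a, grid$validated_b)
  tibble(validated_a = grid$validated_a, validated_b = grid$validated_b,
         n = as.integer(counts))
}
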