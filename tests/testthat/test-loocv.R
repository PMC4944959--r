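# Shared small study used across the LOOCV tests.
toy_study <- function(seed = 5) {
  cfg <- synth_config(n_genes = 120, n_diseases = 20, n_modules = 4,
                      genes_per_disease = c(1L, 3L), seed = seed)
  sim <- simulate_study(cfg)
  sim$calibrated <- logistic_transform(
    normalize_similarity(sim$phenonet, "tanimoto"), -13)
  sim
}

test_that("every LOOCV record is reproduced by an independent prioritize run", {
  sim <- toy_study()
  cv <- loocv(sim$associations, sim$calibrated, sim$gnet)
  records <- tidy(cv)
  expect_equal(nrow(records), nrow(sim$associations))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    remaining <- dplyr::anti_join(
      sim$associations,
      tibble::tibble(disease = rec$disease, gene = rec$target_gene),
      by = c("disease", "gene"))
    seeds <- remaining$gene[remaining$disease == rec$disease]
    ranked <- prioritize(rec$disease, remaining, sim$calibrated, sim$gnet,
                         form = "symmetric", seeds = seeds)
    expect_equal(ranked$rank[ranked$gene == rec$target_gene], rec$rank)
    expect_equal(nrow(ranked), rec$n_candidates)
  }
})

test_that("monogenic and polygenic modes partition the association list", {
  sim <- toy_study()
  mono <- tidy(loocv(sim$associations, sim$calibrated, sim$gnet,
                     mode = "monogenic"))
  poly <- tidy(loocv(sim$associations, sim$calibrated, sim$gnet,
                     mode = "polygenic"))
  all_rec <- tidy(loocv(sim$associations, sim$calibrated, sim$gnet,
                        mode = "all"))
  expect_true(all(mono$n_disease_genes == 1))
  expect_true(all(poly$n_disease_genes >= 2))
  expect_equal(nrow(mono) + nrow(poly), nrow(all_rec))
  # monogenic runs have no seeds: every PPI gene is a candidate
  expect_true(all(mono$n_candidates == length(sim$gnet$gene_ids)))
  # polygenic runs exclude the remaining seed genes from the candidates
  expect_true(all(poly$n_candidates ==
                    length(sim$gnet$gene_ids) - (poly$n_disease_genes - 1)))
})

test_that("the held-out association never leaks into the prior", {
  sim <- toy_study()
  poly <- sim$associations |>
    dplyr::add_count(disease) |>
    dplyr::filter(n >= 2)
  rec <- poly[1, ]
  remaining <- dplyr::anti_join(sim$associations, rec[c("disease", "gene")],
                                by = c("disease", "gene"))
  seeds <- remaining$gene[remaining$disease == rec$disease]
  y <- build_prior(rec$disease, remaining, sim$calibrated, sim$gnet,
                   form = "symmetric", seeds = seeds)
  # the target's prior must come only from *other* diseases' similarities
  other <- remaining[remaining$gene == rec$gene &
                       remaining$disease != rec$disease, ]
  expected <- if (nrow(other) == 0) 0 else {
    max(sim$calibrated$scores[rec$disease, other$disease])
  }
  expect_identical(unname(y[rec$gene]), expected)
  expect_lt(y[rec$gene], 1)
})

test_that("LOOCV is deterministic", {
  sim <- toy_study()
  a <- loocv(sim$associations, sim$calibrated, sim$gnet)
  b <- loocv(sim$associations, sim$calibrated, sim$gnet)
  expect_identical(tidy(a), tidy(b))
  expect_identical(glance(a), glance(b))
})

test_that("summary statistics match hand-computed values", {
  records <- tibble::tibble(rank = c(1L, 10L, 100L),
                            n_candidates = rep(1000L, 3))
  rep <- compute_report(records)
  expect_equal(rep$mrr_percent, (0.1 + 1 + 10) / 3)
  expect_equal(rep$top_count, 1L)
  expect_equal(rep$tpr_at_5, 100 / 3)
  expect_equal(rep$tpr_at_10, 200 / 3)
  expect_equal(rep$tpr_at_30, 200 / 3)
  expect_equal(rep$n_targets, 3L)

  all_top <- tibble::tibble(rank = rep(1L, 4), n_candidates = rep(50L, 4))
  rep2 <- compute_report(all_top)
  expect_equal(rep2$mrr_percent, 2)
  expect_equal(rep2$top_count, 4L)
  expect_equal(rep2$tpr_at_5, 100)

  expect_error(compute_report(records[0, ]), "No rank records")
})

test_that("TPR is monotone nondecreasing in k on random records", {
  for (seed in 1:5) {
    records <- withr::with_seed(seed, {
      n <- 40
      nc <- sample(50:500, n, replace = TRUE)
      tibble::tibble(n_candidates = nc,
                     rank = vapply(nc, function(m) sample.int(m, 1),
                                   integer(1)))
    })
    rep <- compute_report(records)
    expect_lte(rep$tpr_at_5, rep$tpr_at_10)
    expect_lte(rep$tpr_at_10, rep$tpr_at_30)
    expect_lte(rep$top_count, rep$n_targets)
    expect_gte(rep$mrr_percent, 0)
    expect_lte(rep$mrr_percent, 100)
  }
})

test_that("the steepness sweep picks the exhaustively verified optimum", {
  sim <- toy_study()
  norm <- normalize_similarity(sim$phenonet, "tanimoto")
  grid <- c(-17, -14, -11)
  sw <- sweep_c(grid, sim$associations, norm, sim$gnet)
  expect_equal(nrow(tidy(sw)), length(grid))
  # exhaustive oracle: re-run every c independently and recompute the rule
  tops <- vapply(grid, function(cc) {
    glance(loocv(sim$associations, logistic_transform(norm, cc),
                 sim$gnet))$top_count
  }, integer(1))
  best <- grid[tops == max(tops)]
  expect_equal(sw$best_c, best[which.min(abs(best))])
  expect_equal(tidy(sw)$top_count, tops)
  # single-element grid returns that c
  expect_equal(sweep_c(-13, sim$associations, norm, sim$gnet)$best_c, -13)
})

test_that("sweep ties break toward the smallest steepness magnitude", {
  records <- tibble::tibble(rank = 1L, n_candidates = 10L)
  fake <- structure(list(reports = tibble::tibble(
    c = c(-20, -12, -15), n_targets = 1L, top_count = c(3L, 3L, 2L)
  )), class = "phenoprio_sweep")
  ord <- order(-fake$reports$top_count, abs(fake$reports$c), -fake$reports$c)
  expect_equal(fake$reports$c[ord[1]], -12)
})

test_that("network concordance counts partition the target set", {
  a <- tibble::tibble(disease = paste0("d", 1:6), target_gene = paste0("g", 1:6),
                      rank = c(1L, 1L, 2L, 5L, 1L, 3L),
                      n_candidates = 10L)
  b <- a
  b$rank <- c(1L, 4L, 1L, 6L, 1L, 1L)
  cmp <- compare_networks(a, b)
  expect_equal(sum(cmp$n), 6L)
  expect_equal(cmp$n[cmp$validated_a & cmp$validated_b], 2L)       # d1, d5
  expect_equal(cmp$n[cmp$validated_a & !cmp$validated_b], 1L)      # d2
  expect_equal(cmp$n[!cmp$validated_a & cmp$validated_b], 2L)      # d3, d6
  expect_equal(cmp$n[!cmp$validated_a & !cmp$validated_b], 1L)     # d4
  # identical record sets put everything on the diagonal
  same <- compare_networks(a, a)
  expect_equal(sum(same$n[same$validated_a != same$validated_b]), 0L)
  expect_error(compare_networks(a, a[-1, ]), "different associations")
})

test_that("associations outside the PPI or phenotype network are dropped with a warning", {
  sim <- toy_study()
  extra <- dplyr::bind_rows(
    sim$associations,
    tibble::tibble(disease = c(sim$associations$disease[1], "999999"),
                   gene = c("not_a_gene", sim$associations$gene[1])))
  expect_warning(cv <- loocv(extra, sim$calibrated, sim$gnet), "Dropping 2")
  expect_equal(nrow(tidy(cv)), nrow(sim$associations))
})
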