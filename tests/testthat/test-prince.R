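test_that("degree normalization has the expected closed forms and spectrum", {
  # 2-regular ring: every nonzero entry equals 1/2
  ids <- paste0("g", 1:6)
  ring <- gene_net(tibble::tibble(from = ids, to = ids[c(2:6, 1)]),
                   gene_ids = ids)
  w <- as.matrix(normalize_adjacency(ring)$w_norm)
  expect_equal(sort(unique(as.vector(w))), c(0, 0.5))

  # 2-node single edge: off-diagonal entries 1
  two <- path_gnet(c("a", "b"))
  expect_equal(as.matrix(normalize_adjacency(two)$w_norm),
               matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"),
                                                           c("a", "b"))))

  # spectral oracle on random 30-node graphs
  for (seed in 1:3) {
    g <- normalize_adjacency(random_gnet(30, seed = seed))
    ev <- eigen(as.matrix(g$w_norm), symmetric = TRUE, only.values = TRUE)
    expect_lte(max(abs(ev$values)), 1 + 1e-12)
    expect_equal(as.matrix(g$w_norm), t(as.matrix(g$w_norm)))
  }
})

test_that("gene_net drops self-loops and collapses duplicate edges to max weight", {
  edges <- tibble::tibble(from = c("a", "b", "a", "a"),
                          to = c("b", "a", "a", "c"),
                          weight = c(1, 5, 2, 1))
  expect_warning(net <- gene_net(edges), "self-loop")
  expect_equal(net$adjacency["a", "b"], 5)  # duplicate in either orientation
  expect_equal(net$adjacency["a", "a"], 0)
  expect_equal(sort(net$gene_ids), c("a", "b", "c"))
})

test_that("prior construction aggregates calibrated similarity by maximum", {
  # 3 diseases; gene gx causes d2 (sim .2 to d1) and d3 (sim .7 to d1)
  m <- matrix(c(1, .2, .7,
                .2, 1, .4,
                .7, .4, 1), 3, 3, byrow = TRUE,
              dimnames = list(c("d1", "d2", "d3"), c("d1", "d2", "d3")))
  net <- phenotype_net(m)
  assoc <- tibble::tibble(disease = c("d1", "d2", "d3"),
                          gene = c("gseed", "gx", "gx"))
  gnet <- path_gnet(c("gseed", "gx", "gnone"))
  y <- build_prior("d1", assoc, net, gnet, form = "symmetric")
  expect_identical(unname(y["gseed"]), 1)       # seed gene of the query
  expect_identical(unname(y["gx"]), 0.7)        # max over its two diseases
  expect_identical(unname(y["gnone"]), 0)       # no known disease

  expect_error(build_prior("nope", assoc, net, gnet), "not in the phenotype")
})

test_that("row and column forms read the two directions of an asymmetric network", {
  m <- matrix(c(1, .8, .3, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("d1", "d2"), c("d1", "d2")))
  net <- phenotype_net(m)  # sim(d1->d2) = .8, sim(d2->d1) = .3
  assoc <- tibble::tibble(disease = "d2", gene = "gx")
  gnet <- path_gnet(c("gx", "gy"))
  expect_equal(unname(build_prior("d1", assoc, net, gnet, "row")["gx"]), .8)
  expect_equal(unname(build_prior("d1", assoc, net, gnet, "col")["gx"]), .3)
  expect_error(build_prior("d1", assoc, net, gnet, "symmetric"), "symmetric")
  expect_error(build_prior("d1", assoc, symmetrize(net), gnet, "row"),
               "symmetric")
})

test_that("propagation degenerates correctly at the trivial fixed points", {
  gnet <- random_gnet(20, seed = 4)
  y <- random_prior(gnet, seed = 4)
  # alpha -> 0: F = Y after one update
  out <- propagate(gnet, y, alpha = 1e-12)
  expect_equal(out$score, unname(y), tolerance = 1e-9)
  # all-zero prior is a fixed point
  zero <- propagate(gnet, setNames(rep(0, 20), gnet$gene_ids))
  expect_identical(zero$score, rep(0, 20))
  expect_identical(attr(zero, "iterations"), 1L)
  # isolated node: scalar fixed point (1 - alpha) * y
  iso <- gene_net(tibble::tibble(from = "a", to = "b"),
                  gene_ids = c("a", "b", "lone"))
  f <- closed_form_propagate(iso, c(a = 0, b = 0, lone = 1), alpha = 0.9)
  expect_equal(f$score[f$gene == "lone"], 0.1)
  expect_equal(closed_form_propagate(iso, c(a = 1, b = 0, lone = 0),
                                     alpha = 0)$score, c(1, 0, 0))
})

test_that("iterative and closed-form propagation agree on random instances", {
  for (seed in 1:10) {
    gnet <- random_gnet(50, seed = seed)
    y <- random_prior(gnet, seed = seed + 100)
    it <- propagate(gnet, y, alpha = 0.9, tol = 1e-9, max_iter = 1000)
    cf <- closed_form_propagate(gnet, y, alpha = 0.9)
    expect_true(attr(it, "converged"))
    expect_lt(max(abs(it$score - cf$score)), 1e-6)
  }
})

test_that("propagation converges within the default iteration budget on synthetic graphs", {
  for (seed in 1:3) {
    gnet <- gen_ppi(synth_config(n_genes = 1000, seed = seed))
    y <- random_prior(gnet, seed = seed)
    out <- propagate(gnet, y, alpha = 0.9, tol = 1e-9, max_iter = 100)
    expect_true(attr(out, "converged"))
  }
})

test_that("raising the prior of one gene never lowers any propagated score", {
  gnet <- random_gnet(25, seed = 9)
  y <- random_prior(gnet, seed = 9)
  base <- closed_form_propagate(gnet, y)$score
  for (idx in c(1, 10, 25)) {
    y2 <- y
    y2[idx] <- y2[idx] + 0.5
    bumped <- closed_form_propagate(gnet, y2)$score
    expect_true(all(bumped - base >= -1e-12))
  }
})

test_that("propagation is equivariant under gene relabeling", {
  gnet <- random_gnet(15, seed = 13)
  y <- random_prior(gnet, seed = 13)
  f <- propagate(gnet, y)
  perm <- withr::with_seed(13, sample.int(15))
  ids_perm <- gnet$gene_ids[perm]
  edges <- gene_net_edges(gnet)
  relabel <- setNames(paste0("h", seq_len(15)), ids_perm)
  gnet2 <- gene_net(tibble::tibble(from = unname(relabel[edges$from]),
                                   to = unname(relabel[edges$to]),
                                   weight = edges$weight),
                    gene_ids = paste0("h", seq_len(15)))
  y2 <- setNames(y[ids_perm], paste0("h", seq_len(15)))
  f2 <- propagate(gnet2, y2)
  expect_equal(setNames(f2$score, names(relabel)[match(f2$gene, relabel)])[gnet$gene_ids],
               setNames(f$score, f$gene)[gnet$gene_ids])
})

test_that("prioritization ranks by decaying propagated score and excludes seeds", {
  # seed - g1 - g2 path: evidence decays with distance
  gnet <- path_gnet(c("seed", "g1", "g2"))
  net <- phenotype_net(matrix(1, 1, 1, dimnames = list("d", "d")))
  assoc <- tibble::tibble(disease = "d", gene = "seed")
  ranked <- prioritize("d", assoc, net, gnet, form = "symmetric")
  expect_false("seed" %in% ranked$gene)
  expect_equal(nrow(ranked), 2)
  expect_lt(ranked$rank[ranked$gene == "g1"], ranked$rank[ranked$gene == "g2"])

  # closed-form oracle on the same 3-node path
  cf <- closed_form_propagate(gnet, c(seed = 1, g1 = 0, g2 = 0))
  expect_gt(cf$score[cf$gene == "g1"], cf$score[cf$gene == "g2"])

  # a fixed-size candidate set yields exactly that many ranked entries
  gnet2 <- random_gnet(30, seed = 2)
  net2 <- phenotype_net(matrix(1, 1, 1, dimnames = list("d", "d")))
  assoc2 <- tibble::tibble(disease = "d", gene = "g1")
  cand <- paste0("g", 10:24)
  ranked2 <- prioritize("d", assoc2, net2, gnet2, form = "symmetric",
                        candidates = cand)
  expect_equal(nrow(ranked2), 15)
  expect_setequal(ranked2$gene, cand)
  expect_error(prioritize("d", assoc2, net2, gnet2, form = "symmetric",
                          candidates = "g1"), "Empty candidate")
})

test_that("tied scores get the pessimistic competition rank", {
  # two isolated candidates with identical zero evidence tie at rank 2
  gnet <- gene_net(tibble::tibble(from = "s", to = "hub"),
                   gene_ids = c("s", "hub", "x", "y"))
  net <- phenotype_net(matrix(1, 1, 1, dimnames = list("d", "d")))
  assoc <- tibble::tibble(disease = "d", gene = "s")
  ranked <- prioritize("d", assoc, net, gnet, form = "symmetric")
  expect_equal(ranked$rank[ranked$gene == "hub"], 1)
  expect_equal(ranked$rank[ranked$gene == "x"], 3)
  expect_equal(ranked$rank[ranked$gene == "y"], 3)
})
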