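---
title: "Evaluating disease phenotype networks for gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating disease phenotype networks for gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoprio)
```

## The problem

Disease phenotype networks (DPNs) are weighted networks whose nodes are
genetic diseases and whose edge weights score how similar two diseases look
clinically. Under the guilt-by-association principle — genes causing
phenotypically similar diseases tend to encode proteins that interact — a DPN
can serve as prior knowledge for ranking candidate disease genes over a
protein–protein interaction (PPI) network. Different DPNs exist, built from
different vocabularies (MeSH-standardized text mining of OMIM versus Human
Phenotype Ontology semantic similarity), and they disagree in scale, symmetry
and density. phenoprio implements the apparatus needed to compare such
networks fairly: normalization, logistic calibration, PRINCE label
propagation, leave-one-out cross-validation (LOOCV), network integration, and
a generator of synthetic studies in which the guilt-by-association structure
is planted by construction so every stage can be exercised without any
external download.

## The model

### Symmetrization and normalization

Directional semantic similarity $Sim(A \to B)$ is asymmetric; the symmetric
measure averages the two directions,
$$Sim_{sym}(A,B) = \tfrac{1}{2}\left(Sim(A \to B) + Sim(B \to A)\right).$$
Because raw scores are unbounded, four elementwise normalizations map a
similarity matrix into $[0,1]$, writing $S(A,A)$ for the diagonal
self-similarity:

* **Lin** $\;2S(A,B) / (S(A,A)+S(B,B))$
* **Sqrt** $\;S(A,B) / \sqrt{S(A,A)\,S(B,B)}$
* **Maxmin** $\;(S(A,B)-S_{\min})/(S_{\max}-S_{\min})$, extremes over the
  whole matrix, diagonal included
* **Tanimoto** $\;S(A,B) / (S(A,A)+S(B,B)-S(A,B))$

Normalization is applied once to the stored matrix. For an asymmetric matrix
the "-R" and "-C" variants of a normalized network are *not* two different
matrices: they are a read direction — whether, at prior-construction time,
the similarity of a query disease to the others is taken along its row or its
column. `build_prior()` therefore takes a `form` argument (`row`, `col`,
`symmetric`) and the normalization functions know nothing about it.

### Logistic calibration

Similarity is passed through
$$L(x) = \frac{1}{1+e^{cx+d}}, \qquad d = \log(9999),$$
so that $L(0) = 10^{-4}$: a disease pair with no phenotype overlap
contributes essentially nothing to the prior, which suppresses the pervasive
low-level noise in similarity matrices. The steepness $c$ is negative (the
map is then strictly increasing) and is the pipeline's one tuned parameter;
`sweep_c()` selects it by maximizing the number of top-ranked held-out genes
in LOOCV. When two networks are integrated (`combine_networks()`, entrywise
$p\,A + (1-p)\,B$), integration happens *before* calibration, so that a
single steepness is fitted to the integrated network — this matches reporting
one best $c$ per mixing proportion.

### Propagation

With a prior $Y$ over genes (seed genes of the query at 1; any other gene
carrying a disease association at the calibrated similarity between its
most-similar disease and the query; 0 otherwise), PRINCE iterates
$$F^{t} = \alpha\, W_{norm} F^{t-1} + (1-\alpha) Y, \qquad F^1 = Y,$$
where $W_{norm} = D^{-1/2} A D^{-1/2}$ is the symmetric degree normalization
of the PPI adjacency. That choice of $W_{norm}$ bounds the spectral radius by
1, so the update is a contraction for $\alpha < 1$ and converges to the fixed
point $(I-\alpha W_{norm})F = (1-\alpha)Y$, which
`closed_form_propagate()` solves directly and the test suite uses as an
independent oracle. Candidate genes are ranked by $F$; ties get the
pessimistic competition rank (a tied target is placed after everything tied
with it), so reported ranks never flatter the method.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.9 | propagation weight; results are insensitive above 0.5 |
| `tol` | 1e-9 | L1 stopping tolerance on successive iterates |
| `max_iter` | 100 | iteration cap |
| `c` | swept, integers −25..−8 | logistic steepness; optima land around −12..−22 in practice |
| `proportion` | 0.5 | mixing weight when integrating two networks |

Two conventions deserve a note because the underlying literature leaves them
open. The convergence metric is the L1 norm of $F^t - F^{t-1}$ (stricter than
a mean absolute difference at the same tolerance). Seed genes receive prior
exactly 1 rather than the calibrated self-similarity: a direct association is
certain evidence; the choice is exposed through the `seeds` argument for
anyone wanting otherwise. Aggregation over several associated diseases uses
the maximum, not the sum, keeping $Y \le 1$.

On the iteration cap: with $\alpha = 0.9$ the error contracts by at most 0.9
per step on the slowest mode, so reaching an L1 difference of $10^{-9}$ can
in principle need more than 100 iterations; on the preferential-attachment
graphs the generator produces, the relevant spectral gap is large and
convergence happens in 50–60 iterations even at 1000 nodes. Once the L1
tolerance is met, the distance to the exact fixed point is bounded by
$\mathrm{tol}\cdot\alpha/(1-\alpha) \approx 9\times10^{-9}$. Where an
analysis needs the fixed point to high accuracy regardless of graph, raise
`max_iter` (the closed-form comparisons in the tests use 1000) or call
`closed_form_propagate()`.

## Degenerate inputs and numerical choices

* Zero denominators in Lin/Sqrt/Tanimoto (a disease with zero
  self-similarity, e.g. an absent diagonal in a sparse pairwise export) give
  0: no phenotype evidence, no contribution. Sparse pairwise files whose
  diagonal is unlisted hit this rule unless they supply self-similarities.
* Values escaping $[0,1]$ after a ratio normalization — possible when a noisy
  input has $S(A,B)$ above a self-similarity — are clipped, with a warning,
  because the calibration assumes $[0,1]$.
* Maxmin on a constant matrix, empty candidate sets, empty disease
  intersections, and zero reference row sums in `relative_network_mean()` are
  errors that name the offending input.
* Duplicate PPI edges collapse to their maximum weight; self-loops are
  dropped; unweighted edges get weight 1.
* Disease identifiers are opaque strings; nothing assumes 6-digit OMIM
  numbers, so Orphanet/DECIPHER-style identifiers pass through readers
  unharmed.

## The synthetic study

`synth_config()` defines the generative model the whole validation runs on:

* a PPI network grown by preferential attachment (`igraph::sample_pa`),
  connected and simple, whose heavy-tailed degrees resemble curated
  interactomes — 500 genes with 3 edges added per node by default;
* 100 diseases in 10 phenotype modules; each module is anchored at a PPI
  node and its gene pool is a breadth-first neighborhood of the anchor, so
  genes of same-module diseases are close in the PPI graph;
* each disease draws 1–3 causal genes from its module pool (diseases at 1
  are monogenic, matching the real benchmark's mix of monogenic and
  polygenic diseases);
* pairwise similarity is truncated normal — mean 0.6 (sd 0.1) within a
  module, 0.1 (sd 0.05) between — clipped to $[0,1]$; a truncated normal was
  chosen as the simplest bounded family with controllable location and
  spread;
* the diagonal is set to each disease's row maximum, which guarantees the
  ratio normalizations stay in $[0,1]$ without clipping;
* optional independent directional noise (`asym_noise`) produces an
  asymmetric network for exercising the row/col machinery.

The label-permutation control (`permute_labels()`) permutes disease labels
jointly over rows and columns: every disease keeps a realistic similarity
profile, but the profile no longer points at the right genes. On the default
configuration the informative network beats this control on both mean rank
ratio and TPR@30 in essentially every generator seed — that is the package's
headline recovery property, checked over 10 seeds in the acceptance tests.

What the generator does *not* emulate: literature-derived similarity noise
structure (its noise is i.i.d. truncated normal), overlapping disease
modules of heterogeneous size, study bias in the PPI (hub genes are hubs for
topological, not sociological, reasons), or missing annotations. Passing
tests on synthetic data therefore show the machinery is correct and that
planted signal of realistic strength is recovered — not that any particular
real DPN will achieve a particular accuracy.

## Problem sizes used in the checks

The shipped validation runs the recovery comparison at the generator's
default scale (500 genes, 100 diseases, 10 generator seeds, both the
informative and the permuted network — about 4000 propagations), the
propagation-oracle comparison on 100 random 50-node graphs, and the
end-to-end file-based pipeline with a steepness sweep on a 200-gene,
40-disease instance; these sizes are the package's choice of a demonstration
scale that keeps a full run in the order of a minute on one core.

## A worked run

```{r example, eval = FALSE}
sim <- simulate_study(synth_config(seed = 1))
calibrated <- sim$phenonet |>
  normalize_similarity("tanimoto") |>
  logistic_transform(-13)
cv <- loocv(sim$associations, calibrated, sim$gnet)
glance(cv)
autoplot(cv)

# null control
null_cv <- sim$phenonet |>
  permute_labels(seed = 1001) |>
  normalize_similarity("tanimoto") |>
  logistic_transform(-13) |>
  loocv(associations = sim$associations, gnet = sim$gnet)
```

(`loocv()` takes the association table first in normal use; the last chain
pipes the network into the named slot.) The same computation driven from
files:

```{r pipeline, eval = FALSE}
dir <- tempfile()
sim <- simulate_study(synth_config(seed = 1), dir = dir)
res <- run_pipeline(pipeline_config(
  phenonet = sim$paths$phenonet,
  ppi = sim$paths$ppi,
  associations = sim$paths$associations,
  method = "tanimoto",
  c_grid = -20:-9
))
tidy(res)          # one evaluation row per steepness
res$result$best_c  # selected by maximum top-ranking genes
```

## Known limitations

* The asymmetric forms are evaluated by read direction only; normalizing a
  row-extracted and a column-extracted matrix separately is deliberately not
  supported, since they are the same matrix.
* `loocv()` recomputes one propagation per held-out association;
  at interactome scale (~9000 genes, ~1300 associations) a run is minutes,
  not seconds, per steepness value.
* Statistical significance testing between two networks' record sets is out
  of scope; `compare_networks()` reports the concordance counts on which such
  a test could be built.
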