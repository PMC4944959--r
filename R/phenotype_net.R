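#' Disease phenotype similarity network
#'
#' A `phenotype_net` is a labeled square matrix of disease-disease phenotype
#' similarity scores, the central object of a disease phenotype network (DPN).
#' Rows and columns are indexed by the same ordered set of disease identifiers
#' (e.g. 6-digit OMIM numbers, treated as opaque strings). The object carries a
#' `symmetric` flag: semantic-similarity exports such as an averaged
#' information-content matrix are symmetric, while directional measures
#' Sim(A->B) are not.
#'
#' @param scores numeric square matrix. Row and column names, if present, must
#'   agree; they become the disease identifiers.
#' @param disease_ids character vector of unique disease identifiers; defaults
#'   to `rownames(scores)`, or `D1..Dn` when the matrix is unnamed.
#' @param symmetric logical or `NULL`. When `NULL` (default), detected by exact
#'   comparison of `scores` with its transpose.
#'
#' @return An object of class `phenotype_net`: a list with elements `scores`
#'   (named numeric matrix), `disease_ids`, and `symmetric`.
#' @seealso [symmetrize()], [normalize_similarity()], [logistic_transform()],
#'   [combine_networks()], [relative_network_mean()], [intersect_networks()]
#' @export
#' @examples
#' m <- matrix(c(1, .3, .3, 1), 2, 2, dimnames = list(c("100050", "100070"),
#'                                                    c("100050", "100070")))
#' phenotype_net(m)
phenotype_net <- function(scores, disease_ids = NULL, symmetric = NULL) {
  if (!is.matrix(scores) || !is.numeric(scores)) {
    abort("`scores` must be a numeric matrix.")
  }
  if (nrow(scores) != ncol(scores)) {
    abort(sprintf("`scores` must be square, got %d x %d.",
                  nrow(scores), ncol(scores)))
  }
  if (is.null(disease_ids)) {
    disease_ids <- rownames(scores)
    if (!is.null(disease_ids) && !is.null(colnames(scores)) &&
        !identical(disease_ids, colnames(scores))) {
      abort("Row and column names of `scores` disagree.")
    }
    if (is.null(disease_ids)) disease_ids <- paste0("D", seq_len(nrow(scores)))
  }
  disease_ids <- as.character(disease_ids)
  if (length(disease_ids) != nrow(scores)) {
    abort("`disease_ids` length must equal the matrix dimension.")
  }
  if (anyDuplicated(disease_ids)) {
    abort("Disease identifiers must be unique.")
  }
  dimnames(scores) <- list(disease_ids, disease_ids)
  if (is.null(symmetric)) symmetric <- all(scores == base::t(scores))
  structure(
    list(scores = scores, disease_ids = disease_ids,
         symmetric = isTRUE(symmetric)),
    class = "phenotype_net"
  )
}

#' @export
print.phenotype_net <- function(x, ...) {
  rng <- value_range(x)
  cat(sprintf("<phenotype_net> %d diseases, %s, values in [%.4g, %.4g]\n",
              length(x$disease_ids),
              if (x$symmetric) "symmetric" else "asymmetric",
              rng[1], rng[2]))
  invisible(x)
}

#' Observed value range of a phenotype network
#'
#' @param net a [phenotype_net()].
#' @return numeric length-2 vector `(min, max)` of the stored scores.
#' @export
value_range <- function(net) {
  stopifnot(inherits(net, "phenotype_net"))
  range(net$scores)
}

#' Symmetrize a directional similarity network
#'
#' Directional phenotype similarity Sim(A->B) differs from Sim(B->A); the
#' symmetric measure averages the two directions:
#' \deqn{Sim_{sym}(A,B) = (Sim(A \to B) + Sim(B \to A)) / 2.}
#' Applying it to an already-symmetric network returns the network unchanged.
#'
#' @param net a [phenotype_net()].
#' @return a symmetric `phenotype_net` over the same diseases.
#' @export
symmetrize <- function(net) {
  stopifnot(inherits(net, "phenotype_net"))
  s <- (net$scores + base::t(net$scores)) / 2
  phenotype_net(s, net$disease_ids, symmetric = TRUE)
}

#' Normalize similarity scores into \[0, 1\]
#'
#' Raw semantic-similarity scores (e.g. summed information content) are
#' unbounded, which makes networks incomparable and breaks the downstream
#' logistic calibration. Four elementwise normalizations are supported, writing
#' S(A,B) for the stored score and S(A,A), S(B,B) for the diagonal
#' self-similarities:
#' \describe{
#'   \item{lin}{`2 S(A,B) / (S(A,A) + S(B,B))`}
#'   \item{sqrt}{`S(A,B) / sqrt(S(A,A) * S(B,B))`}
#'   \item{maxmin}{`(S(A,B) - S_min) / (S_max - S_min)` with the extremes taken
#'     over the entire matrix, diagonal included}
#'   \item{tanimoto}{`S(A,B) / (S(A,A) + S(B,B) - S(A,B))`}
#' }
#' Entries whose denominator is zero (a disease with zero self-similarity
#' carries no phenotype evidence) are set to 0. Values escaping \[0, 1\] on
#' noisy input are clipped, with a warning. The normalization is applied once
#' to the full stored matrix; reading it row-wise versus column-wise (the -R /
#' -C forms of an asymmetric network) is a choice made later, at prior
#' construction time.
#'
#' @param net a [phenotype_net()].
#' @param method one of `"lin"`, `"sqrt"`, `"maxmin"`, `"tanimoto"`.
#' @return a `phenotype_net` with all values in \[0, 1\].
#' @export
normalize_similarity <- function(net,
                                 method = c("lin", "sqrt", "maxmin",
                                            "tanimoto")) {
  stopifnot(inherits(net, "phenotype_net"))
  method <- match.arg(method)
  s <- net$scores
  n <- nrow(s)
  if (method == "maxmin") {
    smin <- min(s)
    smax <- max(s)
    if (smax <= smin) {
      abort("Maxmin normalization is undefined on a constant matrix.")
    }
    out <- (s - smin) / (smax - smin)
  } else {
    d <- diag(s)
    di <- matrix(d, n, n)            # S(A,A) by row
    dj <- matrix(d, n, n, byrow = TRUE)  # S(B,B) by column
    denom <- switch(method,
      lin      = di + dj,
      sqrt     = sqrt(di * dj),
      tanimoto = di + dj - s
    )
    num <- if (method == "lin") 2 * s else s
    out <- ifelse(denom == 0, 0, num / denom)
  }
  if (any(out < 0) || any(out > 1)) {
    warn(sprintf("%d normalized value(s) escaped [0, 1]; clipped.",
                 sum(out < 0 | out > 1)))
    out <- pmin(pmax(out, 0), 1)
  }
  phenotype_net(out, net$disease_ids, symmetric = net$symmetric)
}

#' Logistic calibration of similarity scores
#'
#' Maps similarity x through the logistic function
#' \deqn{L(x) = 1 / (1 + e^{c x + d}), \quad d = \log(9999),}
#' which sharpens the correlation between phenotype similarity and shared
#' causal genes: L(0) = 1e-4, so unrelated disease pairs contribute almost
#' nothing to the propagation prior, while strong similarities are pushed
#' toward 1. The steepness `c` is negative in practice (typically integers
#' between about -22 and -12, tuned by cross-validation); for `c < 0` the map
#' is strictly increasing.
#'
#' @param net a [phenotype_net()] with values in \[0, 1\] (any real accepted).
#' @param c real steepness; negative for an increasing calibration.
#' @return a `phenotype_net` with values in (0, 1); symmetry is preserved.
#' @export
logistic_transform <- function(net, c) {
  stopifnot(inherits(net, "phenotype_net"), is.numeric(c), length(c) == 1)
  d <- log(9999)
  out <- 1 / (1 + exp(c * net$scores + d))
  phenotype_net(out, net$disease_ids, symmetric = net$symmetric)
}

#' Integrate two phenotype networks
#'
#' Entrywise convex combination `p * netA + (1 - p) * netB` of two networks
#' over the same ordered disease set, both already normalized to \[0, 1\].
#' `p = 0.5` is the arithmetic average; complementary networks integrated this
#' way can outperform either alone. Combination happens before logistic
#' calibration, so a single steepness is fitted to the integrated network.
#'
#' @param netA,netB [phenotype_net()] objects with identical `disease_ids` in
#'   identical order.
#' @param proportion weight `p` of `netA`, in \[0, 1\].
#' @return a `phenotype_net`.
#' @export
combine_networks <- function(netA, netB, proportion) {
  stopifnot(inherits(netA, "phenotype_net"), inherits(netB, "phenotype_net"),
            is.numeric(proportion), length(proportion) == 1,
            proportion >= 0, proportion <= 1)
  if (!identical(netA$disease_ids, netB$disease_ids)) {
    abort("Networks must share identical disease identifiers in identical order; use intersect_networks() first.")
  }
  out <- proportion * netA$scores + (1 - proportion) * netB$scores
  phenotype_net(out, netA$disease_ids,
                symmetric = netA$symmetric && netB$symmetric)
}

#' Relative network mean
#'
#' A diagnostic of how a network's similarity mass is distributed relative to
#' a reference network. The total similarity of a disease is the sum of its
#' row; the statistic is the mean over diseases of the ratio of row sums:
#' \deqn{\frac{1}{n}\sum_d \frac{\sum_j net[d,j]}{\sum_j ref[d,j]}.}
#' It tracks the optimal logistic steepness across networks: denser networks
#' (larger relative mean) want a shallower calibration. A network against
#' itself gives exactly 1.
#'
#' @param net,reference [phenotype_net()] objects over identical aligned
#'   disease sets; reference row sums must be strictly positive.
#' @return a single number.
#' @export
relative_network_mean <- function(net, reference) {
  stopifnot(inherits(net, "phenotype_net"),
            inherits(reference, "phenotype_net"))
  if (!identical(net$disease_ids, reference$disease_ids)) {
    abort("Networks must share identical disease identifiers in identical order.")
  }
  rs_net <- base::rowSums(net$scores)
  rs_ref <- base::rowSums(reference$scores)
  bad <- rs_ref <= 0
  if (any(bad)) {
    abort(sprintf("Reference row sum is not strictly positive for disease(s): %s",
                  paste(net$disease_ids[bad], collapse = ", ")))
  }
  mean(rs_net / rs_ref)
}

#' Restrict two phenotype networks to their shared diseases
#'
#' Networks built from different standardizations cover different disease
#' sets; a fair comparison restricts both to the diseases they share. Both
#' outputs are subset to the sorted intersection of identifiers, rows and
#' columns consistently, in the same order.
#'
#' @param netA,netB [phenotype_net()] objects.
#' @return a named list `list(a = , b = )` of restricted `phenotype_net`s.
#' @export
intersect_networks <- function(netA, netB) {
  stopifnot(inherits(netA, "phenotype_net"), inherits(netB, "phenotype_net"))
  shared <- sort(intersect(netA$disease_ids, netB$disease_ids))
  if (length(shared) == 0) {
    abort("The two networks share no disease identifiers.")
  }
  list(
    a = phenotype_net(netA$scores[shared, shared, drop = FALSE], shared,
                      symmetric = netA$symmetric),
    b = phenotype_net(netB$scores[shared, shared, drop = FALSE], shared,
                      symmetric = netB$symmetric)
  )
}

#' Permute disease labels of a phenotype network
#'
#' Null control for guilt-by-association benchmarks: the disease labels are
#' permuted jointly over rows and columns, so every disease keeps a realistic
#' similarity profile (the multiset of values and of row sums is preserved)
#' but the link between a disease's label and its similarity profile — and
#' hence to its associated genes — is destroyed.
#'
#' @param net a [phenotype_net()].
#' @param seed integer seed for the permutation.
#' @return a `phenotype_net` with the same `disease_ids`.
#' @export
permute_labels <- function(net, seed = 1L) {
  stopifnot(inherits(net, "phenotype_net"))
  n <- length(net$disease_ids)
  perm <- withr::with_seed(seed, sample.int(n))
  s <- net$scores[perm, perm, drop = FALSE]
  phenotype_net(unname(s), net$disease_ids, symmetric = net$symmetric)
}
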