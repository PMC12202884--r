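#' Contingency summary of two partitions
#'
#' Cross-tabulates two label vectors over the same items and precomputes
#' the quantities the clustering-agreement metrics share: the contingency
#' counts `nij`, the row and column sums `a_i`, `b_j`, and the pair counts
#' TP / FP / FN (pairs of items placed together in the true partition, the
#' predicted partition, or both). Label values are opaque: every metric
#' built on this object is invariant to relabeling on either side.
#'
#' @param labels_true,labels_pred Equal-length label vectors (any atomic
#'   type), length >= 2.
#' @return A `partition_comparison` object.
#' @seealso [ari()], [ami()], [nmi()], [fmi()]
#' @export
contingency <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred))
    stop_("label vectors differ in length")
  if (length(labels_true) < 2) stop_("need at least 2 items")
  nij <- unclass(table(true = as.character(labels_true),
                       pred = as.character(labels_pred)))
  n <- sum(nij)
  a <- rowSums(nij)
  b <- colSums(nij)
  tp <- sum(choose(nij, 2))
  structure(list(n = n, nij = nij, a = a, b = b,
                 tp = tp,
                 fp = sum(choose(b, 2)) - tp,
                 fn = sum(choose(a, 2)) - tp),
            class = "partition_comparison")
}

as_pc <- function(labels_true, labels_pred) {
  if (inherits(labels_true, "partition_comparison")) labels_true
  else contingency(labels_true, labels_pred)
}

# entropy of a partition from its cluster sizes, natural log
part_entropy <- function(sizes, n) {
  p <- sizes[sizes > 0] / n
  -sum(p * log(p))
}

# mutual information between the two partitions, natural log
part_mi <- function(pc) {
  nz <- which(pc$nij > 0, arr.ind = TRUE)
  nij <- pc$nij[nz]
  sum(nij / pc$n *
        log(nij * pc$n / (pc$a[nz[, 1]] * pc$b[nz[, 2]])))
}

# Expected mutual information under the permutation (hypergeometric) model:
# for each cluster-size pair (a_i, b_j), nij follows a hypergeometric law,
# and each feasible nij >= 1 contributes its MI term weighted by its
# probability. Exact summation with log-factorials.
part_emi <- function(pc) {
  n <- pc$n
  emi <- 0
  for (ai in pc$a) for (bj in pc$b) {
    lo <- max(1, ai + bj - n)
    hi <- min(ai, bj)
    if (hi < lo) next
    k <- lo:hi
    lp <- lfactorial(ai) + lfactorial(bj) + lfactorial(n - ai) +
      lfactorial(n - bj) - lfactorial(n) - lfactorial(k) -
      lfactorial(ai - k) - lfactorial(bj - k) -
      lfactorial(n - ai - bj + k)
    emi <- emi + sum(k / n * log(k * n / (ai * bj)) * exp(lp))
  }
  emi
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, corrected for chance:
#' `(sum_ij C(nij,2) - E) / (0.5 (sum_i C(a_i,2) + sum_j C(b_j,2)) - E)`
#' with `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)`. Equals 1 for
#' identical partitions and is 0 in expectation for random ones. When both
#' partitions are trivial (numerator and denominator both zero) the value
#' is 1 by convention.
#'
#' @param labels_true,labels_pred Label vectors, or a
#'   `partition_comparison` as first argument.
#' @return The index value (<= 1).
#' @export
ari <- function(labels_true, labels_pred = NULL) {
  pc <- as_pc(labels_true, labels_pred)
  exp_idx <- sum(choose(pc$a, 2)) * sum(choose(pc$b, 2)) / choose(pc$n, 2)
  num <- sum(choose(pc$nij, 2)) - exp_idx
  den <- 0.5 * (sum(choose(pc$a, 2)) + sum(choose(pc$b, 2))) - exp_idx
  if (den == 0) return(1)
  num / den
}

#' Adjusted mutual information
#'
#' Mutual information corrected for chance under the permutation model:
#' `(MI - E[MI]) / (max(H(U), H(V)) - E[MI])`, with the exact
#' hypergeometric expectation and the **maximum** of the two entropies as
#' normalizer. Natural logarithms throughout. Two trivial (single-cluster)
#' partitions compare as 1 by convention.
#'
#' @inheritParams ari
#' @return The index value (<= 1).
#' @export
ami <- function(labels_true, labels_pred = NULL) {
  pc <- as_pc(labels_true, labels_pred)
  hu <- part_entropy(pc$a, pc$n)
  hv <- part_entropy(pc$b, pc$n)
  if (hu == 0 && hv == 0) return(1)
  emi <- part_emi(pc)
  den <- max(hu, hv) - emi
  if (den == 0) return(1)
  (part_mi(pc) - emi) / den
}

#' Normalized mutual information
#'
#' `MI / sqrt(H(U) H(V))`: 0 for independent partitions, 1 for identical
#' ones. Both partitions trivial gives 1 by convention; one trivial
#' partition against a nontrivial one gives 0 (no information shared).
#'
#' @inheritParams ari
#' @return Value in `[0, 1]`.
#' @export
nmi <- function(labels_true, labels_pred = NULL) {
  pc <- as_pc(labels_true, labels_pred)
  hu <- part_entropy(pc$a, pc$n)
  hv <- part_entropy(pc$b, pc$n)
  if (hu == 0 && hv == 0) return(1)
  if (hu == 0 || hv == 0) return(0)
  mi <- part_mi(pc)
  max(0, min(1, mi / sqrt(hu * hv)))
}

#' Fowlkes--Mallows index
#'
#' Geometric mean of pair-level precision and recall:
#' `sqrt(TP/(TP+FP) * TP/(TP+FN))`, where TP counts item pairs placed
#' together in both partitions. Returns 0 when TP is 0.
#'
#' @inheritParams ari
#' @return Value in `[0, 1]`.
#' @export
fmi <- function(labels_true, labels_pred = NULL) {
  pc <- as_pc(labels_true, labels_pred)
  if (pc$tp == 0) return(0)
  pc$tp / sqrt((pc$tp + pc$fp) * (pc$tp + pc$fn))
}

#' All four clustering-agreement metrics at once
#'
#' @inheritParams ari
#' @return Named numeric vector with elements `ari`, `ami`, `nmi`, `fmi`.
#' @export
clustering_agreement <- function(labels_true, labels_pred = NULL) {
  pc <- as_pc(labels_true, labels_pred)
  c(ari = ari(pc), ami = ami(pc), nmi = nmi(pc), fmi = fmi(pc))
}
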