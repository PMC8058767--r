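#' Ordering of mutation pairs induced by a tree
#'
#' Classifies every unordered pair of mutations by the relation of their
#' gain nodes: one an ancestor of the other (an ordered ancestor-descendant
#' pair) or on different lineages (neither ancestral to the other).  Loss
#' nodes are ignored: loss placement can be non-identifiable, so comparison
#' metrics are defined over gains only.
#'
#' @param tree a [dollo_tree()].
#' @return list with `ancestor` (logical m x m matrix: `[p, q]` is `TRUE`
#'   iff the gain of `p` is a strict ancestor of the gain of `q`) and
#'   `different_lineage` (symmetric logical m x m matrix).
#' @export
mutation_order <- function(tree) {
  anc <- ancestor_matrix(tree)
  gains <- which(tree$kind == "gain")
  gain_of <- integer(tree$m)
  gain_of[tree$mutation[gains]] <- gains
  A <- anc[gain_of, gain_of, drop = FALSE]
  DL <- !A & !t(A)
  diag(DL) <- FALSE
  dimnames(A) <- dimnames(DL) <- list(tree$mutation_labels, tree$mutation_labels)
  list(ancestor = A, different_lineage = DL)
}

check_same_mutations <- function(true_tree, inferred_tree) {
  if (true_tree$m != inferred_tree$m ||
      !setequal(true_tree$mutation_labels, inferred_tree$mutation_labels))
    stop("trees are over different mutation sets")
}

# align inferred ancestor/DL matrices to the true tree's label order
aligned_orders <- function(true_tree, inferred_tree) {
  check_same_mutations(true_tree, inferred_tree)
  to <- mutation_order(true_tree)
  io <- mutation_order(inferred_tree)
  perm <- match(true_tree$mutation_labels, inferred_tree$mutation_labels)
  list(true = to,
       inferred = list(ancestor = io$ancestor[perm, perm, drop = FALSE],
                       different_lineage = io$different_lineage[perm, perm,
                                                                drop = FALSE]))
}

#' Ancestor-descendant accuracy
#'
#' The fraction of ordered mutation pairs `(p, q)` with the gain of `p` a
#' strict ancestor of the gain of `q` in the true tree for which the same
#' holds in the inferred tree; 1 when the true tree has no such pairs.
#'
#' @param true_tree,inferred_tree [dollo_tree()]s over the same mutations.
#' @return a number in `[0, 1]`.
#' @export
ancestor_descendant_accuracy <- function(true_tree, inferred_tree) {
  o <- aligned_orders(true_tree, inferred_tree)
  tot <- sum(o$true$ancestor)
  if (tot == 0L) return(1)
  sum(o$true$ancestor & o$inferred$ancestor) / tot
}

#' Different-lineage accuracy
#'
#' The fraction of unordered mutation pairs on different lineages (neither
#' gain ancestral to the other) in the true tree that are also on different
#' lineages in the inferred tree; 1 when the true tree has no such pairs.
#'
#' @inheritParams ancestor_descendant_accuracy
#' @return a number in `[0, 1]`.
#' @export
different_lineage_accuracy <- function(true_tree, inferred_tree) {
  o <- aligned_orders(true_tree, inferred_tree)
  tot <- sum(o$true$different_lineage) / 2
  if (tot == 0) return(1)
  (sum(o$true$different_lineage & o$inferred$different_lineage) / 2) / tot
}

#' Flip-parsimony score
#'
#' Absolute difference between the number of flips a method introduced to
#' correct the input and the number of flips the simulation actually
#' planted; 0 is a perfectly parsimonious correction.
#'
#' @param estimated_flips,true_flips non-negative counts.
#' @return a non-negative integer.
#' @export
flip_parsimony_delta <- function(estimated_flips, true_flips) {
  abs(estimated_flips - true_flips)
}

#' Accuracy of false-negative rate estimation
#'
#' Two summaries of how well estimated per-mutation dropout rates match the
#' planted ones: the absolute error of the average rate, and the mean
#' squared error over mutations (which also reflects the variance of the
#' estimates — important when the true rates are strongly bimodal).
#'
#' @param estimated,true numeric vectors of equal length.
#' @return named numeric vector `c(avg_error, mse)`.
#' @export
fn_rate_errors <- function(estimated, true) {
  if (length(estimated) != length(true))
    stop("estimated and true rate vectors differ in length")
  c(avg_error = abs(mean(estimated) - mean(true)),
    mse = mean((estimated - true)^2))
}

#' Count three-gamete conflicts
#'
#' Counts unordered mutation pairs that violate the infinite-sites
#' assumption: a pair conflicts with a perfect phylogeny iff cells exhibit
#' all three gametes (1,0), (0,1) and (1,1) across the two columns.
#' Missing entries are compatible with anything and are ignored.
#'
#' @param I an [scs_matrix()] (or 0/1/NA matrix).
#' @return number of conflicting pairs.
#' @export
count_conflicts <- function(I) {
  x <- unclass(I)
  A1 <- (x == 1L); A1[is.na(A1)] <- FALSE
  A0 <- (x == 0L); A0[is.na(A0)] <- FALSE
  n11 <- crossprod(A1)        # cells with (1,1)
  n10 <- crossprod(A1, A0)    # cells with (1,0): p = 1, q = 0
  conflict <- n11 > 0 & n10 > 0 & t(n10) > 0
  sum(conflict[upper.tri(conflict)])
}
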