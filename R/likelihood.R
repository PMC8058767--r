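#' Log-likelihood of one observed entry
#'
#' The single-cell error model: a true 1 is observed as 0 with probability
#' `alpha_j` (allelic dropout, mutation-specific), a true 0 is observed as 1
#' with probability `beta` (false positive), and a missing observation is
#' uninformative (probability 1 under either truth).
#'
#' @param observed observed call: 0, 1 or `NA` (missing).
#' @param truth true genotype: 0 or 1.
#' @param alpha_j false-negative rate of the mutation.
#' @param beta global false-positive rate.
#' @return the log probability `log P(observed | truth)`; `-Inf` when the
#'   observation has probability zero (e.g. `alpha_j = 0` with a dropout).
#' @export
entry_log_likelihood <- function(observed, truth, alpha_j, beta) {
  if (is.na(observed)) return(0)
  if (observed == 0 && truth == 0) return(log1p(-beta))
  if (observed == 0 && truth == 1) return(log(alpha_j))
  if (observed == 1 && truth == 0) return(log(beta))
  if (observed == 1 && truth == 1) return(log1p(-alpha_j))
  stop("observed and truth must be 0, 1 or NA (observed only)")
}

# finite stand-in for log(0) in the vectorised path, so that 0 * log(0)
# contributions vanish in matrix products instead of producing NaN
.NEG_SENTINEL <- -1e12
.IMPOSSIBLE_CUTOFF <- -1e11

# precompute the data-dependent factors of the attachment log-likelihood;
# the returned closure maps a genotype-profile matrix to the n x N matrix
# L[i, v] = log-likelihood of cell i's row under node v's profile
make_loglik_kernel <- function(I, rates) {
  A0 <- (unclass(I) == 0L); A0[is.na(A0)] <- FALSE
  A1 <- (unclass(I) == 1L); A1[is.na(A1)] <- FALSE
  storage.mode(A0) <- storage.mode(A1) <- "double"
  clamp <- function(x) { x[x == -Inf] <- .NEG_SENTINEL; x }
  la  <- clamp(log(rates$alpha))    # log P(0|1), per mutation
  l1a <- clamp(log1p(-rates$alpha)) # log P(1|1)
  lb  <- clamp(log(rates$beta))     # log P(1|0)
  l1b <- clamp(log1p(-rates$beta))  # log P(0|0)
  function(P) {
    # weight of an observed 0 (resp. 1) at a node carrying profile P[v, ]
    Q0 <- P * matrix(la,  nrow(P), ncol(P), byrow = TRUE) + (1 - P) * l1b
    Q1 <- P * matrix(l1a, nrow(P), ncol(P), byrow = TRUE) + (1 - P) * lb
    A0 %*% t(Q0) + A1 %*% t(Q1)
  }
}

# n x N matrix of attachment log-likelihoods
attachment_loglik <- function(tree, I, rates, profiles = NULL) {
  if (ncol(I) != tree$m)
    stop("matrix has ", ncol(I), " mutations but tree expects ", tree$m)
  make_loglik_kernel(I, rates)(profiles %||% genotype_profiles(tree))
}

#' Optimal attachment of cells to a tree
#'
#' Attaches every cell to the node whose genotype profile maximizes the
#' cell's log-likelihood under the error model, scanning all nodes of the
#' tree (root, gains and losses alike).  Ties are broken towards the
#' smallest node id, so the result is deterministic.
#'
#' @param tree a valid [dollo_tree()].
#' @param I an [scs_matrix()] (or 0/1/NA matrix) with `m` columns.
#' @param rates an [error_rates()] object.
#' @return list of class `dollo_attachment` with `sigma` (integer vector of
#'   node ids, one per cell) and `per_cell_loglik` (the attained maxima).
#' @export
best_attachment <- function(tree, I, rates) {
  L <- attachment_loglik(tree, I, rates)
  sigma <- max.col(L, ties.method = "first")
  per_cell <- L[cbind(seq_len(nrow(L)), sigma)]
  if (any(per_cell < .IMPOSSIBLE_CUTOFF))
    stop("cell(s) ",
         paste(head(which(per_cell < .IMPOSSIBLE_CUTOFF), 5L), collapse = ", "),
         " cannot be attached: every node has probability zero ",
         "(zero error rates with contradicting observations)")
  structure(list(sigma = sigma, per_cell_loglik = per_cell),
            class = "dollo_attachment")
}

#' Tree objective function
#'
#' The score maximized by the annealing search: the attachment
#' log-likelihood of all cells plus a loss-prior term controlled by
#' `loss_prior_mode`.
#'
#' In `"penalty"` mode (default) each loss of mutation `j` contributes
#' `log(gamma[j])`, a standard per-event log-prior that penalizes losses
#' (and forbids them, with `-Inf`, when `gamma[j] = 0`).  `"as-printed"`
#' mode uses `-c[j] * log(1 - gamma[j])` instead, a non-negative term that
#' rewards losses; it is kept for literal fidelity to the formulation this
#' model derives from, but makes every neutral deletion improve the score
#' up to the `d` cap.
#'
#' @inheritParams best_attachment
#' @param loss_prior_mode `"penalty"` or `"as-printed"`.
#' @param attachment optionally, a precomputed [best_attachment()] result.
#' @return a single number (may be `-Inf` in penalty mode when a loss is
#'   used for a mutation with `gamma = 0`).
#' @export
dollo_objective <- function(tree, I, rates,
                            loss_prior_mode = c("penalty", "as-printed"),
                            attachment = NULL) {
  loss_prior_mode <- match.arg(loss_prior_mode)
  att <- attachment %||% best_attachment(tree, I, rates)
  loss_prior_term(loss_counts(tree), rates$gamma, loss_prior_mode) +
    sum(att$per_cell_loglik)
}

loss_prior_term <- function(cj, gamma, loss_prior_mode) {
  if (loss_prior_mode == "as-printed") {
    -sum(cj * log1p(-gamma))
  } else {
    used <- cj > 0L
    if (!any(used)) return(0)
    sum(cj[used] * log(gamma[used]))   # -Inf when gamma = 0 and a loss is used
  }
}

#' Corrected genotype matrix implied by a fitted tree
#'
#' Row `i` of the corrected (error-free) matrix `E` is the genotype profile
#' of the node cell `i` is attached to.
#'
#' @inheritParams best_attachment
#' @param attachment a [best_attachment()] result.
#' @return integer n x m matrix.
#' @export
corrected_matrix <- function(tree, I, attachment) {
  P <- genotype_profiles(tree)
  E <- P[attachment$sigma, , drop = FALSE]
  dimnames(E) <- dimnames(I)
  E
}

#' Count input-to-output flips
#'
#' Compares the observed matrix `I` with the corrected matrix `E` implied by
#' a tree and attachment: a false-negative flip is an observed 0 corrected
#' to 1, a false-positive flip an observed 1 corrected to 0.  Missing
#' entries contribute to neither.
#'
#' @inheritParams corrected_matrix
#' @return named integer vector `c(fn_flips, fp_flips)`.
#' @export
count_flips <- function(I, tree, attachment) {
  E <- corrected_matrix(tree, I, attachment)
  I <- unclass(I)
  c(fn_flips = sum(I == 0L & E == 1L, na.rm = TRUE),
    fp_flips = sum(I == 1L & E == 0L, na.rm = TRUE))
}

#' Estimate per-mutation false-negative rates from a fit
#'
#' For each mutation, the estimated dropout rate is the fraction of cells
#' whose corrected genotype carries the mutation but whose observed call is
#' 0, among cells with a non-missing observation and corrected genotype 1.
#' Mutations carried by no attached cell get an estimate of 0.
#'
#' @inheritParams corrected_matrix
#' @return numeric vector of length `m`.
#' @export
estimate_fn_rates <- function(I, tree, attachment) {
  E <- corrected_matrix(tree, I, attachment)
  I <- unclass(I)
  num <- colSums(I == 0L & E == 1L, na.rm = TRUE)
  den <- colSums(!is.na(I) & E == 1L)
  ifelse(den > 0L, num / den, 0)
}
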