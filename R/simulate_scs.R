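#' Triangular distribution sampler
#'
#' Inverse-CDF draws from the Triangular distribution with lower limit `a`,
#' mode `c`, upper limit `b` — the conventional choice for loss priors when
#' only plausible bounds and a most-likely value are known.
#'
#' @param n number of draws.
#' @param a,c,b lower limit, mode and upper limit (`a <= c <= b`).
#' @return numeric vector of length `n`.
#' @export
rtriangular <- function(n, a, c, b) {
  if (!(a <= c && c <= b)) stop("need a <= c <= b")
  if (a == b) return(rep(a, n))
  u <- stats::runif(n)
  fc <- (c - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

#' Draw per-mutation error and loss-prior rates
#'
#' False-negative (dropout) rates are i.i.d. Beta draws; with both shape
#' parameters below 1 the distribution is bimodal, mimicking the dropout
#' profile of real single-cell RNA data where rates pile up near 0 and near
#' 1 with gene expression.  Loss priors are i.i.d. Triangular draws.
#'
#' @param m number of mutations.
#' @param beta_shapes length-2 vector of Beta shape parameters (both < 1
#'   for the bimodal regime; default `c(0.3, 0.3)`).
#' @param tri length-3 vector `c(a, c, b)` of Triangular lower limit, mode
#'   and upper limit (default `c(0, 0.05, 0.1)`).
#' @param seed optional integer seed.
#' @return list with numeric vectors `alpha` and `gamma`, each of length `m`.
#' @export
draw_rates <- function(m, beta_shapes = c(0.3, 0.3), tri = c(0, 0.05, 0.1),
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(alpha = stats::rbeta(m, beta_shapes[1L], beta_shapes[2L]),
       gamma = rtriangular(m, tri[1L], tri[2L], tri[3L]))
}

#' Simulate a ground-truth Dollo phylogeny and cell attachment
#'
#' Builds a random gain tree ([random_init()]), plants mutation losses, and
#' attaches each of the `n` cells to a uniformly random node; the true
#' (error-free) genotype matrix has the attached node's profile as each
#' cell's row.
#'
#' Losses are planted in a random mutation order: mutation `j` triggers a
#' loss with probability `gamma[j]` (or exactly `n_losses` mutations are
#' forced to lose, when given), and each triggered loss is spliced at a
#' uniformly chosen valid site below the mutation's gain, respecting the
#' `k` and `d` bounds.
#'
#' @param n number of cells.
#' @param m number of mutations.
#' @param k,d Dollo bounds of the planted tree.
#' @param gamma per-mutation loss priors (scalar broadcast; ignored when
#'   `n_losses` is given).
#' @param n_losses optional exact number of mutations to lose.
#' @param seed optional integer seed.
#' @return list with `tree` (a [dollo_tree()]), `true_matrix` (integer
#'   n x m), `sigma` (true attachment node ids).
#' @export
simulate_phylogeny <- function(n, m, k = 1L, d = 0L, gamma = 0,
                               n_losses = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(gamma) == 1L) gamma <- rep(gamma, m)
  tree <- random_init(m, k = k, d = d)
  ord <- sample.int(m)
  lose <- if (is.null(n_losses)) ord[stats::runif(m) < gamma[ord]] else ord
  planted <- 0L
  target <- if (is.null(n_losses)) length(lose) else min(n_losses, d)
  for (mut in lose) {
    if (planted >= target || sum(loss_counts(tree)) >= d) break
    anc <- ancestor_matrix(tree)
    g <- which(tree$kind == "gain" & tree$mutation == mut)
    sites <- which(anc[g, ])      # splice above any strict descendant
    if (!length(sites)) next      # leaf gain: no valid loss site
    u <- sites[sample.int(length(sites), 1L)]
    new_tree <- tryCatch(add_deletion(tree, u, mut),
                         dollo_move_rejected = function(e) NULL)
    if (!is.null(new_tree)) {
      tree <- new_tree
      planted <- planted + 1L
    }
  }
  sigma <- sample.int(n_nodes(tree), n, replace = TRUE)
  P <- genotype_profiles(tree)
  true_matrix <- P[sigma, , drop = FALSE]
  rownames(true_matrix) <- paste0("cell", seq_len(n))
  list(tree = tree, true_matrix = true_matrix, sigma = sigma)
}

#' Add sequencing noise to a true genotype matrix
#'
#' Per entry, independently: the entry is first set missing with probability
#' `missing_rate`; surviving 1s flip to 0 with the mutation's dropout rate
#' `alpha[j]` and surviving 0s flip to 1 with probability `fp_rate`.  The
#' order (missing first, then flips) is fixed: entries lost to missingness
#' never appear in the flip log.
#'
#' @param true_matrix integer 0/1 matrix (cells x mutations).
#' @param alpha per-mutation false-negative rates (scalar broadcast).
#' @param fp_rate global false-positive rate.
#' @param missing_rate probability an entry is unobserved.
#' @param seed optional integer seed.
#' @return list with `observed` (an [scs_matrix()]) and `flips`, a data
#'   frame (cell, mutation, from, to) logging every introduced flip.
#' @export
sample_observed_matrix <- function(true_matrix, alpha, fp_rate = 1e-5,
                                   missing_rate = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(true_matrix); m <- ncol(true_matrix)
  if (length(alpha) == 1L) alpha <- rep(alpha, m)
  A <- matrix(alpha, n, m, byrow = TRUE)
  obs <- unclass(true_matrix)
  storage.mode(obs) <- "integer"
  miss <- matrix(stats::runif(n * m) < missing_rate, n, m)
  flip_p <- ifelse(obs == 1L, A, fp_rate)
  flip <- !miss & matrix(stats::runif(n * m), n, m) < flip_p
  obs[flip] <- 1L - obs[flip]
  obs[miss] <- NA_integer_
  idx <- which(flip, arr.ind = TRUE)
  flips <- data.frame(cell = idx[, 1L], mutation = idx[, 2L],
                      from = unclass(true_matrix)[idx],
                      to = obs[idx])
  list(observed = scs_matrix(obs,
                             cell_labels = rownames(true_matrix),
                             mutation_labels = colnames(true_matrix)),
       flips = flips[order(flips$cell, flips$mutation), , drop = FALSE])
}

#' Simulate a full noisy single-cell experiment
#'
#' Convenience wrapper chaining [draw_rates()], [simulate_phylogeny()] and
#' [sample_observed_matrix()]: draws mutation-specific dropout rates from a
#' Beta distribution and loss priors from a Triangular distribution, plants
#' losses, attaches cells and adds noise.  Defaults describe a desk-scale
#' single-cell experiment: 100 cells, 20 mutations, bimodal
#' `Beta(0.3, 0.3)` dropout, `Triangular(0, 0.05, 0.1)` loss priors, a
#' false-positive rate of `1e-5` and 1\% missing entries.
#'
#' @inheritParams simulate_phylogeny
#' @inheritParams sample_observed_matrix
#' @inheritParams draw_rates
#' @param alpha optional per-mutation dropout rates (scalar broadcast);
#'   drawn from the Beta distribution when `NULL`.
#' @param gamma optional loss priors (scalar broadcast); drawn from the
#'   Triangular distribution when `NULL`.
#' @param seed integer seed for the whole simulation.
#' @return list with `tree`, `true_matrix`, `sigma`, `observed`, `flips`,
#'   `alpha`, `gamma`.
#' @examples
#' sim <- simulate_scs_data(n = 30, m = 8, k = 1, d = 2, seed = 7)
#' sim$observed
#' @export
simulate_scs_data <- function(n = 100L, m = 20L, k = 1L, d = 3L,
                              alpha = NULL, gamma = NULL,
                              beta_shapes = c(0.3, 0.3), tri = c(0, 0.05, 0.1),
                              fp_rate = 1e-5, missing_rate = 0.01,
                              n_losses = NULL, seed = 1L) {
  set.seed(seed)
  drawn <- draw_rates(m, beta_shapes, tri)
  if (is.null(alpha)) alpha <- drawn$alpha
  if (length(alpha) == 1L) alpha <- rep(alpha, m)
  if (is.null(gamma)) gamma <- drawn$gamma
  if (length(gamma) == 1L) gamma <- rep(gamma, m)
  phy <- simulate_phylogeny(n, m, k = k, d = d, gamma = gamma,
                            n_losses = n_losses)
  colnames(phy$true_matrix) <- phy$tree$mutation_labels
  noisy <- sample_observed_matrix(phy$true_matrix, alpha,
                                  fp_rate = fp_rate,
                                  missing_rate = missing_rate)
  c(phy, noisy, list(alpha = alpha, gamma = gamma))
}
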