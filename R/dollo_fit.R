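#' Fit a Dollo-k cancer progression tree to single-cell data
#'
#' The package's central estimator.  Given a ternary single-cell genotype
#' matrix, `dollo_fit` searches for the Dollo-k mutation tree (each mutation
#' gained once, lost at most `k` times, at most `d` losses overall) that
#' maximizes the likelihood of the observed data under an error model with
#' mutation-specific false-negative rates `alpha`, a global false-positive
#' rate `beta` and per-mutation loss priors `gamma`.  The tree space is
#' explored by simulated annealing ([anneal()]); cells are re-attached
#' optimally after every move and the best tree ever visited is returned.
#'
#' @param I an [scs_matrix()], or any matrix with entries 0, 1 and `NA`.
#' @param beta global false-positive rate.
#' @param alpha per-mutation false-negative rates; a scalar is broadcast.
#'   May also be a path to a rate file ([read_rate_file()]).
#' @param gamma per-mutation loss priors (scalar broadcast or rate-file
#'   path); `gamma = 0` forbids losses of that mutation under the default
#'   prior mode.
#' @param k maximum losses per mutation (0 forces a perfect phylogeny).
#' @param d maximum total losses.
#' @param loss_prior_mode how loss priors enter the objective; see
#'   [dollo_objective()].
#' @param control an [anneal_control()].
#' @param seed integer seed for the search.
#' @return an object of class `dollo_fit`: a list with components `tree`
#'   (the inferred [dollo_tree()]), `attachment`, `objective`, `E` (the
#'   corrected matrix), `alpha_hat` (estimated per-mutation dropout rates),
#'   `flips` (fn/fp flip counts), `rates`, `trace`, `I` and `call`.
#' @examples
#' sim <- simulate_scs_data(n = 40, m = 6, k = 1, d = 1, alpha = 0.1,
#'                          missing_rate = 0, seed = 11)
#' fit <- dollo_fit(sim$observed, beta = 1e-5, alpha = 0.1, gamma = 0.05,
#'                  k = 1, d = 1, control = anneal_control(restarts = 1),
#'                  seed = 2)
#' fit
#' coef(fit)                       # estimated dropout rate per mutation
#' ancestor_descendant_accuracy(sim$tree, fit$tree)
#' @export
dollo_fit <- function(I, beta, alpha = 0.1, gamma = 0.05, k = 1L, d = 0L,
                      loss_prior_mode = c("penalty", "as-printed"),
                      control = anneal_control(), seed = 1L) {
  loss_prior_mode <- match.arg(loss_prior_mode)
  cl <- match.call()
  if (!inherits(I, "scs_matrix")) I <- scs_matrix(I)
  m <- ncol(I)
  if (is.character(alpha)) alpha <- read_rate_file(alpha, m)
  if (is.character(gamma)) gamma <- read_rate_file(gamma, m)
  rates <- error_rates(alpha = alpha, beta = beta, gamma = gamma, m = m)
  res <- anneal(I, rates, k = k, d = d, loss_prior_mode = loss_prior_mode,
                control = control, seed = seed)
  structure(list(tree = res$tree,
                 attachment = res$attachment,
                 objective = res$objective,
                 E = corrected_matrix(res$tree, I, res$attachment),
                 alpha_hat = stats::setNames(
                   estimate_fn_rates(I, res$tree, res$attachment),
                   colnames(I)),
                 flips = count_flips(I, res$tree, res$attachment),
                 rates = rates, trace = res$trace, I = I,
                 k = as.integer(k), d = as.integer(d),
                 loss_prior_mode = loss_prior_mode, seed = seed, call = cl),
            class = "dollo_fit")
}

#' @export
print.dollo_fit <- function(x, ...) {
  cat("Dollo-", x$k, " progression tree fitted by simulated annealing\n",
      sep = "")
  cat("  cells: ", nrow(x$I), "   mutations: ", ncol(x$I),
      "   losses inferred: ", sum(loss_counts(x$tree)),
      " (d = ", x$d, ")\n", sep = "")
  cat("  objective: ", format(x$objective), "\n", sep = "")
  cat("  flips introduced: ", x$flips[["fn_flips"]], " false negatives, ",
      x$flips[["fp_flips"]], " false positives\n", sep = "")
  invisible(x)
}

#' @export
summary.dollo_fit <- function(object, ...) {
  cj <- loss_counts(object$tree)
  counts <- integer(n_nodes(object$tree))
  t <- table(object$attachment$sigma)
  counts[as.integer(names(t))] <- as.integer(t)
  out <- list(fit = object,
              lost_mutations = object$tree$mutation_labels[cj > 0L],
              node_cells = counts,
              mean_alpha_hat = mean(object$alpha_hat))
  class(out) <- "summary.dollo_fit"
  out
}

#' @export
print.summary.dollo_fit <- function(x, ...) {
  print(x$fit)
  cat("  lost mutations: ",
      if (length(x$lost_mutations)) paste(x$lost_mutations, collapse = ", ")
      else "none", "\n", sep = "")
  cat("  mean estimated dropout rate: ", format(signif(x$mean_alpha_hat, 3)),
      "\n", sep = "")
  cat("  cells per node: ", paste(x$node_cells, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
coef.dollo_fit <- function(object, ...) object$alpha_hat

#' @export
logLik.dollo_fit <- function(object, ...) {
  ll <- sum(object$attachment$per_cell_loglik)
  attr(ll, "df") <- n_nodes(object$tree) - 1L   # one free edge per non-root node
  attr(ll, "nobs") <- sum(!is.na(object$I))
  class(ll) <- "logLik"
  ll
}

#' @export
fitted.dollo_fit <- function(object, ...) object$E

#' Residuals of a fitted progression tree
#'
#' The residual matrix `I - E`: +1 marks an observed 1 the tree explains as
#' a false positive, -1 an observed 0 explained as allelic dropout, 0 an
#' entry the tree reproduces, `NA` a missing observation.
#'
#' @param object a [dollo_fit()].
#' @param ... unused.
#' @return integer n x m matrix.
#' @export
residuals.dollo_fit <- function(object, ...) {
  unclass(object$I) - object$E
}

#' Attach new cells to a fitted tree
#'
#' @param object a [dollo_fit()].
#' @param newdata an [scs_matrix()] (or 0/1/NA matrix) over the same
#'   mutations; defaults to the training matrix.
#' @param ... unused.
#' @return data frame with one row per cell: the attachment node id, its
#'   label and the attachment log-likelihood.
#' @export
predict.dollo_fit <- function(object, newdata = NULL, ...) {
  I <- newdata %||% object$I
  if (ncol(I) != object$tree$m)
    stop("newdata has ", ncol(I), " mutations; the tree expects ", object$tree$m)
  att <- best_attachment(object$tree, I, object$rates)
  data.frame(cell = rownames(I) %||% seq_len(nrow(I)),
             node = att$sigma,
             label = node_labels(object$tree)[att$sigma],
             loglik = att$per_cell_loglik)
}

#' Simulate observed matrices from a fitted tree
#'
#' Parametric resampling: keeps the fitted tree and cell attachment, and
#' redraws the observation noise (dropout per the fitted error rates,
#' false positives, no missing entries) on the corrected matrix.
#'
#' @param object a [dollo_fit()].
#' @param nsim number of matrices to draw.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `nsim` [scs_matrix()] objects.
#' @export
simulate.dollo_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(s)
    sample_observed_matrix(object$E, object$rates$alpha,
                           fp_rate = object$rates$beta,
                           missing_rate = 0)$observed)
}

#' Plot a fitted progression tree
#'
#' Draws the inferred mutation tree with a layered tree layout (via
#' igraph); loss nodes are shown in red, node labels carry the mutation
#' name and the number of attached cells.
#'
#' @param x a [dollo_fit()] or a [dollo_tree()].
#' @param collapse_simple merge non-branching paths for display.
#' @param support_threshold if positive, merge nodes with support below the
#'   threshold for display.
#' @param ... passed to [igraph::plot.igraph()].
#' @return the igraph object, invisibly.
#' @export
plot.dollo_fit <- function(x, collapse_simple = FALSE, support_threshold = 0,
                           ...) {
  dt <- display_tree(x$tree, x$attachment)
  if (collapse_simple) dt <- collapse_simple_paths(dt)
  if (support_threshold > 0) dt <- collapse_low_support(dt, support_threshold)
  lab <- vapply(seq_along(dt$parent), function(i)
    paste0(paste(dt$labels[[i]], collapse = ","),
           if (dt$cells[i] > 0L) paste0("\n", dt$cells[i], " cells") else ""),
    character(1))
  ev <- which(!is.na(dt$parent))
  g <- igraph::graph_from_edgelist(cbind(dt$parent[ev], ev))
  col <- ifelse(vapply(dt$loss, any, logical(1)), "indianred1", "lightsteelblue")
  igraph::plot.igraph(g, layout = igraph::layout_as_tree(g, root = 1),
                      vertex.label = lab, vertex.color = col,
                      vertex.shape = "crectangle", vertex.size = 30,
                      vertex.size2 = 15, edge.arrow.size = 0.4, ...)
  invisible(g)
}

#' @rdname plot.dollo_fit
#' @export
plot.dollo_tree <- function(x, ...) {
  fake <- list(tree = x, attachment = list(sigma = integer(0)))
  plot.dollo_fit(structure(fake, class = "dollo_fit"), ...)
}
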