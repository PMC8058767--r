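#' Annealing schedule and search controls
#'
#' Geometric cooling: the temperature at iteration `i` is
#' `T0 * (1 - cooling_rate)^i`, and the chain stops once it falls below
#' `Tmin`.  With the defaults (`T0 = 1e4`, `cooling_rate = 1e-2`,
#' `Tmin = 1e-3`) a restart runs exactly 1604 proposals.
#'
#' @param T0 initial temperature.
#' @param cooling_rate geometric decay factor per iteration, in (0, 1).
#' @param Tmin stopping temperature, below `T0`.
#' @param restarts number of independent restarts; the best tree across all
#'   restarts is returned.  The default of 10 restarts (16040 proposals in
#'   total) is sized for desk-scale problems of a few dozen mutations;
#'   larger instances warrant more.
#' @return a list of class `anneal_control`.
#' @export
anneal_control <- function(T0 = 1e4, cooling_rate = 1e-2, Tmin = 1e-3,
                           restarts = 10L) {
  if (!(cooling_rate > 0 && cooling_rate < 1)) stop("cooling_rate must be in (0, 1)")
  if (!(Tmin < T0)) stop("Tmin must be below T0")
  if (restarts < 1L) stop("restarts must be at least 1")
  structure(list(T0 = T0, cooling_rate = cooling_rate, Tmin = Tmin,
                 restarts = as.integer(restarts)),
            class = "anneal_control")
}

#' @rdname anneal_control
#' @param i iteration index (0-based).
#' @param control an `anneal_control` object.
#' @return `temperature()`: the temperature at iteration `i`.
#' @export
temperature <- function(i, control = anneal_control()) {
  control$T0 * (1 - control$cooling_rate)^i
}

#' Metropolis acceptance rule
#'
#' A proposal changing the objective by `delta` at temperature `temp` is
#' accepted with probability `min(exp(delta / temp), 1)`: improvements
#' always, deteriorations with a probability that shrinks as the chain
#' cools.  Consumes one uniform draw from the current RNG stream when the
#' proposal is not an improvement.
#'
#' @param delta objective change of the proposal (may be `-Inf`).
#' @param temp current temperature (> 0).
#' @return logical.
#' @export
accept_move <- function(delta, temp) {
  if (delta >= 0) return(TRUE)
  stats::runif(1L) < exp(delta / temp)
}

#' Simulated-annealing search for a maximum-likelihood Dollo-k tree
#'
#' Each restart starts from a [random_init()] gain-only tree and repeatedly
#' proposes one neighbourhood move ([propose_move()]), re-attaches all cells
#' optimally ([best_attachment()]), scores the tree ([dollo_objective()])
#' and applies the Metropolis rule under geometric cooling.  The incumbent
#' best tree ever visited (not the final chain state) is returned, tracked
#' across restarts.
#'
#' @param I an [scs_matrix()] (or 0/1/NA matrix).
#' @param rates an [error_rates()] object.
#' @param k,d Dollo bounds for the search.
#' @param loss_prior_mode see [dollo_objective()].
#' @param control an [anneal_control()].
#' @param seed integer seed; restart `r` runs on a sub-seed derived from it,
#'   so runs are reproducible.
#' @param trace_every record every `trace_every`-th iteration in the trace
#'   (1 keeps all).
#' @return list with `tree`, `attachment`, `objective` and `trace` (a data
#'   frame with columns restart, iteration, temperature, kind, current,
#'   best).
#' @export
anneal <- function(I, rates, k = 1L, d = 0L,
                   loss_prior_mode = c("penalty", "as-printed"),
                   control = anneal_control(), seed = 1L, trace_every = 1L) {
  loss_prior_mode <- match.arg(loss_prior_mode)
  m <- ncol(I)
  if (m != rates$m) stop("rates are for ", rates$m, " mutations, matrix has ", m)
  mut_labels <- colnames(I) %||% paste0("mut", seq_len(m))
  set.seed(seed)
  restart_seeds <- sample.int(.Machine$integer.max, control$restarts)

  kernel <- make_loglik_kernel(I, rates)
  score <- function(tree) {
    L <- kernel(genotype_profiles(tree))
    sigma <- max.col(L, ties.method = "first")
    per_cell <- L[cbind(seq_len(nrow(L)), sigma)]
    att <- structure(list(sigma = sigma, per_cell_loglik = per_cell),
                     class = "dollo_attachment")
    list(att = att,
         obj = loss_prior_term(loss_counts(tree), rates$gamma, loss_prior_mode) +
           sum(per_cell))
  }

  best <- NULL
  traces <- vector("list", control$restarts)
  for (r in seq_len(control$restarts)) {
    set.seed(restart_seeds[r])
    cur_tree <- random_init(m, k = k, d = d, mutation_labels = mut_labels)
    cur <- score(cur_tree)
    if (is.null(best) || cur$obj > best$objective)
      best <- list(tree = cur_tree, attachment = cur$att, objective = cur$obj)
    chain_len <- max(0L, ceiling(log(control$Tmin / control$T0) /
                                   log(1 - control$cooling_rate)))
    nrec <- ceiling(chain_len / trace_every)
    it <- temp <- curv <- bestv <- numeric(nrec)
    kindv <- character(nrec)
    rec <- 0L
    i <- 0L
    repeat {
      Ti <- control$T0 * (1 - control$cooling_rate)^i
      if (Ti < control$Tmin) break
      prop <- propose_move(cur_tree)
      new <- score(prop$tree)
      if (accept_move(new$obj - cur$obj, Ti)) {
        cur_tree <- prop$tree
        cur <- new
        if (cur$obj > best$objective)
          best <- list(tree = cur_tree, attachment = cur$att, objective = cur$obj)
      }
      if (i %% trace_every == 0L) {
        rec <- rec + 1L
        it[rec] <- i; temp[rec] <- Ti
        curv[rec] <- cur$obj; bestv[rec] <- best$objective
        kindv[rec] <- prop$kind
      }
      i <- i + 1L
    }
    keep <- seq_len(rec)
    traces[[r]] <- data.frame(restart = r, iteration = it[keep],
                              temperature = temp[keep], kind = kindv[keep],
                              current = curv[keep], best = bestv[keep])
  }
  best$trace <- do.call(rbind, traces)
  best
}
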