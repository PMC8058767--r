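#' Construct a Dollo-k phylogeny
#'
#' A `dollo_tree` is a rooted mutation tree under the restricted Dollo
#' model: every mutation is gained exactly once (one GAIN node per
#' mutation), lost at most `k` times (up to `k` LOSS nodes per mutation,
#' each a strict descendant of the mutation's gain), with at most `d` LOSS
#' nodes in total.  `k = 0` gives a perfect phylogeny, `k = 1` a persistent
#' phylogeny.  Nodes are integer ids `1..N`; node 1 is the unlabeled root
#' (germline, all-zero genotype).
#'
#' @param parent integer vector: `parent[i]` is the parent id of node `i`,
#'   `NA` for the root (node 1).
#' @param kind character vector: `"root"`, `"gain"` or `"loss"` per node.
#' @param mutation integer vector: the mutation index carried by each gain
#'   or loss node, `NA` for the root.
#' @param m number of mutations.
#' @param k maximum losses per mutation.
#' @param d maximum total losses.
#' @param mutation_labels optional character vector of mutation names.
#' @param check if `TRUE` (default) the invariants are verified and a
#'   violation raises an error.
#' @return an object of class `dollo_tree`.
#' @examples
#' # root -> gain(1) -> gain(2) -> loss(1)
#' tr <- dollo_tree(parent = c(NA, 1, 2, 3),
#'                  kind = c("root", "gain", "gain", "loss"),
#'                  mutation = c(NA, 1, 2, 1), m = 2, k = 1, d = 1)
#' genotype_profile(tr, 4)   # mutation 1 gained then lost: c(0, 1)
#' @export
dollo_tree <- function(parent, kind, mutation, m, k = 1L, d = 0L,
                       mutation_labels = NULL, check = TRUE) {
  tr <- structure(list(parent = as.integer(parent),
                       kind = as.character(kind),
                       mutation = as.integer(mutation),
                       m = as.integer(m), k = as.integer(k), d = as.integer(d),
                       mutation_labels = mutation_labels %||%
                         paste0("mut", seq_len(m))),
                  class = "dollo_tree")
  if (check) {
    v <- validate_dollo(tr)
    if (!v$ok)
      stop("invalid Dollo tree: ",
           paste(unique(v$violations$rule), collapse = ", "))
  }
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

n_nodes <- function(tree) length(tree$parent)

#' List children of every node
#' @param tree a [dollo_tree()].
#' @return list of integer vectors, entry `i` holding the children of node `i`.
#' @keywords internal
#' @export
tree_children <- function(tree) {
  N <- n_nodes(tree)
  kids <- vector("list", N)
  for (i in seq_len(N)[-1L]) kids[[tree$parent[i]]] <- c(kids[[tree$parent[i]]], i)
  kids
}

# strict-ancestor matrix: anc[u, v] TRUE iff u is a strict ancestor of v;
# climbs all parent pointers in lock-step (at most tree-depth sweeps)
ancestor_matrix <- function(tree) {
  N <- n_nodes(tree)
  anc <- matrix(FALSE, N, N)
  v <- seq_len(N)
  cur <- tree$parent
  steps <- 0L
  repeat {
    ok <- !is.na(cur)
    if (!any(ok)) break
    anc[cbind(cur[ok], v[ok])] <- TRUE
    cur[ok] <- tree$parent[cur[ok]]
    steps <- steps + 1L
    if (steps > N) stop("cycle detected in parent vector")
  }
  anc
}

# ids on the path root -> node, inclusive
root_path <- function(tree, node) {
  path <- node
  p <- tree$parent[node]
  while (!is.na(p)) {
    path <- c(p, path)
    p <- tree$parent[p]
    if (length(path) > n_nodes(tree)) stop("cycle detected in parent vector")
  }
  path
}

subtree_nodes <- function(tree, node) {
  kids <- tree_children(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    x <- stack[[1L]]; stack <- stack[-1L]
    out <- c(out, x)
    stack <- c(stack, kids[[x]])
  }
  out
}

#' Genotype profile of a tree node
#'
#' The genotype profile of node `v` is the binary vector over mutations with
#' a 1 exactly for the mutations gained but not lost on the path from the
#' root to `v`.  A cell attached at `v` is expected to carry this genotype.
#'
#' @param tree a [dollo_tree()].
#' @param node a node id.
#' @return integer 0/1 vector of length `m`, named by mutation labels.
#' @export
genotype_profile <- function(tree, node) {
  if (!(node %in% seq_len(n_nodes(tree))))
    stop("node ", node, " is not in the tree")
  prof <- integer(tree$m)
  for (x in root_path(tree, node)) {
    if (tree$kind[x] == "gain") prof[tree$mutation[x]] <- 1L
    else if (tree$kind[x] == "loss") prof[tree$mutation[x]] <- 0L
  }
  names(prof) <- tree$mutation_labels
  prof
}

#' Genotype profiles of all nodes
#'
#' @param tree a [dollo_tree()].
#' @return integer N x m matrix; row `v` is [genotype_profile()] of node `v`.
#' @export
genotype_profiles <- function(tree) {
  N <- n_nodes(tree)
  P <- matrix(0L, N, tree$m, dimnames = list(NULL, tree$mutation_labels))
  kids <- tree_children(tree)
  stack <- 1L
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    p <- tree$parent[v]
    if (!is.na(p)) {
      P[v, ] <- P[p, ]
      if (tree$kind[v] == "gain") P[v, tree$mutation[v]] <- 1L
      else if (tree$kind[v] == "loss") P[v, tree$mutation[v]] <- 0L
    }
    stack <- c(stack, kids[[v]])
  }
  P
}

#' Per-mutation loss counts
#'
#' @param tree a [dollo_tree()].
#' @return integer vector `c` of length `m`: `c[j]` is the number of LOSS
#'   nodes carrying mutation `j`.
#' @export
loss_counts <- function(tree) {
  tabulate(tree$mutation[tree$kind == "loss"], nbins = tree$m)
}

#' Check Dollo-k validity
#'
#' Verifies the model invariants: a single root with no parent and a
#' connected acyclic parent structure; exactly one gain node per mutation;
#' every loss node a strict descendant of its mutation's gain
#' (rule `"loss-below-gain"`); at most `k` losses per mutation (rule
#' `"per-mutation-bound"`); at most `d` losses in total (rule
#' `"total-bound"`).
#'
#' @param tree a [dollo_tree()].
#' @return list with `ok` (logical) and `violations`, a data frame with
#'   columns `rule` and `node` (0 for tree-level violations).
#' @export
validate_dollo <- function(tree) {
  bad <- function(rule, node = 0L) data.frame(rule = rule, node = node)
  v <- list()
  N <- n_nodes(tree)
  if (length(tree$kind) != N || length(tree$mutation) != N)
    return(list(ok = FALSE, violations = bad("field-lengths")))
  roots <- which(is.na(tree$parent))
  if (!identical(roots, 1L) || tree$kind[1L] != "root")
    v <- c(v, list(bad("single-root")))
  if (any(!is.na(tree$parent) & (tree$parent < 1L | tree$parent > N)))
    v <- c(v, list(bad("parent-range")))
  # reachability from the root (also catches cycles)
  ok_struct <- !length(v)
  if (ok_struct) {
    seen <- rep(FALSE, N)
    reach <- tryCatch({
      for (x in seq_len(N)) root_path(tree, x)
      TRUE
    }, error = function(e) FALSE)
    if (!reach) {
      v <- c(v, list(bad("cycle")))
      ok_struct <- FALSE
    }
  }
  gains <- which(tree$kind == "gain")
  if (length(gains) != tree$m ||
      !setequal(tree$mutation[gains], seq_len(tree$m)) ||
      anyDuplicated(tree$mutation[gains]))
    v <- c(v, list(bad("one-gain-per-mutation")))
  if (ok_struct) {
    anc <- ancestor_matrix(tree)
    gain_of <- integer(tree$m)
    gain_of[tree$mutation[gains]] <- gains
    for (u in which(tree$kind == "loss")) {
      g <- if (tree$mutation[u] >= 1L && tree$mutation[u] <= tree$m)
        gain_of[tree$mutation[u]] else 0L
      if (g == 0L || !anc[g, u]) v <- c(v, list(bad("loss-below-gain", u)))
    }
  }
  cj <- loss_counts(tree)
  if (any(cj > tree$k))
    v <- c(v, list(bad("per-mutation-bound", which(cj > tree$k)[1L])))
  if (sum(cj) > tree$d) v <- c(v, list(bad("total-bound")))
  violations <- if (length(v)) do.call(rbind, v)
  else data.frame(rule = character(0), node = integer(0))
  list(ok = nrow(violations) == 0L, violations = violations)
}

#' Random gain-only starting tree
#'
#' Draws a valid Dollo tree with exactly one gain node per mutation and no
#' losses: gains are placed one at a time (in shuffled mutation order), each
#' attached uniformly at random to one of the previously placed nodes.
#' Used as the starting state of the annealing search; losses only enter
#' through the add-deletion move.
#'
#' @param m number of mutations.
#' @param k,d Dollo bounds carried by the tree (no losses are planted).
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @param mutation_labels optional mutation names.
#' @return a valid [dollo_tree()] with `m + 1` nodes.
#' @export
random_init <- function(m, k = 1L, d = 0L, seed = NULL, mutation_labels = NULL) {
  if (m < 1L) stop("m must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  ord <- sample.int(m)
  parent <- NA_integer_
  for (i in seq_len(m)) {
    parent <- c(parent, sample.int(i, 1L))  # uniform over nodes placed so far
  }
  mutation <- c(NA_integer_, ord)
  dollo_tree(parent = parent,
             kind = c("root", rep("gain", m)),
             mutation = mutation, m = m, k = k, d = d,
             mutation_labels = mutation_labels, check = FALSE)
}

#' @export
print.dollo_tree <- function(x, ...) {
  cj <- loss_counts(x)
  cat("Dollo-", x$k, " phylogeny: ", x$m, " mutations, ",
      n_nodes(x), " nodes, ", sum(cj), " loss(es) (d = ", x$d, ")\n", sep = "")
  invisible(x)
}

#' @export
format.dollo_tree <- function(x, ...) {
  lab <- node_labels(x)
  paste0(seq_along(lab), ":", lab, "<-",
         ifelse(is.na(x$parent), "*", x$parent), collapse = " ")
}

# display label per node: mutation name, with a minus suffix for losses
node_labels <- function(tree) {
  lab <- character(n_nodes(tree))
  lab[tree$kind == "root"] <- "germline"
  g <- tree$kind == "gain"
  lab[g] <- tree$mutation_labels[tree$mutation[g]]
  l <- tree$kind == "loss"
  lab[l] <- paste0(tree$mutation_labels[tree$mutation[l]], "-")
  lab
}
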