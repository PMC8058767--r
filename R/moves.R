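#' Neighbourhood operations on Dollo trees
#'
#' Four operations define the neighbourhood explored by the annealing
#' search: subtree prune-and-reattach ([spr()]), insertion of a mutation
#' loss ([add_deletion()]), removal of a loss node ([remove_deletion()])
#' and exchange of two gain labels ([swap_labels()]).  Every operation
#' returns a tree that again satisfies the Dollo-k invariants: losses that
#' a move strands away from their gain are repaired by removal.
#'
#' @name dollo_moves
NULL

# drop every loss node whose gain is no longer a strict ancestor
repair_losses <- function(tree) {
  repeat {
    anc <- ancestor_matrix(tree)
    gains <- which(tree$kind == "gain")
    gain_of <- integer(tree$m)
    gain_of[tree$mutation[gains]] <- gains
    losses <- which(tree$kind == "loss")
    bad <- losses[!vapply(losses, function(u) anc[gain_of[tree$mutation[u]], u],
                          logical(1))]
    if (!length(bad)) return(tree)
    tree <- drop_node(tree, bad[1L])
  }
}

# remove one node, reparenting its children; remaining ids are compacted
drop_node <- function(tree, u) {
  p <- tree$parent[u]
  if (is.na(p)) stop("cannot remove the root")
  tree$parent[tree$parent == u & !is.na(tree$parent)] <- p
  keep <- setdiff(seq_len(n_nodes(tree)), u)
  remap <- integer(n_nodes(tree))
  remap[keep] <- seq_along(keep)
  tree$parent <- ifelse(is.na(tree$parent[keep]), NA_integer_,
                        remap[tree$parent[keep]])
  tree$kind <- tree$kind[keep]
  tree$mutation <- tree$mutation[keep]
  tree
}

#' @rdname dollo_moves
#' @param tree a valid [dollo_tree()].
#' @param u,v node ids (see each operation's constraints).
#' @return a valid [dollo_tree()].
#' @details `spr(tree, u, v)` prunes the subtree rooted at `u` and
#'   reattaches it as a new child of `v`.  Neither node may be the root,
#'   `v` may not lie inside the pruned subtree (that would disconnect the
#'   tree), and `v` may not already be `u`'s parent.  Reattachment to an
#'   ancestor of `u` is allowed: forbidding it would make chain topologies
#'   absorbing states of the search (a chain admits no SPR between
#'   incomparable nodes), destroying the ergodicity of the neighbourhood.
#' @export
spr <- function(tree, u, v) {
  if (u == v) stop("spr: u and v must differ")
  if (is.na(tree$parent[u]) || is.na(tree$parent[v]))
    stop("spr: operands must not be the root")
  if (tree$parent[u] == v) stop("spr: v is already the parent of u")
  anc <- ancestor_matrix(tree)
  if (anc[u, v])
    stop("spr: v lies inside the pruned subtree")
  tree$parent[u] <- as.integer(v)
  repair_losses(tree)
}

#' @rdname dollo_moves
#' @param mutation mutation index to lose (its gain node must be a strict
#'   ancestor of `u`).
#' @details `add_deletion(tree, u, mutation)` splices a new loss node for
#'   `mutation` between `u` and its parent.  The move is refused (error of
#'   class `"dollo_move_rejected"`) if the mutation already has `k` losses,
#'   the tree already has `d` losses, or another loss of the same mutation
#'   lies on the root-path of `u` or inside `u`'s subtree.
#' @export
add_deletion <- function(tree, u, mutation) {
  reject <- function(msg)
    stop(structure(class = c("dollo_move_rejected", "error", "condition"),
                   list(message = msg, call = sys.call(-1L))))
  if (is.na(tree$parent[u])) reject("cannot splice a loss above the root")
  cj <- loss_counts(tree)
  if (sum(cj) >= tree$d) reject("total loss bound d reached")
  if (cj[mutation] >= tree$k) reject("per-mutation loss bound k reached")
  gain <- which(tree$kind == "gain" & tree$mutation == mutation)
  path <- root_path(tree, u)
  if (!(gain %in% path) || gain == u)
    reject("mutation's gain is not a strict ancestor of u")
  affected <- c(path, subtree_nodes(tree, u))
  if (any(tree$kind[affected] == "loss" & tree$mutation[affected] == mutation))
    reject("mutation already lost on the root-path or in the subtree of u")
  new <- n_nodes(tree) + 1L
  tree$parent <- c(tree$parent, tree$parent[u])
  tree$parent[u] <- new
  tree$kind <- c(tree$kind, "loss")
  tree$mutation <- c(tree$mutation, as.integer(mutation))
  tree
}

#' @rdname dollo_moves
#' @details `remove_deletion(tree, u)` deletes the loss node `u`; its
#'   children become children of `u`'s former parent.  Node ids above `u`
#'   shift down by one.
#' @export
remove_deletion <- function(tree, u) {
  if (tree$kind[u] != "loss") stop("remove_deletion: node ", u, " is not a loss")
  drop_node(tree, u)
}

#' @rdname dollo_moves
#' @details `swap_labels(tree, u, v)` exchanges the mutations carried by two
#'   gain nodes; losses stranded above their (relocated) gain are removed.
#' @export
swap_labels <- function(tree, u, v) {
  if (u == v) stop("swap_labels: u and v must differ")
  if (tree$kind[u] != "gain" || tree$kind[v] != "gain")
    stop("swap_labels: both operands must be gain nodes")
  tmp <- tree$mutation[u]
  tree$mutation[u] <- tree$mutation[v]
  tree$mutation[v] <- tmp
  repair_losses(tree)
}

#' Draw one random neighbourhood move
#'
#' Samples one valid operation uniformly and applies it.  With
#' `sampling = "instances"` (default) the draw is uniform over all valid
#' operation instances pooled across the four kinds, so kinds with more
#' instances (typically SPR) are proposed proportionally more often.  With
#' `sampling = "kinds"` a kind with at least one valid instance is drawn
#' uniformly first, then an instance uniformly within it.  Sampling uses
#' the current RNG stream, so a fixed seed gives a reproducible proposal
#' sequence.
#'
#' @param tree a valid [dollo_tree()].
#' @param sampling `"instances"` or `"kinds"`.
#' @return list with `kind` (one of `"spr"`, `"add_deletion"`,
#'   `"remove_deletion"`, `"swap_labels"`), `operands` (integer vector) and
#'   `tree` (the resulting valid [dollo_tree()]).
#' @export
propose_move <- function(tree, sampling = c("instances", "kinds")) {
  sampling <- match.arg(sampling)
  N <- n_nodes(tree)
  anc <- ancestor_matrix(tree)
  gains <- which(tree$kind == "gain")
  losses <- which(tree$kind == "loss")
  cj <- loss_counts(tree)

  # SPR instances: non-root (u, v) with v outside u's subtree, v != rho(u)
  spr_ok <- !anc                      # anc[u, v]: v inside u's subtree
  spr_ok[1L, ] <- FALSE; spr_ok[, 1L] <- FALSE
  diag(spr_ok) <- FALSE
  spr_ok[cbind(seq_len(N)[-1L], tree$parent[-1L])] <- FALSE
  spr_idx <- which(spr_ok)

  # add-deletion instances: (u, mutation) with the gain strictly above u
  add_idx <- NULL
  if (sum(cj) < tree$d && any(cj < tree$k)) {
    cand <- list()
    for (mut in which(cj < tree$k)) {
      g <- gains[tree$mutation[gains] == mut]
      below <- which(anc[g, ])          # strict descendants of the gain
      if (!length(below)) next
      # exclude u whose root-path or subtree already holds a loss of mut
      mut_losses <- losses[tree$mutation[losses] == mut]
      if (length(mut_losses)) {
        blocked <- unique(unlist(lapply(mut_losses, function(l)
          c(which(anc[l, ]), l, which(anc[, l])))))
        below <- setdiff(below, blocked)
      }
      if (length(below)) cand[[length(cand) + 1L]] <- cbind(below, mut)
    }
    if (length(cand)) add_idx <- do.call(rbind, cand)
  }

  kinds <- c("spr", "add_deletion", "remove_deletion", "swap_labels")
  counts <- c(length(spr_idx),
              if (is.null(add_idx)) 0L else nrow(add_idx),
              length(losses),
              if (length(gains) >= 2L) choose(length(gains), 2L) else 0L)
  if (all(counts == 0L)) stop("no valid move exists for this tree")
  kind <- if (sampling == "instances") {
    sample(kinds, 1L, prob = counts)
  } else {
    sample(kinds[counts > 0L], 1L)
  }
  switch(kind,
    spr = {
      i <- spr_idx[[sample.int(length(spr_idx), 1L)]]
      u <- (i - 1L) %% N + 1L          # row = u (moved subtree)
      v <- (i - 1L) %/% N + 1L         # col = v (new parent)
      list(kind = kind, operands = c(u, v), tree = spr(tree, u, v))
    },
    add_deletion = {
      r <- add_idx[sample.int(nrow(add_idx), 1L), ]
      list(kind = kind, operands = r,
           tree = add_deletion(tree, r[[1L]], r[[2L]]))
    },
    remove_deletion = {
      u <- losses[sample.int(length(losses), 1L)]
      list(kind = kind, operands = u, tree = remove_deletion(tree, u))
    },
    swap_labels = {
      p <- sort(gains[sample.int(length(gains), 2L)])  # uniform unordered pair
      list(kind = kind, operands = p,
           tree = swap_labels(tree, p[1L], p[2L]))
    })
}
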