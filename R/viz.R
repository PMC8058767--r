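#' Display tree for post-processing
#'
#' A `dollo_display` is a presentation-layer copy of a fitted tree: each
#' display node carries a list of labels (gains by mutation name, losses
#' with a `-` suffix) and a count of attached cells.  Collapsing operations
#' merge display nodes but never alter the underlying inferred history.
#'
#' @param tree a [dollo_tree()].
#' @param attachment optional [best_attachment()] result; cell counts are 0
#'   without it.
#' @return an object of class `dollo_display`: list with `parent` (integer
#'   vector, `NA` for the root), `labels` (list of character vectors),
#'   `loss` (list of logical vectors marking which labels are losses) and
#'   `cells` (integer vector).
#' @export
display_tree <- function(tree, attachment = NULL) {
  N <- n_nodes(tree)
  cells <- integer(N)
  if (!is.null(attachment)) {
    t <- table(attachment$sigma)
    cells[as.integer(names(t))] <- as.integer(t)
  }
  lab <- node_labels(tree)
  structure(list(parent = tree$parent,
                 labels = as.list(lab),
                 loss = as.list(tree$kind == "loss"),
                 cells = cells),
            class = "dollo_display")
}

#' @export
print.dollo_display <- function(x, ...) {
  cat("Display tree:", length(x$parent), "nodes,", sum(x$cells),
      "attached cells\n")
  invisible(x)
}

display_children <- function(dt) {
  N <- length(dt$parent)
  kids <- vector("list", N)
  for (i in seq_len(N)) {
    p <- dt$parent[i]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
  }
  kids
}

display_depths <- function(dt) {
  depth <- integer(length(dt$parent))
  for (i in seq_along(dt$parent)) {
    p <- dt$parent[i]; d <- 0L
    while (!is.na(p)) { d <- d + 1L; p <- dt$parent[p] }
    depth[i] <- d
  }
  depth
}

# merge node `child` into node `into` (into must be child's parent or vice
# versa caller-arranged); labels of `into` come first
merge_display_nodes <- function(dt, into, child) {
  dt$labels[[into]] <- c(dt$labels[[into]], dt$labels[[child]])
  dt$loss[[into]] <- c(dt$loss[[into]], dt$loss[[child]])
  dt$cells[into] <- dt$cells[into] + dt$cells[child]
  dt$parent[!is.na(dt$parent) & dt$parent == child] <- into
  keep <- setdiff(seq_along(dt$parent), child)
  remap <- integer(length(dt$parent)); remap[keep] <- seq_along(keep)
  dt$parent <- ifelse(is.na(dt$parent[keep]), NA_integer_, remap[dt$parent[keep]])
  dt$labels <- dt$labels[keep]
  dt$loss <- dt$loss[keep]
  dt$cells <- dt$cells[keep]
  dt
}

#' Support of a display node
#'
#' The support of node `i` is the number of cells in `i`'s subtree divided
#' by the number of cells in its parent's subtree excluding those attached
#' to the parent itself — the fraction of informative cells below the
#' parent that fall on `i`'s side.  It always lies in `[0, 1]`.  When the
#' denominator is 0 (no informative cells) the support is defined as 1, so
#' uninformative structure is never collapsed.
#'
#' @param dt a [display_tree()].
#' @param node a display-node id with a parent.
#' @return a number in `[0, 1]`.
#' @export
node_support <- function(dt, node) {
  p <- dt$parent[node]
  if (is.na(p)) stop("the root has no support (no parent)")
  kids <- display_children(dt)
  sub_cells <- function(v) {
    tot <- 0L; stack <- v
    while (length(stack)) {
      x <- stack[[1L]]; stack <- stack[-1L]
      tot <- tot + dt$cells[x]
      stack <- c(stack, kids[[x]])
    }
    tot
  }
  den <- sub_cells(p) - dt$cells[p]
  if (den <= 0L) return(1)
  sub_cells(node) / den
}

#' Collapse simple (non-branching) paths
#'
#' Merges every non-root node that has exactly one child with that child,
#' repeatedly, so chains of single-child nodes become one display node
#' listing all their mutations.  Purely presentational; idempotent.
#'
#' @param dt a [display_tree()].
#' @return a [display_tree()].
#' @export
collapse_simple_paths <- function(dt) {
  repeat {
    kids <- display_children(dt)
    unary <- which(lengths(kids) == 1L & !is.na(dt$parent))
    if (!length(unary)) return(dt)
    u <- unary[1L]
    dt <- merge_display_nodes(dt, u, kids[[u]][1L])
  }
}

#' Collapse low-support nodes
#'
#' Repeatedly merges into its parent any node whose [node_support()] falls
#' below `threshold`, deepest node first, recomputing supports after every
#' merge, until no node is below the threshold.  A threshold of 0.05
#' hides branches carried by fewer than 5\% of the informative cells.
#'
#' @param dt a [display_tree()].
#' @param threshold support threshold in `[0, 1]`.
#' @return a [display_tree()].
#' @export
collapse_low_support <- function(dt, threshold) {
  repeat {
    cand <- which(!is.na(dt$parent))
    if (!length(cand)) return(dt)
    sup <- vapply(cand, function(v) node_support(dt, v), numeric(1))
    low <- cand[sup < threshold]
    if (!length(low)) return(dt)
    depth <- display_depths(dt)
    u <- low[order(-depth[low], low)][1L]
    dt <- merge_display_nodes(dt, dt$parent[u], u)
  }
}
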