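#' Write a tree as a Graphviz DOT digraph
#'
#' Emits one DOT node per tree node — gains labeled by mutation name, losses
#' by the name with a `-` suffix, filled red — and one edge per parent-child
#' link.  Machine-readable `kind` and `mutation` attributes are included so
#' the file round-trips through [read_dot()].  With an attachment, node
#' labels are annotated with the number of attached cells.
#'
#' @param tree a [dollo_tree()] or [display_tree()].
#' @param path output file path.
#' @param attachment optional [best_attachment()] result (`dollo_tree`
#'   method only).
#' @param ... unused.
#' @return `path`, invisibly.
#' @export
write_dot <- function(tree, path, ...) UseMethod("write_dot")

dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' @rdname write_dot
#' @export
write_dot.dollo_tree <- function(tree, path, attachment = NULL, ...) {
  N <- n_nodes(tree)
  cells <- integer(N)
  if (!is.null(attachment)) {
    t <- table(attachment$sigma)
    cells[as.integer(names(t))] <- as.integer(t)
  }
  lab <- node_labels(tree)
  if (!is.null(attachment))
    lab <- ifelse(cells > 0L, paste0(lab, " (", cells, " cells)"), lab)
  attrs <- sprintf('label=%s kind="%s" mutation="%s"%s',
                   dot_quote(lab), tree$kind,
                   ifelse(is.na(tree$mutation), "",
                          tree$mutation_labels[tree$mutation]),
                   ifelse(tree$kind == "loss",
                          ' color=indianred1 style=filled', ''))
  nodes <- sprintf("  n%d [%s];", seq_len(N), attrs)
  ev <- which(!is.na(tree$parent))
  edges <- sprintf("  n%d -> n%d;", tree$parent[ev], ev)
  writeLines(c("digraph dollo_tree {", "  node [shape=box];", nodes, edges, "}"),
             path)
  invisible(path)
}

#' @rdname write_dot
#' @export
write_dot.dollo_display <- function(tree, path, ...) {
  dt <- tree
  N <- length(dt$parent)
  lab <- vapply(seq_len(N), function(i) {
    l <- dt$labels[[i]]
    paste0(paste(l, collapse = ", "),
           if (dt$cells[i] > 0L) paste0(" (", dt$cells[i], " cells)") else "")
  }, character(1))
  any_loss <- vapply(dt$loss, any, logical(1))
  attrs <- sprintf('label=%s%s', dot_quote(lab),
                   ifelse(any_loss, ' color=indianred1 style=filled', ''))
  nodes <- sprintf("  n%d [%s];", seq_len(N), attrs)
  ev <- which(!is.na(dt$parent))
  edges <- sprintf("  n%d -> n%d;", dt$parent[ev], ev)
  writeLines(c("digraph dollo_display {", "  node [shape=box];", nodes, edges, "}"),
             path)
  invisible(path)
}

#' Read a tree written by [write_dot()]
#'
#' Parses the restricted DOT dialect emitted by the `dollo_tree` method of
#' [write_dot()] (one node statement per line with `kind` and `mutation`
#' attributes, one edge statement per line) back into a [dollo_tree()].
#'
#' @param path path to a DOT file produced by [write_dot()].
#' @param k,d Dollo bounds to stamp on the reconstructed tree; defaults are
#'   the loss counts observed in the file.
#' @return a [dollo_tree()].
#' @export
read_dot <- function(path, k = NULL, d = NULL) {
  lines <- readLines(path)
  node_re <- "^\\s*n(\\d+)\\s*\\[.*kind=\"(root|gain|loss)\" mutation=\"([^\"]*)\""
  edge_re <- "^\\s*n(\\d+)\\s*->\\s*n(\\d+)\\s*;"
  nl <- regmatches(lines, regexec(node_re, lines))
  nl <- nl[lengths(nl) == 4L]
  if (!length(nl)) stop("no parsable node statements in ", path)
  ids <- as.integer(vapply(nl, `[`, character(1), 2L))
  kind <- vapply(nl, `[`, character(1), 3L)
  mut_name <- vapply(nl, `[`, character(1), 4L)
  o <- order(ids)
  ids <- ids[o]; kind <- kind[o]; mut_name <- mut_name[o]
  if (!identical(ids, seq_along(ids))) stop("node ids in ", path, " are not 1..N")
  labels <- unique(mut_name[kind == "gain"])
  mutation <- ifelse(kind == "root", NA_integer_, match(mut_name, labels))
  el <- regmatches(lines, regexec(edge_re, lines))
  el <- el[lengths(el) == 3L]
  parent <- rep(NA_integer_, length(ids))
  for (e in el) parent[as.integer(e[3L])] <- as.integer(e[2L])
  tr <- dollo_tree(parent = parent, kind = kind, mutation = mutation,
                   m = length(labels), k = k %||% max(1L, max(c(0L, table(
                     mutation[kind == "loss"])))),
                   d = d %||% sum(kind == "loss"),
                   mutation_labels = labels, check = FALSE)
  v <- validate_dollo(tr)
  if (!v$ok) stop("tree read from ", path, " is not a valid Dollo tree: ",
                  paste(unique(v$violations$rule), collapse = ", "))
  tr
}
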