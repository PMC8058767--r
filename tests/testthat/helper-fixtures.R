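# Shared fixtures and independent oracles used across the test files.

# The worked-example Dollo-1 tree over mutations a..g: a is gained at the
# root of the drawn tree and lost on the path leading to the node that has
# accumulated {b, d, f}; losses of b and d sit further down that branch,
# and c -> e -> g forms the sibling branch.
fig1_tree <- function() {
  #  1 germline
  #  2 gain a      (child of 1)
  #  3 gain b      (child of 2)
  #  4 gain c      (child of 2)
  #  5 loss a      (child of 3)
  #  6 gain d      (child of 5)
  #  7 gain f      (child of 6)   <- state {b, d, f}
  #  8 gain e      (child of 4)
  #  9 gain g      (child of 8)
  # 10 loss b      (child of 7)
  # 11 loss d      (child of 7)
  dollo_tree(
    parent   = c(NA, 1, 2, 2, 3, 5, 6, 4, 8, 7, 7),
    kind     = c("root", "gain", "gain", "gain", "loss", "gain", "gain",
                 "gain", "gain", "loss", "loss"),
    mutation = c(NA, 1, 2, 3, 1, 4, 6, 5, 7, 2, 4),
    m = 7, k = 1, d = 3,
    mutation_labels = letters[1:7])
}

# independent genotype-profile oracle: literal walk along the root path,
# recording the last gain/loss event per mutation
oracle_profile <- function(tree, node) {
  prof <- integer(tree$m)
  path <- node
  while (!is.na(tree$parent[path[1L]])) path <- c(tree$parent[path[1L]], path)
  for (x in path) {
    if (tree$kind[x] == "gain") prof[tree$mutation[x]] <- 1L
    if (tree$kind[x] == "loss") prof[tree$mutation[x]] <- 0L
  }
  prof
}

# independent attachment oracle: exhaustive scalar maximization over nodes
oracle_attach_cell <- function(tree, row, rates) {
  best_v <- NA_integer_; best_ll <- -Inf
  for (v in seq_along(tree$parent)) {
    prof <- oracle_profile(tree, v)
    ll <- 0
    for (j in seq_along(row))
      ll <- ll + entry_log_likelihood(row[j], prof[j], rates$alpha[j],
                                      rates$beta)
    if (ll > best_ll + 1e-12) { best_ll <- ll; best_v <- v }
  }
  list(node = best_v, loglik = best_ll)
}

# random valid Dollo tree: random gain tree plus random valid deletions
random_valid_tree <- function(m, k = 1L, d = 2L, n_loss_tries = 4L) {
  tree <- random_init(m, k = k, d = d)
  for (t in seq_len(n_loss_tries)) {
    anc <- dollosa:::ancestor_matrix(tree)
    gains <- which(tree$kind == "gain")
    mut <- tree$mutation[gains[sample.int(length(gains), 1L)]]
    g <- gains[tree$mutation[gains] == mut]
    below <- which(anc[g, ])
    if (!length(below)) next
    u <- below[sample.int(length(below), 1L)]
    tree <- tryCatch(add_deletion(tree, u, mut),
                     dollo_move_rejected = function(e) tree,
                     error = function(e) tree)
  }
  tree
}

# enumerate every valid Dollo tree over m mutations with at most one loss
# in total (k = 1, d = 1), as parent-vector configurations
enumerate_dollo_trees <- function(m, mutation_labels = paste0("mut", 1:m)) {
  trees <- list()
  push <- function(tr) trees[[length(trees) + 1L]] <<- tr
  # gain-only trees: nodes 1 (root), 2..m+1 (gain of mutation i-1)
  N <- m + 1L
  grids <- rep(list(seq_len(N)), m)
  combos <- as.matrix(expand.grid(grids))
  for (r in seq_len(nrow(combos))) {
    parent <- c(NA_integer_, combos[r, ])
    if (any(parent[-1L] == seq_len(N)[-1L])) next   # self-parent
    tr <- dollo_tree(parent, c("root", rep("gain", m)),
                     c(NA, 1:m), m = m, k = 1, d = 1,
                     mutation_labels = mutation_labels, check = FALSE)
    if (validate_dollo(tr)$ok) push(tr)
  }
  n_gain_only <- length(trees)
  # one loss of mutation v at node m+2
  N <- m + 2L
  grids <- rep(list(seq_len(N)), m + 1L)
  combos <- as.matrix(expand.grid(grids))
  for (v in 1:m) {
    for (r in seq_len(nrow(combos))) {
      parent <- c(NA_integer_, combos[r, ])
      if (any(parent[-1L] == seq_len(N)[-1L])) next
      tr <- dollo_tree(parent,
                       c("root", rep("gain", m), "loss"),
                       c(NA, 1:m, v), m = m, k = 1, d = 1,
                       mutation_labels = mutation_labels, check = FALSE)
      if (validate_dollo(tr)$ok) push(tr)
    }
  }
  attr(trees, "n_gain_only") <- n_gain_only
  trees
}

# brute-force three-gamete conflict oracle
oracle_conflicts <- function(I) {
  x <- unclass(I); m <- ncol(x); n <- 0L
  for (p in seq_len(m - 1L)) for (q in (p + 1L):m) {
    has <- c(FALSE, FALSE, FALSE)  # (1,0), (0,1), (1,1)
    for (i in seq_len(nrow(x))) {
      a <- x[i, p]; b <- x[i, q]
      if (is.na(a) || is.na(b)) next
      if (a == 1L && b == 0L) has[1L] <- TRUE
      if (a == 0L && b == 1L) has[2L] <- TRUE
      if (a == 1L && b == 1L) has[3L] <- TRUE
    }
    if (all(has)) n <- n + 1L
  }
  n
}
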