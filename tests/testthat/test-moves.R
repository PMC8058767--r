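test_that("spr relocates a subtree and repairs stranded losses", {
  # chain root -> a -> b -> c; move c under a
  tr <- dollo_tree(parent = c(NA, 1, 2, 3), kind = c("root", rep("gain", 3)),
                   mutation = c(NA, 1, 2, 3), m = 3, k = 1, d = 1)
  out <- spr(tr, 4, 2)
  expect_identical(out$parent[4], 2L)
  expect_true(validate_dollo(out)$ok)

  # moving a subtree containing a loss of b outside b's subtree removes it
  fig <- fig1_tree()   # node 5 = loss of a sits under gain b (node 3)
  loss_b <- which(fig$kind == "loss" & fig$mutation == 2)
  # move the {b,d,f} branch's loss-of-b node under gain c (node 4): gain b
  # no longer ancestral, so the loss must vanish
  out2 <- spr(fig, loss_b, 4)
  expect_true(validate_dollo(out2)$ok)
  expect_identical(loss_counts(out2)[2], 0L)

  expect_error(spr(tr, 2, 4), "pruned subtree")   # v inside subtree(u)
  expect_error(spr(tr, 1, 2), "root")
  expect_error(spr(tr, 3, 2), "already the parent")
})

test_that("add/remove deletion are inverse and enforce the k and d bounds", {
  tr <- dollo_tree(parent = c(NA, 1, 2), kind = c("root", "gain", "gain"),
                   mutation = c(NA, 1, 2), m = 2, k = 1, d = 1)
  withl <- add_deletion(tr, 3, 1)       # lose mutation 1 above gain 2
  expect_true(validate_dollo(withl)$ok)
  expect_identical(loss_counts(withl), c(1L, 0L))
  expect_identical(withl$kind[withl$parent[3]], "loss")

  # k bound: a second loss of mutation 1 is rejected (total bound d = 2)
  tr2 <- withl; tr2$d <- 2L
  expect_error(add_deletion(tr2, 3, 1), class = "dollo_move_rejected")
  # d bound: rejected regardless of k when the total is exhausted
  tr3 <- withl; tr3$k <- 5L
  expect_error(add_deletion(tr3, 3, 2), class = "dollo_move_rejected")
  # gain must be a strict ancestor
  expect_error(add_deletion(tr, 2, 2), class = "dollo_move_rejected")

  back <- remove_deletion(withl, which(withl$kind == "loss"))
  expect_identical(back$parent, tr$parent)
  expect_identical(back$mutation, tr$mutation)
  expect_error(remove_deletion(tr, 2), "not a loss")
})

test_that("removing a loss reparents all of its children", {
  tr <- dollo_tree(parent = c(NA, 1, 2, 3, 3, 3),
                   kind = c("root", "gain", "loss", "gain", "gain", "gain"),
                   mutation = c(NA, 1, 1, 2, 3, 4), m = 4, k = 1, d = 1)
  out <- remove_deletion(tr, 3)
  expect_true(validate_dollo(out)$ok)
  # former children of the loss now hang from the gain (old id 2)
  expect_identical(sum(out$parent == 2, na.rm = TRUE), 3L)
})

test_that("label swaps exchange mutations and drop invalidated losses", {
  fig <- fig1_tree()
  gain_of <- function(t, lab) which(t$kind == "gain" &
                                      t$mutation_labels[t$mutation] == lab)
  # swapping e and g (same branch, no losses involved) is a pure exchange
  out <- swap_labels(fig, gain_of(fig, "e"), gain_of(fig, "g"))
  expect_true(validate_dollo(out)$ok)
  expect_identical(length(out$parent), length(fig$parent))

  # swapping b (ancestor of loss b) with g strands the loss of b
  out2 <- swap_labels(fig, gain_of(fig, "b"), gain_of(fig, "g"))
  expect_true(validate_dollo(out2)$ok)
  expect_identical(loss_counts(out2)[2], 0L)
  expect_lt(length(out2$parent), length(fig$parent))

  expect_error(swap_labels(fig, 1, 2), "gain nodes")
})

test_that("every move preserves the gain set (one gain per mutation)", {
  set.seed(77)
  for (rep in 1:200) {
    tr <- random_valid_tree(sample(3:7, 1), k = 1, d = 2)
    out <- propose_move(tr)$tree
    expect_true(validate_dollo(out)$ok)
    expect_identical(sort(out$mutation[out$kind == "gain"]), 1:out$m)
  }
})

test_that("proposals are closed over validity on random trees", {
  set.seed(88)
  for (rep in 1:1000) {
    tr <- random_valid_tree(sample(2:8, 1), k = sample(1:2, 1), d = 3)
    expect_true(validate_dollo(propose_move(tr)$tree)$ok)
  }
})

test_that("infeasible kinds are never proposed and feasible ones all appear", {
  # gain-only tree with d = 0: no deletion move can ever fire
  tr0 <- random_init(4, k = 1, d = 0, seed = 9)
  set.seed(10)
  kinds0 <- replicate(300, propose_move(tr0)$kind)
  expect_false(any(kinds0 %in% c("add_deletion", "remove_deletion")))

  # a tree where all four kinds are feasible: one loss present, room for
  # more, several branches; under kind-uniform sampling each kind gets
  # about a quarter of the proposals
  tr1 <- dollo_tree(parent = c(NA, 1, 2, 3, 1, 5),
                    kind = c("root", "gain", "gain", "loss", "gain", "gain"),
                    mutation = c(NA, 1, 2, 1, 3, 4), m = 4, k = 1, d = 3)
  set.seed(11)
  kinds1 <- replicate(2000, propose_move(tr1, sampling = "kinds")$kind)
  feasible_kinds <- c("spr", "swap_labels", "add_deletion", "remove_deletion")
  expect_true(all(feasible_kinds %in% unique(kinds1)))
  expect_true(all(table(kinds1) > 2000 / 8))
  # instance-pooled sampling favours kinds with more instances: SPR and
  # label swaps dominate but both appear
  set.seed(12)
  kinds2 <- replicate(500, propose_move(tr1)$kind)
  expect_true(all(c("spr", "swap_labels") %in% kinds2))
  expect_gt(mean(kinds2 == "spr"), mean(kinds2 == "remove_deletion"))

  # a single-mutation perfect-phylogeny tree admits no move at all
  trd <- random_init(1, k = 0, d = 0, seed = 1)
  expect_error(propose_move(trd), "no valid move")
})

test_that("a fixed RNG state reproduces the proposal sequence", {
  tr <- random_valid_tree(5, k = 1, d = 2)
  set.seed(123)
  seq1 <- replicate(20, propose_move(tr)$kind)
  set.seed(123)
  seq2 <- replicate(20, propose_move(tr)$kind)
  expect_identical(seq1, seq2)
})

test_that("repeated proposals explore many topologies (reachability smoke)", {
  set.seed(202)
  tr <- random_init(4, k = 1, d = 1)
  seen <- character(0)
  for (i in 1:2000) {
    tr <- propose_move(tr)$tree
    # canonical topology signature over gain labels
    sig <- paste(vapply(seq_len(tr$m), function(mut) {
      g <- which(tr$kind == "gain" & tr$mutation == mut)
      paste(sort(tr$mutation[intersect(dollosa:::root_path(tr, g),
                                       which(tr$kind == "gain"))]),
            collapse = ".")
    }, character(1)), collapse = "|")
    seen <- union(seen, sig)
    if (length(seen) >= 50) break
  }
  expect_gte(length(seen), 50)
})
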