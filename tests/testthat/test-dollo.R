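test_that("hand-checkable columns score correctly", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_identical(dollo_char_steps(tr, c(A = "0", B = "0", C = "0",
                                          D = "0"))$steps, 0L)
  r <- dollo_char_steps(tr, c(A = "1", B = "1", C = "0", D = "0"))
  expect_identical(r$steps, 1L)
  expect_setequal(r$gain_clade, c("A", "B"))
  expect_length(r$loss_nodes, 0L)
  # presences spanning a deeper ancestor force losses
  tr5 <- ape::read.tree(text = "(O,((A,B),(C,D)));")
  r2 <- dollo_char_steps(tr5, c(A = "1", C = "1"))
  expect_identical(r2$steps, 3L)
  expect_setequal(r2$gain_clade, c("A", "B", "C", "D"))
  expect_setequal(unlist(r2$loss_clades), c("B", "D"))
})

test_that("a present leaf missing from the tree is an input error", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_error(dollo_char_steps(tr, c(A = "1", Z = "1")), "missing from tree")
})

test_that("engine equals exhaustive minimisation on all trees up to 6 leaves", {
  # every rooted binary shape x every binary column; the oracle enumerates all
  # internal-state assignments under the single-gain rule
  for (n in 4:6) {
    labels <- paste0("t", seq_len(n))
    trees <- all_rooted_phylos(labels)
    if (n == 6) trees <- trees[seq(1, length(trees), by = 7)]  # thin 945 -> 135
    cols <- as.matrix(expand.grid(rep(list(0:1), n)))
    for (phy in trees) {
      pt <- sinephylo:::phylo_to_ptree(phy)
      got <- sinephylo:::dollo_steps_cpp(pt$parent, pt$root, pt$n_tip, t(cols))
      want <- apply(cols, 1L, function(cl)
        oracle_dollo_steps(pt$parent, pt$root, pt$n_tip, as.integer(cl)))
      expect_identical(as.integer(got), as.integer(want))
    }
  }
})

test_that("engine equals the oracle with unknown leaves too", {
  labels <- paste0("t", 1:5)
  trees <- all_rooted_phylos(labels)
  cols <- as.matrix(expand.grid(rep(list(0:2), 5)))
  for (phy in trees[seq(1, length(trees), by = 5)]) {
    pt <- sinephylo:::phylo_to_ptree(phy)
    got <- sinephylo:::dollo_steps_cpp(pt$parent, pt$root, pt$n_tip, t(cols))
    want <- apply(cols, 1L, function(cl)
      oracle_dollo_steps(pt$parent, pt$root, pt$n_tip, as.integer(cl)))
    expect_identical(as.integer(got), as.integer(want))
  }
})

test_that("R reconstruction and C++ scorer agree on random inputs", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:9, 1L)
    phy <- ape::rtree(n, rooted = TRUE)
    phy$tip.label <- paste0("t", seq_len(n))
    m <- random_matrix(n, 20, p_unknown = 0.15, seed = seed)
    rec <- reconstruct(phy, m)
    ts <- tree_length(phy, m)
    expect_identical(rec$table$steps, unname(ts$per_locus))
    # steps decompose as one gain plus the recorded losses
    has_gain <- !is.na(rec$table$gain_node) & rec$table$steps > 0L
    expect_identical(rec$table$steps[has_gain],
                     1L + rec$table$n_losses[has_gain])
  }
})

test_that("adding a loss-requiring taxon never decreases steps", {
  tr4 <- ape::read.tree(text = "((A,B),(C,D));")
  tr5 <- ape::read.tree(text = "(((A,E),B),(C,D));")  # E splits the A+B clade
  base <- dollo_char_steps(tr4, c(A = "1", B = "1"))$steps
  more <- dollo_char_steps(tr5, c(A = "1", B = "1", E = "0"))$steps
  expect_gte(more, base)
})

test_that("unknowns resolve without increasing steps, ties to absent", {
  tr <- ape::read.tree(text = "(O,((A,B),(C,D)));")
  # unknown strictly inside a forced gain clade resolves present: making B
  # absent would cost an extra loss
  r <- dollo_char_steps(tr, c(A = "1", B = "?", C = "1", D = "0", O = "0"))
  expect_identical(r$steps, 2L)
  expect_identical(unname(r$resolved_states["B"]), 1L)
  # unknown outside the gain clade resolves absent
  r2 <- dollo_char_steps(tr, c(A = "1", B = "1", C = "?", D = "0", O = "0"))
  expect_identical(r2$steps, 1L)
  expect_identical(unname(r2$resolved_states["C"]), 0L)
  # a tie (gain on the pendant edge vs a larger clade) resolves to absent
  r3 <- dollo_char_steps(tr, c(A = "1", B = "?", C = "0", D = "0", O = "0"))
  expect_identical(r3$steps, 1L)
  expect_identical(unname(r3$resolved_states["B"]), 0L)
  expect_identical(r3$gain_clade, "A")
})

test_that("gains map to pendant edges for private insertions and to clades", {
  tr <- ape::read.tree(text = "(O,((A,B),(C,D)));")
  r <- dollo_char_steps(tr, c(C = "1"))
  expect_identical(r$gain_clade, "C")
  r2 <- dollo_char_steps(tr, c(C = "1", D = "1"))
  expect_setequal(r2$gain_clade, c("C", "D"))
  expect_length(r2$loss_nodes, 0L)
})

test_that("tree length sums per-character steps; fixture scores 95", {
  m0 <- character_matrix(matrix(character(0), 4, 0,
                                dimnames = list(paste0("t", 1:4), character(0))))
  tr <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  expect_identical(tree_length(tr, m0)$total_length, 0L)
  m1 <- character_matrix(matrix("1", 4, 1,
                                dimnames = list(paste0("t", 1:4), "l1")))
  expect_identical(tree_length(tr, m1)$total_length, 1L)
  m <- build_lemur_fixture()
  ts <- tree_length(lemur_reference_tree(), m)
  expect_identical(ts$total_length, 95L)
  expect_true(all(ts$per_locus == 1L))
})

test_that("closed-form per-character maximum matches the enumerator", {
  for (np in 0:4) for (na in 0:4) {
    if (np + na < 2L || np + na > 6L) next
    expect_identical(max_dollo_steps(np, na),
                     max_dollo_steps(np, na, method = "enumerate"),
                     info = paste(np, na))
  }
})

test_that("indices are exactly 1/0/1 on a homoplasy-free matrix", {
  m <- build_lemur_fixture()
  idx <- ensemble_indices(m, lemur_reference_tree())
  expect_identical(idx$CI, 1)
  expect_identical(idx$HI, 0)
  expect_identical(idx$RI, 1)
  # and on clean simulated matrices scored on their generating tree
  tr <- sim_study_tree()
  sim <- simulate_insertions(tr, rate = 4, outgroups = "OUT", seed = 11)
  idx2 <- ensemble_indices(sim$matrix, tr)
  expect_identical(idx2$CI, 1)
  expect_identical(idx2$RI, 1)
})

test_that("a conflicting informative column halves the consistency index", {
  # single informative column on a tree where its clade needs one loss
  tr <- ape::read.tree(text = "(((A,C),B),D);")
  m <- character_matrix(matrix(c("1", "1", "0", "0"), 4, 1,
                               dimnames = list(c("A", "B", "C", "D"), "l1")))
  idx <- ensemble_indices(m, tr)
  expect_identical(idx$CI, 0.5)
  expect_identical(idx$HI, 0.5)
  # brute force: among rooted 4-leaf trees, trees with {A,B} as a clade score
  # 1, and the minimum over the rest is 2
  lens <- vapply(all_rooted_phylos(c("A", "B", "C", "D")), function(phy) {
    oracle_dollo_steps_phylo(phy, c(A = "1", B = "1", C = "0", D = "0"))
  }, 0)
  expect_identical(min(lens[lens > 1]), 2)
})

test_that("RI is undefined when no character can show homoplasy", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  m <- character_matrix(matrix(c("1", "0", "0", "0"), 4, 1,
                               dimnames = list(c("A", "B", "C", "D"), "l1")))
  idx <- ensemble_indices(m, tr)
  expect_true(is.na(idx$RI))
  expect_identical(idx$CI, 1)
})

test_that("synapomorphy counts attribute clean loci to single edges", {
  tr <- sim_study_tree()
  sim <- simulate_insertions(tr, rate = 4, outgroups = "OUT", seed = 5)
  rec <- reconstruct(tr, sim$matrix)
  sc <- synapomorphy_counts(rec)
  expect_identical(sum(sc$count), n_loci(sim$matrix))
  expect_length(attr(sc, "ambiguous"), 0L)
  # counts equal the simulator's per-branch tallies
  for (i in seq_len(nrow(sc))) {
    node <- sc$node[i]
    expect_identical(sc$count[i],
                     unname(sim$truth$edge_counts[as.character(node)]))
  }
})
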