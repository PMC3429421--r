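test_that("a single informative column yields its clade at length 1", {
  states <- matrix("0", 5, 1, dimnames = list(c("A", "B", "C", "D", "O"), "l1"))
  states[c("A", "B"), 1] <- "1"
  m <- character_matrix(states, outgroups = "O")
  res <- search_mp_tree(m, search_config(seed = 1))
  expect_identical(res$length, 1L)
  expect_true("A|B" %in% clade_keys_of(res$trees[[1L]]))
})

test_that("search refuses degenerate inputs", {
  m3 <- random_matrix(3, 4, p_unknown = 0, seed = 1)
  expect_error(search_mp_tree(m3), "at least 4 taxa")
  states <- matrix("1", 5, 2, dimnames = list(paste0("t", 1:5), c("a", "b")))
  expect_error(search_mp_tree(character_matrix(states)), "no signal")
})

test_that("heuristic best length equals brute force on small panels", {
  for (seed in 1:6) {
    m <- random_matrix(6, 8, p_unknown = 0.1, seed = 100 + seed)
    res <- search_mp_tree(m, search_config(seed = seed))
    brute <- min(vapply(all_rooted_phylos(m$panel$taxa), function(phy) {
      tree_length(phy, m)$total_length
    }, 0L))
    expect_identical(res$length, as.integer(brute))
  }
})

test_that("SPR search matches brute force where NNI may stall", {
  for (seed in 1:3) {
    m <- random_matrix(7, 10, p_unknown = 0.15, seed = 200 + seed)
    res <- search_mp_tree(m, search_config(seed = seed, rearrangement = "spr"))
    brute <- min(vapply(all_rooted_phylos(m$panel$taxa), function(phy) {
      tree_length(phy, m)$total_length
    }, 0L))
    expect_identical(res$length, as.integer(brute))
  }
})

test_that("clean simulated matrices return the generating topology", {
  tr <- sim_study_tree()
  for (seed in 1:5) {
    sim <- simulate_insertions(tr, rate = 6, outgroups = "OUT", seed = seed)
    internal <- as.character(setdiff(unique(tr$edge[, 1L]),
                                     length(tr$tip.label) + 1L))
    if (min(sim$truth$edge_counts[internal]) < 1L) next
    res <- search_mp_tree(sim$matrix, search_config(seed = seed))
    expect_true(same_topology(res$trees[[1L]], tr))
  }
})

test_that("fixture search finds length 95 and keeps all ten fixture clades", {
  m <- build_lemur_fixture()
  res <- search_mp_tree(m, search_config(seed = 1, max_equal_trees = 16))
  expect_identical(res$length, 95L)
  cons <- strict_consensus(res$trees)
  fixture_keys <- vapply(sinephylo:::lemur_clades(), function(x) {
    paste(sort(x), collapse = "|")
  }, "")
  expect_true(all(fixture_keys %in% clade_keys_of(cons)))
  # rooting: both outgroups lie outside the 22-lemur clade
  lemurs <- setdiff(m$panel$taxa, m$panel$outgroups)
  expect_true(paste(sort(lemurs), collapse = "|") %in%
                clade_keys_of(res$trees[[1L]]))
})

test_that("strict consensus keeps exactly the shared clades", {
  t1 <- ape::read.tree(text = "((A,(B,C)),(D,E));")
  expect_true(same_topology(strict_consensus(list(t1)), t1))
  t2 <- ape::read.tree(text = "((B,(A,C)),(D,E));")
  cons <- strict_consensus(list(t1, t2))
  keys <- clade_keys_of(cons)
  expect_true("D|E" %in% keys)
  expect_true("A|B|C" %in% keys)
  expect_false("B|C" %in% keys)
  expect_false("A|C" %in% keys)
  expect_error(strict_consensus(list()), "empty")
})

test_that("outgroup rooting places the root between outgroups and ingroup", {
  phy <- ape::read.tree(text = "((((A,B),C),O1),O2);")
  panel <- taxon_panel(c("A", "B", "C", "O1", "O2"), c("O1", "O2"))
  r <- root_with_outgroups(phy, panel)
  expect_true("A|B|C" %in% clade_keys_of(r))
  expect_true(isTRUE(attr(r, "outgroup_monophyletic")))
  # already-basal outgrouping keeps the unrooted topology intact
  phy2 <- ape::read.tree(text = "((O1,O2),((A,B),C));")
  r2 <- root_with_outgroups(phy2, panel)
  expect_true(same_topology(r2, phy2))
  expect_error(root_with_outgroups(phy, taxon_panel(phy$tip.label,
                                                    phy$tip.label)),
               "all taxa")
})

test_that("non-monophyletic outgroups are flagged and ingroup kept together", {
  # O1 nested inside the ingroup: no edge separates both outgroups
  phy <- ape::read.tree(text = "(((A,O1),B),(C,O2));")
  panel <- taxon_panel(c("A", "B", "C", "O1", "O2"), c("O1", "O2"))
  r <- root_with_outgroups(phy, panel)
  expect_false(isTRUE(attr(r, "outgroup_monophyletic")))
})

test_that("collapsing evidence-free edges leaves supported clades alone", {
  m <- build_lemur_fixture()
  res <- search_mp_tree(m, search_config(seed = 3))
  col <- collapse_unsupported_edges(res$trees[[1L]], m)
  keys <- clade_keys_of(col)
  fixture_keys <- vapply(sinephylo:::lemur_clades(), function(x) {
    paste(sort(x), collapse = "|")
  }, "")
  expect_true(all(fixture_keys %in% keys))
  # the fulvus-group interior has no resolving loci: no clade strictly inside
  fulvus <- c("Eulemur albifrons", "Eulemur collaris", "Eulemur fulvus",
              "Eulemur sanfordi")
  inside <- vapply(strsplit(keys, "|", fixed = TRUE), function(k) {
    all(k %in% fulvus) && length(k) > 1L
  }, TRUE)
  expect_false(any(inside))
  expect_identical(tree_length(col, m)$total_length, 95L)
})
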