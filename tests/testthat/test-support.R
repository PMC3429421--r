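test_that("exact test closed forms hold: p(k,0,0) = (1/3)^k, empty gives 1", {
  expect_identical(sine_likelihood_test(0, 0, 0), 1)
  expect_equal(sine_likelihood_test(1, 0, 0), 1 / 3)
  expect_equal(sine_likelihood_test(6, 0, 0), (1 / 3)^6)
  expect_equal(sine_likelihood_test(10, 0, 0), (1 / 3)^10)
  expect_equal(sine_likelihood_test(19, 0, 0), (1 / 3)^19)
})

test_that("exact test agrees with brute-force enumeration for all N <= 8", {
  for (N in 1:8) {
    for (k in 0:N) for (m in 0:(N - k)) {
      n <- N - k - m
      expect_equal(sine_likelihood_test(k, m, n), oracle_trinomial_p(k, m, n),
                   tolerance = 1e-12, info = paste(k, m, n))
    }
  }
})

test_that("the test is symmetric in the alternatives and monotone in k", {
  for (k in 0:5) for (m in 0:3) for (n in 0:3) {
    expect_equal(sine_likelihood_test(k, m, n), sine_likelihood_test(k, n, m))
  }
  for (m in 0:2) for (n in 0:2) {
    ps <- vapply(0:8, function(k) sine_likelihood_test(k, m, n), 0)
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("the agnostic variant is more conservative for dominant support", {
  p1 <- sine_likelihood_test(6, 0, 0)
  p3 <- sine_likelihood_test(6, 0, 0, variant = "agnostic")
  expect_gt(p3, p1)
  expect_equal(p3, 3 * p1, tolerance = 1e-9)
  # both variants agree on every fixture decision at the 0.05 level
  for (k in c(1, 6, 8, 10, 19)) {
    a <- sine_likelihood_test(k, 0, 0) < 0.05
    b <- sine_likelihood_test(k, 0, 0, variant = "agnostic") < 0.05
    expect_identical(a, b)
  }
})

test_that("fixture branch supports match the published counts and pattern", {
  m <- build_lemur_fixture()
  tree <- collapse_unsupported_edges(
    search_mp_tree(m, search_config(seed = 1))$trees[[1L]], m)
  sup <- branch_support_counts(m, tree)
  lookup <- function(taxa) {
    sup[sup$clade == paste(sort(taxa), collapse = "|"), ]
  }
  cl <- sinephylo:::lemur_clades()
  expect_identical(lookup(cl$lemuriformes)$k_support, 10L)
  expect_identical(lookup(cl$lemuridae)$k_support, 10L)
  expect_identical(lookup(cl$lepilemuridae_cheirogaleidae)$k_support, 1L)
  expect_identical(lookup(cl$indriidae_lemuridae)$k_support, 1L)
  expect_identical(lookup(cl$microcebus_mirza)$k_support, 19L)
  expect_true(all(sup$k_conflict_a == 0L) && all(sup$k_conflict_b == 0L))
  # exactly the two single-locus family pairings fail p < 0.05; every branch
  # with >= 6 loci clears the ** level
  failing <- sup[sup$p_value >= 0.05, ]
  expect_identical(nrow(failing), 2L)
  expect_setequal(failing$k_support, c(1L, 1L))
  expect_true(all(sup$p_value[sup$k_support >= 6L] < 0.01))
  expect_true(all(sup$stars[sup$k_support >= 6L] == "**"))
})

test_that("conflicting loci are counted against the local trichotomy", {
  # 6 taxa: clade (A,B) vs alternatives (A,C) and (B,C) under sibling C
  tr <- ape::read.tree(text = "(O,(((A,B),C),(D,E)));")
  states <- matrix("0", 6, 4,
                   dimnames = list(c("A", "B", "C", "D", "E", "O"),
                                   paste0("l", 1:4)))
  states[c("A", "B"), 1] <- "1"
  states[c("A", "B"), 2] <- "1"
  states[c("A", "C"), 3] <- "1"   # supports one alternative resolution
  states[c("D", "E"), 4] <- "1"
  m <- character_matrix(states, outgroups = "O")
  sup <- branch_support_counts(m, tr)
  row <- sup[sup$clade == "A|B", ]
  expect_identical(row$k_support, 2L)
  expect_identical(sort(c(row$k_conflict_a, row$k_conflict_b)), c(0L, 1L))
  expect_equal(row$p_value, sine_likelihood_test(2, 1, 0))
})

test_that("ambiguous (loss-requiring) loci never count as conflicts", {
  tr <- ape::read.tree(text = "(O,(((A,B),C),(D,E)));")
  states <- matrix("0", 6, 2,
                   dimnames = list(c("A", "B", "C", "D", "E", "O"),
                                   c("l1", "l2")))
  states[c("A", "B"), 1] <- "1"
  states[c("A", "C", "D"), 2] <- "1"   # needs losses on any resolution here
  m <- character_matrix(states, outgroups = "O")
  sup <- branch_support_counts(m, tr)
  row <- sup[sup$clade == "A|B", ]
  expect_identical(row$k_conflict_a + row$k_conflict_b, 0L)
})

test_that("autapomorphy counts and tree annotation carry the figure numbers", {
  m <- build_lemur_fixture()
  auta <- autapomorphy_counts(m)
  expect_identical(unname(auta["Microcebus murinus"]), 16L)
  expect_identical(unname(auta["Lemur catta"]), 3L)
  expect_identical(unname(auta["Eulemur macaco"]), 2L)
  expect_identical(unname(auta["Avahi laniger"]), 1L)
  tree <- collapse_unsupported_edges(
    search_mp_tree(m, search_config(seed = 1))$trees[[1L]], m)
  sup <- branch_support_counts(m, tree)
  ann <- annotate_tree(tree, sup, m = m)
  expect_true("Microcebus murinus (16)" %in% ann$tip.label)
  expect_true(any(grepl("/19/", ann$node.label)))
  expect_true(any(grepl("\\*\\*$", ann$node.label)))
})
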