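# Independent oracles and small generators used across the suite. These stay
# deliberately naive: exhaustive enumeration, never the package's own
# algorithms.

# Exhaustive Dollo minimum for one column on one rooted tree: enumerate every
# assignment of 0/1 to internal nodes and unknown leaves; the root may be 1
# only by spending the single allowed gain on its stem. Count 0->1 edges as
# gains (at most one in total) and 1->0 edges as losses.
oracle_dollo_steps <- function(parent, root, n_tip, col) {
  nodes <- sinephylo:::ptree_postorder(parent, root)
  internal <- nodes[nodes > n_tip]
  tips <- nodes[nodes <= n_tip]
  unknown_tips <- tips[col[tips] == 2L]
  free <- c(internal, unknown_tips)
  edges_child <- nodes[nodes != root]
  n_free <- length(free)
  n_masks <- 2L^n_free
  base <- integer(length(parent))
  base[tips] <- ifelse(col[tips] == 2L, 0L, col[tips])
  S <- matrix(rep(base, each = n_masks), n_masks, length(parent))
  if (n_free) {
    S[, free] <- vapply(seq_len(n_free) - 1L, function(b) {
      as.integer(bitwAnd(0:(n_masks - 1L), 2L^b) > 0L)
    }, integer(n_masks))
  }
  P <- S[, parent[edges_child], drop = FALSE]
  C <- S[, edges_child, drop = FALSE]
  gains <- rowSums(C == 1L & P == 0L) + S[, root]  # root stem may carry a gain
  losses <- rowSums(C == 0L & P == 1L)
  min(ifelse(gains > 1L, Inf, gains + losses))
}

oracle_dollo_steps_phylo <- function(phy, column) {
  pt <- sinephylo:::phylo_to_ptree(phy)
  col <- integer(pt$n_tip)
  col[match(names(column), pt$labels)] <-
    ifelse(column == "?", 2L, as.integer(column))
  oracle_dollo_steps(pt$parent, pt$root, pt$n_tip, col)
}

# Exact trinomial test by brute force over all 3^N marker assignments: the
# p-value is the total probability of assignments whose (focal, alt-a, alt-b)
# counts are at least as favourable to the focal resolution, favourability
# ordered exactly as in the implementation but computed from first principles
# over raw outcomes (each of the 3^N equally likely under the null).
oracle_trinomial_p <- function(k, m, n) {
  N <- k + m + n
  if (N == 0) return(1)
  stat <- function(a, b, c) {
    if (a / N <= 1 / 3) return(0)
    xlx <- function(x, p) if (x == 0) 0 else x * log(x / (N * p))
    2 * (xlx(a, 1 / 3) + xlx(b + c, 2 / 3))
  }
  t_obs <- stat(k, m, n)
  hits <- 0L
  grid <- expand.grid(rep(list(1:3), N))
  for (i in seq_len(nrow(grid))) {
    counts <- tabulate(as.integer(grid[i, ]), 3L)
    if (stat(counts[1L], counts[2L], counts[3L]) >= t_obs - 1e-9) {
      hits <- hits + 1L
    }
  }
  hits / 3^N
}

# All rooted binary trees on the given labels, as phylo objects.
all_rooted_phylos <- function(labels) {
  trees <- sinephylo:::enumerate_rooted_trees(length(labels))
  lapply(trees, function(tr) {
    sinephylo:::ptree_to_phylo(
      sinephylo:::ptree(tr$parent, tr$root, length(labels), labels))
  })
}

random_matrix <- function(n_taxa, n_loci, p_unknown = 0.1, seed = 1L) {
  set.seed(seed)
  states <- matrix(sample(c("0", "1", "?"), n_taxa * n_loci, replace = TRUE,
                          prob = c((1 - p_unknown) / 2, (1 - p_unknown) / 2,
                                   p_unknown)),
                   n_taxa, n_loci,
                   dimnames = list(paste0("t", seq_len(n_taxa)),
                                   paste0("L", seq_len(n_loci))))
  character_matrix(states)
}

# A fixed 9-taxon study tree (8 ingroup + outgroup), unit branch lengths.
sim_study_tree <- function() {
  tr <- ape::read.tree(
    text = "(OUT,(((t1,t2),(t3,t4)),((t5,t6),(t7,t8))));")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

clade_keys_of <- function(phy) {
  vapply(tree_clades(phy), function(x) paste(sort(x), collapse = "|"), "")
}

same_topology <- function(a, b) setequal(clade_keys_of(a), clade_keys_of(b))
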