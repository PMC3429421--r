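# Likelihood-based significance testing of insertion support for a branch.
#
# Around any internal branch there is a local trichotomy: three ways of
# resolving the three subtrees that meet there. Under the null that each
# informative marker independently supports one of the three resolutions with
# probability 1/3, the counts (k, m, n) for (focal, alternative A,
# alternative B) are trinomial. The test is exact: enumerate the trinomial
# sample space at N = k + m + n and sum the probability of every outcome at
# least as favourable to the focal resolution, with favourability ordered by
# the likelihood-ratio statistic.

lr_stat <- function(a, b, c, variant) {
  N <- a + b + c
  xlx <- function(x, p) ifelse(x == 0, 0, x * log(x / (N * p)))
  if (variant == "prespecified") {
    # one-sided: evidence for the focal resolution only, alternatives pooled
    if (a / N <= 1 / 3) return(0)
    2 * (xlx(a, 1 / 3) + xlx(b + c, 2 / 3))
  } else {
    # agnostic: evidence against the null in favour of any resolution
    2 * (xlx(a, 1 / 3) + xlx(b, 1 / 3) + xlx(c, 1 / 3))
  }
}

#' Exact trinomial likelihood test for insertion support of a branch
#'
#' `k` markers support the (prespecified) focal resolution of a local
#' trichotomy, `m` and `n` the two alternatives. Under the null each marker
#' supports one of the three resolutions with probability 1/3. The p-value is
#' the exact probability of outcomes at least as favourable to the focal
#' resolution, ordered by likelihood ratio; for `m = n = 0` it reduces to
#' `(1/3)^k`. The `"agnostic"` variant does not prespecify the resolution and
#' counts any outcome as extreme as the observed one (roughly three times the
#' prespecified p when one resolution dominates).
#'
#' @param k,m,n Non-negative marker counts; `k` is the focal resolution's.
#' @param variant `"prespecified"` (default) or `"agnostic"`.
#' @return p-value in `(0, 1]`. All counts zero gives 1 by convention.
#' @examples
#' sine_likelihood_test(6, 0, 0)   # (1/3)^6
#' sine_likelihood_test(1, 0, 0)   # 1/3, not significant
#' @export
sine_likelihood_test <- function(k, m, n,
                                 variant = c("prespecified", "agnostic")) {
  variant <- match.arg(variant)
  stopifnot(k >= 0, m >= 0, n >= 0)
  N <- k + m + n
  if (N == 0) return(1)
  t_obs <- lr_stat(k, m, n, variant)
  p <- 0
  for (a in 0:N) for (b in 0:(N - a)) {
    cc <- N - a - b
    if (lr_stat(a, b, cc, variant) >= t_obs - 1e-9) {
      p <- p + exp(stats::dmultinom(c(a, b, cc), prob = rep(1, 3) / 3,
                                    log = TRUE))
    }
  }
  min(p, 1)
}

stars_for <- function(p, alpha = c(0.05, 0.01)) {
  ifelse(p < alpha[2L], "**", ifelse(p < alpha[1L], "*", ""))
}

#' Per-branch insertion support counts and significance
#'
#' For every internal branch (below the root), reports the number of
#' unambiguous supporting loci (single gain on that branch, no losses), the
#' counts of loci unambiguously supporting each alternative resolution of the
#' local trichotomy around the branch, and the exact likelihood-test p-value.
#' A locus conflicts with a branch only if its present-taxon set is exactly
#' the union of subtrees prescribed by one of the two alternative resolutions;
#' loss-requiring (ambiguous) loci are never counted as conflicts.
#'
#' @param m A [character_matrix()].
#' @param tree A rooted `phylo` tree on the matrix panel.
#' @param alpha Significance thresholds `c(alpha1, alpha2)` with
#'   `0 < alpha2 < alpha1 < 1`; `*` marks `p < alpha1`, `**` `p < alpha2`.
#' @param variant Passed to [sine_likelihood_test()].
#' @return A data frame of class `branch_support` with columns `node`,
#'   `clade`, `n_taxa`, `k_support`, `k_conflict_a`, `k_conflict_b`,
#'   `p_value`, `stars`.
#' @export
branch_support_counts <- function(m, tree, alpha = c(0.05, 0.01),
                                  variant = "prespecified") {
  stopifnot(alpha[2L] < alpha[1L], alpha[1L] < 1, alpha[2L] > 0)
  rec <- reconstruct(tree, m)
  counts <- synapomorphy_counts(rec, tree)
  pt <- phylo_to_ptree(tree)
  kids <- ptree_children(pt$parent)
  ls <- ptree_leafsets(pt)
  # A locus conflicts with a branch only when its present set is EXACTLY one
  # of the alternative unions of the local trichotomy: such a locus would be
  # loss-free under that alternative resolution. Any other loss-requiring
  # pattern is ambiguous and counts for nobody.
  present_keys <- vapply(seq_len(n_loci(m)), function(j) {
    clade_key(rownames(m$states)[m$states[, j] == "1"])
  }, "")
  ord <- ptree_postorder(pt$parent, pt$root)
  internal <- ord[ord > pt$n_tip & ord != pt$root]
  rows <- lapply(sort(internal), function(v) {
    u <- pt$parent[v]
    sibs <- setdiff(kids[[u]], v)
    ka <- kb <- 0L
    if (length(sibs) == 1L && length(kids[[v]]) == 2L) {
      s <- ls[[sibs]]
      aset <- ls[[kids[[v]][1L]]]
      bset <- ls[[kids[[v]][2L]]]
      ka <- sum(present_keys == clade_key(c(aset, s)))
      kb <- sum(present_keys == clade_key(c(bset, s)))
    }
    k <- clade_support(counts, ls[[v]])
    data.frame(node = v, clade = clade_key(ls[[v]]),
               n_taxa = length(ls[[v]]), k_support = k,
               k_conflict_a = ka, k_conflict_b = kb,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_value <- mapply(sine_likelihood_test, out$k_support,
                        out$k_conflict_a, out$k_conflict_b,
                        MoreArgs = list(variant = variant))
  out$stars <- stars_for(out$p_value, alpha)
  out <- out[order(-out$n_taxa, out$clade), ]
  rownames(out) <- NULL
  class(out) <- c("branch_support", "data.frame")
  out
}

#' Autapomorphy counts per taxon
#'
#' Counts characters present in exactly one taxon (the per-tip parenthesised
#' numbers of a marker phylogeny figure).
#'
#' @param m A [character_matrix()].
#' @return Named integer vector over taxa with at least one private insertion.
#' @export
autapomorphy_counts <- function(m) {
  cl <- suppressWarnings(classify_characters(m))
  auta <- cl$class == "autapomorphic" & cl$n_present == 1L
  if (!any(auta)) return(stats::setNames(integer(0), character(0)))
  owner <- vapply(which(auta), function(j) {
    rownames(m$states)[m$states[, j] == "1"]
  }, "")
  tab <- table(owner)
  stats::setNames(as.integer(tab), names(tab))
}

#' Annotate a tree with bootstrap, support counts and significance
#'
#' Writes node labels of the form `boot%/k/p stars` on internal nodes and
#' appends parenthesised private-insertion counts to tip labels, the usual
#' figure convention for marker phylogenies. The full annotation table is
#' attached as attribute `support`.
#'
#' @param tree A rooted `phylo` tree.
#' @param supports A [branch_support_counts()] table for this tree.
#' @param boot Optional [bootstrap()] result.
#' @param m Optional [character_matrix()]; when given, tip labels gain
#'   autapomorphy counts.
#' @return The annotated `phylo` tree.
#' @export
annotate_tree <- function(tree, supports, boot = NULL, m = NULL) {
  pt <- phylo_to_ptree(tree)
  ls <- ptree_leafsets(pt)
  n_int <- tree$Nnode
  labs <- character(n_int)
  for (i in seq_len(n_int)) {
    v <- pt$n_tip + i
    row <- supports[supports$node == v, ]
    if (nrow(row) == 1L) {
      bs <- if (!is.null(boot)) {
        sprintf("%.0f", 100 * clade_frequency(boot, ls[[v]]))
      } else ""
      labs[i] <- sprintf("%s/%d/%.3g%s", bs, row$k_support, row$p_value,
                         row$stars)
    }
  }
  tree$node.label <- labs
  if (!is.null(m)) {
    auta <- autapomorphy_counts(m)
    has <- tree$tip.label %in% names(auta)
    tree$tip.label[has] <- sprintf("%s (%d)", tree$tip.label[has],
                                   auta[tree$tip.label[has]])
  }
  attr(tree, "support") <- supports
  tree
}
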