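# Internal rooted-tree representation used by the search engine: a "ptree" is
# a list(parent, root, n_tip, labels) where `parent` is an integer vector over
# node ids (tips are 1..n_tip in `labels` order, internal nodes any ids above
# n_tip), parent[root] == 0. Nodes not reachable from the root (e.g. stale ids
# left by pruning) are simply ignored by every traversal, which lets the
# search reuse ids without renumbering.

ptree <- function(parent, root, n_tip, labels) {
  list(parent = as.integer(parent), root = as.integer(root),
       n_tip = as.integer(n_tip), labels = labels)
}

ptree_children <- function(parent) {
  kids <- vector("list", length(parent))
  for (i in seq_along(parent)) {
    p <- parent[i]
    if (!is.na(p) && p > 0L) kids[[p]] <- c(kids[[p]], i)
  }
  kids
}

# Postorder node ids reachable from root (children before parents).
ptree_postorder <- function(parent, root) {
  kids <- ptree_children(parent)
  out <- integer(0)
  stack <- root
  # reverse-preorder then reverse = postorder
  pre <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pre <- c(pre, v)
    stack <- c(stack, kids[[v]])
  }
  rev(pre)
}

phylo_to_ptree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  n_tip <- length(phy$tip.label)
  m <- n_tip + phy$Nnode
  parent <- integer(m)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  root <- setdiff(phy$edge[, 1L], phy$edge[, 2L])[1L]
  ptree(parent, root, n_tip, phy$tip.label)
}

ptree_to_phylo <- function(pt) {
  ord <- ptree_postorder(pt$parent, pt$root)
  internal <- ord[ord > pt$n_tip]
  # ape numbering: root = n_tip + 1, other internals following
  newid <- integer(length(pt$parent))
  newid[seq_len(pt$n_tip)] <- seq_len(pt$n_tip)
  newid[pt$root] <- pt$n_tip + 1L
  rest <- setdiff(rev(internal), pt$root)  # preorder-ish
  newid[rest] <- pt$n_tip + 1L + seq_along(rest)
  nodes <- ord[ord != pt$root]
  edge <- cbind(newid[pt$parent[nodes]], newid[nodes])
  # cladewise-ish ordering (parents first)
  edge <- edge[order(edge[, 1L], edge[, 2L]), , drop = FALSE]
  phy <- structure(list(edge = edge, Nnode = length(internal),
                        tip.label = pt$labels), class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

# Leaf-label set below each reachable node, as a list indexed by node id.
ptree_leafsets <- function(pt) {
  ord <- ptree_postorder(pt$parent, pt$root)
  kids <- ptree_children(pt$parent)
  ls <- vector("list", length(pt$parent))
  for (v in ord) {
    ls[[v]] <- if (v <= pt$n_tip) pt$labels[v]
      else sort(unlist(lapply(kids[[v]], function(k) ls[[k]])))
  }
  ls
}

clade_key <- function(taxa) paste(sort(taxa), collapse = "|")

# Non-trivial rooted clades (internal nodes below the root) as label vectors.
ptree_clades <- function(pt) {
  ls <- ptree_leafsets(pt)
  ord <- ptree_postorder(pt$parent, pt$root)
  internal <- ord[ord > pt$n_tip & ord != pt$root]
  lapply(internal, function(v) ls[[v]])
}

#' Rooted clades of a tree
#'
#' Returns the leaf-label sets of all internal nodes strictly below the root.
#'
#' @param phy A rooted `phylo` tree.
#' @return A list of character vectors (sorted taxon labels).
#' @export
tree_clades <- function(phy) ptree_clades(phylo_to_ptree(phy))

# Canonical topology string: invariant to node ids and child order.
ptree_key <- function(pt) {
  kids <- ptree_children(pt$parent)
  ord <- ptree_postorder(pt$parent, pt$root)
  key <- character(length(pt$parent))
  for (v in ord) {
    key[v] <- if (v <= pt$n_tip) pt$labels[v]
      else paste0("(", paste(sort(key[kids[[v]]]), collapse = ","), ")")
  }
  key[pt$root]
}

#' Canonical topology key of a rooted tree
#'
#' A string representation invariant to node numbering and child order, used
#' to deduplicate topologies and compare trees for topological identity.
#'
#' @param phy A rooted `phylo` tree.
#' @return A character scalar.
#' @export
topology_key <- function(phy) ptree_key(phylo_to_ptree(phy))

#' Build a rooted (possibly multifurcating) tree from a set of nested clades
#'
#' Given pairwise-compatible clades (each a vector of taxon labels), returns
#' the rooted tree whose internal nodes are exactly those clades plus the
#' root. Used for strict and majority-rule consensus construction and for
#' assembling reference topologies from clade lists.
#'
#' @param clades List of character vectors; must be pairwise compatible
#'   (nested or disjoint).
#' @param taxa Character vector of all taxon labels.
#' @return A `phylo` tree.
#' @export
build_tree_from_clades <- function(clades, taxa) {
  clades <- clades[vapply(clades, length, 0L) > 1L]
  clades <- clades[!duplicated(vapply(clades, clade_key, ""))]
  clades <- clades[vapply(clades, length, 0L) < length(taxa)]
  for (cl in clades) {
    if (!all(cl %in% taxa)) stop("clade contains unknown taxa")
  }
  sizes <- vapply(clades, length, 0L)
  o <- order(-sizes)
  clades <- clades[o]; sizes <- sizes[o]
  n <- length(taxa)
  n_nodes <- n + 1L + length(clades)
  parent <- integer(n_nodes)
  root <- n + 1L
  # parent of each clade node = smallest strictly-containing clade (or root)
  clade_id <- n + 1L + seq_along(clades)
  for (i in seq_along(clades)) {
    parent[clade_id[i]] <- root
    for (j in seq_len(i - 1L)) {
      # clades sorted by decreasing size: j < i can only contain i
      if (all(clades[[i]] %in% clades[[j]])) {
        if (sizes[j] == sizes[i]) stop("incompatible clades")
        parent[clade_id[i]] <- clade_id[j]
      } else if (any(clades[[i]] %in% clades[[j]])) {
        stop("incompatible clades: ", clade_key(clades[[i]]), " vs ",
             clade_key(clades[[j]]))
      }
    }
  }
  for (t in seq_len(n)) {
    parent[t] <- root
    for (j in seq_along(clades)) {
      if (taxa[t] %in% clades[[j]]) parent[t] <- clade_id[j]  # smallest wins
    }
  }
  ptree_to_phylo(ptree(parent, root, n, taxa))
}

#' Root a tree on the edge separating outgroups from the ingroup
#'
#' If the outgroup set is monophyletic on the unrooted topology, the root is
#' placed on the edge separating it from the ingroup. Otherwise the tree is
#' rooted on the edge subtending the largest pure-ingroup clade (maximising
#' ingroup monophyly) and the result carries attribute
#' `outgroup_monophyletic = FALSE`.
#'
#' @param phy A `phylo` tree (rooted or unrooted).
#' @param panel A [taxon_panel()] whose outgroups are present in the tree.
#' @return A rooted `phylo` tree.
#' @export
root_with_outgroups <- function(phy, panel) {
  og <- panel$outgroups
  if (length(og) == 0L) stop("panel has no outgroups; rooting requires one")
  if (!all(og %in% phy$tip.label)) stop("outgroup taxa missing from tree")
  ig <- setdiff(phy$tip.label, og)
  if (length(ig) == 0L) stop("outgroups cannot be all taxa")
  uphy <- if (ape::is.rooted(phy)) ape::unroot(phy) else phy
  mono <- ape::is.monophyletic(uphy, og) || length(og) == 1L ||
    ape::is.monophyletic(uphy, ig)
  if (mono) {
    out <- ape::root(uphy, outgroup = og, resolve.root = TRUE)
    attr(out, "outgroup_monophyletic") <- TRUE
    return(out)
  }
  # fall back: root above the largest clade containing only ingroup taxa
  pt <- phylo_to_ptree(ape::root(uphy, outgroup = og[1L], resolve.root = TRUE))
  ls <- ptree_leafsets(pt)
  ord <- ptree_postorder(pt$parent, pt$root)
  cand <- ord[ord != pt$root]
  pure <- cand[vapply(cand, function(v) !any(ls[[v]] %in% og), TRUE)]
  best <- pure[which.max(vapply(pure, function(v) length(ls[[v]]), 0L))]
  node_lab <- if (best <= pt$n_tip) pt$labels[best] else NULL
  out <- if (!is.null(node_lab)) {
    ape::root(uphy, outgroup = node_lab, resolve.root = TRUE)
  } else {
    ape::root(uphy, outgroup = ls[[best]], resolve.root = TRUE)
  }
  attr(out, "outgroup_monophyletic") <- FALSE
  out
}
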