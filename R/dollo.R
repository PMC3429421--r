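# Dollo parsimony on rooted trees.
#
# Model: a presence/absence character can be gained exactly once (the gain
# edge may be any edge, including the root's stem) and lost any number of
# times below the gain; the state ancestral to the root is absence. Unknown
# leaves ("?") take whichever state does not increase the step count, with
# ties resolved to absent. Multifurcations are scored directly: each maximal
# all-absent child subtree inside the gain clade costs one loss.

# R dynamic programme with traceback (the C++ scorer in src/dollo.cpp computes
# steps only and is used on the search/bootstrap hot path; the two are held
# equal by tests).
dollo_column_rec <- function(pt, col) {
  kids <- ptree_children(pt$parent)
  ord <- ptree_postorder(pt$parent, pt$root)
  M <- length(pt$parent)
  a0 <- a1 <- pr <- rep(Inf, M)
  ch1 <- integer(M)
  for (v in ord) {
    if (v <= pt$n_tip) {
      s <- col[v]
      a0[v] <- if (s == 1L) Inf else 0
      pr[v] <- if (s == 0L) Inf else 0
    } else {
      cs <- kids[[v]]
      a0[v] <- sum(a0[cs])
      pr[v] <- sum(pmin(pr[cs], 1 + a0[cs]))
      best <- Inf; besti <- 0L
      for (c in cs) {
        others <- sum(a0[setdiff(cs, c)])
        cand <- others + min(a1[c], 1 + pr[c])
        if (cand < best) { best <- cand; besti <- c }
      }
      a1[v] <- best; ch1[v] <- besti
    }
  }
  steps <- min(a0[pt$root], a1[pt$root], 1 + pr[pt$root])
  resolved <- integer(pt$n_tip)
  gain_node <- NA_integer_
  loss_nodes <- integer(0)
  assign_mode <- function(v, mode) {
    if (v <= pt$n_tip) {
      resolved[v] <<- if (mode == "P") 1L else 0L
      return(invisible())
    }
    cs <- kids[[v]]
    if (mode == "A0") {
      for (c in cs) assign_mode(c, "A0")
    } else if (mode == "A1") {
      c <- ch1[v]
      for (o in setdiff(cs, c)) assign_mode(o, "A0")
      if (a1[c] <= 1 + pr[c]) {           # prefer the deeper gain on ties
        assign_mode(c, "A1")
      } else {
        gain_node <<- c
        assign_mode(c, "P")
      }
    } else {                               # mode == "P"
      for (c in cs) {
        if (pr[c] < 1 + a0[c]) {           # ties resolve to absent (a loss)
          assign_mode(c, "P")
        } else {
          loss_nodes <<- c(loss_nodes, c)
          assign_mode(c, "A0")
        }
      }
    }
  }
  r <- pt$root
  if (a0[r] <= steps) {
    assign_mode(r, "A0")
  } else if (a1[r] <= steps) {
    assign_mode(r, "A1")
  } else {
    gain_node <- r                         # gain on the root's stem
    assign_mode(r, "P")
  }
  list(steps = as.integer(steps), gain_node = gain_node,
       loss_nodes = loss_nodes, resolved = resolved)
}

encode_column <- function(column, labels) {
  if (is.character(column)) {
    col <- match(column, MATRIX_STATES) - 1L
    names(col) <- names(column)
  } else {
    col <- as.integer(column)
    names(col) <- names(column)
  }
  if (is.null(names(col))) stop("column must be named by taxon")
  present <- names(col)[col == 1L]
  missing <- setdiff(present, labels)
  if (length(missing)) {
    stop("present taxa missing from tree: ", paste(missing, collapse = ", "))
  }
  out <- rep(0L, length(labels))
  idx <- match(names(col), labels)
  out[idx[!is.na(idx)]] <- col[!is.na(idx)]
  out
}

#' Dollo steps and reconstruction for a single character
#'
#' Places the single gain on the edge above the most recent common ancestor of
#' the present leaves (or on the root's stem if they span the root) and counts
#' one loss per maximal all-absent subtree inside the gain clade. Unknown
#' leaves are resolved to whichever state does not increase the count, ties to
#' absent. Returns the minimal step count under these constraints.
#'
#' @param tree A rooted `phylo` tree whose tip labels cover the column's taxa.
#' @param column Named vector of states over taxa: `"0"`/`"1"`/`"?"`
#'   (or integers 0/1/2).
#' @return A list with `steps` (integer, gains + losses), `gain_node` (ape
#'   node id below the gain edge, `NA` if the character is all-absent),
#'   `gain_clade` (taxon labels below the gain), `loss_nodes`, `loss_clades`,
#'   and `resolved_states` (named 0/1 vector after `"?"` resolution).
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' dollo_char_steps(tr, c(A = "1", B = "1", C = "0", D = "0"))
#' @export
dollo_char_steps <- function(tree, column) {
  pt <- phylo_to_ptree(tree)
  col <- encode_column(column, pt$labels)
  rec <- dollo_column_rec(pt, col)
  ls <- ptree_leafsets(pt)
  clade_of <- function(v) if (is.na(v)) character(0) else ls[[v]]
  list(steps = rec$steps,
       gain_node = rec$gain_node,
       gain_clade = clade_of(rec$gain_node),
       loss_nodes = rec$loss_nodes,
       loss_clades = lapply(rec$loss_nodes, clade_of),
       resolved_states = stats::setNames(rec$resolved, pt$labels))
}

states_for_tree <- function(m, pt) {
  if (!setequal(pt$labels, m$panel$taxa)) {
    stop("tree leaf set does not match the taxon panel")
  }
  encode_states(m)[pt$labels, , drop = FALSE]
}

#' Dollo tree length of a matrix on a tree
#'
#' @param tree A rooted `phylo` tree; leaf set must equal the matrix panel.
#' @param m A [character_matrix()].
#' @return An object of class `tree_score`: list with `per_locus` (named
#'   integer step counts) and `total_length`.
#' @export
tree_length <- function(tree, m) {
  pt <- phylo_to_ptree(tree)
  st <- states_for_tree(m, pt)
  steps <- dollo_steps_cpp(pt$parent, pt$root, pt$n_tip, st)
  structure(list(per_locus = stats::setNames(as.integer(steps), colnames(st)),
                 total_length = sum(steps)),
            class = "tree_score")
}

#' @export
print.tree_score <- function(x, ...) {
  cat("Dollo tree length:", x$total_length, "steps over",
      length(x$per_locus), "loci\n")
  invisible(x)
}

#' Dollo reconstruction of every character on a tree
#'
#' @inheritParams tree_length
#' @return An object of class `dollo_reconstruction`: list with `tree`, a
#'   summary data frame `table` (columns `id`, `steps`, `gain_node`,
#'   `n_losses`, `ambiguous`), `loss_nodes` (list per locus), and `resolved`
#'   (taxa-by-loci 0/1 matrix after `"?"` resolution).
#' @export
reconstruct <- function(tree, m) {
  pt <- phylo_to_ptree(tree)
  st <- states_for_tree(m, pt)
  recs <- lapply(seq_len(ncol(st)), function(j) dollo_column_rec(pt, st[, j]))
  tab <- data.frame(
    id = colnames(st),
    steps = vapply(recs, function(r) r$steps, 0L),
    gain_node = vapply(recs, function(r) r$gain_node, 0L),
    n_losses = vapply(recs, function(r) length(r$loss_nodes), 0L),
    stringsAsFactors = FALSE)
  tab$ambiguous <- tab$n_losses > 0L
  resolved <- vapply(recs, function(r) r$resolved, integer(pt$n_tip))
  dimnames(resolved) <- list(pt$labels, colnames(st))
  structure(list(tree = tree, table = tab,
                 loss_nodes = lapply(recs, function(r) r$loss_nodes),
                 resolved = resolved),
            class = "dollo_reconstruction")
}

#' @export
print.dollo_reconstruction <- function(x, ...) {
  cat("Dollo reconstruction:", nrow(x$table), "loci,",
      sum(x$table$steps), "steps,",
      sum(x$table$ambiguous), "loss-requiring (ambiguous) loci\n")
  invisible(x)
}

#' Per-edge unambiguous synapomorphy counts
#'
#' For every edge (identified by the node below it), counts the characters
#' whose single gain maps to that edge with no losses anywhere: the
#' "unambiguous" support of the clade below the edge. Loss-requiring
#' characters are reported separately as ambiguous.
#'
#' @param rec A [reconstruct()] result.
#' @param tree The tree the reconstruction was computed on (defaults to
#'   `rec$tree`).
#' @return A data frame with one row per edge carrying at least one gain:
#'   `node`, `clade` (sorted labels collapsed with `|`), `n_taxa`, `count`.
#'   The ids of ambiguous loci are in `attr(, "ambiguous")`.
#' @export
synapomorphy_counts <- function(rec, tree = rec$tree) {
  stopifnot(inherits(rec, "dollo_reconstruction"))
  pt <- phylo_to_ptree(tree)
  ls <- ptree_leafsets(pt)
  tab <- rec$table
  un <- tab[!tab$ambiguous & !is.na(tab$gain_node) & tab$steps > 0L, ]
  counts <- table(un$gain_node)
  nodes <- as.integer(names(counts))
  out <- data.frame(
    node = nodes,
    clade = vapply(nodes, function(v) clade_key(ls[[v]]), ""),
    n_taxa = vapply(nodes, function(v) length(ls[[v]]), 0L),
    count = as.integer(counts),
    stringsAsFactors = FALSE)
  out <- out[order(-out$n_taxa, out$clade), ]
  rownames(out) <- NULL
  attr(out, "ambiguous") <- tab$id[tab$ambiguous]
  out
}

#' Look up the synapomorphy count of the edge subtending a given clade
#'
#' @param counts A [synapomorphy_counts()] data frame.
#' @param taxa Character vector: the exact descendant leaf set of the edge.
#' @return Integer count (0 if no gain maps to that edge).
#' @export
clade_support <- function(counts, taxa) {
  key <- clade_key(taxa)
  i <- match(key, counts$clade)
  if (is.na(i)) 0L else counts$count[i]
}

# cache for enumerated per-character maxima
.dollo_cache <- new.env(parent = emptyenv())

# All rooted binary tree shapes on n labelled leaves (as ptree parent vectors),
# built by inserting leaf k on every edge (and the root stem) of each (k-1)-
# leaf tree. (2n-3)!! trees; intended for n <= 8.
enumerate_rooted_trees <- function(n) {
  stopifnot(n >= 2L)
  M <- 2L * n - 1L
  p0 <- rep(0L, M); p0[1:2] <- n + 1L
  trees <- list(list(parent = p0, root = n + 1L, nxt = n + 2L))
  if (n >= 3L) for (t in 3L:n) {
    new <- vector("list", length(trees) * (2L * t - 3L))
    k <- 0L
    for (tr in trees) {
      nodes <- ptree_postorder(tr$parent, tr$root)
      for (c in nodes) {
        p2 <- tr$parent; w <- tr$nxt
        p2[t] <- w; p2[w] <- p2[c]; p2[c] <- w
        k <- k + 1L
        new[[k]] <- list(parent = p2,
                         root = if (c == tr$root) w else tr$root,
                         nxt = w + 1L)
      }
    }
    trees <- new
  }
  trees
}

max_dollo_steps_enum <- function(n_present, n_absent) {
  key <- paste0("max_", n_present, "_", n_absent)
  hit <- .dollo_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- n_present + n_absent
  if (n_present == 0L) return(0L)
  if (n == 1L) return(1L)
  col <- matrix(c(rep(1L, n_present), rep(0L, n_absent)), ncol = 1L)
  best <- 0L
  for (tr in enumerate_rooted_trees(n)) {
    s <- dollo_steps_cpp(tr$parent, tr$root, n, col)
    if (s > best) best <- s
  }
  .dollo_cache[[key]] <- best
  best
}

#' Maximum Dollo steps of a binary character over all rooted binary trees
#'
#' Used as the per-character worst case in the retention index. The closed
#' form is `1 + n_absent` when at least two taxa are present (a caterpillar
#' interleaving the absent leaves between present ones isolates every absent
#' leaf inside the gain clade), `1` when exactly one is present, `0` when
#' none. `method = "enumerate"` computes it exhaustively over all rooted
#' binary trees (feasible up to ~8 taxa) and is used to validate the closed
#' form.
#'
#' @param n_present,n_absent Counts of known present / absent taxa.
#' @param method `"closed_form"` or `"enumerate"`.
#' @return Integer.
#' @export
max_dollo_steps <- function(n_present, n_absent,
                            method = c("closed_form", "enumerate")) {
  method <- match.arg(method)
  if (method == "enumerate") return(max_dollo_steps_enum(n_present, n_absent))
  if (n_present == 0L) 0L
  else if (n_present == 1L) 1L
  else 1L + n_absent
}

#' Ensemble consistency, homoplasy and retention indices under Dollo parsimony
#'
#' CI is the ratio of the minimum conceivable length (one step per character
#' with at least one present taxon) to the observed Dollo length; HI = 1 - CI.
#' RI rescales the observed length between the per-character minimum and the
#' per-character maximum over all rooted binary trees: RI = 1 means the matrix
#' fits the tree with no homoplasy at all. Per-character maxima are taken by
#' exhaustive enumeration when the panel has at most 8 taxa and by the
#' validated closed form above otherwise. Unknown cells are excluded from the
#' present/absent counts (they can always be resolved for free).
#'
#' @param m A [character_matrix()].
#' @param tree A rooted `phylo` tree on the matrix panel.
#' @return An object of class `dollo_indices`: list with `CI`, `HI`, `RI`
#'   (`RI` is `NA` when no character can show homoplasy, i.e. sum of maxima
#'   equals sum of minima), `length`, `min_length`, `max_length`.
#' @export
ensemble_indices <- function(m, tree) {
  ts <- tree_length(tree, m)
  obs <- ts$per_locus
  n1 <- colSums(m$states == "1")
  n0 <- colSums(m$states == "0")
  minim <- ifelse(n1 >= 1L, 1L, 0L)
  nt <- n_taxa(m)
  maxim <- if (nt <= 8L) {
    mapply(max_dollo_steps, n1, n0, MoreArgs = list(method = "enumerate"))
  } else {
    mapply(max_dollo_steps, n1, n0)
  }
  s_obs <- sum(obs); s_min <- sum(minim); s_max <- sum(maxim)
  ci <- if (s_obs == 0) NA_real_ else s_min / s_obs
  ri <- if (s_max > s_min) (s_max - s_obs) / (s_max - s_min) else NA_real_
  structure(list(CI = ci, HI = if (is.na(ci)) NA_real_ else 1 - ci, RI = ri,
                 length = s_obs, min_length = s_min, max_length = s_max),
            class = "dollo_indices")
}

#' @export
print.dollo_indices <- function(x, ...) {
  cat(sprintf("Length %d  CI %.3f  HI %.3f  RI %s\n", x$length, x$CI, x$HI,
              if (is.na(x$RI)) "undefined (no character can show homoplasy)"
              else sprintf("%.3f", x$RI)))
  invisible(x)
}
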