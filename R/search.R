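#' Configuration for the heuristic most-parsimonious-tree search
#'
#' @param seed Integer seed; a fixed seed makes the whole search trajectory
#'   (and any bootstrap built on it) reproducible.
#' @param addition_order `"as_given"` adds taxa in panel order; `"random"`
#'   permutes them (seeded).
#' @param rearrangement Branch-swapping neighbourhood: `"nni"`
#'   (nearest-neighbour interchange) or `"spr"` (subtree pruning and
#'   regrafting, a larger neighbourhood).
#' @param n_starts Number of addition-sequence starts for the heuristic
#'   search; starts after the first use seeded random addition orders.
#'   Branch swapping can stop in a local optimum, and independent starts are
#'   the standard insurance.
#' @param exhaustive_cutoff Panels with at most this many taxa are searched
#'   exactly, by scoring every rooted binary topology; the heuristic machinery
#'   only engages above it. All rooted trees on 7 taxa number 10,395, well
#'   within a blink, so exact search is both feasible and the honest default
#'   at that scale.
#' @param max_equal_trees Cap on the number of distinct equally-best
#'   topologies collected from the optimum plateau.
#' @param collapse_unsupported If `TRUE`, internal edges to which no character
#'   gain maps are collapsed in the reported trees (zero-length edges carry no
#'   evidence).
#' @return A `search_config` list.
#' @export
search_config <- function(seed = 1L,
                          addition_order = c("as_given", "random"),
                          rearrangement = c("nni", "spr"),
                          n_starts = 1L,
                          exhaustive_cutoff = 7L,
                          max_equal_trees = 64L,
                          collapse_unsupported = FALSE) {
  structure(list(seed = as.integer(seed),
                 addition_order = match.arg(addition_order),
                 rearrangement = match.arg(rearrangement),
                 n_starts = as.integer(n_starts),
                 exhaustive_cutoff = as.integer(exhaustive_cutoff),
                 max_equal_trees = as.integer(max_equal_trees),
                 collapse_unsupported = isTRUE(collapse_unsupported)),
            class = "search_config")
}

# --- neighbourhood moves on ptree parent vectors (binary rooted trees) ------

# Attach tip `t` on the edge above node `c` (c == root attaches on the root
# stem, creating a new root). `w` is the id of the new internal node.
ptree_attach <- function(parent, root, c, t, w) {
  if (w > length(parent)) parent <- c(parent, integer(w - length(parent)))
  parent[t] <- w
  parent[w] <- parent[c]
  parent[c] <- w
  list(parent = parent, root = if (c == root) w else root)
}

# All NNI rearrangements, in a deterministic node-id order.
nni_moves <- function(parent, root) {
  kids <- ptree_children(parent)
  ord <- sort(ptree_postorder(parent, root))
  out <- list()
  for (v in ord) {
    if (v == root || length(kids[[v]]) == 0L) next   # v must be internal
    if (length(kids[[v]]) != 2L) next
    u <- parent[v]
    s <- setdiff(kids[[u]], v)
    if (length(s) != 1L) next
    for (c in kids[[v]]) {
      p2 <- parent
      p2[s] <- v
      p2[c] <- u
      out[[length(out) + 1L]] <- list(parent = p2, root = root)
    }
  }
  out
}

# All SPR rearrangements: prune the subtree at x, regraft above any node of
# the remaining tree (including its root stem).
spr_moves <- function(parent, root) {
  kids <- ptree_children(parent)
  ord <- sort(ptree_postorder(parent, root))
  out <- list()
  for (x in ord) {
    if (x == root) next
    p <- parent[x]
    s <- setdiff(kids[[p]], x)
    if (length(s) != 1L) next
    # prune: splice p out (disconnecting x hides the whole pruned subtree
    # from traversals of the remaining tree)
    pp <- parent[p]
    par2 <- parent
    par2[s] <- pp                       # pp == 0 makes s the new root
    par2[p] <- 0L; par2[x] <- 0L
    root2 <- if (p == root) s else root
    targets <- sort(ptree_postorder(par2, root2))
    for (c in targets) {
      p3 <- par2
      p3[x] <- p
      p3[p] <- p3[c]
      p3[c] <- p
      out[[length(out) + 1L]] <- list(parent = p3,
                                      root = if (c == root2) p else root2)
    }
  }
  out
}

# Greedy stepwise addition over the tip order 1..n (ids are positions in
# `labels`); ties broken by the first (lowest-id) attachment point.
stepwise_addition <- function(states, order_idx, score_fun) {
  n <- nrow(states)
  stopifnot(n >= 3L)
  parent <- rep(0L, n)
  w <- n + 1L
  parent[order_idx[1:2]] <- w
  parent <- c(parent, 0L)
  root <- w
  nxt <- w + 1L
  for (k in 3:n) {
    t <- order_idx[k]
    nodes <- sort(ptree_postorder(parent, root))
    best <- Inf; best_tr <- NULL
    for (c in nodes) {
      tr <- ptree_attach(parent, root, c, t, nxt)
      sc <- score_fun(tr$parent, tr$root)
      if (sc < best) { best <- sc; best_tr <- tr }
    }
    parent <- best_tr$parent; root <- best_tr$root; nxt <- nxt + 1L
  }
  list(parent = parent, root = root, length = best)
}

#' Search for minimum-length Dollo trees
#'
#' Panels of up to `exhaustive_cutoff` taxa are searched exactly by scoring
#' every rooted binary topology. Larger panels get the classic heuristic:
#' greedy stepwise-addition start(s), hill climbing by branch swapping (first
#' improving neighbour in a deterministic edge order) until no neighbour is
#' shorter, then collection of distinct equally-best topologies from the
#' optimum plateau (up to `max_equal_trees`). The returned trees are rooted on
#' the panel outgroups via [root_with_outgroups()].
#'
#' @param m A [character_matrix()] with at least 4 taxa and one variable
#'   character.
#' @param config A [search_config()].
#' @return An object of class `mp_search`: list with `trees` (list of rooted
#'   `phylo`), `length` (best Dollo length), `score` (a `tree_score` for the
#'   first tree) and `config`.
#' @export
search_mp_tree <- function(m, config = search_config()) {
  stopifnot(inherits(m, "character_matrix"))
  if (n_taxa(m) < 4L) stop("search requires at least 4 taxa")
  cl <- suppressWarnings(classify_characters(m))
  if (all(cl$class == "constant")) stop("no signal: all characters constant")
  st_full <- encode_states(m)
  # collapse duplicate column patterns into weights (scoring-equivalent)
  pat <- apply(st_full, 2L, paste, collapse = "")
  upat <- !duplicated(pat)
  st <- st_full[, upat, drop = FALSE]
  wts <- as.numeric(table(factor(pat, levels = pat[upat])))
  n <- nrow(st)
  labels <- m$panel$taxa
  score_fun <- function(parent, root) {
    dollo_total_cpp(parent, root, n, st, wts)
  }
  if (n <= config$exhaustive_cutoff) {
    # exact search: score every rooted binary topology
    all_trees <- enumerate_rooted_trees(n)
    scores <- vapply(all_trees, function(tr) score_fun(tr$parent, tr$root), 0)
    best <- min(scores)
    hit <- which(scores == best)
    hit <- hit[seq_len(min(length(hit), config$max_equal_trees))]
    pool <- lapply(all_trees[hit], function(tr) {
      list(parent = tr$parent, root = tr$root)
    })
  } else {
    moves_fun <- if (config$rearrangement == "spr") spr_moves else nni_moves
    climb <- function(parent, root) {
      best <- score_fun(parent, root)
      repeat {
        improved <- FALSE
        for (tr in moves_fun(parent, root)) {
          sc <- score_fun(tr$parent, tr$root)
          if (sc < best) {
            best <- sc; parent <- tr$parent; root <- tr$root
            improved <- TRUE
            break                         # first improvement, then restart
          }
        }
        if (!improved) break
      }
      list(parent = parent, root = root, length = best)
    }
    best <- Inf; parent <- NULL; root <- NULL
    for (i in seq_len(max(1L, config$n_starts))) {
      order_idx <- seq_len(n)
      if (config$addition_order == "random" || i > 1L) {
        set.seed(config$seed + 7919L * (i - 1L))
        order_idx <- sample.int(n)
      }
      start <- stepwise_addition(st, order_idx, score_fun)
      res <- climb(start$parent, start$root)
      if (res$length < best) {
        best <- res$length; parent <- res$parent; root <- res$root
      }
    }
    # plateau: breadth-first over equal-length neighbours
    pool <- list(list(parent = parent, root = root))
    keys <- ptree_key(ptree(parent, root, n, labels))
    queue <- pool
    visited <- 0L
    while (length(queue) && length(pool) < config$max_equal_trees &&
           visited < 4L * config$max_equal_trees) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      visited <- visited + 1L
      for (tr in moves_fun(cur$parent, cur$root)) {
        if (length(pool) >= config$max_equal_trees) break
        sc <- score_fun(tr$parent, tr$root)
        if (sc == best) {
          k <- ptree_key(ptree(tr$parent, tr$root, n, labels))
          if (!(k %in% keys)) {
            keys <- c(keys, k)
            pool[[length(pool) + 1L]] <- tr
            queue[[length(queue) + 1L]] <- tr
          }
        }
      }
    }
  }
  trees <- lapply(pool, function(tr) {
    phy <- ptree_to_phylo(ptree(tr$parent, tr$root, n, labels))
    if (length(m$panel$outgroups)) phy <- root_with_outgroups(phy, m$panel)
    phy
  })
  if (config$collapse_unsupported) {
    trees <- lapply(trees, collapse_unsupported_edges, m = m)
  }
  structure(list(trees = trees, length = tree_length(trees[[1L]], m)$total_length,
                 score = tree_length(trees[[1L]], m), config = config),
            class = "mp_search")
}

#' @export
print.mp_search <- function(x, ...) {
  cat("MP search:", length(x$trees), "equally-best tree(s) of Dollo length",
      x$length, "\n")
  invisible(x)
}

#' Collapse internal edges carrying no character gain
#'
#' Internal edges to which no gain maps under the Dollo reconstruction carry
#' no insertion evidence; collapsing them reports honest polytomies instead of
#' arbitrary resolutions.
#'
#' @param phy A rooted `phylo` tree.
#' @param m The [character_matrix()] scored on it.
#' @return A rooted `phylo` tree, possibly multifurcating.
#' @export
collapse_unsupported_edges <- function(phy, m) {
  rec <- reconstruct(phy, m)
  pt <- phylo_to_ptree(phy)
  supported <- unique(rec$table$gain_node[rec$table$steps > 0L])
  ord <- ptree_postorder(pt$parent, pt$root)
  internal <- ord[ord > pt$n_tip & ord != pt$root]
  drop <- setdiff(internal, supported)
  parent <- pt$parent
  for (v in drop) {
    for (i in seq_along(parent)) if (parent[i] == v) parent[i] <- parent[v]
    parent[v] <- 0L
  }
  ptree_to_phylo(ptree(parent, pt$root, pt$n_tip, pt$labels))
}

#' Strict consensus of rooted trees
#'
#' Retains exactly the clades present in every input tree.
#'
#' @param trees A list of rooted `phylo` trees with identical leaf sets.
#' @return A rooted `phylo` tree (with polytomies where trees disagree).
#' @export
strict_consensus <- function(trees) {
  if (length(trees) == 0L) stop("empty tree set")
  taxa <- sort(trees[[1L]]$tip.label)
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), taxa)) stop("leaf sets differ")
  }
  keysets <- lapply(trees, function(tr) {
    vapply(tree_clades(tr), clade_key, "")
  })
  shared <- Reduce(intersect, keysets)
  clades <- lapply(shared, function(k) strsplit(k, "|", fixed = TRUE)[[1L]])
  build_tree_from_clades(clades, trees[[1L]]$tip.label)
}
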