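#' Simulate insertion presence/absence characters on a tree
#'
#' Models retrotransposon insertions as identity-by-descent markers: each
#' insertion arises once on a branch (Poisson with mean `rate` times branch
#' length) and is inherited by every descendant leaf. Optional confounders
#' emulate the rare events that break the clean picture:
#'
#' * `p_excision`: a descendant subtree inside the gain clade reverts to
#'   absent (precise excision / deletion of the element);
#' * `p_parallel`: an extra column is created for an independent insertion of
#'   the same locus on another branch (near-parallel insertion before
#'   recoding);
#' * `p_ils`: the column's presence set follows a discordant resolution of the
#'   local trichotomy (incomplete lineage sorting);
#' * `p_missing`: each cell is independently replaced by `"?"` (failed
#'   amplification).
#'
#' @param tree A rooted binary `phylo` tree with branch lengths.
#' @param rate Expected insertions per unit branch length.
#' @param p_excision,p_parallel,p_ils,p_missing Per-column / per-cell
#'   confounder probabilities (all default 0: perfectly clean,
#'   clade-consistent characters).
#' @param outgroups Taxa to flag as outgroups in the resulting panel.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A list with `matrix` (a [character_matrix()]) and `truth`: a list
#'   with `edge_counts` (named by the node below each edge: insertions that
#'   arose there), `gain_node` (per column), and `events` (per-column
#'   confounder log).
#' @export
simulate_insertions <- function(tree, rate, p_excision = 0, p_parallel = 0,
                                p_ils = 0, p_missing = 0,
                                outgroups = character(), seed = 1L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length), rate >= 0)
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    stop("simulation requires a rooted binary tree")
  }
  probs <- c(p_excision, p_parallel, p_ils, p_missing)
  stopifnot(all(probs >= 0), all(probs <= 1))
  set.seed(seed)
  pt <- phylo_to_ptree(tree)
  ls <- ptree_leafsets(pt)
  kids <- ptree_children(pt$parent)
  taxa <- pt$labels
  n_ins <- stats::rpois(nrow(tree$edge), rate * tree$edge.length)
  below <- tree$edge[, 2L]
  gain_node <- rep(below, n_ins)
  events <- vector("list", length(gain_node))
  cols <- list()
  col_gain <- integer(0)
  for (i in seq_along(gain_node)) {
    v <- gain_node[i]
    ev <- character(0)
    clade <- ls[[v]]
    if (p_ils > 0 && stats::runif(1) < p_ils && v > pt$n_tip &&
        pt$parent[v] != pt$root && pt$parent[v] != 0L) {
      # discordant resolution: one child of v groups with v's sibling
      u <- pt$parent[v]
      s <- setdiff(kids[[u]], v)[1L]
      cpick <- kids[[v]][sample.int(2L, 1L)]
      clade <- sort(c(ls[[cpick]], ls[[s]]))
      ev <- c(ev, "ils")
    }
    state <- stats::setNames(rep("0", length(taxa)), taxa)
    state[clade] <- "1"
    if (p_excision > 0 && stats::runif(1) < p_excision) {
      inside <- ptree_postorder(pt$parent, v)
      inside <- setdiff(inside, v)
      if (length(inside)) {
        w <- inside[sample.int(length(inside), 1L)]
        state[ls[[w]]] <- "0"
        ev <- c(ev, "excision")
      }
    }
    cols[[length(cols) + 1L]] <- state
    col_gain <- c(col_gain, v)
    events[[i]] <- ev
    if (p_parallel > 0 && stats::runif(1) < p_parallel) {
      others <- setdiff(below, v)
      w <- others[sample.int(length(others), 1L)]
      dup <- stats::setNames(rep("0", length(taxa)), taxa)
      dup[ls[[w]]] <- "1"
      cols[[length(cols) + 1L]] <- dup
      col_gain <- c(col_gain, w)
      events[[i]] <- c(events[[i]], "parallel")
    }
  }
  L <- length(cols)
  states <- if (L) do.call(cbind, cols) else
    matrix(character(0), length(taxa), 0L, dimnames = list(taxa, NULL))
  if (L) colnames(states) <- sprintf("sim%03d", seq_len(L))
  if (p_missing > 0 && L) {
    miss <- stats::runif(length(states)) < p_missing
    states[miss] <- "?"
  }
  edge_counts <- stats::setNames(n_ins, as.character(below))
  list(matrix = character_matrix(states, outgroups = outgroups),
       truth = list(edge_counts = edge_counts,
                    gain_node = col_gain,
                    gain_clades = lapply(col_gain, function(v) ls[[v]]),
                    events = events))
}
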