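#' Construct a taxon panel
#'
#' A taxon panel is the ordered set of taxa scored in a presence/absence
#' matrix, together with the subset flagged as outgroups. Outgroups carry the
#' ancestral (absent) state for every marker and anchor the root.
#'
#' @param taxa Character vector of unique taxon labels, in matrix row order.
#' @param outgroups Character vector, subset of `taxa`, possibly empty.
#' @return An object of class `taxon_panel`: a list with elements `taxa` and
#'   `outgroups`.
#' @examples
#' taxon_panel(c("A", "B", "Out"), outgroups = "Out")
#' @export
taxon_panel <- function(taxa, outgroups = character()) {
  taxa <- as.character(taxa)
  outgroups <- as.character(outgroups)
  if (anyDuplicated(taxa)) {
    stop("taxon labels must be unique: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  if (!all(outgroups %in% taxa)) {
    stop("outgroups must be a subset of taxa: ",
         paste(setdiff(outgroups, taxa), collapse = ", "))
  }
  structure(list(taxa = taxa, outgroups = outgroups), class = "taxon_panel")
}

#' @export
print.taxon_panel <- function(x, ...) {
  cat("Taxon panel:", length(x$taxa), "taxa,",
      length(x$outgroups), "outgroup(s)\n")
  invisible(x)
}

MATRIX_STATES <- c("0", "1", "?")

#' Construct a presence/absence character matrix
#'
#' The central container: a taxa-by-loci matrix of insertion states. `"1"`
#' codes a filled site (element present), `"0"` an empty site (element
#' absent), and `"?"` a site that could not be resolved for that taxon (e.g.
#' no amplification). Presence is the derived state; absence is ancestral.
#'
#' @param states Character matrix with taxon labels as rownames and locus ids
#'   as colnames; cells must be `"0"`, `"1"` or `"?"`.
#' @param outgroups Taxa to flag as outgroups (default none).
#' @param loci Optional data frame describing loci, with columns `id`,
#'   `source`, `note`; defaults are synthesised from the column names.
#' @return An object of class `character_matrix` with elements `states`,
#'   `panel` (a [taxon_panel()]) and `loci`.
#' @examples
#' m <- character_matrix(
#'   matrix(c("1", "0", "0", "0"), 2, 2,
#'          dimnames = list(c("A", "B"), c("L1", "L2"))))
#' @export
character_matrix <- function(states, outgroups = character(), loci = NULL) {
  if (!is.matrix(states) || !is.character(states)) {
    stop("`states` must be a character matrix")
  }
  if (is.null(rownames(states)) ||
      (ncol(states) > 0L && is.null(colnames(states)))) {
    stop("`states` must have taxon rownames and locus colnames")
  }
  if (ncol(states) == 0L && is.null(colnames(states))) {
    colnames(states) <- character(0)
  }
  bad <- !(states %in% MATRIX_STATES)
  if (any(bad)) {
    i <- which(bad)[1L]
    rc <- arrayInd(i, dim(states))
    stop(sprintf("illegal state '%s' at taxon '%s', locus '%s'",
                 states[i], rownames(states)[rc[1L]], colnames(states)[rc[2L]]))
  }
  if (anyDuplicated(colnames(states))) {
    stop("locus ids must be unique within a matrix")
  }
  panel <- taxon_panel(rownames(states), outgroups)
  if (is.null(loci)) {
    ids <- colnames(states)
    loci <- data.frame(id = ids, source = rep("unspecified", length(ids)),
                       note = rep("", length(ids)), stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(loci), identical(loci$id, colnames(states)))
    if (is.null(loci$source)) loci$source <- "unspecified"
    if (is.null(loci$note)) loci$note <- ""
  }
  structure(list(states = states, panel = panel, loci = loci),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cl <- classify_characters(x)
  cat("Presence/absence character matrix:",
      nrow(x$states), "taxa x", ncol(x$states), "loci\n")
  cat("  outgroups:", if (length(x$panel$outgroups))
    paste(x$panel$outgroups, collapse = ", ") else "(none)", "\n")
  cat("  characters:", sum(cl$class == "parsimony_informative"), "informative,",
      sum(cl$class == "autapomorphic"), "autapomorphic,",
      sum(cl$class == "constant"), "constant\n")
  invisible(x)
}

#' Number of taxa / loci in a character matrix
#' @param m A [character_matrix()].
#' @return Integer count.
#' @export
n_taxa <- function(m) nrow(m$states)

#' @rdname n_taxa
#' @export
n_loci <- function(m) ncol(m$states)

#' Test two character matrices for equality of content
#'
#' Compares taxa (order included), locus ids and all states. Locus metadata
#' (`source`, `note`) is not compared: the CSV interchange format carries
#' states only.
#'
#' @param a,b [character_matrix()] objects.
#' @return Logical scalar.
#' @export
matrices_identical <- function(a, b) {
  identical(a$panel$taxa, b$panel$taxa) &&
    identical(colnames(a$states), colnames(b$states)) &&
    identical(unname(a$states), unname(b$states))
}

#' Classify characters as constant, autapomorphic or parsimony-informative
#'
#' Unknown (`"?"`) cells never participate: classification is over the known
#' states of each column. A column is *constant* when all known states agree
#' (or when no state is known at all, which is flagged), *autapomorphic* when
#' exactly one taxon carries the minority state, and *parsimony-informative*
#' when at least two taxa carry each state. The three labels partition the
#' loci.
#'
#' @param m A [character_matrix()].
#' @return A data frame with columns `id`, `class` (factor with levels
#'   `constant`, `autapomorphic`, `parsimony_informative`), `n_present`,
#'   `n_absent`, `n_unknown`, and `all_unknown` (logical flag). Columns that
#'   are entirely unknown are classified `constant` with `all_unknown = TRUE`
#'   and a warning.
#' @examples
#' m <- character_matrix(matrix(c("1","0","0","0", "1","1","0","0"), 4, 2,
#'   dimnames = list(LETTERS[1:4], c("L1", "L2"))))
#' classify_characters(m)
#' @export
classify_characters <- function(m) {
  stopifnot(inherits(m, "character_matrix"))
  if (n_loci(m) == 0L) stop("matrix has no loci")
  n1 <- colSums(m$states == "1")
  n0 <- colSums(m$states == "0")
  nu <- colSums(m$states == "?")
  all_unknown <- (n1 + n0) == 0L
  if (any(all_unknown)) {
    warning("column(s) entirely unknown, classified constant: ",
            paste(colnames(m$states)[all_unknown], collapse = ", "))
  }
  mn <- pmin(n1, n0)
  cls <- ifelse(mn == 0L, "constant",
                ifelse(mn == 1L, "autapomorphic", "parsimony_informative"))
  data.frame(
    id = colnames(m$states),
    class = factor(cls, levels = c("constant", "autapomorphic",
                                   "parsimony_informative")),
    n_present = as.integer(n1), n_absent = as.integer(n0),
    n_unknown = as.integer(nu), all_unknown = all_unknown,
    row.names = NULL, stringsAsFactors = FALSE)
}

# Internal: integer encoding used by the scorer (0 absent, 1 present, 2 unknown)
encode_states <- function(m) {
  s <- matrix(match(m$states, MATRIX_STATES) - 1L, nrow(m$states),
              dimnames = dimnames(m$states))
  storage.mode(s) <- "integer"
  s
}
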