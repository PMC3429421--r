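#' Nonparametric bootstrap over characters
#'
#' Each replicate resamples the loci with replacement (keeping the locus
#' count), re-runs the heuristic search on the resampled matrix, and tallies
#' the rooted clades of the first best tree. Replicates whose resample carries
#' no signal (all characters constant) are recorded as failed and skipped.
#' Fully deterministic given `config$seed`.
#'
#' @param m A [character_matrix()].
#' @param reps Number of replicates (>= 1). The published scale for this kind
#'   of analysis is 10,000; 1,000 is comfortable at a desk and has binomial
#'   error below a percentage point for well-supported clades.
#' @param config A [search_config()]; the bootstrap uses its seed,
#'   addition order and rearrangement type.
#' @return An object of class `bootstrap_result`: list with `replicates`,
#'   `n_failed`, `frequencies` (named numeric, clade key -> proportion),
#'   `clades` (list of taxon vectors, parallel to `frequencies`) and
#'   `consensus` (majority-rule, clades with frequency > 0.5).
#' @export
bootstrap <- function(m, reps = 1000L, config = search_config()) {
  stopifnot(inherits(m, "character_matrix"), reps >= 1L)
  L <- n_loci(m)
  set.seed(config$seed)
  tally <- new.env(parent = emptyenv())
  n_failed <- 0L
  rep_config <- config
  rep_config$max_equal_trees <- 1L
  rep_config$collapse_unsupported <- FALSE
  # all randomness lives in the resample: the per-replicate search must not
  # touch the RNG stream
  rep_config$addition_order <- "as_given"
  rep_config$n_starts <- 1L
  for (r in seq_len(reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    mb <- character_matrix(m$states[, idx, drop = FALSE] |>
                             `colnames<-`(paste0("b", seq_len(L))),
                           outgroups = m$panel$outgroups)
    res <- tryCatch(search_mp_tree(mb, rep_config), error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    for (cl in tree_clades(res$trees[[1L]])) {
      k <- clade_key(cl)
      tally[[k]] <- (if (is.null(tally[[k]])) 0L else tally[[k]]) + 1L
    }
  }
  ok <- reps - n_failed
  keys <- sort(ls(tally))
  freq <- vapply(keys, function(k) tally[[k]] / ok, 0)
  clades <- lapply(keys, function(k) strsplit(k, "|", fixed = TRUE)[[1L]])
  maj <- freq > 0.5
  consensus <- build_tree_from_clades(clades[maj], m$panel$taxa)
  structure(list(replicates = reps, n_failed = n_failed,
                 frequencies = freq, clades = clades, consensus = consensus),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Bootstrap:", x$replicates, "replicates (", x$n_failed, "failed ),",
      sum(x$frequencies > 0.5), "majority-rule clades\n")
  invisible(x)
}

#' Bootstrap frequency of a clade
#'
#' @param boot A [bootstrap()] result.
#' @param taxa Taxon labels of the clade.
#' @return Proportion in `[0, 1]` (0 if the clade was never seen).
#' @export
clade_frequency <- function(boot, taxa) {
  k <- clade_key(taxa)
  f <- boot$frequencies[k]
  if (is.na(f)) 0 else unname(f)
}

#' Bootstrap frequencies as a table
#'
#' @param boot A [bootstrap()] result.
#' @param min_freq Report only clades at or above this frequency.
#' @return A data frame with columns `clade`, `n_taxa`, `frequency` and
#'   `percent`, sorted by decreasing frequency.
#' @export
bootstrap_table <- function(boot, min_freq = 0) {
  keep <- boot$frequencies >= min_freq
  out <- data.frame(
    clade = names(boot$frequencies)[keep],
    n_taxa = vapply(boot$clades[keep], length, 0L),
    frequency = unname(boot$frequencies[keep]),
    stringsAsFactors = FALSE)
  out$percent <- round(100 * out$frequency, 1)
  out <- out[order(-out$frequency, out$clade), ]
  rownames(out) <- NULL
  out
}
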