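#' End-to-end marker phylogeny run
#'
#' Matrix in, annotated tree out: reads (or takes) a presence/absence matrix,
#' classifies its characters, finds the most parsimonious Dollo trees, roots
#' them on the outgroups, collapses evidence-free edges, computes ensemble
#' indices, per-branch support counts with likelihood-test significance, and a
#' character bootstrap, then writes the report bundle to `out_dir`:
#'
#' * `tree.nwk` — annotated newick (node labels `boot%/k/p stars`)
#' * `support.tsv` — per-branch table (clade, bootstrap, k, conflicts, p, stars)
#' * `indices.txt` — length, CI/HI/RI, character-class counts
#' * `bootstrap.tsv` — clade frequencies
#' * `run_log.txt` — seed, parameters, package version
#'
#' Deterministic given the seed.
#'
#' @param matrix A [character_matrix()] or path to a matrix CSV.
#' @param out_dir Output directory (created if needed); `NULL` writes nothing.
#' @param outgroups Outgroup taxa (used when `matrix` is a path).
#' @param seed Integer seed for search and bootstrap.
#' @param reps Bootstrap replicates (0 skips the bootstrap).
#' @param alpha Significance thresholds `c(alpha1, alpha2)`.
#' @param rearrangement Branch-swapping type, see [search_config()].
#' @param collapse If `TRUE` (default), report trees with evidence-free edges
#'   collapsed.
#' @return A list (invisibly when writing): `tree` (annotated), `trees` (all
#'   equally-best), `consensus` (strict), `indices`, `support`, `bootstrap`,
#'   `classification`, `length`.
#' @export
run_phylogeny <- function(matrix, out_dir = NULL, outgroups = character(),
                          seed = 1L, reps = 1000L, alpha = c(0.05, 0.01),
                          rearrangement = "nni", collapse = TRUE) {
  m <- if (is.character(matrix)) read_matrix_csv(matrix, outgroups) else matrix
  stopifnot(inherits(m, "character_matrix"))
  cfg <- search_config(seed = seed, rearrangement = rearrangement)
  cl <- suppressWarnings(classify_characters(m))
  res <- search_mp_tree(m, cfg)
  cons <- strict_consensus(res$trees)
  tree <- if (collapse) collapse_unsupported_edges(res$trees[[1L]], m)
    else res$trees[[1L]]
  idx <- ensemble_indices(m, tree)
  sup <- branch_support_counts(m, tree, alpha = alpha)
  boot <- if (reps > 0L) bootstrap(m, reps = reps, config = cfg) else NULL
  annotated <- annotate_tree(tree, sup, boot = boot, m = m)
  out <- list(tree = annotated, trees = res$trees, consensus = cons,
              indices = idx, support = sup, bootstrap = boot,
              classification = cl, length = res$length)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    nwk <- annotated
    nwk$tip.label <- gsub(" ", "_", nwk$tip.label)
    ape::write.tree(nwk, file.path(out_dir, "tree.nwk"))
    sup_out <- sup
    if (!is.null(boot)) {
      sup_out$bootstrap_pct <- vapply(sup$clade, function(k) {
        round(100 * clade_frequency(boot,
                                    strsplit(k, "|", fixed = TRUE)[[1L]]), 1)
      }, 0)
    }
    utils::write.table(sup_out, file.path(out_dir, "support.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(boot)) {
      utils::write.table(bootstrap_table(boot),
                         file.path(out_dir, "bootstrap.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeLines(c(
      sprintf("tree length: %d", idx$length),
      sprintf("CI: %.3f", idx$CI),
      sprintf("HI: %.3f", idx$HI),
      sprintf("RI: %s", if (is.na(idx$RI)) "undefined"
              else sprintf("%.3f", idx$RI)),
      sprintf("loci: %d", n_loci(m)),
      sprintf("parsimony informative: %d",
              sum(cl$class == "parsimony_informative")),
      sprintf("autapomorphic: %d", sum(cl$class == "autapomorphic")),
      sprintf("constant: %d", sum(cl$class == "constant"))
    ), file.path(out_dir, "indices.txt"))
    writeLines(c(
      sprintf("sinephylo %s", as.character(utils::packageVersion("sinephylo"))),
      sprintf("seed: %d", seed),
      sprintf("bootstrap replicates: %d", reps),
      sprintf("rearrangement: %s", rearrangement),
      sprintf("alpha: %g / %g", alpha[1L], alpha[2L]),
      sprintf("collapse unsupported edges: %s", collapse),
      sprintf("equally-best trees found: %d", length(res$trees)),
      sprintf("date: %s", format(Sys.Date()))
    ), file.path(out_dir, "run_log.txt"))
    return(invisible(out))
  }
  out
}

#' Screen repeat annotations for candidate lineage-specific elements
#'
#' Parses a RepeatMasker `.out` file (or takes a hit table), applies the
#' family and length filters, and reports every hit with its fate and the rule
#' that decided it. Optionally extracts primer-design flanks for the
#' survivors.
#'
#' @param hits Path to a `.out` file or a hit data frame.
#' @param fasta Optional path to the contig FASTA (or a named character vector
#'   of contigs) for flank extraction.
#' @param families Target subfamily set; default: names starting `"AluL"`.
#' @param min_len Strict length threshold in bp (default 280).
#' @param flank Flank length in bp.
#' @param out_dir Optional output directory for `candidates.tsv` and
#'   `flanks.fa`.
#' @return A list with `table` (all hits with `kept` and `rule` columns),
#'   `candidates` (surviving hits) and `flanks` (list, when sequence given).
#' @export
run_screen <- function(hits, fasta = NULL, families = NULL, min_len = 280L,
                       flank = 50L, out_dir = NULL) {
  h <- if (is.character(hits)) parse_repeatmasker_out(hits) else hits
  fam_ok <- if (is.null(families)) startsWith(h$family, "AluL")
    else h$family %in% families
  len_ok <- h$length > min_len
  h$kept <- fam_ok & len_ok
  h$rule <- ifelse(!fam_ok, "family not in target set",
                   ifelse(!len_ok, sprintf("length <= %d bp", min_len),
                          "kept"))
  cand <- filter_candidates(h[, setdiff(names(h), c("kept", "rule"))],
                            families = families, min_len = min_len)
  flanks <- NULL
  if (!is.null(fasta) && nrow(cand)) {
    contigs <- if (is.character(fasta) && length(fasta) == 1L &&
                   file.exists(fasta)) {
      s <- Biostrings::readDNAStringSet(fasta)
      stats::setNames(as.character(s), names(s))
    } else fasta
    flanks <- lapply(seq_len(nrow(cand)), function(i) {
      extract_flanks(contigs[[cand$contig[i]]], cand[i, ], flank = flank)
    })
    names(flanks) <- sprintf("%s:%d-%d", cand$contig, cand$begin, cand$end)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(h, file.path(out_dir, "candidates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(flanks)) {
      fa <- unlist(lapply(names(flanks), function(nm) {
        c(paste0(">", nm, "|upstream"), flanks[[nm]]$upstream,
          paste0(">", nm, "|downstream"), flanks[[nm]]$downstream)
      }))
      writeLines(fa, file.path(out_dir, "flanks.fa"))
    }
  }
  list(table = h, candidates = cand, flanks = flanks)
}
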