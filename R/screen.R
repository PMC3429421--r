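# In-silico analogs of the wet-lab screening stages: parse repeat annotations,
# filter for candidate lineage-specific elements, extract primer-design
# flanks, call filled/empty sites from amplicon sizes, and classify
# confounding events at loci whose amplification pattern conflicts with the
# tree. Coordinates are 1-based inclusive throughout (the RepeatMasker
# convention).

#' Parse a RepeatMasker `.out` annotation file
#'
#' Expects the standard layout: two header lines and a blank line, then one
#' whitespace-delimited record per repeat hit. Orientation `C` (complement)
#' maps to strand `-`.
#'
#' @param path Path to a `.out` file.
#' @return A data frame of repeat hits: `contig`, `begin`, `end`, `strand`,
#'   `family`, `divergence`, `length` (= end - begin + 1), `score`.
#' @export
parse_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  body <- if (length(lines) > 3L) lines[-(1:3)] else character(0)
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) {
    return(data.frame(contig = character(0), begin = integer(0),
                      end = integer(0), strand = character(0),
                      family = character(0), divergence = numeric(0),
                      length = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    if (length(f) < 11L) {
      stop("malformed RepeatMasker record at line ", i + 3L, ": ", body[i])
    }
    begin <- suppressWarnings(as.integer(f[6L]))
    end <- suppressWarnings(as.integer(f[7L]))
    if (is.na(begin) || is.na(end) || begin > end) {
      stop("bad coordinates at line ", i + 3L, ": ", body[i])
    }
    data.frame(contig = f[5L], begin = begin, end = end,
               strand = if (f[9L] == "C") "-" else "+",
               family = f[10L],
               divergence = suppressWarnings(as.numeric(f[2L])),
               length = end - begin + 1L,
               score = suppressWarnings(as.numeric(f[1L])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter repeat hits for candidate lineage-specific elements
#'
#' Keeps hits whose repeat family belongs to the target subfamily set and
#' whose length is strictly greater than `min_len` (the screening rule for
#' near-full-length elements; truncated copies make poor PCR markers).
#' Idempotent.
#'
#' @param hits A data frame from [parse_repeatmasker_out()].
#' @param families Character vector of family names to keep; by default any
#'   family whose name starts with `"AluL"` (the lemur-specific subfamilies).
#' @param min_len Minimum length in bp, strict inequality (default 280).
#' @return The filtered hit data frame.
#' @export
filter_candidates <- function(hits, families = NULL, min_len = 280L) {
  fam_ok <- if (is.null(families)) {
    startsWith(hits$family, "AluL")
  } else {
    hits$family %in% families
  }
  hits[fam_ok & hits$length > min_len, , drop = FALSE]
}

#' Extract flanking sequence around a repeat hit
#'
#' Returns the upstream and downstream flanks of an element, for primer
#' design against orthologous sequence. Flanks are truncated at contig ends
#' and flagged.
#'
#' @param contig_seq The contig sequence: a character scalar or a
#'   `Biostrings::DNAString`.
#' @param hit A single-row hit (list or data frame row) with `begin`, `end`.
#' @param flank Flank length in bp (>= 1).
#' @return A list with `upstream`, `downstream` (character), and
#'   `truncated_upstream`, `truncated_downstream` flags.
#' @export
extract_flanks <- function(contig_seq, hit, flank = 50L) {
  stopifnot(flank >= 1L)
  seq <- as.character(contig_seq)
  len <- nchar(seq)
  begin <- as.integer(hit$begin); end <- as.integer(hit$end)
  if (begin < 1L || end > len || begin > end) {
    stop("hit coordinates [", begin, ", ", end, "] outside contig of length ",
         len)
  }
  up_start <- max(1L, begin - flank)
  dn_end <- min(len, end + flank)
  list(upstream = substr(seq, up_start, begin - 1L),
       downstream = substr(seq, end + 1L, dn_end),
       truncated_upstream = up_start > begin - flank,
       truncated_downstream = dn_end < end + flank)
}

#' Call filled/empty sites from PCR product sizes
#'
#' A product near the empty-site size means no element (`"0"`); a product near
#' empty-site size plus the element length means the element is present
#' (`"1"`); no product, or a size outside both windows, is unresolved (`"?"`).
#' Total: every observation maps to exactly one state.
#'
#' @param observations Data frame with columns `taxon` and `product_len`
#'   (bp; `NA` for no amplification).
#' @param empty_size Expected empty-site product size in bp.
#' @param element_size Element length added by a filled site (~300 bp for an
#'   Alu).
#' @param tol Size-calling tolerance in bp; the two windows must not overlap
#'   (`2 * tol < element_size`).
#' @return Named character vector of states over taxa.
#' @export
call_presence <- function(observations, empty_size, element_size, tol = 20L) {
  if (2L * tol >= element_size) {
    stop("tolerance too large: presence and absence windows overlap")
  }
  if (empty_size <= 0L || element_size <= 0L) {
    stop("sizes must be positive")
  }
  lens <- observations$product_len
  state <- rep("?", nrow(observations))
  state[!is.na(lens) & abs(lens - empty_size) <= tol] <- "0"
  state[!is.na(lens) & abs(lens - (empty_size + element_size)) <= tol] <- "1"
  stats::setNames(state, observations$taxon)
}

#' Classify a confounding event at a multi-lineage locus
#'
#' When two lineages both carry an element inside the same amplicon, the
#' element may be one orthologous insertion (shared ancestry) or two
#' independent insertions at nearly the same position (a near-parallel event,
#' which must be recoded as two characters). The verdict is a pure function of
#' the evidence: subfamily identity, insertion-point offset, and target-site
#' duplication (TSD) compatibility.
#'
#' * same subfamily, offset <= `offset_tol`, TSDs compatible ->
#'   `orthologous_same_element`
#' * different subfamilies, or offset > `offset_tol` ->
#'   `near_parallel_independent`
#' * same subfamily and position but incompatible TSDs -> `other_indel`
#'
#' @param events Data frame with one row per taxon carrying the element:
#'   columns `taxon`, `subfamily`, `position` (insertion point, bp, on a
#'   common flank coordinate system), `tsd` (target site duplication sequence,
#'   `NA` if unknown).
#' @param offset_tol Positional tolerance in bp for "nearly the same
#'   location" (default 50).
#' @return A list of class `confound_call`: `verdict`, `evidence` (list with
#'   `same_subfamily`, `max_offset`, `tsd_match`), and `groups` (split of
#'   taxa by subfamily, for recoding).
#' @export
classify_confounding <- function(events, offset_tol = 50L) {
  if (nrow(events) < 2L) stop("need elements from at least 2 taxa to classify")
  subs <- unique(events$subfamily)
  same_sub <- length(subs) == 1L
  max_offset <- diff(range(events$position))
  tsds <- events$tsd[!is.na(events$tsd)]
  tsd_match <- length(tsds) < 2L || length(unique(toupper(tsds))) == 1L
  verdict <- if (!same_sub || max_offset > offset_tol) {
    "near_parallel_independent"
  } else if (tsd_match) {
    "orthologous_same_element"
  } else {
    "other_indel"
  }
  structure(list(
    verdict = verdict,
    evidence = list(same_subfamily = same_sub,
                    max_offset = as.integer(max_offset),
                    tsd_match = tsd_match),
    groups = split(events$taxon, events$subfamily)),
    class = "confound_call")
}

#' @export
print.confound_call <- function(x, ...) {
  cat("Confounding-event verdict:", x$verdict, "\n  same subfamily:",
      x$evidence$same_subfamily, " max offset:", x$evidence$max_offset,
      "bp  TSD match:", x$evidence$tsd_match, "\n")
  invisible(x)
}

#' Recode a near-parallel independent insertion into two characters
#'
#' Splits the column of `locus_id` into one column per independent insertion:
#' the original id keeps the first group's taxa, and each further group gets a
#' suffixed id (`A`, `B`, ...), present only in its own taxa. This is the
#' recoding that turns one apparently conflicting locus into two clean
#' lineage-specific characters.
#'
#' @param m A [character_matrix()].
#' @param locus_id Column to recode.
#' @param groups List of taxon-label vectors, one per independent insertion
#'   (e.g. the `groups` field of a [classify_confounding()] call).
#' @return A new [character_matrix()] with `length(groups) - 1` extra columns.
#' @export
recode_near_parallel <- function(m, locus_id, groups) {
  j <- match(locus_id, colnames(m$states))
  if (is.na(j)) stop("locus not in matrix: ", locus_id)
  stopifnot(length(groups) >= 2L)
  old <- m$states[, j]
  cols <- lapply(groups, function(g) {
    s <- old
    s[s == "1"] <- "0"             # keep ?/0 as observed, reassign presences
    s[rownames(m$states) %in% g] <- "1"
    s
  })
  ids <- c(locus_id, paste0(locus_id, LETTERS[seq_len(length(groups) - 1L)]))
  states <- m$states
  states[, j] <- cols[[1L]]
  extra <- do.call(cbind, cols[-1L])
  colnames(extra) <- ids[-1L]
  states <- cbind(states[, seq_len(j), drop = FALSE], extra,
                  if (j < ncol(states)) states[, (j + 1L):ncol(states),
                                               drop = FALSE])
  character_matrix(states, outgroups = m$panel$outgroups)
}
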