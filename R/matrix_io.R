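#' Read a presence/absence matrix from CSV
#'
#' The interchange format is a rectangular comma-separated table: header row
#' of locus ids, first column of taxon labels, cells in `{0, 1, ?}`. Unknown
#' cells are kept as unknown, never imputed.
#'
#' @param path Path to a CSV file.
#' @param outgroups Taxa to flag as outgroups in the resulting panel (the CSV
#'   itself carries no panel metadata).
#' @return A [character_matrix()].
#' @seealso [write_matrix_csv()]
#' @export
read_matrix_csv <- function(path, outgroups = character()) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("matrix CSV needs a header and at least one row")
  fields <- strsplit(lines, ",", fixed = TRUE)
  # unquote simple quoted fields as written by write_matrix_csv
  fields <- lapply(fields, function(f) gsub('^"|"$', "", f))
  width <- length(fields[[1L]])
  ragged <- which(vapply(fields, length, 0L) != width)
  if (length(ragged)) {
    stop("ragged CSV: line ", ragged[1L], " has ",
         length(fields[[ragged[1L]]]), " fields, expected ", width)
  }
  ids <- fields[[1L]][-1L]
  rows <- fields[-1L]
  taxa <- vapply(rows, `[`, "", 1L)
  states <- do.call(rbind, lapply(rows, function(r) r[-1L]))
  dimnames(states) <- list(taxa, ids)
  bad <- !(states %in% MATRIX_STATES)
  if (any(bad)) {
    i <- which(bad)[1L]
    rc <- arrayInd(i, dim(states))
    stop(sprintf("illegal cell '%s' at row '%s', column '%s'",
                 states[i], taxa[rc[1L]], ids[rc[2L]]))
  }
  character_matrix(states, outgroups = outgroups)
}

#' Write a presence/absence matrix to CSV
#'
#' @param m A [character_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  stopifnot(inherits(m, "character_matrix"))
  quote_if <- function(x) ifelse(grepl('[,"]', x), paste0('"', x, '"'), x)
  header <- paste(c("taxon", quote_if(colnames(m$states))), collapse = ",")
  body <- vapply(seq_len(nrow(m$states)), function(i) {
    paste(c(quote_if(rownames(m$states)[i]), m$states[i, ]), collapse = ",")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

nexus_quote <- function(x) {
  ifelse(grepl("[^A-Za-z0-9_.]", x),
         paste0("'", gsub("'", "''", x), "'"), x)
}

#' Write a matrix as NEXUS with Dollo character-type assumptions
#'
#' Emits TAXA and CHARACTERS blocks (`symbols="01"`, `missing=?`) and an
#' ASSUMPTIONS block declaring every character `Dollo.up`, the character type
#' under which presence can be gained once and lost any number of times,
#' matching the biology of retrotransposon insertions.
#'
#' @param m A [character_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_nexus_matrix()]
#' @export
write_nexus <- function(m, path) {
  stopifnot(inherits(m, "character_matrix"))
  nt <- n_taxa(m); nc <- n_loci(m)
  labs <- nexus_quote(rownames(m$states))
  pad <- max(nchar(labs))
  rows <- vapply(seq_len(nt), function(i) {
    sprintf("    %-*s %s", pad, labs[i], paste(m$states[i, ], collapse = ""))
  }, "")
  out <- c(
    "#NEXUS",
    "",
    "BEGIN TAXA;",
    sprintf("  DIMENSIONS NTAX=%d;", nt),
    "  TAXLABELS",
    paste0("    ", labs),
    "  ;",
    "END;",
    "",
    "BEGIN CHARACTERS;",
    sprintf("  DIMENSIONS NCHAR=%d;", nc),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
    "  MATRIX",
    rows,
    "  ;",
    "END;",
    "",
    "BEGIN ASSUMPTIONS;",
    sprintf("  CTYPE Dollo.up: 1-%d;", nc),
    "END;"
  )
  con <- file(path, "w")
  on.exit(close(con))
  tryCatch(writeLines(out, con),
           error = function(e) stop("cannot write NEXUS to ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Read a NEXUS character matrix written by [write_nexus()]
#'
#' A reader for the dialect this package emits (quoted labels, one matrix row
#' per taxon, `0/1/?` symbols). Locus ids are not stored in NEXUS; columns are
#' named `c1..cN`, or taken from `locus_ids` when supplied.
#'
#' @param path Path to a NEXUS file.
#' @param outgroups Outgroup taxa for the panel.
#' @param locus_ids Optional character vector of column names.
#' @return A [character_matrix()].
#' @export
read_nexus_matrix <- function(path, outgroups = character(), locus_ids = NULL) {
  lines <- readLines(path)
  i0 <- grep("^\\s*MATRIX\\s*$", lines)
  if (length(i0) != 1L) stop("no MATRIX block found in ", path)
  rows <- list()
  for (ln in lines[(i0 + 1L):length(lines)]) {
    ln <- trimws(ln)
    if (ln == ";" || ln == "") break
    if (startsWith(ln, "'")) {
      m <- regmatches(ln, regexec("^'((?:[^']|'')*)'\\s+(\\S+)$", ln))[[1L]]
      if (length(m) != 3L) stop("unparseable MATRIX row: ", ln)
      taxon <- gsub("''", "'", m[2L]); states <- m[3L]
    } else {
      parts <- strsplit(ln, "\\s+")[[1L]]
      if (length(parts) != 2L) stop("unparseable MATRIX row: ", ln)
      taxon <- parts[1L]; states <- parts[2L]
    }
    rows[[taxon]] <- strsplit(states, "")[[1L]]
  }
  states <- do.call(rbind, rows)
  if (is.null(locus_ids)) locus_ids <- paste0("c", seq_len(ncol(states)))
  dimnames(states) <- list(names(rows), locus_ids)
  character_matrix(states, outgroups = outgroups)
}
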