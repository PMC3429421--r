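# The 24-taxon lemur Alu fixture: a presence/absence matrix reconstructed
# from per-clade locus counts printed for a published Alu-insertion phylogeny
# of Lemuriformes. Only loci whose counts are printed in running text are
# included (95 of the 138 assayed loci); nodes whose counts were shown only in
# the figure get no fixture loci, so the fixture tree has polytomies there.
# Every fixture column is clade-consistent with the published topology.

LEMUR_OUTGROUPS <- c("Galago senegalensis", "Homo sapiens")

lemur_taxa <- function() {
  c("Lemur catta", "Eulemur coronatus", "Eulemur albifrons",
    "Eulemur collaris", "Eulemur fulvus", "Eulemur sanfordi",
    "Eulemur macaco", "Eulemur flavifrons", "Eulemur mongoz",
    "Eulemur rubriventer", "Hapalemur griseus", "Varecia variegata rubra",
    "Varecia variegata variegata", "Microcebus murinus", "Mirza coquereli",
    "Cheirogaleus medius", "Lepilemur ruficaudatus", "Avahi laniger",
    "Propithecus coquereli", "Propithecus coronatus", "Propithecus verreauxi",
    "Daubentonia madagascariensis", "Galago senegalensis", "Homo sapiens")
}

#' The 24-taxon lemur panel
#'
#' All 22 lemur species of the fixture plus the two outgroups (a galago and
#' human).
#'
#' @return A [taxon_panel()].
#' @export
lemur_panel <- function() taxon_panel(lemur_taxa(), LEMUR_OUTGROUPS)

# Named clades of the fixture topology (taxon label sets).
lemur_clades <- function() {
  taxa <- lemur_taxa()
  eulemur <- grep("^Eulemur", taxa, value = TRUE)
  macaco_fulvus <- c("Eulemur macaco", "Eulemur flavifrons",
                     "Eulemur albifrons", "Eulemur collaris",
                     "Eulemur fulvus", "Eulemur sanfordi")
  lemur_hapalemur <- c("Lemur catta", "Hapalemur griseus")
  lemuridae <- c(lemur_hapalemur, eulemur, "Varecia variegata rubra",
                 "Varecia variegata variegata")
  indriidae <- c("Avahi laniger", "Propithecus coquereli",
                 "Propithecus coronatus", "Propithecus verreauxi")
  cheiro_lepi <- c("Lepilemur ruficaudatus", "Microcebus murinus",
                   "Mirza coquereli", "Cheirogaleus medius")
  lemurs <- setdiff(taxa, LEMUR_OUTGROUPS)
  list(
    lemuriformes = lemurs,
    non_daubentonia = setdiff(lemurs, "Daubentonia madagascariensis"),
    lepilemuridae_cheirogaleidae = cheiro_lepi,
    indriidae_lemuridae = c(indriidae, lemuridae),
    lemuridae = lemuridae,
    lemur_hapalemur = lemur_hapalemur,
    lemur_hapalemur_eulemur = c(lemur_hapalemur, eulemur),
    macaco_fulvus = macaco_fulvus,
    microcebus_mirza = c("Microcebus murinus", "Mirza coquereli"),
    indriidae = indriidae)
}

# locus counts per clade, with the real locus ids where they are known
lemur_fixture_spec <- function() {
  list(
    lemuriformes = list(n = 10L, ids = c("Str71B", sprintf("Lf%02d", 2:10))),
    non_daubentonia = list(n = 6L, ids = sprintf("Nd%02d", 1:6)),
    lepilemuridae_cheirogaleidae = list(n = 1L, ids = "MmM97"),
    indriidae_lemuridae = list(n = 1L, ids = "LI1"),
    lemuridae = list(n = 10L, ids = c("Em6", sprintf("Ld%02d", 2:10))),
    lemur_hapalemur = list(n = 6L, ids = sprintf("Lh%02d", 1:6)),
    lemur_hapalemur_eulemur = list(n = 8L, ids = sprintf("Lhe%02d", 1:8)),
    macaco_fulvus = list(n = 6L, ids = sprintf("Mf%02d", 1:6)),
    microcebus_mirza = list(n = 19L, ids = c("MmA27", sprintf("Mm%02d", 2:19))),
    indriidae = list(n = 6L, ids = c("PcC1", "PcC2", sprintf("Ind%02d", 3:6))))
}

lemur_autapomorphies <- function() {
  list(
    "Lemur catta" = c("Lc01", "Lc02", "Lc03"),
    "Eulemur macaco" = c("Ema01", "Ema02"),
    "Microcebus murinus" = c("Str59", sprintf("Mmu%02d", 2:16)),
    "Avahi laniger" = "MmA2c")
}

#' Build the 24-taxon, 95-locus lemur fixture matrix
#'
#' Reconstructs, from published per-clade locus counts, the presence/absence
#' matrix of lemur-specific Alu insertions: 73 parsimony-informative columns
#' spread over 10 nested clades plus 22 autapomorphic columns, all absent in
#' both outgroups and all clade-consistent with the published topology (so the
#' matrix is homoplasy-free: one Dollo step per column on that tree).
#'
#' @return A [character_matrix()] (24 taxa x 95 loci).
#' @examples
#' m <- build_lemur_fixture()
#' classify_characters(m)
#' @export
build_lemur_fixture <- function() {
  taxa <- lemur_taxa()
  clades <- lemur_clades()
  spec <- lemur_fixture_spec()
  cols <- list()
  ids <- character(0)
  src <- character(0)
  for (nm in names(spec)) {
    clade <- clades[[nm]]
    for (id in spec[[nm]]$ids) {
      s <- stats::setNames(rep("0", length(taxa)), taxa)
      s[clade] <- "1"
      cols[[length(cols) + 1L]] <- s
      ids <- c(ids, id)
      src <- c(src, nm)
    }
  }
  for (taxon in names(lemur_autapomorphies())) {
    for (id in lemur_autapomorphies()[[taxon]]) {
      s <- stats::setNames(rep("0", length(taxa)), taxa)
      s[taxon] <- "1"
      cols[[length(cols) + 1L]] <- s
      ids <- c(ids, id)
      src <- c(src, paste0("autapomorphy:", taxon))
    }
  }
  states <- do.call(cbind, cols)
  colnames(states) <- ids
  loci <- data.frame(id = ids, source = "fixture", note = src,
                     stringsAsFactors = FALSE)
  character_matrix(states, outgroups = LEMUR_OUTGROUPS, loci = loci)
}

#' The fixture reference topology
#'
#' The rooted tree whose internal nodes are exactly the ten fixture clades
#' (polytomies where the fixture carries no resolving loci), with the two
#' outgroups attached at the root.
#'
#' @return A rooted `phylo` tree on the 24-taxon panel.
#' @export
lemur_reference_tree <- function() {
  build_tree_from_clades(lemur_clades(), lemur_taxa())
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a synthetic genome + RepeatMasker fixture
#'
#' Generates random-sequence contigs, implants repeat elements of given
#' families and lengths at random non-overlapping positions, and returns the
#' contigs, the matching RepeatMasker-format annotation rows, and a truth
#' table. The `lineage` labels record which simulated lineage carries each
#' element (plumbing for screening tests; the screen itself only sees the
#' reference contigs and annotations).
#'
#' @param implants Data frame with columns `family`, `length`, `lineage`.
#' @param n_contigs Number of contigs.
#' @param contig_len Length of each contig in bp (must exceed every implant).
#' @param seed Integer seed.
#' @param max_tries Placement retries before giving up on overlap-free layout.
#' @return A list with `contigs` (named character vector), `hits` (annotation
#'   data frame in [parse_repeatmasker_out()] layout) and `truth` (implants
#'   with assigned `contig`, `begin`, `end`).
#' @export
build_genome_fixture <- function(implants, n_contigs = 3L, contig_len = 5000L,
                                 seed = 1L, max_tries = 100L) {
  stopifnot(all(implants$length < contig_len))
  set.seed(seed)
  contigs <- stats::setNames(
    vapply(seq_len(n_contigs), function(i) random_dna(contig_len), ""),
    sprintf("contig%02d", seq_len(n_contigs)))
  placed <- list()
  n_imp <- nrow(implants)
  truth <- implants
  truth$contig <- rep(NA_character_, n_imp)
  truth$begin <- rep(NA_integer_, n_imp)
  truth$end <- rep(NA_integer_, n_imp)
  if (n_imp > 0L) for (i in seq_len(n_imp)) {
    len <- implants$length[i]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ctg <- sample(names(contigs), 1L)
      begin <- sample.int(contig_len - len + 1L, 1L)
      end <- begin + len - 1L
      clash <- any(vapply(placed, function(p) {
        p$contig == ctg && begin <= p$end && end >= p$begin
      }, TRUE))
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place implant ", i, " without overlap")
    placed[[length(placed) + 1L]] <- list(contig = ctg, begin = begin,
                                          end = end)
    truth$contig[i] <- ctg; truth$begin[i] <- begin; truth$end[i] <- end
    element <- random_dna(len)
    substr(contigs[[ctg]], begin, end) <- element
  }
  hits <- data.frame(
    contig = truth$contig, begin = truth$begin, end = truth$end,
    strand = rep("+", n_imp), family = truth$family,
    divergence = round(stats::runif(n_imp, 1, 15), 1),
    length = truth$end - truth$begin + 1L,
    score = round(stats::runif(n_imp, 200, 2000)),
    stringsAsFactors = FALSE)
  list(contigs = contigs, hits = hits, truth = truth)
}

#' Write a genome fixture to FASTA and RepeatMasker `.out` files
#'
#' @param fx A [build_genome_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of paths (`fasta`, `out`), invisibly.
#' @export
write_genome_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "contigs.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(fx$contigs), fasta)
  out <- file.path(dir, "hits.out")
  header <- c(
    paste("   SW   perc perc perc  query     position in query    ",
          "matching  repeat           position in repeat"),
    paste("score   div. del. ins.  sequence  begin  end   (left)  ",
          "repeat    class/family      begin end (left)  ID"),
    "")
  recs <- if (nrow(fx$hits)) {
    sprintf("%5.0f %6.1f  0.0  0.0  %s %6d %6d (%d) %s %-12s SINE/Alu %6d %4d (0) %d",
            fx$hits$score, fx$hits$divergence, fx$hits$contig, fx$hits$begin,
            fx$hits$end, 0L, "+", fx$hits$family, 1L, fx$hits$length,
            seq_len(nrow(fx$hits)))
  } else character(0)
  writeLines(c(header, recs), out)
  invisible(list(fasta = fasta, out = out))
}

#' Aligned-amplicon fixture reproducing a near-parallel insertion
#'
#' Emulates the classic confounding case: two families carry Alu elements of
#' different subfamilies inserted a few bp apart inside the same amplicon, so
#' PCR alone scores them as one shared insertion. The classifier must call the
#' event `near_parallel_independent`, after which the locus is recoded into
#' two lineage-specific characters (the MmA20 -> MmA20 + MmA20A pattern).
#'
#' @param offset Insertion-point offset in bp between the two elements
#'   (default 4).
#' @param same_subfamily If `TRUE`, builds the orthologous variant instead
#'   (same subfamily, zero offset, matching TSDs).
#' @return A list with `events` (input for [classify_confounding()]),
#'   `groups` (taxa per independent insertion) and `locus_id`.
#' @export
inject_confounder_fixture <- function(offset = 4L, same_subfamily = FALSE) {
  cheiro <- c("Microcebus murinus", "Mirza coquereli", "Cheirogaleus medius")
  indri <- c("Avahi laniger", "Propithecus coquereli",
             "Propithecus coronatus", "Propithecus verreauxi")
  if (same_subfamily) {
    events <- data.frame(
      taxon = c(cheiro, indri),
      subfamily = "AluL1",
      position = 120L,
      tsd = "AGCTTAGGCAATT",
      stringsAsFactors = FALSE)
  } else {
    events <- data.frame(
      taxon = c(cheiro, indri),
      subfamily = c(rep("AluL1", length(cheiro)), rep("AluL8", length(indri))),
      position = c(rep(120L, length(cheiro)),
                   rep(120L + offset, length(indri))),
      tsd = c(rep("AGCTTAGGCAATT", length(cheiro)),
              rep("TTGACCA", length(indri))),
      stringsAsFactors = FALSE)
  }
  list(events = events,
       groups = list(cheirogaleidae = cheiro, indriidae = indri),
       locus_id = "MmA20")
}
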