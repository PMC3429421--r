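test_that("RepeatMasker parsing handles empty bodies, records and orientation", {
  fx <- build_genome_fixture(data.frame(family = character(0),
                                        length = integer(0),
                                        lineage = character(0)), seed = 1)
  dir <- withr::local_tempdir()
  p <- write_genome_fixture(fx, dir)
  expect_identical(nrow(parse_repeatmasker_out(p$out)), 0L)

  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c("h1", "h2", "",
    " 1200  3.1  0.0  0.0  contig01   101   400 (4600) +  AluL1  SINE/Alu  1 300 (0) 1",
    "  900 12.0  0.0  0.0  contig01  1000  1280 (3720) C  AluJb  SINE/Alu  1 281 (0) 2",
    "  700  5.5  0.0  0.0  contig02    50   329 (4671) +  AluL2  SINE/Alu  1 280 (0) 3"), f)
  h <- parse_repeatmasker_out(f)
  expect_identical(nrow(h), 3L)
  expect_identical(h$begin, c(101L, 1000L, 50L))
  expect_identical(h$length, c(300L, 281L, 280L))
  expect_identical(h$strand, c("+", "-", "+"))
  writeLines(c("h1", "h2", "", "garbage row"), f)
  expect_error(parse_repeatmasker_out(f), "line 4")
})

test_that("candidate filter is strict on length, family-aware and idempotent", {
  hits <- data.frame(
    contig = "c", begin = 1L, end = c(280L, 281L, 300L, 300L),
    strand = "+", family = c("AluL1", "AluL1", "AluJo", "AluL5"),
    divergence = 1, length = c(280L, 281L, 300L, 300L), score = 100,
    stringsAsFactors = FALSE)
  kept <- filter_candidates(hits, min_len = 280L)
  expect_identical(kept$length, c(281L, 300L))
  expect_identical(kept$family, c("AluL1", "AluL5"))
  expect_identical(filter_candidates(kept, min_len = 280L), kept)
})

test_that("flank extraction truncates at contig ends and errors off-contig", {
  seq <- paste(rep("ACGT", 25), collapse = "")   # 100 bp
  hit <- list(begin = 41L, end = 60L)
  fl <- extract_flanks(seq, hit, flank = 20L)
  expect_identical(nchar(fl$upstream), 20L)
  expect_identical(nchar(fl$downstream), 20L)
  expect_false(fl$truncated_upstream || fl$truncated_downstream)
  expect_identical(paste0(fl$upstream, substr(seq, 41, 60), fl$downstream),
                   substr(seq, 21, 80))
  fl2 <- extract_flanks(seq, list(begin = 11L, end = 30L), flank = 50L)
  expect_identical(nchar(fl2$upstream), 10L)
  expect_true(fl2$truncated_upstream)
  expect_error(extract_flanks(seq, list(begin = 90L, end = 120L)), "outside")
})

test_that("flanks of implanted elements match the recorded insertion context", {
  imp <- data.frame(family = "AluL1", length = 300L, lineage = "lemur")
  fx <- build_genome_fixture(imp, n_contigs = 1L, contig_len = 2000L, seed = 8)
  tr <- fx$truth[1L, ]
  fl <- extract_flanks(fx$contigs[[tr$contig]], tr, flank = 30L)
  expect_identical(fl$upstream,
                   substr(fx$contigs[[tr$contig]], tr$begin - 30L,
                          tr$begin - 1L))
  expect_identical(fl$downstream,
                   substr(fx$contigs[[tr$contig]], tr$end + 1L, tr$end + 30L))
})

test_that("presence calling is total and follows the size windows", {
  obs <- data.frame(taxon = c("A", "B", "C", "D"),
                    product_len = c(200L, 500L, 350L, NA))
  st <- call_presence(obs, empty_size = 200L, element_size = 300L, tol = 20L)
  expect_identical(unname(st), c("0", "1", "?", "?"))
  expect_identical(length(st), nrow(obs))
  expect_error(call_presence(obs, empty_size = 200L, element_size = 30L,
                             tol = 20L), "overlap")
})

test_that("confound classification follows the evidence rules", {
  fx <- inject_confounder_fixture()
  call <- classify_confounding(fx$events)
  expect_identical(call$verdict, "near_parallel_independent")
  same <- inject_confounder_fixture(same_subfamily = TRUE)
  expect_identical(classify_confounding(same$events)$verdict,
                   "orthologous_same_element")
  # same subfamily but far apart is still independent
  ev <- same$events
  ev$position[1:3] <- ev$position[1:3] + 500L
  expect_identical(classify_confounding(ev)$verdict,
                   "near_parallel_independent")
  # same subfamily, same spot, clashing TSDs: some other indel
  ev2 <- same$events
  ev2$tsd[1:3] <- "GGGGGGG"
  expect_identical(classify_confounding(ev2)$verdict, "other_indel")
  expect_error(classify_confounding(fx$events[1L, , drop = FALSE]),
               "at least 2")
})

test_that("near-parallel recoding splits one column into two clean ones", {
  m <- build_lemur_fixture()
  fx <- inject_confounder_fixture()
  # fake the pre-sequencing state: one column present in both families
  states <- cbind(m$states,
                  MmA20 = ifelse(m$panel$taxa %in% unlist(fx$groups), "1", "0"))
  rownames(states) <- m$panel$taxa
  m2 <- character_matrix(states, outgroups = m$panel$outgroups)
  m3 <- recode_near_parallel(m2, "MmA20", fx$groups)
  expect_identical(n_loci(m3), n_loci(m2) + 1L)
  expect_setequal(rownames(m3$states)[m3$states[, "MmA20"] == "1"],
                  fx$groups[[1L]])
  expect_setequal(rownames(m3$states)[m3$states[, "MmA20A"] == "1"],
                  fx$groups[[2L]])
})

test_that("the screen keeps exactly the implanted truth subset", {
  imp <- data.frame(
    family = c("AluL1", "AluL2", "AluL1", "AluJb", "AluL3", "AluL4"),
    length = c(300L, 281L, 280L, 310L, 150L, 295L),
    lineage = c("lemur", "lemur", "lemur", "ancient", "lemur", "microcebus"),
    stringsAsFactors = FALSE)
  fx <- build_genome_fixture(imp, seed = 3)
  dir <- withr::local_tempdir()
  p <- write_genome_fixture(fx, dir)
  res <- run_screen(p$out, fasta = p$fasta, min_len = 280L, out_dir = dir)
  want <- fx$truth[startsWith(fx$truth$family, "AluL") &
                     fx$truth$length > 280L, ]
  expect_identical(nrow(res$candidates), nrow(want))
  expect_setequal(sprintf("%s:%d", res$candidates$contig,
                          res$candidates$begin),
                  sprintf("%s:%d", want$contig, want$begin))
  expect_true(file.exists(file.path(dir, "candidates.tsv")))
  expect_identical(length(res$flanks), nrow(want))
})
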