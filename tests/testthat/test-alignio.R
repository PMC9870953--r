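test_that("FASTA reading enforces the alignment contract", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTAT"), fa)
  aln <- readAlignedFasta(fa)
  expect_s4_class(aln, "AlignedSeqSet")
  expect_equal(length(aln), 2L)
  expect_equal(seqLength(aln), 10L)

  writeLines(c(">a", "ACGT", ">a", "ACGA"), fa)
  expect_error(readAlignedFasta(fa), "duplicate sample ids")

  writeLines(c(">a", "ACGT", ">b", "ACG"), fa)
  expect_error(readAlignedFasta(fa), "unequal sequence lengths for b")

  writeLines(c("ACGT", ">b", "ACGT"), fa)
  expect_error(readAlignedFasta(fa), "line 1")
})

test_that("the packaged study fixture round-trips through FASTA", {
  fx <- makePaperFixture(seed = 1)
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeAlignedFasta(fx$seqs, fa)
  back <- readAlignedFasta(fa)
  expect_equal(length(back), 119L)
  expect_equal(seqLength(back), 658L)
  expect_identical(as.character(back), as.character(fx$seqs))
})

test_that("NEXUS export writes a standard DATA block and round-trips", {
  aln <- AlignedSeqSet(c(a = "ACGTAC", b = "ACGTAT"))
  nx <- withr::local_tempfile(fileext = ".nex")
  writeNexus(aln, nx)
  txt <- toupper(readLines(nx))
  expect_true(any(grepl("NTAX\\s*=\\s*2", txt)))
  expect_true(any(grepl("NCHAR\\s*=\\s*6", txt)))
  expect_true(any(grepl("DATATYPE\\s*=\\s*DNA", txt)))
  back <- readNexus(nx)
  expect_identical(as.character(back), as.character(aln))

  fx <- makePaperFixture(seed = 1)
  writeNexus(fx$seqs, nx)
  txt <- toupper(readLines(nx))
  expect_true(any(grepl("NTAX\\s*=\\s*119", txt)))
  expect_true(any(grepl("NCHAR\\s*=\\s*658", txt)))
  expect_identical(as.character(readNexus(nx)), as.character(fx$seqs))
})

test_that("iupacMatch agrees with an exhaustive degeneracy table", {
  # independent lookup table, written out by hand
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
               S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
               V = c("A", "C", "G"), H = c("A", "C", "T"),
               D = c("A", "G", "T"), B = c("C", "G", "T"),
               N = c("A", "C", "G", "T"))
  for (code in names(sets)) for (base in c("A", "C", "G", "T"))
    expect_identical(iupacMatch(code, base), base %in% sets[[code]],
                     info = paste(code, base))
  expect_true(iupacMatch("Y", "C"))
  expect_false(iupacMatch("Y", "A"))
  expect_true(iupacMatch("W", "A"))
  expect_true(iupacMatch("N", "G"))
  expect_error(iupacMatch("Z", "A"), "unknown IUPAC")
  expect_error(iupacMatch("N", "N"), "base must be")
})

test_that("primer trimming removes matched columns and keeps the alignment", {
  core <- "ATGGCTGCTATGGCT"
  aln <- AlignedSeqSet(c(a = paste0("CCAACCACAAAGATATAGGTAC", core),
                         b = paste0("CCAACCACAAAGATATAGGTAC", core)))
  tr <- trimPrimers(aln, "CCAACCAYAAAGATATWGGTAC", "AAAAAA",
                    maxMismatch = 0)
  expect_equal(seqLength(tr$seqs), nchar(core))  # 22 leading columns gone
  expect_equal(length(tr$seqs), 2L)
  expect_true(all(tr$log$fwd_trimmed))
  expect_false(any(tr$log$rev_trimmed))
  expect_identical(unname(as.character(tr$seqs)[1]), core)

  # no primer present: identity, logged as untrimmed
  untouched <- trimPrimers(AlignedSeqSet(c(a = core)), "GGGGGGGG", "CCCCCCCC",
                           maxMismatch = 0)
  expect_identical(as.character(untouched$seqs)[[1]], core)
  expect_length(untouched$trimmedColumns, 0L)
})

test_that("700 bp reads flanked by the barcode primers trim to 658 columns", {
  fx <- makePaperFixture(seed = 3, withPrimers = TRUE)
  expect_equal(seqLength(fx$seqs), 700L)
  pr <- coiPrimers()
  tr <- trimPrimers(fx$seqs, pr[["forward"]], pr[["reverse"]], maxMismatch = 1)
  expect_equal(seqLength(tr$seqs), 658L)
  expect_equal(length(tr$trimmedColumns), 42L)    # 22 + 20
  expect_equal(length(tr$seqs), 119L)
  expect_true(all(tr$log$fwd_trimmed & tr$log$rev_trimmed))
  expect_true(all(tr$log$mismatches == 0))
  # trimming recovers the primer-free core exactly
  bare <- makePaperFixture(seed = 3, withPrimers = FALSE)
  expect_identical(as.character(tr$seqs), as.character(bare$seqs))
})

test_that("translation QC counts internal stops and picks frames", {
  aln <- AlignedSeqSet(c(good = "ATGGCTGCT", bad = "ATGTAAGCT"))
  qc0 <- translationQc(aln, frame = 0)
  expect_identical(qc0$internal_stop_count, c(0L, 1L))
  expect_identical(qc0$passed, c(TRUE, FALSE))
  expect_true(qc0$passed[1])

  # gap inside a codon: codon skipped, no false stop
  qcGap <- translationQc(AlignedSeqSet(c(x = "ATGTA-GCTAAA")), frame = 0)
  expect_equal(qcGap$internal_stop_count, 0L)

  # free frame choice finds a stop-free frame where one exists
  qcBest <- translationQc(AlignedSeqSet(c(bad = "ATGTAAGCTGCTGCT")))
  expect_true(qcBest$frame_used != 0 || qcBest$internal_stop_count > 0)

  fx <- makePaperFixture(seed = 1)
  qc <- translationQc(fx$seqs, frame = 0)
  expect_true(all(qc$passed))
  expect_equal(nrow(qc), 119L)
})
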