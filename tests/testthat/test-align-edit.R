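test_that("clean_sites removes columns strictly above the gap cutoff", {
  a <- alignment(c("s1", "s2", "s3"), c("A-A", "AA-", "A-A"))
  r <- suppressMessages(clean_sites(a, 0.5))
  expect_equal(aln_length(r), 2)               # column 2 (2/3 gaps) removed
  expect_identical(r$seqs, c("AA", "A-", "AA"))
  expect_equal(attr(r, "n_removed"), 1)

  # boundary: exactly-at-cutoff columns are kept, even at cutoff 1
  half <- alignment(c("a", "b"), c("A-", "AA"))
  expect_equal(aln_length(suppressMessages(clean_sites(half, 0.5))), 2)
  allgap <- alignment(c("a", "b"), c("A-", "A-"))
  expect_equal(aln_length(suppressMessages(clean_sites(allgap, 1))), 2)
  nogap <- random_alignment(3, 20, gap_frac = 0, seed = 1)
  expect_identical(suppressMessages(clean_sites(nogap, 0))$seqs, nogap$seqs)
  expect_error(clean_sites(a, 1.5), "cutoff")
})

test_that("clean_seqs drops gappy rows without reordering the rest", {
  a <- alignment(c("s1", "s2"), c("----", "ACGT"))
  expect_identical(suppressMessages(clean_seqs(a, 0.5))$names, "s2")
  b <- alignment(c("x", "y", "z"), c("AC-T", "ACGT", "A-G-"))
  expect_identical(suppressMessages(clean_seqs(b, 0))$names, "y")
  expect_identical(suppressMessages(clean_seqs(b, 0.6))$names, c("x", "y", "z"))
})

test_that("rename and sanitize keep names unique", {
  a <- alignment(c("A", "B"), c("AC", "GT"))
  expect_identical(rename_seqs(a, c(A = "X"))$names, c("X", "B"))
  expect_error(rename_seqs(a, c(A = "B")), "duplicate")
  expect_error(rename_seqs(a, c(C = "Y")), "match no")
  expect_identical(rename_seqs(a, c(C = "Y"), allow_missing = TRUE)$names,
                   c("A", "B"))

  sn <- sanitize_names(seqset(c("Homo sapiens", "Homo/sapiens", "ok"),
                              c("AA", "CC", "GG")))
  expect_identical(sn$x$names, c("Homo_sapiens", "Homo_sapiens_2", "ok"))
  expect_identical(unname(sn$map["Homo/sapiens"]), "Homo_sapiens_2")
  expect_false("ok" %in% names(sn$map))
})

test_that("mask fills a half-open window and preserves gaps", {
  expect_identical(mask(alignment("s", "ACGT"), 1, 2)$seqs, "ANNT")
  expect_identical(mask(alignment("s", "A-GT"), 1, 2)$seqs, "A-NT")
  expect_identical(mask(alignment("s", "ACGT"), 1, 0)$seqs, "ACGT")
  prot <- alignment("p", "MKVL", alphabet = "amino-acid")
  expect_identical(mask(prot, 0, 2)$seqs, "XXVL")
  expect_error(mask(alignment("s", "ACGT"), 2, 3), "out of range")
})

test_that("extract selects sorted non-overlapping ranges", {
  a <- alignment("s", "ACGTAC")
  expect_identical(extract(a, list(c(0, 2), c(4, 6)))$seqs, "ACAC")
  expect_identical(extract(a, list(c(0, 6)))$seqs, "ACGTAC")
  expect_error(extract(a, list()), "at least one")
  expect_error(extract(a, list(c(0, 3), c(2, 5))), "overlapping")
  expect_error(extract(a, list(c(4, 8))), "invalid range")
})

test_that("concat joins by name, fills or errors on missing blocks", {
  b1 <- alignment(c("a", "b"), c("AAA", "CCC"))
  b2 <- alignment(c("a", "b"), c("GGGG", "TTTT"))
  cc <- concat(list(b1, b2))
  expect_equal(aln_length(cc), 7)
  expect_identical(cc$seqs, c("AAAGGGG", "CCCTTTT"))

  b3 <- alignment("a", "GG")
  expect_error(concat(list(b1, b3)), "missing sequence")
  filled <- concat(list(b1, b3), fill_missing = TRUE)
  expect_identical(filled$seqs[filled$names == "b"], "CCC--")

  # associativity over name-aligned blocks
  b4 <- alignment(c("a", "b"), c("AT", "GC"))
  left <- concat(list(concat(list(b1, b2)), b4))
  right <- concat(list(b1, concat(list(b2, b4))))
  expect_identical(left$seqs, right$seqs)
})

test_that("translate follows the genetic code with gap and remainder rules", {
  expect_identical(translate(alignment("s", "ATGAAA"))$seqs, "MK")
  expect_identical(translate(alignment("s", "ATG---AAA"))$seqs, "M-K")
  expect_identical(translate(alignment("s", "ATGTAA"))$seqs, "M*")
  expect_identical(translate(alignment("s", "ATGA-A"))$seqs, "MX")
  expect_message(out <- translate(alignment("s", "ATGA")), "1 trailing")
  expect_identical(out$seqs, "M")
  expect_identical(translate(alignment("s", "AATGAAA"), phase = 1)$seqs, "MK")
  expect_error(translate(alignment("p", "MK", alphabet = "amino-acid")),
               "nucleotide")
  # vertebrate mitochondrial reassignments
  expect_identical(translate(alignment("s", "TGAAGAATA"),
                             code = "vertebrate-mito")$seqs, "W*M")
})

test_that("genetic code tables match the Biostrings references", {
  std <- genetic_code("standard")
  ref <- Biostrings::getGeneticCode("1")
  expect_identical(unname(std[names(ref)]), unname(as.character(ref)))
  mito <- genetic_code("vertebrate-mito")
  ref2 <- Biostrings::getGeneticCode("2")
  expect_identical(unname(mito[names(ref2)]), unname(as.character(ref2)))
})

test_that("codon_align maps protein gaps to --- codons and checks coherence", {
  prot <- alignment(c("s1", "s2"), c("M-K", "MLK"), alphabet = "amino-acid")
  cds <- seqset(c("s1", "s2"), c("ATGAAA", "ATGCTGAAA"))
  ca <- codon_align(prot, cds)
  expect_identical(ca$seqs, c("ATG---AAA", "ATGCTGAAA"))
  expect_equal(aln_length(ca), 3 * aln_length(prot))

  # trailing stop on the CDS is tolerated
  cds_stop <- seqset(c("s1", "s2"), c("ATGAAATAA", "ATGCTGAAA"))
  expect_identical(codon_align(prot, cds_stop)$seqs[1], "ATG---AAA")

  bad <- seqset(c("s1", "s2"), c("ATGCAA", "ATGCTGAAA"))  # codes MQ, not MK
  expect_error(codon_align(prot, bad), "residue 2")
  expect_error(codon_align(prot, seqset("s1", "ATGAAA")), "name sets differ")
})

test_that("translate after codon_align restores the protein alignment", {
  code <- genetic_code("standard")
  sense <- names(code)[code != "*"]
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(2:5, 1); len <- sample(4:12, 1)
    prot_rows <- vapply(seq_len(n), function(i) {
      aa <- unname(code[sample(sense, len, replace = TRUE)])
      gaps <- stats::runif(len) < 0.25
      aa[gaps] <- "-"
      if (all(gaps)) aa[1] <- "M"
      paste(aa, collapse = "")
    }, character(1))
    prot <- alignment(paste0("s", 1:n), prot_rows, alphabet = "amino-acid")
    cds <- seqset(prot$names, vapply(prot_rows, function(r) {
      aa <- strsplit(r, "")[[1]]
      paste(vapply(aa[aa != "-"], function(x) {
        sample(names(code)[code == x], 1)
      }, character(1)), collapse = "")
    }, character(1)))
    back <- translate(codon_align(prot, cds))
    expect_identical(back$seqs, prot$seqs)
  }
})

test_that("seqboot replicates resample whole columns, reproducibly", {
  a <- random_alignment(4, 30, seed = 5)
  reps <- seqboot(a, 5, seed = 9)
  expect_length(reps, 5)
  cols <- strsplit(apply(aln_matrix(a), 2, paste, collapse = ""), NULL)
  colset <- apply(aln_matrix(a), 2, paste, collapse = "")
  for (r in reps) {
    expect_identical(r$names, a$names)
    expect_equal(aln_length(r), aln_length(a))
    repcols <- apply(aln_matrix(r), 2, paste, collapse = "")
    expect_true(all(repcols %in% colset))
  }
  expect_identical(seqboot(a, 5, seed = 9), reps)
  expect_false(identical(seqboot(a, 5, seed = 10), reps))
  expect_error(seqboot(a, 0), "positive")
})

test_that("seqboot column sampling is uniform with replacement", {
  a <- alignment(c("x", "y"), c("AC", "GT"))
  reps <- seqboot(a, 1000, seed = 42)
  both_first <- mean(vapply(reps, function(r) {
    identical(r$seqs, c("AA", "GG"))
  }, logical(1)))
  expect_gt(both_first, 0.20)   # binomial(1000, 1/4): 0.25 +/- 0.05
  expect_lt(both_first, 0.30)
})
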