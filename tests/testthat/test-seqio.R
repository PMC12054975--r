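test_that("reverse complement matches hand checks and both oracles", {
  expect_identical(revComp("ACGT"), "ACGT")     # revcomp palindrome
  expect_identical(revComp(""), "")
  expect_identical(revComp("AAACCC"), "GGGTTT")
  expect_identical(revComp("acgtn"), "NACGT")   # lowercase folded, N kept

  for (seed in 1:10) {
    g <- unname(randomGenome(200, seed = seed))
    expect_identical(revComp(g), naive_revcomp(g))
    expect_identical(revComp(g),
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(g))))
  }
  # involution
  g <- unname(randomGenome(500, seed = 99))
  expect_identical(revComp(revComp(g)), g)
})

test_that("invalid characters are rejected with their position", {
  expect_error(revComp("ACGX"), "position 4")
  expect_error(extractKmers("ACGTQ", k = 2), "position 5")
})

test_that("k-mer extraction obeys window, N-masking and coordinate rules", {
  # windows touching the N at position 4 are dropped entirely
  km <- extractKmers("ACGTNACGT", k = 4)
  expect_identical(km$pos, c(0L, 5L))

  # canonical form: revcomp("TTTT") = "AAAA" wins lexicographically
  km <- extractKmers("TTTT", k = 4)
  expect_identical(decodeKmers(km$code, 4), "AAAA")

  # window count is len - k + 1 for a clean sequence
  g <- randomGenome(1000, seed = 5)
  expect_identical(nrow(extractKmers(g, k = 21)), 980L)

  # sequence shorter than k: empty stream, not an error
  expect_identical(nrow(extractKmers("ACG", k = 5)), 0L)

  # positions are 0-based window starts
  km <- extractKmers("AACCA", k = 2, canonical = FALSE)
  expect_identical(km$pos, 0:3)
  expect_identical(decodeKmers(km$code, 2), c("AA", "AC", "CC", "CA"))
})

test_that("encode/decode round trip and strand invariance hold", {
  g <- unname(randomGenome(300, seed = 11))
  km <- extractKmers(g, k = 9)
  strs <- decodeKmers(km$code, 9)
  expect_identical(encodeKmers(strs), km$code)
  # canonical string is min(kmer, revcomp(kmer))
  expect_true(all(strs <= vapply(strs, naive_revcomp, character(1))))

  # same canonical multiset from a sequence and its reverse complement
  a <- sort(decodeKmers(extractKmers(g, k = 9)$code, 9))
  b <- sort(decodeKmers(extractKmers(revComp(g), k = 9)$code, 9))
  expect_identical(a, b)
})

test_that("FASTA/FASTQ readers handle multi-record, multi-line and gzip", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">g1 first", "ACGTAC", "GTACGT", ">g2", "TTTT"), fa)
  ss <- readSequences(fa)
  expect_identical(length(ss), 2L)
  expect_identical(as.character(ss[[1]]), "ACGTACGTACGT")
  expect_identical(as.character(ss[[2]]), "TTTT")

  fq <- tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGTACGT", "+", "IIIIIIII",
               "@r2", "GGGG", "+", "IIII"), fq)
  sq <- readSequences(fq)
  expect_identical(unname(as.character(sq)), c("ACGTACGT", "GGGG"))

  gz <- tempfile(fileext = ".fa.gz")
  con <- gzfile(gz, "wt")
  writeLines(c(">g1", "ACGTACGT"), con)
  close(con)
  expect_identical(unname(as.character(readSequences(gz))), "ACGTACGT")

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_identical(length(readSequences(empty)), 0L)

  bad <- tempfile()
  writeLines("not a sequence file", bad)
  expect_error(readSequences(bad), "cannot detect")
})
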