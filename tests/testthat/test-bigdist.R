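make_minhash_set <- function(n, len = 1500, k = 21, s = 200, base_seed = 500) {
  base <- randomGenome(len, seed = base_seed)
  lapply(seq_len(n), function(i) {
    g <- mutateGenome(base, rate = 0.02 * (i - 1), seed = base_seed + i,
                      name = sprintf("g%02d", i))
    minhashSketch(g, k = k, s = s)
  })
}

test_that("index structure invariants hold", {
  sk <- make_minhash_set(1)
  idx <- buildIndex(sk)
  expect_true(all(lengths(idx@postings) == 1L))

  # duplicate sketches: every posting list has both ids
  sk2 <- sk[[1]]
  sketchName(sk2) <- "copy"
  idx2 <- buildIndex(list(sk[[1]], sk2))
  expect_true(all(lengths(idx2@postings) == 2L))

  # posting mass equals sketch mass on a larger random collection
  many <- make_minhash_set(20)
  idx3 <- buildIndex(many)
  expect_identical(sum(lengths(idx3@postings)), sum(idx3@sketchSizes))
  # compact: only observed hashes are stored
  expect_identical(sort(idx3@keys),
                   sort(unique(unlist(lapply(many, sketchHashes)))))
  expect_true(all(lengths(idx3@postings) > 0L))
})

test_that("index engine equals the pairwise loop exactly (minhash)", {
  sketches <- make_minhash_set(10)
  viaIndex <- pairwiseDistances(sketches, engine = "index")
  viaLoop <- pairwiseDistances(sketches, engine = "pairwise")
  expect_identical(viaIndex, viaLoop)

  # two identical sketches: off-diagonal jaccard is 1
  dup <- sketches[[1]]
  sketchName(dup) <- "dup"
  tab <- pairwiseDistances(list(sketches[[1]], dup), engine = "index")
  expect_true(all(tab$jaccard == 1))
  expect_true(all(tab$mash_distance == 0))
})

test_that("index engine equals the pairwise loop exactly (kssd)", {
  d <- kssdDictionary(halfK = 5, drlevel = 1, seed = 42)
  base <- randomGenome(2000, seed = 600)
  sketches <- lapply(1:10, function(i) {
    g <- mutateGenome(base, rate = 0.01 * (i - 1), seed = 600 + i,
                      name = sprintf("g%02d", i))
    kssdSketch(g, dict = d, k = 21)
  })
  expect_identical(pairwiseDistances(sketches, engine = "index"),
                   pairwiseDistances(sketches, engine = "pairwise"))
})

test_that("diagonal and symmetry conventions", {
  sketches <- make_minhash_set(4)
  tab <- pairwiseDistances(sketches)
  nm <- vapply(sketches, sketchName, character(1))
  self <- tab[tab$ref == tab$query, ]
  expect_identical(nrow(self), 4L)
  expect_true(all(self$jaccard == 1))
  # rows are lexicographic with ref <= query, one per unordered pair
  expect_identical(nrow(tab), 4L + as.integer(choose(4, 2)))
  expect_true(all(tab$ref <= tab$query))
  expect_false(is.unsorted(paste(tab$ref, tab$query)))
})

test_that("mixed or inconsistent collections are rejected", {
  mh <- make_minhash_set(2)
  d <- kssdDictionary(halfK = 4, drlevel = 1)
  ks <- kssdSketch(randomGenome(500, seed = 1), dict = d, k = 21)
  expect_error(buildIndex(list(mh[[1]], ks)), "mixed")
  expect_error(buildIndex(list()), "at least one")
  other <- minhashSketch(randomGenome(500, seed = 2), k = 15, s = 200)
  expect_error(buildIndex(list(mh[[1]], other)), "disagree on k")
  ksOther <- kssdSketch(randomGenome(500, seed = 3),
                        dict = kssdDictionary(halfK = 4, drlevel = 1, seed = 9),
                        k = 21)
  expect_error(buildIndex(list(ks, ksOther)), "incomparable")
  expect_error(buildIndex(list(hllSketch(p = 8), hllSketch(p = 8))),
               "pure-hash")
})
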