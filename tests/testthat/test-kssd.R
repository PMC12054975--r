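test_that("shuffle dictionary is a seeded permutation with the right valid count", {
  d0 <- kssdDictionary(halfK = 3, drlevel = 0, seed = 42)
  expect_identical(sum(d0@perm < 4^3), 64L)       # no reduction: all valid

  d1 <- kssdDictionary(halfK = 3, drlevel = 1, seed = 42)
  expect_identical(sum(d1@perm < 4^2), 16L)
  expect_identical(sort(d1@perm), 0:63)           # bijection

  # determinism across builds; sensitivity to the seed
  expect_identical(kssdDictionary(3, 1, 42)@perm, d1@perm)
  expect_false(identical(kssdDictionary(3, 1, 43)@perm, d1@perm))
  expect_false(identical(kssdDictionary(3, 1, 43)@dictId, d1@dictId))

  expect_error(kssdDictionary(halfK = 3, drlevel = 4), "drlevel")
  expect_error(kssdDictionary(halfK = 11, drlevel = 0), "half_k")
})

test_that("map dictionary agrees with the full permutation on every code", {
  d <- kssdDictionary(halfK = 4, drlevel = 2, seed = 9)
  mp <- kssdMapDictionary(d)
  expect_identical(nrow(mp), 16L)                 # 4^(4-2)
  # exhaustive over the 4^L space: membership and rank agree
  nValid <- 4^(4 - 2)
  for (code in 0:(4^4 - 1)) {
    inMap <- code %in% mp$code
    expect_identical(inMap, d@perm[code + 1] < nValid)
    if (inMap) expect_identical(mp$rank[mp$code == code], d@perm[code + 1])
  }
  # drlevel 0: map size equals the full space
  expect_identical(nrow(kssdMapDictionary(kssdDictionary(3, 0, 1))), 64L)
})

test_that("kssd selection matches the string-level oracle and the map path", {
  d <- kssdDictionary(halfK = 4, drlevel = 1, seed = 42)
  for (seed in 1:5) {
    g <- randomGenome(2000, seed = 60 + seed)
    sk <- kssdSketch(g, dict = d, k = 15)
    expect_identical(kssdCodes(sk), oracle_kssd_codes(g, 15, d))
    skMap <- updateSketch(kssdSketch(dict = d, k = 15), g, dict = d,
                          useMap = TRUE)
    expect_identical(kssdCodes(skMap), kssdCodes(sk))
  }
})

test_that("drlevel 0 keeps every distinct canonical k-mer", {
  d <- kssdDictionary(halfK = 3, drlevel = 0, seed = 5)
  g <- randomGenome(500, seed = 66)
  sk <- kssdSketch(g, dict = d, k = 11)
  expect_identical(kssdCodes(sk),
                   sortHashes(extractKmers(g, k = 11)$code, unique = TRUE))
})

test_that("the sampled fraction concentrates around 4^-d", {
  d <- kssdDictionary(halfK = 6, drlevel = 2, seed = 42)
  g <- randomGenome(100000, seed = 67)
  sk <- kssdSketch(g, dict = d, k = 21)
  nDistinct <- length(unique(extractKmers(g, k = 21)$code))
  frac <- length(kssdCodes(sk)) / nDistinct
  p <- 4^-2
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / nDistinct))
})

test_that("kssd jaccard equals brute force on the dictionary-selected sets", {
  d <- kssdDictionary(halfK = 5, drlevel = 1, seed = 42)
  for (seed in 1:5) {
    pr <- shared_block_pair(1500, 1500, seed + 40)
    sa <- kssdSketch(pr$a, dict = d, k = 17)
    sb <- kssdSketch(pr$b, dict = d, k = 17)
    got <- jaccard(sa, sb)
    ca <- oracle_kssd_codes(pr$a, 17, d)
    cb <- oracle_kssd_codes(pr$b, 17, d)
    inter <- length(intersect(ca, cb))
    expect_identical(got@shared, as.numeric(inter))
    expect_identical(got@denom, as.numeric(length(union(ca, cb))))
    expect_identical(jaccard(sa, sa)@jaccard, 1)
  }
})

test_that("kssd estimates are nearly unbiased against the exact jaccard", {
  d <- kssdDictionary(halfK = 6, drlevel = 2, seed = 42)
  diffs <- vapply(1:30, function(seed) {
    pr <- shared_block_pair(2000, 2000, seed + 300)
    sa <- kssdSketch(pr$a, dict = d, k = 21)
    sb <- kssdSketch(pr$b, dict = d, k = 21)
    jaccard(sa, sb)@jaccard - exactJaccard(pr$a, pr$b, 21)$jaccard
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.02)
})

test_that("dictionary binding and k constraints are enforced", {
  d1 <- kssdDictionary(halfK = 4, drlevel = 1, seed = 1)
  d2 <- kssdDictionary(halfK = 4, drlevel = 1, seed = 2)
  g <- randomGenome(300, seed = 70)
  sk <- kssdSketch(g, dict = d1, k = 15)
  expect_error(updateSketch(sk, g, dict = d2), "incomparable")
  expect_error(jaccard(sk, kssdSketch(g, dict = d2, k = 15)), "dictId differs")
  expect_error(kssdSketch(g, dict = d1, k = 3), "halfK")

  # merge = set union, and equals the joint build
  a <- randomGenome(600, seed = 71)
  b <- randomGenome(600, seed = 72)
  m <- mergeSketches(kssdSketch(a, dict = d1, k = 15),
                     kssdSketch(b, dict = d1, k = 15))
  expect_identical(kssdCodes(m), kssdCodes(kssdSketch(c(a, b), dict = d1, k = 15)))
})
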