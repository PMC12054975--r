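test_that("minhash update matches the brute-force bottom-s oracle", {
  g <- randomGenome(5000, seed = 21)
  sk <- minhashSketch(g, k = 21, s = 1000)
  expect_identical(sketchHashes(sk), oracle_minhash_hashes(g, 21, 1000))
  expect_identical(nKmers(sk), 4980)

  # a second configuration
  sk2 <- minhashSketch(g, k = 11, s = 64, seed = 7)
  expect_identical(sketchHashes(sk2), oracle_minhash_hashes(g, 11, 64, seed = 7))
})

test_that("update is streaming, set-semantic and order independent", {
  a <- randomGenome(800, seed = 1)
  b <- randomGenome(700, seed = 2)
  sk0 <- minhashSketch(k = 15, s = 100)

  one_pass <- updateSketch(sk0, c(a, b))
  two_pass <- updateSketch(updateSketch(sk0, a), b)
  reversed <- updateSketch(updateSketch(sk0, b), a)
  expect_identical(sketchHashes(one_pass), sketchHashes(two_pass))
  expect_identical(sketchHashes(one_pass), sketchHashes(reversed))

  # shorter than k: unchanged
  expect_identical(sketchHashes(updateSketch(one_pass, "ACGT")),
                   sketchHashes(one_pass))
  # same sequence twice: unchanged retained set
  expect_identical(sketchHashes(updateSketch(one_pass, a)),
                   sketchHashes(one_pass))
})

test_that("merge is the bottom-s of the union and equals the joint build", {
  a <- randomGenome(900, seed = 31)
  b <- randomGenome(900, seed = 32)
  ska <- minhashSketch(a, k = 17, s = 150)
  skb <- minhashSketch(b, k = 17, s = 150)
  empty <- minhashSketch(k = 17, s = 150)

  expect_identical(sketchHashes(mergeSketches(ska, empty)), sketchHashes(ska))
  expect_identical(sketchHashes(mergeSketches(ska, ska)), sketchHashes(ska))
  expect_identical(sketchHashes(mergeSketches(ska, skb)),
                   sketchHashes(mergeSketches(skb, ska)))
  joint <- minhashSketch(c(a, b), k = 17, s = 150)
  expect_identical(sketchHashes(mergeSketches(ska, skb)), sketchHashes(joint))

  # two halves of one genome rebuild its sketch
  g <- unname(randomGenome(2000, seed = 33))
  halves <- c(substr(g, 1, 1010), substr(g, 991, 2000))  # k-1 overlap keeps all windows
  whole <- minhashSketch(g, k = 21, s = 300)
  parts <- mergeSketches(minhashSketch(halves[1], k = 21, s = 300),
                         minhashSketch(halves[2], k = 21, s = 300))
  expect_identical(sketchHashes(parts), sketchHashes(whole))

  expect_error(mergeSketches(ska, minhashSketch(k = 17, s = 99)), "s differs")
})

test_that("sketch jaccard follows the bottom-s' union estimator", {
  a <- randomGenome(1500, seed = 41)
  ska <- minhashSketch(a, k = 21, s = 200)
  self <- jaccard(ska, ska)
  expect_identical(self@jaccard, 1)
  expect_identical(self@mashDistance, 0)

  # disjoint genomes at k=21 share no hashes with overwhelming probability
  skb <- minhashSketch(randomGenome(1500, seed = 42), k = 21, s = 200)
  expect_identical(jaccard(ska, skb)@jaccard, 0)
  expect_identical(jaccard(ska, skb)@mashDistance, 1)

  # independent estimator oracle on partially overlapping genomes
  for (seed in 1:5) {
    pr <- shared_block_pair(1200, 1200, seed)
    sa <- minhashSketch(pr$a, k = 21, s = 150)
    sb <- minhashSketch(pr$b, k = 21, s = 150)
    got <- jaccard(sa, sb)
    want <- oracle_minhash_jaccard(sketchHashes(sa), sketchHashes(sb), 150)
    expect_identical(got@shared, as.numeric(want$shared))
    expect_identical(got@denom, as.numeric(want$denom))
  }

  expect_error(jaccard(ska, minhashSketch(a, k = 19, s = 200)), "k differs")
  expect_error(jaccard(ska, minhashSketch(a, k = 21, s = 200, seed = 1)),
               "seed differs")
})

test_that("with s above the distinct k-mer count the estimate is exact", {
  for (seed in 1:10) {
    pr <- shared_block_pair(400, 400, seed)
    sa <- minhashSketch(pr$a, k = 21, s = 2000)
    sb <- minhashSketch(pr$b, k = 21, s = 2000)
    expect_equal(jaccard(sa, sb)@jaccard,
                 exactJaccard(pr$a, pr$b, 21)$jaccard, tolerance = 1e-12)
  }
})

test_that("mash distance closed form, clamps and errors", {
  expect_identical(mashDistance(1, 21), 0)
  expect_identical(mashDistance(0, 21), 1)
  expect_equal(mashDistance(0.5, 21), -log(2 / 3) / 21, tolerance = 1e-15)
  expect_equal(mashDistance(0.2, 16), -log(0.4 / 1.2) / 16, tolerance = 1e-15)
  # tiny jaccard at small k exceeds 1 before clamping
  expect_identical(mashDistance(1e-9, 1), 1)
  expect_error(mashDistance(1.2, 21), "\\[0, 1\\]")
  expect_error(mashDistance(-0.1, 21), "\\[0, 1\\]")
})
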