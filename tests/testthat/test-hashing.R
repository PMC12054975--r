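# Frozen vectors computed with an independent pure-Python implementation of
# MurmurHash3 x64_128 (validated against the published digest of "The quick
# brown fox jumps over the lazy dog", seed 0) and of Wang's 64-bit mix.
test_that("murmur64 reproduces the reference MurmurHash3 x64_128 lower half", {
  expect_identical(murmur64("", seed = 0), "0")
  expect_identical(murmur64("", seed = 42), "17305828677633410339")
  expect_identical(murmur64("a", seed = 0), "9607679276477937801")
  expect_identical(murmur64("ACGT", seed = 42), "2597925387403686983")
  expect_identical(murmur64("ACGT", seed = 43), "10443591901245547052")
  # 21 bytes: one 16-byte block plus a 5-byte tail
  expect_identical(murmur64("ACGTACGTACGTACGTACGTA", seed = 42),
                   "13036166743686632327")
  expect_identical(murmur64("The quick brown fox jumps over the lazy dog",
                            seed = 0), "16378391709484522348")
  # exactly one block, no tail
  expect_identical(murmur64(strrep("N", 16), seed = 7),
                   "10239177877516024698")

  # determinism and seed sensitivity
  expect_identical(murmur64("ACGT", seed = 42), murmur64("ACGT", seed = 42))
  expect_false(murmur64("ACGT", seed = 42) == murmur64("ACGT", seed = 43))
})

test_that("wang mix matches the reference and is bijective on a subdomain", {
  expect_identical(wangMix("0"), "8633297058295171728")
  expect_identical(wangMix(wangMix("0")), "12571007321581959831")
  expect_identical(wangMix("1"), "6614235796240398542")
  expect_identical(wangMix("123456789"), "16581954974024456952")

  # 16-bit subdomain embedded in 64 bits: injective
  out <- wangMix(as.character(0:65535))
  expect_identical(length(unique(out)), 65536L)
})

test_that("batch hashing is bit-identical to scalar hashing", {
  expect_identical(murmur64Batch(character(), 42), character())

  set.seed(1)
  for (seed in c(0, 42, 4294967295)) {
    strs <- vapply(1:250, function(i)
      paste(sample(c("A", "C", "G", "T"), sample(0:40, 1), replace = TRUE),
            collapse = ""), character(1))
    strs <- c(strs, strs[1:10])  # duplicates must duplicate
    expect_identical(murmur64Batch(strs, seed), murmur64(strs, seed))
  }
})

test_that("hashing a k-mer string equals hashing its decoded encoding", {
  g <- randomGenome(400, seed = 3)
  km <- extractKmers(g, k = 15)
  strs <- decodeKmers(km$code, 15)
  expect_identical(murmur64(strs), murmur64(decodeKmers(encodeKmers(strs), 15)))
})

test_that("hash seed validation rejects out-of-range seeds", {
  expect_error(murmur64("x", seed = -1), "seed")
  expect_error(murmur64("x", seed = 2^32), "seed")
  expect_error(murmur64("x", seed = 1.5), "seed")
})

test_that("sortHashes orders decimal strings numerically", {
  x <- c("10", "2", "18446744073709551615", "9", "2")
  expect_identical(sortHashes(x),
                   c("2", "9", "10", "18446744073709551615"))
  expect_identical(sortHashes(x, unique = FALSE),
                   c("2", "2", "9", "10", "18446744073709551615"))
  expect_error(sortHashes("18446744073709551616"), "overflow")
})
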