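test_that("register updates follow the bucket/rank rule (independent oracle)", {
  hashes <- genosketch:::cpp_random_u64(200, 12345)
  for (p in c(4L, 6L, 8L)) {
    sk <- hllAddHashes(hllSketch(p = p), hashes)
    expect_identical(hllRegisters(sk), oracle_hll_registers(hashes, p))
    expect_equal(hllCardinality(sk),
                 oracle_hll_estimate(oracle_hll_registers(hashes, p)),
                 tolerance = 1e-12)
  }
})

test_that("fresh, single-insert and idempotence behaviour", {
  sk <- hllSketch(p = 8)
  expect_true(all(hllRegisters(sk) == 0L))
  expect_identical(hllCardinality(sk), 0)

  one <- hllAddHashes(sk, "123456789123")
  expect_identical(sum(hllRegisters(one) > 0L), 1L)
  expect_identical(hllRegisters(hllAddHashes(one, "123456789123")),
                   hllRegisters(one))

  # registers are monotone under any insertion stream
  cur <- sk
  for (chunk in split(genosketch:::cpp_random_u64(300, 9), rep(1:10, 30))) {
    nxt <- hllAddHashes(cur, chunk)
    expect_true(all(hllRegisters(nxt) >= hllRegisters(cur)))
    cur <- nxt
  }
  expect_true(all(hllRegisters(cur) <= 64L - 8L + 1L))
})

test_that("merge is the register lattice join and equals the union stream", {
  x <- genosketch:::cpp_random_u64(4000, 101)
  y <- genosketch:::cpp_random_u64(3000, 102)
  a <- hllAddHashes(hllSketch(p = 10), x)
  b <- hllAddHashes(hllSketch(p = 10), y)
  m <- mergeSketches(a, b)
  expect_identical(hllRegisters(m), pmax(hllRegisters(a), hllRegisters(b)))
  expect_identical(hllRegisters(m),
                   hllRegisters(hllAddHashes(hllSketch(p = 10), c(x, y))))
  expect_identical(hllRegisters(mergeSketches(a, a)), hllRegisters(a))
  expect_identical(hllRegisters(mergeSketches(a, hllSketch(p = 10))),
                   hllRegisters(a))
  expect_identical(hllRegisters(mergeSketches(a, b)),
                   hllRegisters(mergeSketches(b, a)))
  expect_error(mergeSketches(a, hllSketch(p = 11)), "p differs")
})

test_that("branch-free and branchy register comparison agree everywhere", {
  # exhaustive over all register value pairs in [0, 61]
  va <- as.integer(rep(0:61, each = 62))
  vb <- as.integer(rep(0:61, times = 62))
  pad <- function(v) c(v, integer(4096 - length(v)))  # p=12 array
  bf <- genosketch:::cpp_hll_merge(pad(va), pad(vb), TRUE)
  br <- genosketch:::cpp_hll_merge(pad(va), pad(vb), FALSE)
  expect_identical(bf, br)
  expect_identical(bf[seq_along(va)], pmax(va, vb))
})

test_that("cardinality estimates are accurate at p = 14", {
  errs <- vapply(1:5, function(seed) {
    sk <- hllAddHashes(hllSketch(p = 14),
                       genosketch:::cpp_random_u64(10000, 1000 + seed))
    abs(hllCardinality(sk) - 10000) / 10000
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("sequence updates hash canonical k-mers like minhash does", {
  g <- randomGenome(3000, seed = 77)
  sk <- updateSketch(hllSketch(p = 12, k = 21), g)
  want <- genosketch:::cpp_hll_add_hashes(integer(2^12),
                                          oracle_minhash_hashes(g, 21, 10^9),
                                          12L)
  expect_identical(hllRegisters(sk), want)
  # estimate is close to the true distinct count
  truth <- length(unique(extractKmers(g, k = 21)$code))
  expect_lt(abs(hllCardinality(sk) - truth) / truth, 0.1)
})

test_that("hll jaccard brackets self and disjoint comparisons", {
  x <- genosketch:::cpp_random_u64(10000, 201)
  y <- genosketch:::cpp_random_u64(10000, 202)
  a <- hllAddHashes(hllSketch(p = 14), x)
  b <- hllAddHashes(hllSketch(p = 14), y)
  self <- jaccard(a, a)
  expect_gte(self@jaccard, 0.95)
  expect_lte(self@jaccard, 1)
  expect_lte(jaccard(a, b)@jaccard, 0.05)
  expect_gte(jaccard(a, b)@jaccard, 0)
})
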