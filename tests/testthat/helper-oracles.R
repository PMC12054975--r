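# Independent reference implementations used as oracles. These deliberately
# take different code paths from the package internals they check.

# Naive per-character reverse complement.
naive_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            a = "T", c = "G", g = "C", t = "A", n = "N")
  ch <- strsplit(seq, "")[[1]]
  out <- comp[ch]
  if (anyNA(out)) stop("invalid character")
  paste(rev(unname(out)), collapse = "")
}

# Brute-force bottom-s MinHash: enumerate every canonical k-mer, hash its
# string form, sort, truncate. Composed from exported primitives only.
oracle_minhash_hashes <- function(seq, k, s, seed = 42) {
  km <- extractKmers(seq, k = k, canonical = TRUE)
  if (nrow(km) == 0) return(character())
  h <- murmur64(decodeKmers(km$code, k), seed = seed)
  head(sortHashes(h, unique = TRUE), s)
}

# Mash-style Jaccard from two full retained-hash lists (independent of the
# C++ merge): bottom-s' of the union, count members present in both.
oracle_minhash_jaccard <- function(ha, hb, s) {
  uni <- sortHashes(c(ha, hb), unique = TRUE)
  denom <- min(s, length(uni))
  top <- head(uni, denom)
  shared <- sum(top %in% ha & top %in% hb)
  list(shared = shared, denom = denom)
}

# Naive OrderMinHash repetition: hash every (k-mer, occurrence) pair with the
# repetition seed, keep the l smallest (ties by earlier position), then order
# by position.
oracle_omh_row <- function(seq, k, l, row_seed) {
  km <- extractKmers(seq, k = k, canonical = FALSE)
  kmers <- decodeKmers(km$code, k)
  occ <- stats::ave(seq_along(kmers), kmers, FUN = seq_along) - 1L
  h <- murmur64(paste0(kmers, ":", occ), seed = row_seed)
  ord <- order(nchar(h), h, km$pos)           # numeric hash order, pos ties
  sel <- sort(head(ord, l))                   # back to positional order
  data.frame(hash = h[sel], kmer = kmers[sel], occ = occ[sel],
             pos = km$pos[sel], stringsAsFactors = FALSE)
}

# Kssd selection oracle working on k-mer strings: central substring ->
# code -> shuffled rank, keeping the full k-mer encodings that pass.
oracle_kssd_codes <- function(seq, k, dict) {
  km <- extractKmers(seq, k = k, canonical = TRUE)
  if (nrow(km) == 0) return(character())
  kmers <- decodeKmers(km$code, k)
  L <- dict@halfK
  start <- (k - L) %/% 2
  sub <- substr(kmers, start + 1, start + L)
  code <- as.numeric(encodeKmers(sub))
  keep <- dict@perm[code + 1] < 4^(L - dict@drlevel)
  sortHashes(km$code[keep], unique = TRUE)
}

# Base-2 digits of a decimal-string 64-bit integer, most significant first
# (string long-division; independent of any C++ conversion).
u64_bits <- function(dec) {
  digits <- as.integer(strsplit(dec, "")[[1]])
  bits <- integer(64)
  for (b in 64:1) {
    carry <- 0L
    quo <- integer(length(digits))
    for (i in seq_along(digits)) {
      cur <- carry * 10L + digits[i]
      quo[i] <- cur %/% 2L
      carry <- cur %% 2L
    }
    bits[b] <- carry
    digits <- quo
    while (length(digits) > 1 && digits[1] == 0L) digits <- digits[-1]
  }
  bits
}

# Independent HLL register computation from decimal-string hashes.
oracle_hll_registers <- function(hashes, p) {
  regs <- integer(2^p)
  for (h in hashes) {
    bits <- u64_bits(h)
    bucket <- sum(bits[1:p] * 2^((p - 1):0)) + 1
    suffix <- bits[(p + 1):64]
    nz <- which(suffix == 1)
    rank <- if (length(nz)) nz[1] else (64 - p + 1)
    regs[bucket] <- max(regs[bucket], rank)
  }
  regs
}

oracle_hll_estimate <- function(regs) {
  m <- length(regs)
  alpha <- if (m == 16) 0.673 else if (m == 32) 0.697 else if (m == 64) 0.709
           else 0.7213 / (1 + 1.079 / m)
  raw <- alpha * m^2 / sum(2^(-regs))
  v <- sum(regs == 0)
  if (v > 0 && raw <= 2.5 * m) m * log(m / v) else raw
}

# Quadratic-time Levenshtein DP, the oracle for editDistance().
dp_edit_distance <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  prev <- 0:length(y)
  for (i in seq_along(x)) {
    cur <- numeric(length(y) + 1)
    cur[1] <- i
    for (j in seq_along(y)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (x[i] != y[j]))
    }
    prev <- cur
  }
  prev[length(y) + 1]
}

# Random strictly-increasing 64-bit sets for intersection tests.
random_sorted_set <- function(n, seed) sortHashes(cpp_rand_chr(n, seed))
cpp_rand_chr <- function(n, seed) genosketch:::cpp_random_u64(n, seed)

# Two genomes sharing a block: a unique prefix each plus a common suffix.
shared_block_pair <- function(n_unique, n_shared, seed) {
  shared <- randomGenome(n_shared, seed = seed * 1000 + 3)
  a <- paste0(randomGenome(n_unique, seed = seed * 1000 + 1), shared)
  b <- paste0(randomGenome(n_unique, seed = seed * 1000 + 2), shared)
  list(a = setNames(a, "A"), b = setNames(b, "B"))
}
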