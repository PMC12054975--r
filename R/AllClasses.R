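.check_u64 <- function(x, what) {
  if (anyNA(x)) return(sprintf("%s must not contain NA", what))
  if (length(x) && !cpp_u64_sorted_distinct(x))
    return(sprintf("%s must be strictly increasing 64-bit values", what))
  TRUE
}

#' MinHashSketch: bottom-s (KMV) MinHash sketch
#'
#' Holds the \code{s} numerically smallest distinct MurmurHash3 values of the
#' canonical k-mers seen so far. Because R has no native unsigned 64-bit
#' integer, hash values are carried as decimal strings throughout the package
#' (and in serialized sketches), preserving them bit-exactly.
#'
#' @slot k k-mer length (1--32).
#' @slot s sketch size: the maximum number of retained hash values.
#' @slot seed 32-bit MurmurHash3 seed (default 42).
#' @slot hashes character vector of retained hash values, strictly increasing.
#' @slot nKmers number of k-mer windows consumed so far.
#' @slot name sketch label used in distance tables.
#'
#' @seealso \code{\link{minhashSketch}}, \code{\link{updateSketch}},
#'   \code{\link{jaccard}}, \code{\link{mergeSketches}}
#' @exportClass MinHashSketch
setClass("MinHashSketch",
  representation(k = "integer", s = "integer", seed = "numeric",
                 hashes = "character", nKmers = "numeric", name = "character"),
  prototype(k = 21L, s = 1000L, seed = 42, hashes = character(),
            nKmers = 0, name = ""))

setValidity("MinHashSketch", function(object) {
  msgs <- character()
  if (object@k < 1L || object@k > 32L) msgs <- c(msgs, "k must be in [1, 32]")
  if (object@s < 1L) msgs <- c(msgs, "s must be >= 1")
  if (length(object@hashes) > object@s)
    msgs <- c(msgs, "more than s retained hashes")
  ok <- .check_u64(object@hashes, "hashes")
  if (!isTRUE(ok)) msgs <- c(msgs, ok)
  if (length(msgs)) msgs else TRUE
})

#' OMHSketch: OrderMinHash sketch of a single sequence
#'
#' \code{m} repetitions (independent hash functions); each repetition keeps
#' the \code{l} (k-mer, occurrence-index) pairs with the smallest hash values
#' and stores them ordered by their position in the sequence. Two sketches are
#' compared by the fraction of repetitions whose ordered selections agree
#' exactly, a proxy for edit distance.
#'
#' @slot k k-mer length.
#' @slot m number of hash repetitions.
#' @slot l minima retained per repetition.
#' @slot seed base hash seed; per-repetition seeds are derived from it.
#' @slot rows list of \code{m} data frames with columns \code{hash},
#'   \code{kmer}, \code{occ}, \code{pos}, rows ordered by \code{pos}.
#' @slot name sketch label.
#'
#' @seealso \code{\link{omhSketch}}, \code{\link{omhSimilarity}}
#' @exportClass OMHSketch
setClass("OMHSketch",
  representation(k = "integer", m = "integer", l = "integer", seed = "numeric",
                 rows = "list", name = "character"))

setValidity("OMHSketch", function(object) {
  if (length(object@rows) != object@m)
    return("rows must hold exactly m entries")
  for (r in object@rows) {
    if (!all(c("hash", "kmer", "occ", "pos") %in% names(r)))
      return("each row needs hash/kmer/occ/pos columns")
    if (nrow(r) > object@l) return("a row holds more than l entries")
    if (is.unsorted(r$pos, strictly = TRUE)) return("row entries must be ordered by position")
  }
  TRUE
})

#' KssdDictionary: seeded shuffle of the k-mer substring code space
#'
#' A Fisher--Yates permutation (driven by a seeded splitmix64 stream) of the
#' \eqn{4^L} codes of length-\eqn{L} nucleotide substrings. The codes whose
#' shuffled rank falls below \eqn{4^{L-d}} are "valid"; a k-mer is sampled
#' into a \linkS4class{KssdSketch} exactly when the code of its central
#' length-\eqn{L} substring is valid, giving a deterministic \eqn{4^{-d}}
#' sampling fraction shared by every genome sketched with the same dictionary.
#'
#' @slot halfK substring length L in bases (1--10).
#' @slot drlevel dimension-reduction level d (0 <= d <= L).
#' @slot seed shuffle seed.
#' @slot perm integer vector of length \eqn{4^L}; \code{perm[code + 1]} is the
#'   shuffled rank of \code{code}.
#' @slot dictId digest binding sketches to this dictionary.
#'
#' @seealso \code{\link{kssdDictionary}}, \code{\link{kssdMapDictionary}}
#' @exportClass KssdDictionary
setClass("KssdDictionary",
  representation(halfK = "integer", drlevel = "integer", seed = "numeric",
                 perm = "integer", dictId = "character"))

setValidity("KssdDictionary", function(object) {
  n <- 4^object@halfK
  if (length(object@perm) != n) return("perm length must be 4^halfK")
  if (!setequal(range(object@perm), c(0L, n - 1L)) ||
      anyDuplicated(object@perm) > 0L)
    return("perm must be a permutation of 0..4^halfK-1")
  nv <- sum(object@perm < 4^(object@halfK - object@drlevel))
  if (nv != 4^(object@halfK - object@drlevel))
    return("number of valid codes must be 4^(halfK - drlevel)")
  TRUE
})

#' KssdSketch: k-mer substring space sampling sketch
#'
#' The sorted set of 2-bit-encoded canonical k-mers whose central substring
#' code is valid under the bound \linkS4class{KssdDictionary}. Sketches are
#' only comparable when built from the same dictionary (same \code{dictId}).
#'
#' @slot k k-mer length.
#' @slot halfK,drlevel,dictSeed dictionary parameters, carried for
#'   serialization round trips (the dictionary is reproducible from them).
#' @slot dictId digest of the dictionary this sketch is bound to.
#' @slot codes character vector of selected k-mer encodings, strictly
#'   increasing (decimal strings of the 2-bit packed k-mer).
#' @slot nKmers number of k-mer windows consumed.
#' @slot name sketch label.
#'
#' @seealso \code{\link{kssdSketch}}, \code{\link{kssdDictionary}}
#' @exportClass KssdSketch
setClass("KssdSketch",
  representation(k = "integer", halfK = "integer", drlevel = "integer",
                 dictSeed = "numeric", dictId = "character",
                 codes = "character", nKmers = "numeric", name = "character"))

setValidity("KssdSketch", function(object) {
  if (object@k < object@halfK) return("k must be >= halfK")
  .check_u64(object@codes, "codes")
})

#' HLLSketch: HyperLogLog cardinality sketch
#'
#' \eqn{2^p} registers, each holding the maximum over inserted k-mer hashes of
#' (leading-zero count of the hash suffix + 1); the bucket is chosen by the
#' top \eqn{p} bits of the hash. Supports cardinality estimation, exact
#' (register-wise max) merging, and inclusion-exclusion Jaccard estimation.
#'
#' @slot p precision (4--18); the sketch has \eqn{2^p} registers.
#' @slot k k-mer length.
#' @slot seed MurmurHash3 seed.
#' @slot registers integer vector of length \eqn{2^p}, values in
#'   \code{[0, 64 - p + 1]}.
#' @slot name sketch label.
#'
#' @seealso \code{\link{hllSketch}}, \code{\link{hllCardinality}}
#' @exportClass HLLSketch
setClass("HLLSketch",
  representation(p = "integer", k = "integer", seed = "numeric",
                 registers = "integer", name = "character"))

setValidity("HLLSketch", function(object) {
  if (object@p < 4L || object@p > 18L) return("p must be in [4, 18]")
  if (length(object@registers) != 2^object@p)
    return("registers must have length 2^p")
  if (any(object@registers < 0L) ||
      any(object@registers > 64L - object@p + 1L))
    return("register values out of [0, 64 - p + 1]")
  TRUE
})

#' DistanceResult: a single sketch-based distance estimate
#'
#' @slot jaccard estimated Jaccard index in [0, 1].
#' @slot mashDistance Mash distance derived from the Jaccard estimate.
#' @slot shared number of shared sketch elements (or an estimate for HLL).
#' @slot denom estimator denominator (bottom-s' union size for MinHash, full
#'   union size for Kssd, union cardinality estimate for HLL).
#'
#' @seealso \code{\link{jaccard}}, \code{\link{mashDistance}}
#' @exportClass DistanceResult
setClass("DistanceResult",
  representation(jaccard = "numeric", mashDistance = "numeric",
                 shared = "numeric", denom = "numeric"))

setValidity("DistanceResult", function(object) {
  if (object@jaccard < 0 || object@jaccard > 1) return("jaccard out of [0, 1]")
  if (object@denom > 0 && abs(object@jaccard - object@shared / object@denom) > 1e-9)
    return("jaccard must equal shared/denom")
  if ((object@mashDistance == 0) != (object@jaccard == 1))
    return("mashDistance must be 0 exactly when jaccard is 1")
  TRUE
})

#' IndexDict: inverted index over pure-hash sketches
#'
#' Maps every hash value observed in a collection of
#' \linkS4class{MinHashSketch} or \linkS4class{KssdSketch} objects to the
#' (sorted) ids of the sketches containing it. The compact representation
#' stores an entry only for observed hashes, so memory grows with the number
#' of distinct observed values, never with the hash-space size.
#'
#' @slot algorithm "minhash" or "kssd".
#' @slot k,seed,s,dictId parameters shared by all indexed sketches
#'   (\code{s}/\code{dictId} are \code{NA} when not applicable).
#' @slot keys observed hash values, strictly increasing.
#' @slot postings list (parallel to \code{keys}) of sorted integer sketch ids.
#' @slot sketchNames,sketchSizes per-sketch labels and retained-set sizes.
#'
#' @seealso \code{\link{buildIndex}}, \code{\link{allVsAll}}
#' @exportClass IndexDict
setClass("IndexDict",
  representation(algorithm = "character", k = "integer", seed = "numeric",
                 s = "integer", dictId = "character", keys = "character",
                 postings = "list", sketchNames = "character",
                 sketchSizes = "integer"))

setValidity("IndexDict", function(object) {
  if (length(object@keys) != length(object@postings))
    return("keys and postings must be parallel")
  if (sum(lengths(object@postings)) != sum(object@sketchSizes))
    return("sum of posting-list lengths must equal sum of sketch sizes")
  if (any(lengths(object@postings) == 0L))
    return("compact index must not store unobserved hashes")
  ok <- .check_u64(object@keys, "keys")
  if (!isTRUE(ok)) return(ok)
  TRUE
})
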