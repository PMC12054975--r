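#' Create a HyperLogLog sketch
#'
#' A HyperLogLog sketch summarizes the set of canonical k-mer hashes with
#' \eqn{2^p} one-byte registers: the top \eqn{p} bits of each 64-bit hash
#' select a register, and the register keeps the maximum over insertions of
#' (number of leading zeros of the remaining \eqn{64-p} bits + 1). Insertion
#' is idempotent and registers only ever grow, so merging two sketches by
#' register-wise maximum reproduces exactly the sketch of the combined input.
#'
#' @param seqs optional sequences to fold in immediately.
#' @param p precision (4--18); the sketch uses \eqn{2^p} registers and the
#'   cardinality estimate has relative standard error about
#'   \eqn{1.04/\sqrt{2^p}} (0.81\% at the default p = 14).
#' @param k k-mer length, default 21.
#' @param seed MurmurHash3 seed, default 42.
#' @param name sketch label.
#' @return an \linkS4class{HLLSketch}.
#' @examples
#' sk <- hllSketch(randomGenome(5000, seed = 2), p = 10)
#' hllCardinality(sk)  # close to the distinct canonical 21-mer count
#' @export
hllSketch <- function(seqs = NULL, p = 14L, k = 21L, seed = 42, name = "") {
  sk <- new("HLLSketch", p = as.integer(p), k = as.integer(k),
            seed = .check_seed(seed), registers = integer(2^as.integer(p)),
            name = as.character(name))
  validObject(sk)
  if (!is.null(seqs)) sk <- updateSketch(sk, seqs)
  sk
}

#' @rdname updateSketch
setMethod("updateSketch", "HLLSketch", function(x, seqs, ...) {
  ss <- .seqChars(seqs)
  for (i in seq_along(ss))
    x@registers <- cpp_hll_update_seq(x@registers, ss[[i]], x@k, x@p, x@seed, TRUE)
  if (!nzchar(x@name) && length(ss) == 1L) x@name <- names(ss)[1L]
  x
})

#' Insert pre-computed 64-bit hashes into a HyperLogLog sketch
#'
#' Lower-level companion to the sequence-based \code{\link{updateSketch}}
#' method, used for estimator calibration on arbitrary hash streams.
#'
#' @param x an \linkS4class{HLLSketch}.
#' @param hashes character vector of decimal-string 64-bit hash values.
#' @return the updated sketch.
#' @export
hllAddHashes <- function(x, hashes) {
  stopifnot(is(x, "HLLSketch"))
  x@registers <- cpp_hll_add_hashes(x@registers, as.character(hashes), x@p)
  x
}

#' HyperLogLog cardinality estimate
#'
#' The bias-corrected original HyperLogLog estimator: the raw harmonic-mean
#' estimate \eqn{\alpha_m m^2 / \sum_j 2^{-M_j}} is replaced by linear
#' counting \eqn{m \ln(m/V)} (V = number of zero registers) whenever zero
#' registers remain and the raw estimate falls below \eqn{2.5m}. With 64-bit
#' hashes no large-range correction is needed. An untouched sketch estimates
#' exactly 0.
#'
#' @param x an \linkS4class{HLLSketch}.
#' @return estimated number of distinct inserted elements (non-negative).
#' @export
hllCardinality <- function(x) {
  stopifnot(is(x, "HLLSketch"))
  m <- 2^x@p
  alpha <- if (m == 16) 0.673 else if (m == 32) 0.697 else if (m == 64) 0.709
           else 0.7213 / (1 + 1.079 / m)
  raw <- alpha * m^2 / sum(2^(-x@registers))
  zeros <- sum(x@registers == 0L)
  if (zeros > 0L && raw <= 2.5 * m) m * log(m / zeros) else raw
}

#' @rdname mergeSketches
#' @param branchfree use the branch-free register-max kernel (default TRUE);
#'   the branchy reference gives identical results on all register pairs.
setMethod("mergeSketches", signature("HLLSketch", "HLLSketch"),
  function(x, y, branchfree = TRUE, ...) {
    .check_pair(x, y, c("p", "k", "seed"))
    x@registers <- cpp_hll_merge(x@registers, y@registers, isTRUE(branchfree))
    x
  })

#' @rdname jaccard
setMethod("jaccard", signature("HLLSketch", "HLLSketch"),
  function(x, y, ...) {
    .check_pair(x, y, c("p", "k", "seed"))
    ca <- hllCardinality(x)
    cb <- hllCardinality(y)
    cu <- hllCardinality(mergeSketches(x, y))
    inter <- max(0, ca + cb - cu)
    j <- if (cu > 0) min(1, inter / cu) else 0
    new("DistanceResult", jaccard = j, mashDistance = mashDistance(j, x@k),
        shared = min(inter, cu), denom = cu)
  })

#' @rdname accessors
#' @export
setMethod("hllRegisters", "HLLSketch", function(x) x@registers)

#' @rdname accessors
#' @export
setMethod("precision", "HLLSketch", function(x) x@p)

#' @rdname accessors
#' @export
setMethod("kmerSize", "HLLSketch", function(x) x@k)

#' @rdname accessors
#' @export
setMethod("sketchSeed", "HLLSketch", function(x) x@seed)

#' @rdname accessors
#' @export
setMethod("sketchName", "HLLSketch", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("sketchName<-", "HLLSketch", function(x, value) {
  x@name <- as.character(value); x
})

setMethod("show", "HLLSketch", function(object) {
  cat(sprintf(
    "HLLSketch '%s': p=%d (%d registers) k=%d seed=%s | cardinality ~ %.4g\n",
    object@name, object@p, length(object@registers), object@k,
    format(object@seed), hllCardinality(object)))
})
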