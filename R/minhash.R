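#' Create a bottom-s (KMV) MinHash sketch
#'
#' Builds the classic Mash-style sketch: every canonical k-mer is hashed with
#' MurmurHash3 (lower 64 bits of the x64_128 digest of the k-mer's ASCII
#' string), and the \code{s} smallest distinct hash values are retained.
#' Duplicate hash values are stored once (set semantics). The sketch can be
#' grown incrementally with \code{\link{updateSketch}} and combined with
#' \code{\link{mergeSketches}}; either route yields bit-identical results to
#' a single batch build.
#'
#' @param seqs optional sequences to fold in immediately (character vector or
#'   \code{DNAStringSet}).
#' @param k k-mer length (1--32), default 21.
#' @param s sketch size: number of retained hash values, default 1000.
#' @param seed 32-bit MurmurHash3 seed, default 42.
#' @param name sketch label used in distance tables.
#' @return a \linkS4class{MinHashSketch}.
#' @examples
#' g <- randomGenome(2000, seed = 1)
#' sk <- minhashSketch(g, k = 21, s = 200)
#' sk
#' @export
minhashSketch <- function(seqs = NULL, k = 21L, s = 1000L, seed = 42,
                          name = "") {
  sk <- new("MinHashSketch", k = as.integer(k), s = as.integer(s),
            seed = .check_seed(seed), hashes = character(), nKmers = 0,
            name = as.character(name))
  validObject(sk)
  if (!is.null(seqs)) sk <- updateSketch(sk, seqs)
  sk
}

#' @rdname updateSketch
setMethod("updateSketch", "MinHashSketch", function(x, seqs, ...) {
  ss <- .seqChars(seqs)
  for (i in seq_along(ss)) {
    res <- cpp_minhash_update(x@hashes, ss[[i]], x@k, x@s, x@seed)
    x@hashes <- res$hashes
    x@nKmers <- x@nKmers + res$n_kmers
  }
  if (!nzchar(x@name) && length(ss) == 1L) x@name <- names(ss)[1L]
  x
})

.check_pair <- function(x, y, fields) {
  for (f in fields) {
    a <- slot(x, f); b <- slot(y, f)
    if (!identical(a, b))
      stop(sprintf("sketches are incompatible: %s differs (%s vs %s)",
                   f, format(a), format(b)))
  }
}

#' @rdname mergeSketches
setMethod("mergeSketches", signature("MinHashSketch", "MinHashSketch"),
  function(x, y, ...) {
    .check_pair(x, y, c("k", "s", "seed"))
    x@hashes <- cpp_bottom_union(x@hashes, y@hashes, x@s)
    x@nKmers <- x@nKmers + y@nKmers
    x
  })

#' @rdname jaccard
setMethod("jaccard", signature("MinHashSketch", "MinHashSketch"),
  function(x, y, ...) {
    .check_pair(x, y, c("k", "seed"))
    res <- cpp_minhash_jaccard(x@hashes, y@hashes, min(x@s, y@s))
    .distanceResult(res$shared, res$denom, x@k)
  })

#' @rdname accessors
#' @export
setMethod("sketchHashes", "MinHashSketch", function(x) x@hashes)

#' @rdname accessors
#' @export
setMethod("sketchSize", "MinHashSketch", function(x) x@s)

#' @rdname accessors
#' @export
setMethod("kmerSize", "MinHashSketch", function(x) x@k)

#' @rdname accessors
#' @export
setMethod("sketchSeed", "MinHashSketch", function(x) x@seed)

#' @rdname accessors
#' @export
setMethod("nKmers", "MinHashSketch", function(x) x@nKmers)

#' @rdname accessors
#' @export
setMethod("sketchName", "MinHashSketch", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("sketchName<-", "MinHashSketch", function(x, value) {
  x@name <- as.character(value); x
})

setMethod("show", "MinHashSketch", function(object) {
  cat(sprintf(
    "MinHashSketch '%s': k=%d s=%d seed=%s | %d retained hashes, %s k-mers seen\n",
    object@name, object@k, object@s, format(object@seed),
    length(object@hashes), format(object@nKmers)))
})
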