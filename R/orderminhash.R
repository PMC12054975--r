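#' OrderMinHash sketch of a single sequence
#'
#' OrderMinHash extends MinHash with positional information, which makes the
#' resulting similarity sensitive to edit distance rather than to k-mer
#' content alone. The sketch runs \code{m} independent hash repetitions. In
#' repetition \eqn{i}, every k-mer occurrence is hashed together with its
#' occurrence index (the j-th occurrence of an identical k-mer string hashes
#' the k-mer bytes followed by j), the \code{l} occurrences with the smallest
#' hashes are selected, and the selection is re-sorted by position in the
#' sequence. Per-repetition hash seeds are derived reproducibly from
#' \code{seed} (see \code{\link{omhRepetitionSeed}}).
#'
#' OrderMinHash is a per-sequence sketch: building one sketch across the many
#' records of a multi-FASTA would scramble positional order, so multi-record
#' inputs are sketched record by record.
#'
#' The \code{block} argument selects how many repetitions are advanced
#' together while scanning the sequence (the cache-blocked traversal); any
#' value produces bit-identical sketches.
#'
#' @param seq a single sequence of length >= k (character or
#'   \code{DNAStringSet} of length 1).
#' @param k k-mer length, default 16.
#' @param m number of hash repetitions, default 256.
#' @param l minima retained per repetition, default 2.
#' @param seed base hash seed, default 42.
#' @param block repetitions processed per pass, default 1 (row-wise).
#' @param name sketch label.
#' @return an \linkS4class{OMHSketch}.
#' @examples
#' g <- randomGenome(300, seed = 7)
#' sk <- omhSketch(g, k = 8, m = 16, l = 2)
#' omhSimilarity(sk, sk)  # 1
#' @export
omhSketch <- function(seq, k = 16L, m = 256L, l = 2L, seed = 42, block = 1L,
                      name = "") {
  s <- .seqChars(seq)
  if (length(s) != 1L) stop("omhSketch expects a single sequence (per-sequence sketching)")
  rows <- cpp_omh_sketch(s[[1L]], as.integer(k), as.integer(m), as.integer(l),
                         .check_seed(seed), as.integer(block))
  rows <- lapply(rows, function(r) {
    data.frame(hash = r$hash, kmer = r$kmer, occ = r$occ, pos = r$pos,
               stringsAsFactors = FALSE)
  })
  if (!nzchar(name)) name <- names(s)[1L]
  new("OMHSketch", k = as.integer(k), m = as.integer(m), l = as.integer(l),
      seed = as.numeric(seed), rows = rows, name = as.character(name))
}

#' Per-repetition hash seed derivation
#'
#' Repetition \code{i} (0-based) of an OrderMinHash sketch hashes with seed
#' \code{seed XOR fold32(wangMix(i))}, where \code{fold32} xors the two
#' 32-bit halves of the mixed value. Exposed so that independent
#' reimplementations can reproduce the sketch.
#'
#' @param seed the sketch's base seed.
#' @param i repetition index, 0-based.
#' @return the derived 32-bit seed as a numeric value.
#' @export
omhRepetitionSeed <- function(seed, i) cpp_omh_row_seed(.check_seed(seed), as.integer(i))

#' OrderMinHash similarity
#'
#' The fraction of the \code{m} repetitions whose position-ordered selections
#' agree exactly between the two sketches: a repetition counts as matching
#' only when its full l-tuple of (k-mer, occurrence-index) pairs, in
#' positional order, is identical in both sketches. The expectation of this
#' fraction decreases with the edit distance between the underlying
#' sequences.
#'
#' @param a,b two \linkS4class{OMHSketch} objects with identical k, m, l and
#'   seed.
#' @return similarity in [0, 1].
#' @export
omhSimilarity <- function(a, b) {
  stopifnot(is(a, "OMHSketch"), is(b, "OMHSketch"))
  .check_pair(a, b, c("k", "m", "l", "seed"))
  same <- vapply(seq_len(a@m), function(i) {
    ra <- a@rows[[i]]; rb <- b@rows[[i]]
    nrow(ra) == nrow(rb) &&
      identical(ra$kmer, rb$kmer) && identical(ra$occ, rb$occ)
  }, logical(1))
  mean(same)
}

#' @rdname accessors
#' @export
setMethod("omhRows", "OMHSketch", function(x) x@rows)

#' @rdname accessors
#' @export
setMethod("kmerSize", "OMHSketch", function(x) x@k)

#' @rdname accessors
#' @export
setMethod("sketchSeed", "OMHSketch", function(x) x@seed)

#' @rdname accessors
#' @export
setMethod("sketchName", "OMHSketch", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("sketchName<-", "OMHSketch", function(x, value) {
  x@name <- as.character(value); x
})

setMethod("show", "OMHSketch", function(object) {
  cat(sprintf("OMHSketch '%s': k=%d m=%d l=%d seed=%s\n", object@name,
              object@k, object@m, object@l, format(object@seed)))
})
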