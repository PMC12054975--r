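#' Build a Kssd shuffle dictionary
#'
#' Performs a seeded Fisher--Yates shuffle (splitmix64 stream) of the
#' \eqn{4^L} codes of length-\eqn{L} nucleotide substrings. The \eqn{4^{L-d}}
#' codes whose shuffled rank is below \eqn{4^{L-d}} are "valid"; a k-mer
#' enters a sketch exactly when the code of its central length-\eqn{L}
#' substring is valid. Because the dictionary is a deterministic function of
#' \code{(halfK, drlevel, seed)}, every genome sketched with the same
#' parameters samples the same \eqn{4^{-d}} slice of k-mer space, which is
#' what makes Kssd sketches directly comparable across datasets.
#'
#' @param halfK substring length L in bases (1--10), default 6.
#' @param drlevel dimension-reduction level d (0 <= d <= halfK), default 3.
#' @param seed shuffle seed, default 42.
#' @return a \linkS4class{KssdDictionary}.
#' @examples
#' d <- kssdDictionary(halfK = 3, drlevel = 1)
#' sum(d@perm < 4^(3 - 1))  # 16 valid codes
#' @export
kssdDictionary <- function(halfK = 6L, drlevel = 3L, seed = 42) {
  perm <- cpp_kssd_dictionary(as.integer(halfK), as.integer(drlevel),
                              .check_seed(seed))
  id <- sprintf("kssd:L%d:d%d:seed%s:%s", as.integer(halfK),
                as.integer(drlevel), format(seed), cpp_perm_checksum(perm))
  new("KssdDictionary", halfK = as.integer(halfK), drlevel = as.integer(drlevel),
      seed = as.numeric(seed), perm = perm, dictId = id)
}

#' Compact map dictionary of valid codes
#'
#' Extracts the valid codes (those with shuffled rank below \eqn{4^{L-d}})
#' into a compact table of \eqn{4^{L-d}} entries, the cache-resident
#' replacement for the full \eqn{4^L} permutation array. Sketching through
#' the map is bit-identical to sketching through the full array.
#'
#' @param dict a \linkS4class{KssdDictionary}.
#' @return a data frame with columns \code{code} (valid substring code) and
#'   \code{rank} (its shuffled rank), sorted by code.
#' @export
kssdMapDictionary <- function(dict) {
  stopifnot(is(dict, "KssdDictionary"))
  nValid <- 4^(dict@halfK - dict@drlevel)
  idx <- which(dict@perm < nValid)
  data.frame(code = idx - 1, rank = dict@perm[idx])
}

#' Create a Kssd sketch
#'
#' @param seqs optional sequences to fold in immediately.
#' @param dict the \linkS4class{KssdDictionary} the sketch is bound to.
#' @param k k-mer length (>= \code{halfK} of the dictionary), default 21.
#' @param name sketch label.
#' @return a \linkS4class{KssdSketch} whose \code{codes} slot holds the
#'   2-bit encodings of the selected canonical k-mers.
#' @examples
#' d <- kssdDictionary(halfK = 4, drlevel = 1)
#' sk <- kssdSketch(randomGenome(1000, seed = 3), dict = d, k = 21)
#' sk
#' @export
kssdSketch <- function(seqs = NULL, dict, k = 21L, name = "") {
  stopifnot(is(dict, "KssdDictionary"))
  sk <- new("KssdSketch", k = as.integer(k), halfK = dict@halfK,
            drlevel = dict@drlevel, dictSeed = dict@seed, dictId = dict@dictId,
            codes = character(), nKmers = 0, name = as.character(name))
  validObject(sk)
  if (!is.null(seqs)) sk <- updateSketch(sk, seqs, dict = dict)
  sk
}

#' @rdname updateSketch
#' @param dict for the \linkS4class{KssdSketch} method: the dictionary the
#'   sketch was created with (checked by \code{dictId}). Pass
#'   \code{useMap = TRUE} to route membership tests through the compact map
#'   dictionary; the result is identical either way.
#' @param useMap use the compact map-dictionary path (default FALSE).
setMethod("updateSketch", "KssdSketch", function(x, seqs, dict,
                                                 useMap = FALSE, ...) {
  stopifnot(is(dict, "KssdDictionary"))
  if (!identical(dict@dictId, x@dictId))
    stop("dictionary mismatch: sketch is bound to ", x@dictId,
         " but was given ", dict@dictId,
         " (sketches from different dictionaries are incomparable)")
  ss <- .seqChars(seqs)
  mapCodes <- if (useMap) kssdMapDictionary(dict)$code
  for (i in seq_along(ss)) {
    nk <- length(cpp_extract_kmers(ss[[i]], x@k, TRUE)$pos)
    x@codes <- if (useMap)
      cpp_kssd_update_map(x@codes, ss[[i]], x@k, x@halfK, mapCodes, TRUE)
    else
      cpp_kssd_update(x@codes, ss[[i]], x@k, x@halfK, x@drlevel, dict@perm, TRUE)
    x@nKmers <- x@nKmers + nk
  }
  if (!nzchar(x@name) && length(ss) == 1L) x@name <- names(ss)[1L]
  x
})

#' @rdname mergeSketches
setMethod("mergeSketches", signature("KssdSketch", "KssdSketch"),
  function(x, y, ...) {
    .check_pair(x, y, c("k", "dictId"))
    x@codes <- cpp_sort_u64(c(x@codes, y@codes), TRUE)
    x@nKmers <- x@nKmers + y@nKmers
    x
  })

#' @rdname jaccard
setMethod("jaccard", signature("KssdSketch", "KssdSketch"),
  function(x, y, ...) {
    .check_pair(x, y, c("k", "dictId"))
    shared <- cpp_intersect_count(x@codes, y@codes, "merge", 8L, FALSE)
    denom <- length(x@codes) + length(y@codes) - shared
    .distanceResult(shared, denom, x@k)
  })

#' @rdname accessors
#' @export
setMethod("kssdCodes", "KssdSketch", function(x) x@codes)

#' @rdname accessors
#' @export
setMethod("dictId", "KssdSketch", function(x) x@dictId)

#' @rdname accessors
#' @export
setMethod("dictId", "KssdDictionary", function(x) x@dictId)

#' @rdname accessors
#' @export
setMethod("kmerSize", "KssdSketch", function(x) x@k)

#' @rdname accessors
#' @export
setMethod("sketchSeed", "KssdSketch", function(x) x@dictSeed)

#' @rdname accessors
#' @export
setMethod("nKmers", "KssdSketch", function(x) x@nKmers)

#' @rdname accessors
#' @export
setMethod("sketchName", "KssdSketch", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("sketchName<-", "KssdSketch", function(x, value) {
  x@name <- as.character(value); x
})

setMethod("show", "KssdSketch", function(object) {
  cat(sprintf(
    "KssdSketch '%s': k=%d L=%d d=%d | %d selected k-mers of %s seen (%s)\n",
    object@name, object@k, object@halfK, object@drlevel,
    length(object@codes), format(object@nKmers), object@dictId))
})

setMethod("show", "KssdDictionary", function(object) {
  cat(sprintf("KssdDictionary: L=%d d=%d seed=%s | %d codes, %d valid (%s)\n",
              object@halfK, object@drlevel, format(object@seed),
              length(object@perm), 4^(object@halfK - object@drlevel),
              object@dictId))
})
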