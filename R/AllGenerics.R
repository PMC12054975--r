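#' Fold sequences into a sketch (streaming update)
#'
#' Streams the canonical k-mers of one or more nucleotide sequences into an
#' existing sketch. Updating with sequences one at a time produces a sketch
#' identical to a single pass over all of them, and the result never depends
#' on the order in which sequences are supplied.
#'
#' @param x a \linkS4class{MinHashSketch}, \linkS4class{KssdSketch} or
#'   \linkS4class{HLLSketch}.
#' @param seqs sequences: a (possibly named) character vector or a
#'   \code{DNAStringSet}. Lowercase is accepted; windows containing any
#'   non-ACGT character are skipped.
#' @param ... method-specific arguments; the \linkS4class{KssdSketch} method
#'   takes \code{dict}, the bound \linkS4class{KssdDictionary}.
#' @return the updated sketch object.
#' @export
setGeneric("updateSketch", function(x, seqs, ...) standardGeneric("updateSketch"))

#' Merge two sketches
#'
#' Combines two sketches built with identical parameters into the sketch of
#' the union of their inputs: bottom-s of the hash union for MinHash, set
#' union for Kssd, register-wise maximum for HyperLogLog. Merging is
#' commutative, associative and idempotent, and
#' \code{mergeSketches(sketch(X), sketch(Y))} equals the sketch built from X
#' and Y in one pass.
#'
#' @param x,y sketches of the same class with matching parameters.
#' @param ... unused.
#' @return a merged sketch of the same class.
#' @export
setGeneric("mergeSketches", function(x, y, ...) standardGeneric("mergeSketches"))

#' Estimate the Jaccard index of two sketches
#'
#' @param x,y two sketches of the same class, built with compatible
#'   parameters (same k and seed; same sketch size family for MinHash; same
#'   dictionary for Kssd; same precision for HyperLogLog).
#' @param ... unused.
#' @return a \linkS4class{DistanceResult} with the Jaccard estimate, the
#'   derived Mash distance, and the estimator's shared/denominator counts.
#' @export
setGeneric("jaccard", function(x, y, ...) standardGeneric("jaccard"))

#' @rdname accessors
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))

#' @rdname accessors
#' @export
setGeneric("sketchSeed", function(x) standardGeneric("sketchSeed"))

#' @rdname accessors
#' @export
setGeneric("sketchName", function(x) standardGeneric("sketchName"))

#' @rdname accessors
#' @export
setGeneric("sketchName<-", function(x, value) standardGeneric("sketchName<-"))

#' @rdname accessors
#' @export
setGeneric("nKmers", function(x) standardGeneric("nKmers"))

#' Accessors for sketch objects
#'
#' \code{kmerSize} returns k; \code{sketchSeed} the hash seed;
#' \code{sketchName}/\code{sketchName<-} get and set the label used in
#' distance tables; \code{nKmers} the number of k-mer windows consumed;
#' \code{sketchHashes} the retained MinHash values; \code{sketchSize} the
#' MinHash capacity s; \code{kssdCodes} the selected k-mer encodings;
#' \code{dictId} the dictionary digest; \code{omhRows} the per-repetition
#' selections; \code{hllRegisters} and \code{precision} the HyperLogLog
#' register array and p.
#'
#' @param x a sketch object (or \linkS4class{KssdDictionary} for
#'   \code{dictId}).
#' @param value replacement value.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sketchHashes", function(x) standardGeneric("sketchHashes"))

#' @rdname accessors
#' @export
setGeneric("sketchSize", function(x) standardGeneric("sketchSize"))

#' @rdname accessors
#' @export
setGeneric("kssdCodes", function(x) standardGeneric("kssdCodes"))

#' @rdname accessors
#' @export
setGeneric("dictId", function(x) standardGeneric("dictId"))

#' @rdname accessors
#' @export
setGeneric("omhRows", function(x) standardGeneric("omhRows"))

#' @rdname accessors
#' @export
setGeneric("hllRegisters", function(x) standardGeneric("hllRegisters"))

#' @rdname accessors
#' @export
setGeneric("precision", function(x) standardGeneric("precision"))
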