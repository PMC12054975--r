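.sketch_elements <- function(sk) {
  if (is(sk, "MinHashSketch")) sk@hashes else sk@codes
}

# Validate a sketch collection for joint indexing/comparison and return its
# shared parameter set.
.collection_params <- function(sketches) {
  if (!length(sketches)) stop("need at least one sketch")
  cls <- vapply(sketches, function(s) class(s)[1], character(1))
  if (length(unique(cls)) != 1L)
    stop("mixed sketch classes: ", paste(unique(cls), collapse = ", "))
  algo <- switch(cls[1], MinHashSketch = "minhash", KssdSketch = "kssd",
                 stop("all-vs-all indexing supports pure-hash sketches ",
                      "(MinHashSketch or KssdSketch), not ", cls[1]))
  ks <- vapply(sketches, kmerSize, integer(1))
  if (length(unique(ks)) != 1L) stop("sketches disagree on k: ",
                                     paste(unique(ks), collapse = ", "))
  s <- NA_integer_
  dId <- NA_character_
  if (algo == "minhash") {
    sv <- vapply(sketches, sketchSize, integer(1))
    if (length(unique(sv)) != 1L) stop("sketches disagree on sketch size s")
    s <- sv[1]
  } else {
    ids <- vapply(sketches, dictId, character(1))
    if (length(unique(ids)) != 1L)
      stop("sketches from different dictionaries are incomparable")
    dId <- ids[1]
  }
  seeds <- vapply(sketches, sketchSeed, numeric(1))
  if (length(unique(seeds)) != 1L) stop("sketches disagree on seed")
  nm <- vapply(sketches, sketchName, character(1))
  blank <- !nzchar(nm)
  nm[blank] <- paste0("sketch", which(blank))
  if (anyDuplicated(nm)) stop("sketch names must be unique for distance tables")
  list(algorithm = algo, k = ks[1], seed = seeds[1], s = s, dictId = dId,
       names = nm)
}

#' Build an inverted index over a collection of sketches
#'
#' Maps each hash value to the ids of the sketches containing it, the
#' index_dict structure that accelerates all-vs-all comparison. Only observed
#' hashes get an entry (compact representation). All sketches must share
#' their parameters; mixing algorithms, k, seeds, sketch sizes or Kssd
#' dictionaries is an error.
#'
#' @param sketches a list of \linkS4class{MinHashSketch} or of
#'   \linkS4class{KssdSketch} objects.
#' @return an \linkS4class{IndexDict}.
#' @seealso \code{\link{allVsAll}}, \code{\link{pairwiseDistances}}
#' @export
buildIndex <- function(sketches) {
  pp <- .collection_params(sketches)
  lists <- lapply(sketches, .sketch_elements)
  all <- unlist(lists, use.names = FALSE)
  ids <- rep(seq_along(lists), lengths(lists))
  ord <- order(nchar(all), all, ids)  # length-then-lexicographic == numeric
  keys <- unique(all[ord])
  postings <- unname(split(ids[ord], factor(all[ord], levels = keys)))
  new("IndexDict", algorithm = pp$algorithm, k = pp$k, seed = pp$seed,
      s = pp$s, dictId = pp$dictId, keys = keys, postings = postings,
      sketchNames = pp$names,
      sketchSizes = lengths(lists))
}

# Reassemble per-sketch sorted hash lists from the index postings.
.index_lists <- function(idx) {
  n <- length(idx@sketchNames)
  reps <- rep(idx@keys, lengths(idx@postings))
  ids <- unlist(idx@postings, use.names = FALSE)
  out <- split(reps, factor(ids, levels = seq_len(n)))
  unname(out)
}

.pair_table <- function(names, jmat, k, shared, denom) {
  n <- length(names)
  rows <- list()
  t <- 1L
  for (i in seq_len(n)) {
    for (j in i:n) {
      rows[[t]] <- data.frame(ref = names[i], query = names[j],
                              jaccard = jmat[i, j],
                              mash_distance = mashDistance(jmat[i, j], k),
                              shared = shared[i, j], denom = denom[i, j],
                              stringsAsFactors = FALSE)
      t <- t + 1L
    }
  }
  out <- do.call(rbind, rows)
  # fixed lexicographic row order so outputs are byte-comparable
  swap <- out$ref > out$query
  tmp <- out$ref[swap]; out$ref[swap] <- out$query[swap]; out$query[swap] <- tmp
  out <- out[order(out$ref, out$query), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' All-vs-all distances through the inverted index
#'
#' Streams the index in ascending hash order, accumulating per-pair shared
#' counts (and, for MinHash, per-pair union ranks so that the bottom-s'
#' estimator is reproduced exactly). Results are bit-identical to the naive
#' loop over all sketch pairs -- the index is an acceleration, not an
#' approximation.
#'
#' @param idx an \linkS4class{IndexDict}.
#' @return a data frame with one row per unordered sketch pair (self-pairs
#'   included), columns \code{ref}, \code{query}, \code{jaccard},
#'   \code{mash_distance}, \code{shared}, \code{denom}, ordered
#'   lexicographically by (ref, query).
#' @export
allVsAll <- function(idx) {
  stopifnot(is(idx, "IndexDict"))
  lists <- .index_lists(idx)
  n <- length(lists)
  res <- cpp_index_allvsall(lists, if (idx@algorithm == "minhash") idx@s else 0L)
  sh <- res$shared
  denom <- res$union_size
  if (idx@algorithm == "minhash") denom[] <- pmin(denom, idx@s)
  jmat <- ifelse(denom > 0, sh / denom, 0)
  # diagonal: each sketch against itself
  for (i in seq_len(n)) {
    sz <- idx@sketchSizes[i]
    d <- if (idx@algorithm == "minhash") min(idx@s, sz) else sz
    sh[i, i] <- d
    denom[i, i] <- d
    jmat[i, i] <- if (d > 0) 1 else 0
  }
  .pair_table(idx@sketchNames, jmat, idx@k, sh, denom)
}

#' Pairwise distances over a sketch collection
#'
#' Front end over the two equivalent engines: \code{engine = "index"} builds
#' the inverted index and streams it (\code{\link{buildIndex}} +
#' \code{\link{allVsAll}}); \code{engine = "pairwise"} runs
#' \code{\link{jaccard}} on every sketch pair. Both produce identical tables.
#'
#' @param sketches list of \linkS4class{MinHashSketch} or
#'   \linkS4class{KssdSketch} objects with matching parameters.
#' @param engine "index" (default) or "pairwise".
#' @return a data frame as in \code{\link{allVsAll}}.
#' @export
pairwiseDistances <- function(sketches, engine = c("index", "pairwise")) {
  engine <- match.arg(engine)
  if (engine == "index") return(allVsAll(buildIndex(sketches)))
  pp <- .collection_params(sketches)
  n <- length(sketches)
  jmat <- matrix(0, n, n)
  sh <- matrix(0, n, n)
  denom <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      dr <- jaccard(sketches[[i]], sketches[[j]])
      jmat[i, j] <- jmat[j, i] <- dr@jaccard
      sh[i, j] <- sh[j, i] <- dr@shared
      denom[i, j] <- denom[j, i] <- dr@denom
    }
  }
  .pair_table(pp$names, jmat, pp$k, sh, denom)
}

setMethod("show", "IndexDict", function(object) {
  cat(sprintf(
    "IndexDict (%s): %d sketches, %d distinct hashes, k=%d\n",
    object@algorithm, length(object@sketchNames), length(object@keys),
    object@k))
})
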