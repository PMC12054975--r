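#' Synthetic genome fixtures
#'
#' Deterministic sequence generators used throughout the test-suite and in
#' simulation studies. All randomness flows from an explicit seed through a
#' splitmix64 stream, independent of R's global RNG, so fixtures are
#' bit-reproducible across sessions and platforms.
#'
#' \code{randomGenome} draws an i.i.d. uniform ACGT sequence.
#' \code{mutateGenome} substitutes each base independently with the given
#' probability, always to a different base (the divergence model under which
#' the Mash distance estimates the substitution rate). \code{randomEdits}
#' applies a number of random single-character edits (substitution,
#' insertion, deletion with equal probability), the divergence model for
#' OrderMinHash's edit-distance behaviour.
#'
#' @param length genome length in bases.
#' @param seed integer seed (>= 0).
#' @param name sequence name.
#' @return a named character vector of length 1 (accepted by every sketch
#'   constructor; convert with \code{Biostrings::DNAStringSet} if needed).
#' @examples
#' g <- randomGenome(100, seed = 1)
#' m <- mutateGenome(g, rate = 0.05, seed = 2)
#' mean(strsplit(g, "")[[1]] != strsplit(m, "")[[1]])  # about 0.05
#' @export
randomGenome <- function(length, seed, name = paste0("g", seed)) {
  stopifnot(length >= 0, seed >= 0)
  setNames(cpp_random_genome(as.numeric(length), as.numeric(seed)), name)
}

#' @rdname randomGenome
#' @param seq sequence to diverge (character or \code{DNAStringSet} of
#'   length 1).
#' @param rate per-base substitution probability in [0, 1].
#' @export
mutateGenome <- function(seq, rate, seed, name = NULL) {
  s <- .seqChars(seq)
  stopifnot(length(s) == 1L)
  if (is.null(name)) name <- paste0(names(s)[1L], "_mut", seed)
  setNames(cpp_mutate(s[[1L]], rate, as.numeric(seed)), name)
}

#' @rdname randomGenome
#' @param nEdits number of random edits to apply.
#' @export
randomEdits <- function(seq, nEdits, seed, name = NULL) {
  s <- .seqChars(seq)
  stopifnot(length(s) == 1L)
  if (is.null(name)) name <- paste0(names(s)[1L], "_edit", seed)
  setNames(cpp_random_edits(s[[1L]], as.integer(nEdits), as.numeric(seed)), name)
}

#' Exact Jaccard index of two sequences' canonical k-mer sets
#'
#' Brute-force enumeration of the distinct canonical k-mers of both
#' sequences; the reference every sketch-based Jaccard estimator is judged
#' against. Two identical sequences give 1; two sequences whose window sets
#' are both empty also give 1 by convention (empty sets are equal).
#'
#' @param a,b sequences (character or \code{DNAStringSet} of length 1).
#' @param k k-mer length.
#' @return a list with \code{jaccard}, \code{shared} (intersection size) and
#'   \code{denom} (union size).
#' @export
exactJaccard <- function(a, b, k = 21L) {
  sa <- .seqChars(a); sb <- .seqChars(b)
  stopifnot(length(sa) == 1L, length(sb) == 1L)
  cpp_exact_jaccard(sa[[1L]], sb[[1L]], as.integer(k))
}

#' Levenshtein edit distance
#'
#' Unit-cost edit distance (substitutions, insertions, deletions) via
#' \code{utils::adist}; the oracle for OrderMinHash's edit-distance
#' behaviour.
#'
#' @param a,b sequences (character or \code{DNAStringSet} of length 1).
#' @return integer edit distance.
#' @examples
#' editDistance("ACGT", "ACGA")  # 1
#' @export
editDistance <- function(a, b) {
  sa <- .seqChars(a); sb <- .seqChars(b)
  stopifnot(length(sa) == 1L, length(sb) == 1L)
  as.integer(adist(sa[[1L]], sb[[1L]]))
}

#' Write sequences to a FASTA file
#'
#' Small fixture writer used for command-line round trips.
#'
#' @param seqs named character vector (or \code{DNAStringSet}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  s <- .seqChars(seqs)
  lines <- character(2L * length(s))
  lines[c(TRUE, FALSE)] <- paste0(">", names(s))
  lines[c(FALSE, TRUE)] <- unname(s)
  writeLines(lines, path)
  invisible(path)
}
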