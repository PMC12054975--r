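# Coerce sequence input (character / DNAString / DNAStringSet) to a named
# character vector; unnamed entries get seq1, seq2, ...
.seqChars <- function(x) {
  if (is(x, "DNAStringSet")) {
    out <- as.character(x)
  } else if (is(x, "XString")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- x
  } else {
    stop("sequences must be a character vector, DNAString or DNAStringSet")
  }
  nm <- names(out)
  if (is.null(nm)) nm <- rep("", length(out))
  blank <- !nzchar(nm)
  nm[blank] <- paste0("seq", which(blank))
  names(out) <- nm
  out
}

#' Read sequences from a FASTA or FASTQ file
#'
#' The format is autodetected from the first record marker (\code{>} for
#' FASTA, \code{@} for FASTQ) after transparent gzip decompression (detected
#' by magic bytes). FASTQ quality strings are ignored.
#'
#' @param path path to a FASTA/FASTQ file, plain or gzip-compressed.
#' @return a named \code{DNAStringSet}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "ACGTACGT", ">g2", "TTTTACGT"), fa)
#' readSequences(fa)
#' @export
readSequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rt")  # gzfile reads plain files transparently
  first <- tryCatch(readLines(con, n = 1L), finally = close(con))
  if (length(first) == 0L)
    return(Biostrings::DNAStringSet())
  fmt <- if (startsWith(first, ">")) "fasta"
         else if (startsWith(first, "@")) "fastq"
         else stop("cannot detect sequence format of ", path,
                   " (first record starts with '", substr(first, 1, 1), "')")
  Biostrings::readDNAStringSet(path, format = fmt)
}

#' Reverse complement of a nucleotide string
#'
#' Branchless per base: each character maps through a 256-entry complement
#' table (lowercase folded to uppercase, N mapping to N) and the result is
#' reversed. Characters outside A/C/G/T/N are rejected with their position.
#'
#' @param seq character vector of nucleotide strings over A/C/G/T/N
#'   (case-insensitive).
#' @return character vector of reverse complements (uppercase).
#' @examples
#' revComp("AAACCC")  # "GGGTTT"
#' @export
revComp <- function(seq) {
  stopifnot(is.character(seq))
  vapply(seq, cpp_revcomp, character(1), USE.NAMES = !is.null(names(seq)))
}

#' Extract (canonical) k-mers from a sequence
#'
#' Slides a length-k window over the sequence and reports one entry per
#' window consisting only of A/C/G/T (case-insensitive); windows containing
#' any other character (N in particular) are skipped entirely. With
#' \code{canonical = TRUE} each k-mer is replaced by the lexicographic
#' minimum of itself and its reverse complement, so sketches are
#' strand-independent.
#'
#' K-mers are reported as decimal strings of their 2-bit packed encoding
#' (A=0, C=1, G=2, T=3, leftmost base in the most significant bits), which is
#' why k is capped at 32. \code{decodeKmers} recovers the strings.
#'
#' @param seq a single nucleotide string (or length-1 \code{DNAStringSet}).
#' @param k k-mer length, 1--32.
#' @param canonical replace each k-mer by its canonical form (default TRUE).
#' @return a data frame with columns \code{pos} (0-based window start) and
#'   \code{code} (encoded k-mer as a decimal string).
#' @examples
#' extractKmers("ACGTNACGT", k = 4)   # windows at positions 0 and 5 only
#' @export
extractKmers <- function(seq, k = 21L, canonical = TRUE) {
  s <- .seqChars(seq)
  if (length(s) != 1L) stop("extractKmers expects a single sequence")
  res <- cpp_extract_kmers(s[[1L]], as.integer(k), isTRUE(canonical))
  data.frame(pos = res$pos, code = res$code, stringsAsFactors = FALSE)
}

#' @rdname extractKmers
#' @param codes decimal-string k-mer encodings, as produced by
#'   \code{extractKmers}.
#' @export
decodeKmers <- function(codes, k) cpp_decode_kmer(as.character(codes), as.integer(k))

#' @rdname extractKmers
#' @param kmers k-mer strings to encode.
#' @export
encodeKmers <- function(kmers) cpp_encode_kmer(as.character(kmers))
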