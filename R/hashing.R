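.check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed < 0 || seed >= 2^32 || seed != floor(seed))
    stop("hash seed must be a single integer in [0, 2^32)")
  seed
}

#' 64-bit string and integer hashes
#'
#' \code{murmur64} hashes the bytes of each input string with MurmurHash3
#' x64_128 and keeps the lower 64 bits of the digest. \code{murmur64Batch}
#' processes many strings per call through a fixed-width lane layout and is
#' contractually bit-identical to the element-wise \code{murmur64}.
#' \code{wangMix} applies Thomas Wang's 64-bit invertible integer mix. All
#' 64-bit values are exchanged as decimal strings (R has no native unsigned
#' 64-bit type).
#'
#' Output is endianness-independent: the same bytes and seed give the same
#' hash on every platform.
#'
#' @param x character vector of byte strings to hash (for \code{murmur64}),
#'   or of decimal-string 64-bit integers (for \code{wangMix}).
#' @param seed 32-bit integer seed (default 42).
#' @return character vector of decimal-string 64-bit hash values.
#' @examples
#' murmur64("ACGT")
#' identical(murmur64Batch(c("a", "b")), murmur64(c("a", "b")))
#' wangMix("0")
#' @export
murmur64 <- function(x, seed = 42) {
  stopifnot(is.character(x))
  cpp_murmur64(x, .check_seed(seed))
}

#' @rdname murmur64
#' @export
murmur64Batch <- function(x, seed = 42) {
  stopifnot(is.character(x))
  cpp_murmur64_batch(x, .check_seed(seed))
}

#' @rdname murmur64
#' @export
wangMix <- function(x) {
  if (is.numeric(x)) {
    if (any(x < 0) || any(x != floor(x)) || any(x >= 2^53))
      stop("numeric input to wangMix must be non-negative integers below 2^53; ",
           "use decimal strings for the full 64-bit domain")
    x <- sprintf("%.0f", x)
  }
  cpp_wang_mix(x)
}

#' Sort 64-bit values held as decimal strings
#'
#' @param x character vector of decimal-string 64-bit values.
#' @param unique drop duplicates (default TRUE).
#' @return sorted (ascending, numeric order) character vector.
#' @export
sortHashes <- function(x, unique = TRUE) cpp_sort_u64(as.character(x), isTRUE(unique))
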