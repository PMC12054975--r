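#' Count the intersection of two sorted 64-bit hash sets
#'
#' Shared engine behind MinHash and Kssd sketch comparison. Two
#' implementations are provided: the plain two-pointer merge and a block
#' method that compares fixed-width blocks of elements and advances the list
#' whose block maximum is smaller (the branch-misprediction optimization).
#' Both return exactly the same count on every valid input.
#'
#' @param a,b character vectors of strictly increasing decimal-string 64-bit
#'   values.
#' @param method "merge" (two-pointer) or "block".
#' @param blockWidth elements per block for the block method, default 8.
#' @param check verify that inputs are strictly increasing (debug mode,
#'   default TRUE); with \code{check = FALSE} inputs are trusted.
#' @return the intersection size, \eqn{|a \cap b|}.
#' @examples
#' intersectCount(c("1", "5", "9"), c("5", "9", "12"))  # 2
#' @export
intersectCount <- function(a, b, method = c("merge", "block"), blockWidth = 8L,
                           check = TRUE) {
  method <- match.arg(method)
  cpp_intersect_count(as.character(a), as.character(b), method,
                      as.integer(blockWidth), isTRUE(check))
}
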