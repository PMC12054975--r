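#' Mash distance from a sketch Jaccard estimate
#'
#' Converts a Jaccard index \eqn{j} estimated from k-mer sketches into the
#' Mash distance
#' \deqn{D = -\frac{1}{k}\,\ln\!\frac{2j}{1+j},}
#' an estimate of the per-base mutation rate between two genomes under a
#' Poisson model of random site substitution. \eqn{D} is 0 exactly when
#' \eqn{j = 1}, is clamped to 1 when \eqn{j = 0}, and is truncated to
#' \code{[0, 1]} otherwise.
#'
#' @param j Jaccard estimate(s) in [0, 1].
#' @param k the k-mer length the sketches were built with.
#' @return Mash distance(s) in [0, 1].
#' @examples
#' mashDistance(1, 21)    # 0
#' mashDistance(0, 21)    # 1 (clamped)
#' mashDistance(0.5, 21)  # -log(2/3)/21
#' @export
mashDistance <- function(j, k) {
  if (any(is.na(j)) || any(j < 0) || any(j > 1))
    stop("jaccard values must lie in [0, 1]")
  stopifnot(k >= 1)
  d <- ifelse(j == 0, 1, -log(2 * j / (1 + j)) / k)
  pmin(1, pmax(0, d))
}

# Internal constructor: shared/denom counts -> DistanceResult.
.distanceResult <- function(shared, denom, k) {
  j <- if (denom > 0) shared / denom else 0
  new("DistanceResult", jaccard = j, mashDistance = mashDistance(j, k),
      shared = as.numeric(shared), denom = as.numeric(denom))
}

#' @describeIn DistanceResult-class compact display.
#' @param object a \linkS4class{DistanceResult}.
#' @export
setMethod("show", "DistanceResult", function(object) {
  cat(sprintf("DistanceResult: jaccard %.6g (%s/%s), mash distance %.6g\n",
              object@jaccard, format(object@shared), format(object@denom),
              object@mashDistance))
})
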