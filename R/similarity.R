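#' L1 distance between two histograms
#'
#' Minkowski distance with exponent 1 (city-block), the classical
#' edge-histogram matching distance.
#'
#' @param h1,h2 Equal-length numeric vectors.
#' @return Sum of absolute bin differences.
#' @examples
#' l1HistogramDistance(c(1, 0, 0), c(0, 1, 0))   # 2
#' @export
l1HistogramDistance <- function(h1, h2) {
    if (length(h1) != length(h2))
        stop("histograms must have equal length")
    sum(abs(h1 - h2))
}

#' Texture distance between two edge-histogram descriptors
#'
#' L1 distance over all 150 bins with the 5 global bins weighted five-fold:
#' sum |EH_q - EH_t| over the 80 local bins, plus 5 times the sum over the
#' 5 global bins, plus the sum over the 65 semiglobal bins. The up-weighting
#' lets the whole-image edge distribution carry as much weight as a
#' localized difference.
#'
#' @param q,t [EdgeHistogramDescriptor-class] objects.
#' @return Nonnegative distance; a metric on descriptor space.
#' @examples
#' loc <- matrix(0, 16, 5)
#' a <- EdgeHistogramDescriptor(loc)
#' textureDistance(a, a)   # 0
#' @export
textureDistance <- function(q, t) {
    if (!is(q, "EdgeHistogramDescriptor") || !is(t, "EdgeHistogramDescriptor"))
        stop("both arguments must be EdgeHistogramDescriptor objects")
    sum(abs(q@local - t@local)) +
        5 * sum(abs(q@global - t@global)) +
        sum(abs(q@semiglobal - t@semiglobal))
}

#' Map a distance to a similarity in [0, 1]
#'
#' Affine normalization (dmax - d)/dmax: identical items (d = 0) score 1,
#' maximally distant items (d = dmax) score 0.
#'
#' @param d Nonnegative distance, at most `dmax`.
#' @param dmax Positive normalizing maximum distance.
#' @return Similarity in [0, 1].
#' @examples
#' normalizeDistance(0, 3)     # 1
#' normalizeDistance(1.5, 3)   # 0.5
#' @export
normalizeDistance <- function(d, dmax) {
    if (any(dmax <= 0)) stop("'dmax' must be positive")
    if (any(d < 0) || any(d > dmax))
        stop("'d' must lie in [0, dmax]")
    (dmax - d) / dmax
}

#' Fuse color and texture similarities
#'
#' Convex combination w1 * d1 + w2 * d2 of the two normalized per-feature
#' similarities; the default weighting 0.6 : 0.4 favors color.
#'
#' @param d1,d2 Normalized similarities in [0, 1] (color, texture).
#' @param w1,w2 Nonnegative weights summing to 1.
#' @return Fused similarity in [0, 1].
#' @examples
#' fuseSimilarities(1, 0)   # 0.6
#' @export
fuseSimilarities <- function(d1, d2, w1 = 0.6, w2 = 0.4) {
    if (any(d1 < 0 | d1 > 1) || any(d2 < 0 | d2 > 1))
        stop("similarities must lie in [0, 1]")
    if (w1 < 0 || w2 < 0 || abs(w1 + w2 - 1) > 1e-9)
        stop("weights must be nonnegative and sum to 1")
    w1 * d1 + w2 * d2
}
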