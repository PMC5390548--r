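#' @import methods
NULL

## ---------------------------------------------------------------------------
## Parameter classes
## ---------------------------------------------------------------------------

#' Parameters for dominant-color extraction
#'
#' Bundles all tuning knobs of the generalized-Lloyd (LBG) dominant-color
#' extractor: the coarse-region occupancy threshold used to seed the palette,
#' the split and merge thresholds of the refinement phase, the per-channel
#' weights of the HSV distance, and the convergence controls.
#'
#' All distances and errors are computed in normalized HSV coordinates
#' (hue divided by 360 with circular differences, saturation and value as-is),
#' so thresholds are unitless fractions.
#'
#' @slot areaThreshold Fraction of image pixels a coarse HSV region must
#'   exceed to seed an initial palette color (default 0.15).
#' @slot splitThreshold Within-cluster weighted mean squared error above which
#'   a cluster is split in two (default 0.01).
#' @slot mergeThreshold Weighted center distance below which two clusters are
#'   merged (default 0.1).
#' @slot weights Positive weights for the (hue, saturation, value) channels in
#'   every distance computation (default c(2, 1, 1), emphasizing hue).
#' @slot maxIter Maximum Lloyd iterations per assignment/update phase.
#' @slot maxRounds Maximum outer split/merge rounds.
#' @slot tol Center-movement convergence tolerance in normalized units.
#' @slot seed Integer seed carried in configuration round-trips; the extractor
#'   itself is deterministic.
#'
#' @seealso [extractMainColors()], [GlaParams()]
#' @export
setClass("GlaParams", representation(
    areaThreshold = "numeric",
    splitThreshold = "numeric",
    mergeThreshold = "numeric",
    weights = "numeric",
    maxIter = "integer",
    maxRounds = "integer",
    tol = "numeric",
    seed = "integer"
))

setValidity("GlaParams", function(object) {
    msg <- character()
    if (length(object@areaThreshold) != 1L ||
        object@areaThreshold <= 0 || object@areaThreshold >= 1)
        msg <- c(msg, "'areaThreshold' must be a single value in (0, 1)")
    if (length(object@splitThreshold) != 1L || object@splitThreshold <= 0)
        msg <- c(msg, "'splitThreshold' must be a single positive value")
    if (length(object@mergeThreshold) != 1L || object@mergeThreshold <= 0)
        msg <- c(msg, "'mergeThreshold' must be a single positive value")
    if (length(object@weights) != 3L || any(object@weights <= 0))
        msg <- c(msg, "'weights' must be 3 positive values (h, s, v)")
    if (object@maxIter < 1L) msg <- c(msg, "'maxIter' must be >= 1")
    if (object@maxRounds < 0L) msg <- c(msg, "'maxRounds' must be >= 0")
    if (object@tol <= 0) msg <- c(msg, "'tol' must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct dominant-color extraction parameters
#'
#' @param areaThreshold,splitThreshold,mergeThreshold,weights,maxIter,maxRounds,tol,seed
#'   See the slot documentation in [GlaParams-class].
#' @return A `GlaParams` object.
#' @examples
#' GlaParams(areaThreshold = 0.15)
#' @export
GlaParams <- function(areaThreshold = 0.15, splitThreshold = 0.01,
                      mergeThreshold = 0.1, weights = c(2, 1, 1),
                      maxIter = 100L, maxRounds = 10L, tol = 1e-6,
                      seed = 1L) {
    new("GlaParams", areaThreshold = areaThreshold,
        splitThreshold = splitThreshold, mergeThreshold = mergeThreshold,
        weights = as.numeric(weights), maxIter = as.integer(maxIter),
        maxRounds = as.integer(maxRounds), tol = tol,
        seed = as.integer(seed))
}

#' Parameters for edge-histogram extraction
#'
#' @slot blocksPerSubimage Number of blocks tiling each of the 16 subimages;
#'   must be a perfect square (default 256, a 16x16 grid).
#' @slot edgeThreshold Minimum edge-filter response for a block to count as an
#'   edge block, on the 0-255 gray scale (default 20).
#' @slot quantize Whether to also emit 3-bit quantized local bins.
#'
#' @seealso [extractEdgeDescriptor()], [EhdParams()]
#' @export
setClass("EhdParams", representation(
    blocksPerSubimage = "integer",
    edgeThreshold = "numeric",
    quantize = "logical"
))

setValidity("EhdParams", function(object) {
    msg <- character()
    g <- sqrt(object@blocksPerSubimage)
    if (length(object@blocksPerSubimage) != 1L ||
        object@blocksPerSubimage < 1L || g != floor(g))
        msg <- c(msg, "'blocksPerSubimage' must be a perfect square >= 1")
    if (length(object@edgeThreshold) != 1L || object@edgeThreshold < 0)
        msg <- c(msg, "'edgeThreshold' must be a single nonnegative value")
    if (length(object@quantize) != 1L || is.na(object@quantize))
        msg <- c(msg, "'quantize' must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
})

#' Construct edge-histogram extraction parameters
#'
#' @param blocksPerSubimage,edgeThreshold,quantize See
#'   [EhdParams-class].
#' @return An `EhdParams` object.
#' @examples
#' EhdParams()                         # defaults: 256 blocks, threshold 20
#' EhdParams(blocksPerSubimage = 64)   # for images smaller than 128x128
#' @export
EhdParams <- function(blocksPerSubimage = 256L, edgeThreshold = 20,
                      quantize = FALSE) {
    new("EhdParams", blocksPerSubimage = as.integer(blocksPerSubimage),
        edgeThreshold = edgeThreshold, quantize = quantize)
}

## ---------------------------------------------------------------------------
## Descriptor classes
## ---------------------------------------------------------------------------

#' Dominant-color descriptor
#'
#' A compact color signature: k representative HSV colors with the fraction
#' of image pixels each one covers. Fractions sum to 1 and entries are stored
#' in decreasing order of coverage.
#'
#' @slot colors k x 3 numeric matrix with columns h (degrees, [0, 360)),
#'   s and v (both [0, 1]).
#' @slot fractions Numeric vector of k coverage fractions, summing to 1,
#'   nonincreasing.
#'
#' @seealso [extractMainColors()], [traditionalMainColors()], [dcdDistance()]
#' @export
setClass("MainColorDescriptor", representation(
    colors = "matrix",
    fractions = "numeric"
))

setValidity("MainColorDescriptor", function(object) {
    msg <- character()
    k <- nrow(object@colors)
    if (k < 1L) msg <- c(msg, "descriptor must contain at least one color")
    if (ncol(object@colors) != 3L)
        msg <- c(msg, "'colors' must have 3 columns (h, s, v)")
    if (length(object@fractions) != k)
        msg <- c(msg, "'fractions' length must match number of colors")
    else {
        if (abs(sum(object@fractions) - 1) > 1e-9)
            msg <- c(msg, "'fractions' must sum to 1")
        if (any(object@fractions < 0))
            msg <- c(msg, "'fractions' must be nonnegative")
        if (is.unsorted(rev(object@fractions)))
            msg <- c(msg, "'fractions' must be nonincreasing")
    }
    if (k >= 1L && ncol(object@colors) == 3L) {
        h <- object@colors[, 1L]; s <- object@colors[, 2L]
        v <- object@colors[, 3L]
        if (any(h < 0 | h >= 360)) msg <- c(msg, "hue must be in [0, 360)")
        if (any(s < 0 | s > 1 | v < 0 | v > 1))
            msg <- c(msg, "s and v must be in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a dominant-color descriptor
#'
#' Entries are sorted by fraction (decreasing) on construction.
#'
#' @param colors k x 3 matrix of HSV colors (h in degrees, s and v in [0,1]).
#' @param fractions Numeric vector of k fractions summing to 1.
#' @return A `MainColorDescriptor`.
#' @examples
#' MainColorDescriptor(rbind(c(0, 1, 1), c(120, 1, 1)), c(0.3, 0.7))
#' @export
MainColorDescriptor <- function(colors, fractions) {
    colors <- rbind(colors)
    ord <- order(fractions, decreasing = TRUE)
    new("MainColorDescriptor",
        colors = colors[ord, , drop = FALSE],
        fractions = as.numeric(fractions[ord]))
}

#' Edge-histogram descriptor
#'
#' Edge structure of an image summarized at three scales: a 16 x 5 local
#' histogram (fraction of edge blocks of each of five edge types per
#' subimage of the 4 x 4 grid), a 5-bin global histogram (mean over
#' subimages), and a 13 x 5 semiglobal histogram (means over the 4 columns,
#' 4 rows and 5 overlapping 2x2 clusters of subimages). Edge types, in bin
#' order, are vertical, horizontal, 45 degree, 135 degree, nondirectional.
#'
#' @slot local 16 x 5 numeric matrix, values in [0, 1]; rows are subimages in
#'   row-major order, row sums may be below 1 (blocks with no edge).
#' @slot global Numeric vector of 5 values, the column means of `local`.
#' @slot semiglobal 13 x 5 numeric matrix of group means of `local` rows.
#' @slot quantized Integer vector of 80 3-bit codes in [0, 7] (row-major
#'   flattening of `local`), or `integer(0)` when quantization was not
#'   requested.
#'
#' @seealso [extractEdgeDescriptor()], [textureDistance()]
#' @export
setClass("EdgeHistogramDescriptor", representation(
    local = "matrix",
    global = "numeric",
    semiglobal = "matrix",
    quantized = "integer"
))

setValidity("EdgeHistogramDescriptor", function(object) {
    msg <- character()
    if (!all(dim(object@local) == c(16L, 5L)))
        msg <- c(msg, "'local' must be 16 x 5")
    if (length(object@global) != 5L)
        msg <- c(msg, "'global' must have 5 bins")
    if (!all(dim(object@semiglobal) == c(13L, 5L)))
        msg <- c(msg, "'semiglobal' must be 13 x 5")
    if (any(object@local < -1e-12 | object@local > 1 + 1e-12))
        msg <- c(msg, "'local' bins must lie in [0, 1]")
    nq <- length(object@quantized)
    if (nq != 0L && nq != 80L)
        msg <- c(msg, "'quantized' must be empty or 80 codes")
    if (nq == 80L && any(object@quantized < 0L | object@quantized > 7L))
        msg <- c(msg, "'quantized' codes must be in [0, 7]")
    if (length(msg)) msg else TRUE
})

#' Construct an edge-histogram descriptor
#'
#' @param local 16 x 5 matrix of local bins.
#' @param global 5-vector of global bins; computed from `local` if missing.
#' @param semiglobal 13 x 5 matrix of semiglobal bins; computed from `local`
#'   if missing.
#' @param quantized Optional 80 integer codes in [0, 7].
#' @return An `EdgeHistogramDescriptor`.
#' @export
EdgeHistogramDescriptor <- function(local, global = globalHistogram(local),
                                    semiglobal = semiglobalHistogram(local),
                                    quantized = integer(0)) {
    new("EdgeHistogramDescriptor", local = local, global = global,
        semiglobal = semiglobal, quantized = as.integer(quantized))
}

## ---------------------------------------------------------------------------
## Retrieval classes
## ---------------------------------------------------------------------------

#' Descriptor index of an image collection
#'
#' Stores, per image, the dominant-color and edge-histogram descriptors plus
#' an optional class label used for retrieval evaluation. Image ids are
#' unique within an index.
#'
#' @slot ids Character vector of unique image ids.
#' @slot labels Character vector of class labels (`NA` when unlabeled).
#' @slot colorDescriptors List of [MainColorDescriptor-class] objects.
#' @slot edgeDescriptors List of [EdgeHistogramDescriptor-class] objects.
#' @slot glaParams,ehdParams Parameters the descriptors were extracted with.
#'
#' @seealso [buildIndex()], [queryIndex()]
#' @export
setClass("TongueIndex", representation(
    ids = "character",
    labels = "character",
    colorDescriptors = "list",
    edgeDescriptors = "list",
    glaParams = "GlaParams",
    ehdParams = "EhdParams"
))

setValidity("TongueIndex", function(object) {
    msg <- character()
    n <- length(object@ids)
    if (anyDuplicated(object@ids))
        msg <- c(msg, "image ids must be unique")
    if (length(object@labels) != n ||
        length(object@colorDescriptors) != n ||
        length(object@edgeDescriptors) != n)
        msg <- c(msg, "ids, labels and descriptor lists must align")
    if (length(msg)) msg else TRUE
})

#' Ranked retrieval result
#'
#' @slot queryId Identifier of the query image.
#' @slot ranking data.frame with columns `image_id`, `fused`, `d1`, `d2`
#'   (fused similarity and the two normalized per-feature similarities),
#'   sorted by `fused` decreasing with ties broken by `image_id`.
#' @slot weights Fusion weights (color, texture) used.
#'
#' @seealso [queryIndex()], [precisionRecall()]
#' @export
setClass("QueryResult", representation(
    queryId = "character",
    ranking = "data.frame",
    weights = "numeric"
))

setValidity("QueryResult", function(object) {
    msg <- character()
    need <- c("image_id", "fused", "d1", "d2")
    if (!all(need %in% names(object@ranking)))
        msg <- c(msg, "ranking must have columns image_id, fused, d1, d2")
    else if (is.unsorted(rev(object@ranking$fused)))
        msg <- c(msg, "ranking must be sorted by fused similarity, decreasing")
    if (length(object@weights) != 2L)
        msg <- c(msg, "weights must be length 2")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "MainColorDescriptor", function(object) {
    k <- nrow(object@colors)
    cat("MainColorDescriptor with", k, if (k == 1L) "color\n" else "colors\n")
    df <- data.frame(h = round(object@colors[, 1L], 1),
                     s = round(object@colors[, 2L], 3),
                     v = round(object@colors[, 3L], 3),
                     fraction = round(object@fractions, 4))
    print(df, row.names = FALSE)
    invisible(NULL)
})

setMethod("show", "EdgeHistogramDescriptor", function(object) {
    cat("EdgeHistogramDescriptor: 80 local + 5 global + 65 semiglobal bins\n")
    g <- round(object@global, 4)
    names(g) <- c("vert", "horiz", "diag45", "diag135", "nondir")
    cat("global:\n"); print(g)
    cat(if (length(object@quantized)) "quantized codes: present\n"
        else "quantized codes: absent\n")
    invisible(NULL)
})

setMethod("show", "TongueIndex", function(object) {
    cat("TongueIndex of", length(object@ids), "images\n")
    lab <- object@labels[!is.na(object@labels)]
    if (length(lab)) {
        cat("classes:\n")
        print(table(lab))
    } else cat("unlabeled\n")
    invisible(NULL)
})

setMethod("show", "QueryResult", function(object) {
    cat("QueryResult for query '", object@queryId, "' (w_color = ",
        object@weights[1L], ", w_texture = ", object@weights[2L], ")\n",
        sep = "")
    print(utils::head(object@ranking, 9L), row.names = FALSE)
    if (nrow(object@ranking) > 9L)
        cat("...", nrow(object@ranking) - 9L, "more\n")
    invisible(NULL)
})

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' Accessors for descriptors, indexes and query results
#'
#' `mainColors()` and `colorFractions()` return the HSV color matrix and the
#' coverage fractions of a dominant-color descriptor; `numColors()` its k.
#' `localHist()`, `globalHist()`, `semiglobalHist()` and `quantizedHist()`
#' return the components of an edge-histogram descriptor. `indexIds()` and
#' `indexLabels()` return the ids and class labels of an index; `ranking()`
#' the ranked data.frame of a query result.
#'
#' @param x The object to access.
#' @return The corresponding slot value.
#' @name accessors
#' @aliases mainColors colorFractions numColors localHist globalHist
#'   semiglobalHist quantizedHist indexIds indexLabels ranking
#' @examples
#' d <- MainColorDescriptor(rbind(c(0, 1, 1)), 1)
#' mainColors(d)
#' colorFractions(d)
NULL

#' @rdname accessors
#' @export
mainColors <- function(x) x@colors

#' @rdname accessors
#' @export
colorFractions <- function(x) x@fractions

#' @rdname accessors
#' @export
numColors <- function(x) nrow(x@colors)

#' @rdname accessors
#' @export
localHist <- function(x) x@local

#' @rdname accessors
#' @export
globalHist <- function(x) x@global

#' @rdname accessors
#' @export
semiglobalHist <- function(x) x@semiglobal

#' @rdname accessors
#' @export
quantizedHist <- function(x) x@quantized

#' @rdname accessors
#' @export
indexIds <- function(x) x@ids

#' @rdname accessors
#' @export
indexLabels <- function(x) x@labels

#' @rdname accessors
#' @export
ranking <- function(x) x@ranking

#' @describeIn TongueIndex-class Number of indexed images.
#' @param x A `TongueIndex`.
#' @export
setMethod("length", "TongueIndex", function(x) length(x@ids))
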