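#' Build a descriptor index from an image collection
#'
#' Extracts the dominant-color and edge-histogram descriptors of every
#' image and stores them with the image ids and optional class labels.
#' Images that fail to load or process are skipped with a warning.
#'
#' @param images Either a named list of H x W x 3 RGB arrays, or a
#'   character vector of image file paths (read with [readImageRGB()];
#'   ids default to file names without extension).
#' @param labels Optional character vector of class labels, parallel to
#'   `images`, used by the evaluation functions.
#' @param glaParams A [GlaParams-class] object.
#' @param ehdParams An [EhdParams-class] object.
#' @param grayCoeffs Gray conversion coefficient set, see [rgbToGray()].
#' @return A [TongueIndex-class].
#' @examples
#' imgs <- list(a = array(200, c(32, 32, 3)), b = array(40, c(32, 32, 3)))
#' idx <- buildIndex(imgs, labels = c("bright", "dark"),
#'                   ehdParams = EhdParams(blocksPerSubimage = 16))
#' length(idx)   # 2
#' @export
buildIndex <- function(images, labels = NULL, glaParams = GlaParams(),
                       ehdParams = EhdParams(),
                       grayCoeffs = c("standard", "alt")) {
    grayCoeffs <- match.arg(grayCoeffs)
    fromPaths <- is.character(images)
    n <- length(images)
    if (n < 1L) stop("empty image collection")
    ids <- if (fromPaths)
        sub("\\.[A-Za-z]+$", "", basename(images))
    else if (!is.null(names(images))) names(images)
    else sprintf("img%03d", seq_len(n))
    if (is.null(labels)) labels <- rep(NA_character_, n)

    keep <- logical(n)
    cds <- eds <- vector("list", n)
    for (i in seq_len(n)) {
        res <- tryCatch({
            img <- if (fromPaths) readImageRGB(images[[i]]) else images[[i]]
            list(cd = extractMainColors(img, glaParams),
                 ed = extractEdgeDescriptor(img, ehdParams,
                                            coeffs = grayCoeffs))
        }, error = function(e) {
            warning("skipping '", ids[i], "': ", conditionMessage(e),
                    call. = FALSE)
            NULL
        })
        if (!is.null(res)) {
            keep[i] <- TRUE
            cds[[i]] <- res$cd
            eds[[i]] <- res$ed
        }
    }
    if (!any(keep)) stop("no image could be indexed")
    new("TongueIndex", ids = ids[keep], labels = as.character(labels[keep]),
        colorDescriptors = cds[keep], edgeDescriptors = eds[keep],
        glaParams = glaParams, ehdParams = ehdParams)
}

## raw color and texture distances from a query's descriptors to all entries
.indexDistances <- function(index, colorDesc, edgeDesc, weights, dmax) {
    d1 <- vapply(index@colorDescriptors, dcdDistance, numeric(1L),
                 f2 = colorDesc, weights = weights, dmax = dmax)
    d2 <- vapply(index@edgeDescriptors, textureDistance, numeric(1L),
                 t = edgeDesc)
    list(d1 = d1, d2 = d2)
}

#' Rank an index against a query image
#'
#' Computes the dominant-color distance and the texture distance from the
#' query to every indexed image, converts each to a similarity in [0, 1]
#' by [normalizeDistance()] against the per-query maximum over the index
#' (so the farthest entry scores 0 on that feature), fuses them with
#' weights `w1` (color) and `w2` (texture), and returns the entries ranked
#' by fused similarity (ties broken by image id).
#'
#' Setting `w1 = 1, w2 = 0` gives a color-only ranking, `w1 = 0, w2 = 1` a
#' texture-only one.
#'
#' @param index A [TongueIndex-class].
#' @param image H x W x 3 RGB array, or a file path, or a list with
#'   precomputed elements `color` ([MainColorDescriptor-class]) and `edge`
#'   ([EdgeHistogramDescriptor-class]).
#' @param w1,w2 Fusion weights (color, texture), nonnegative, summing to 1.
#' @param topK Number of entries to return (defaults to the whole index).
#' @param queryId Id recorded in the result.
#' @param dcdWeights,dcdDmax Parameters of [dcdDistance()].
#' @return A [QueryResult-class].
#' @export
queryIndex <- function(index, image, w1 = 0.6, w2 = 0.4,
                       topK = length(index), queryId = "query",
                       dcdWeights = index@glaParams@weights, dcdDmax = 0.1) {
    if (length(index) < 1L) stop("empty index")
    if (w1 < 0 || w2 < 0 || abs(w1 + w2 - 1) > 1e-9)
        stop("weights must be nonnegative and sum to 1")
    if (is.list(image) && !is.null(image$color)) {
        cd <- image$color; ed <- image$edge
    } else {
        if (is.character(image)) image <- readImageRGB(image)
        cd <- extractMainColors(image, index@glaParams)
        ed <- extractEdgeDescriptor(image, index@ehdParams)
    }
    dd <- .indexDistances(index, cd, ed, dcdWeights, dcdDmax)
    ## per-query empirical maxima; an all-identical feature scores 1 for all
    s1 <- if (max(dd$d1) > 0) normalizeDistance(dd$d1, max(dd$d1))
          else rep(1, length(dd$d1))
    s2 <- if (max(dd$d2) > 0) normalizeDistance(dd$d2, max(dd$d2))
          else rep(1, length(dd$d2))
    fused <- w1 * s1 + w2 * s2
    ord <- order(-fused, index@ids)
    ord <- ord[seq_len(min(topK, length(ord)))]
    new("QueryResult", queryId = queryId,
        ranking = data.frame(image_id = index@ids[ord], fused = fused[ord],
                             d1 = s1[ord], d2 = s2[ord],
                             stringsAsFactors = FALSE),
        weights = c(w1, w2))
}

#' Precision and recall of a retrieval result
#'
#' With L returned images, M of them relevant, and D relevant images in
#' the whole database: precision = M/L and recall = M/D.
#'
#' @param result A [QueryResult-class].
#' @param relevantIds Character vector of all relevant image ids in the
#'   database.
#' @return One-row data.frame with columns `precision`, `recall`, `L`,
#'   `M`, `D`.
#' @export
precisionRecall <- function(result, relevantIds) {
    returned <- result@ranking$image_id
    if (length(returned) < 1L) stop("empty result list")
    D <- length(unique(relevantIds))
    if (D == 0L) stop("the relevant set is empty")
    L <- length(returned)
    M <- sum(returned %in% relevantIds)
    data.frame(precision = M / L, recall = M / D, L = L, M = M, D = D)
}

#' Average precision-recall curve over a query set
#'
#' For every cutoff L from 1 to the index size, averages precision and
#' recall over the queries; each query's relevant set is the set of
#' same-class entries. Queries are entries of the index itself and are
#' excluded from their own ranking (and relevant set) by default.
#'
#' @param index A labeled [TongueIndex-class].
#' @param queryIds Ids of index entries to use as queries (default: all).
#' @param w1,w2 Fusion weights (color, texture).
#' @param excludeSelf Drop the query image from its own ranking.
#' @param dcdDmax Passed to [queryIndex()].
#' @return data.frame with columns `L`, `precision`, `recall`.
#' @export
prCurve <- function(index, queryIds = indexIds(index), w1 = 0.6, w2 = 0.4,
                    excludeSelf = TRUE, dcdDmax = 0.1) {
    if (anyNA(index@labels)) stop("all index entries must be labeled")
    pos <- match(queryIds, index@ids)
    if (anyNA(pos)) stop("unknown query id(s)")
    nL <- length(index) - as.integer(excludeSelf)
    P <- R <- matrix(0, length(pos), nL)
    for (qi in seq_along(pos)) {
        i <- pos[qi]
        res <- queryIndex(index,
                          list(color = index@colorDescriptors[[i]],
                               edge = index@edgeDescriptors[[i]]),
                          w1 = w1, w2 = w2, queryId = index@ids[i],
                          dcdDmax = dcdDmax)
        rk <- res@ranking$image_id
        rel <- index@ids[index@labels == index@labels[i]]
        if (excludeSelf) {
            rk <- rk[rk != index@ids[i]]
            rel <- setdiff(rel, index@ids[i])
        }
        hits <- cumsum(rk %in% rel)
        P[qi, ] <- hits / seq_len(nL)
        R[qi, ] <- hits / length(rel)
    }
    data.frame(L = seq_len(nL), precision = colMeans(P),
               recall = colMeans(R))
}

#' Mean precision/recall at a fixed cutoff
#'
#' Convenience wrapper around [prCurve()] reporting the average precision
#' and recall of the top-`topK` retrieval over a query set.
#'
#' @inheritParams prCurve
#' @param topK Retrieval cutoff (default 9).
#' @return One-row data.frame with columns `precision`, `recall`, `topK`.
#' @export
evaluateRetrieval <- function(index, topK = 9L, queryIds = indexIds(index),
                              w1 = 0.6, w2 = 0.4, excludeSelf = TRUE,
                              dcdDmax = 0.1) {
    curve <- prCurve(index, queryIds, w1, w2, excludeSelf, dcdDmax)
    topK <- min(topK, nrow(curve))
    data.frame(precision = curve$precision[topK],
               recall = curve$recall[topK], topK = topK)
}
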