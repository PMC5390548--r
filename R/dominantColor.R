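## Dominant-color extraction.
##
## The extractor works in normalized HSV coordinates: hue divided by 360
## (differences circular), saturation and value as-is. All thresholds in
## GlaParams are expressed in these units.

.normHsv <- function(m) cbind(m[, 1L] / 360, m[, 2L], m[, 3L])

.denormHsv <- function(m) cbind((m[, 1L] %% 1) * 360, m[, 2L], m[, 3L])

.circDiff <- function(a, b) {
    d <- abs(a - b) %% 1
    pmin(d, 1 - d)
}

## circular mean of normalized hues; degenerate resultants fall back to the
## arithmetic mean for determinism
.circMean <- function(hn, wts = NULL) {
    ang <- 2 * pi * hn
    if (is.null(wts)) {
        sx <- mean(cos(ang)); sy <- mean(sin(ang))
    } else {
        wts <- wts / sum(wts)
        sx <- sum(wts * cos(ang)); sy <- sum(wts * sin(ang))
    }
    if (sqrt(sx^2 + sy^2) < 1e-12)
        return(mean(hn) %% 1)
    (atan2(sy, sx) / (2 * pi)) %% 1
}

## squared weighted distance of every row of P (n x 3 normalized) to a center
.wdist2 <- function(P, center, w) {
    w[1L] * .circDiff(P[, 1L], center[1L])^2 +
        w[2L] * (P[, 2L] - center[2L])^2 +
        w[3L] * (P[, 3L] - center[3L])^2
}

.wdist2Centers <- function(c1, c2, w) {
    w[1L] * .circDiff(c1[1L], c2[1L])^2 +
        w[2L] * (c1[2L] - c2[2L])^2 + w[3L] * (c1[3L] - c2[3L])^2
}

## nearest-center labels (1-based); ties go to the lowest center index
.assignNorm <- function(P, C, w) {
    D <- matrix(vapply(seq_len(nrow(C)),
                       function(i) .wdist2(P, C[i, ], w),
                       numeric(nrow(P))),
                nrow = nrow(P), ncol = nrow(C))
    max.col(-D, ties.method = "first")
}

## per-cluster centroids (circular hue); empty clusters dropped
.centersNorm <- function(P, labels, k) {
    keep <- sort(unique(labels))
    C <- t(vapply(keep, function(i) {
        Pi <- P[labels == i, , drop = FALSE]
        c(.circMean(Pi[, 1L]), mean(Pi[, 2L]), mean(Pi[, 3L]))
    }, numeric(3L)))
    C
}

.objective <- function(P, C, labels, w) {
    s <- 0
    for (i in seq_len(nrow(C))) {
        sel <- labels == i
        if (any(sel)) s <- s + sum(.wdist2(P[sel, , drop = FALSE], C[i, ], w))
    }
    s
}

## one Lloyd phase: alternate assignment and centroid update to convergence;
## returns centers, labels and the per-iteration objective trace
.lloyd <- function(P, C, w, tol, maxIter) {
    trace <- numeric(0)
    labels <- .assignNorm(P, C, w)
    for (iter in seq_len(maxIter)) {
        Cnew <- .centersNorm(P, labels, nrow(C))
        newLabels <- .assignNorm(P, Cnew, w)
        trace <- c(trace, .objective(P, Cnew, newLabels, w))
        moved <- if (nrow(Cnew) != nrow(C)) Inf else
            max(sqrt(vapply(seq_len(nrow(C)),
                            function(i) .wdist2Centers(C[i, ], Cnew[i, ], w),
                            numeric(1L))))
        C <- Cnew
        labels <- newLabels
        if (moved < tol) break
    }
    list(centers = C, labels = labels, trace = trace)
}

#' Coarse HSV region occupancies of an image
#'
#' Fraction of pixels falling in each of the nine coarse HSV regions
#' (see [quantizeHsv()]).
#'
#' @param image H x W x 3 HSV array.
#' @return Named numeric vector of 9 fractions summing to 1.
#' @examples
#' img <- array(rep(c(120, 0.8, 0.6), each = 16), c(4, 4, 3))
#' areaProbabilities(img)["green"]   # 1
#' @export
areaProbabilities <- function(image) {
    labels <- quantizeHsvImage(image)
    if (length(labels) == 0L) stop("empty image")
    p <- tabulate(as.vector(labels) + 1L, nbins = 9L) / length(labels)
    names(p) <- colorAreaNames
    p
}

#' Data-driven initial palette for dominant-color clustering
#'
#' Counts the coarse HSV regions occupied by more than `areaThreshold` of
#' the pixels; each such region seeds one initial cluster at the mean color
#' of its pixels (circular mean on hue). When no region passes the
#' threshold, the single most occupied region is used (k = 1).
#'
#' @param image H x W x 3 HSV array.
#' @param params A [GlaParams-class] object.
#' @return List with `k` (number of initial colors) and `centers`
#'   (k x 3 HSV matrix, hue in degrees).
#' @export
initialPalette <- function(image, params = GlaParams()) {
    labels <- quantizeHsvImage(image)
    p <- tabulate(as.vector(labels) + 1L, nbins = 9L) / length(labels)
    sel <- which(p > params@areaThreshold) - 1L
    if (length(sel) == 0L) sel <- which.max(p) - 1L
    P <- .normHsv(cbind(as.vector(image[, , 1L]), as.vector(image[, , 2L]),
                        as.vector(image[, , 3L])))
    lv <- as.vector(labels)
    centers <- t(vapply(sel, function(a) {
        Pa <- P[lv == a, , drop = FALSE]
        c(.circMean(Pa[, 1L]), mean(Pa[, 2L]), mean(Pa[, 3L]))
    }, numeric(3L)))
    list(k = length(sel), centers = .denormHsv(centers))
}

#' Assign pixels to the nearest cluster center
#'
#' Weighted squared HSV distance with circular hue differences; hue is
#' normalized to [0, 1) internally. Ties go to the lowest center index.
#'
#' @param image H x W x 3 HSV array.
#' @param centers k x 3 HSV matrix (hue in degrees).
#' @param weights Channel weights (h, s, v).
#' @return H x W integer matrix of 1-based center indices.
#' @export
assignPixels <- function(image, centers, weights = c(2, 1, 1)) {
    .checkHsvImage(image)
    centers <- rbind(centers)
    if (nrow(centers) < 1L) stop("at least one center is required")
    d <- dim(image)
    P <- .normHsv(cbind(as.vector(image[, , 1L]), as.vector(image[, , 2L]),
                        as.vector(image[, , 3L])))
    matrix(.assignNorm(P, .normHsv(centers), weights), d[1L], d[2L])
}

#' Recompute cluster centers from an assignment
#'
#' Each center becomes the mean of its member pixels (circular mean on hue);
#' clusters with no members are dropped.
#'
#' @param image H x W x 3 HSV array.
#' @param labels H x W integer matrix of 1-based cluster indices.
#' @return k' x 3 HSV matrix (k' <= max label), with a `counts` attribute
#'   giving the member count of each retained cluster.
#' @export
updateCenters <- function(image, labels) {
    .checkHsvImage(image)
    P <- .normHsv(cbind(as.vector(image[, , 1L]), as.vector(image[, , 2L]),
                        as.vector(image[, , 3L])))
    lv <- as.vector(labels)
    C <- .centersNorm(P, lv, max(lv))
    out <- .denormHsv(C)
    attr(out, "counts") <- as.integer(table(factor(lv, sort(unique(lv)))))
    out
}

## ---------------------------------------------------------------------------
## Cluster lists for the split / merge refinement
## ---------------------------------------------------------------------------

#' Build a cluster list from an image and cluster centers
#'
#' Assigns pixels to `centers` and packages each cluster with its member
#' pixels, count and within-cluster error (weighted mean squared deviation
#' from the center in normalized HSV units). This is the representation the
#' split and merge passes operate on.
#'
#' @param image H x W x 3 HSV array.
#' @param centers k x 3 HSV matrix (hue in degrees).
#' @param weights Channel weights (h, s, v).
#' @return List of clusters; each is a list with `center` (HSV triple,
#'   degrees), `pixels` (m x 3 HSV matrix), `count` and `withinError`.
#' @seealso [splitClusters()], [mergeClusters()]
#' @export
colorClusters <- function(image, centers, weights = c(2, 1, 1)) {
    labels <- assignPixels(image, centers, weights)
    centers <- rbind(centers)
    lv <- as.vector(labels)
    pix <- cbind(as.vector(image[, , 1L]), as.vector(image[, , 2L]),
                 as.vector(image[, , 3L]))
    lapply(seq_len(nrow(centers)), function(i) {
        M <- pix[lv == i, , drop = FALSE]
        err <- if (nrow(M) == 0L) 0 else
            mean(.wdist2(.normHsv(M), .normHsv(rbind(centers[i, ]))[1L, ],
                         weights))
        list(center = centers[i, ], pixels = M, count = nrow(M),
             withinError = err)
    })
}

#' Split overdispersed clusters
#'
#' Every cluster whose within-cluster error exceeds `splitThreshold` is
#' replaced by two clusters whose centers are offset from the old one by
#' plus and minus half the member standard deviation along the coordinate
#' of largest weighted variance (the standard LBG split). Other clusters
#' pass through unchanged. New clusters carry no members until the next
#' assignment pass.
#'
#' @param clusters Cluster list from [colorClusters()].
#' @param splitThreshold Error threshold (normalized units).
#' @param weights Channel weights (h, s, v).
#' @return A cluster list, possibly longer than the input.
#' @export
splitClusters <- function(clusters, splitThreshold = 0.01,
                          weights = c(2, 1, 1)) {
    out <- list()
    for (cl in clusters) {
        if (cl$withinError <= splitThreshold || cl$count < 2L) {
            out <- c(out, list(cl))
            next
        }
        Pn <- .normHsv(cl$pixels)
        cn <- .normHsv(rbind(cl$center))[1L, ]
        dev <- cbind(((Pn[, 1L] - cn[1L] + 0.5) %% 1) - 0.5,
                     Pn[, 2L] - cn[2L], Pn[, 3L] - cn[3L])
        wvar <- weights * apply(dev, 2L, function(x) mean(x^2))
        j <- which.max(wvar)
        off <- sqrt(mean(dev[, j]^2)) / 2
        c1 <- cn; c2 <- cn
        c1[j] <- c1[j] - off; c2[j] <- c2[j] + off
        if (j == 1L) { c1[1L] <- c1[1L] %% 1; c2[1L] <- c2[1L] %% 1 }
        else { c1[j] <- min(max(c1[j], 0), 1); c2[j] <- min(max(c2[j], 0), 1) }
        out <- c(out, list(
            list(center = .denormHsv(rbind(c1))[1L, ], pixels = NULL,
                 count = 0L, withinError = 0),
            list(center = .denormHsv(rbind(c2))[1L, ], pixels = NULL,
                 count = 0L, withinError = 0)))
    }
    out
}

#' Merge close cluster pairs
#'
#' While any two centers are closer than `mergeThreshold` (weighted HSV
#' distance, circular hue), the closest such pair is merged into a single
#' cluster whose center is the count-weighted mean of the two (circular on
#' hue) and whose count is the sum.
#'
#' @param clusters Cluster list from [colorClusters()].
#' @param mergeThreshold Center-distance threshold (normalized units).
#' @param weights Channel weights (h, s, v).
#' @return A cluster list, possibly shorter than the input.
#' @export
mergeClusters <- function(clusters, mergeThreshold = 0.1,
                          weights = c(2, 1, 1)) {
    if (length(clusters) < 2L) return(clusters)
    repeat {
        k <- length(clusters)
        if (k < 2L) break
        Cn <- .normHsv(t(vapply(clusters, `[[`, numeric(3L), "center")))
        best <- NULL; bestd <- Inf
        for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
            dij <- sqrt(.wdist2Centers(Cn[i, ], Cn[j, ], weights))
            if (dij < bestd) { bestd <- dij; best <- c(i, j) }
        }
        if (bestd >= mergeThreshold) break
        i <- best[1L]; j <- best[2L]
        ci <- clusters[[i]]; cj <- clusters[[j]]
        ni <- max(ci$count, 1L); nj <- max(cj$count, 1L)
        hn <- .circMean(c(Cn[i, 1L], Cn[j, 1L]), wts = c(ni, nj))
        sv <- (ni * Cn[i, 2:3] + nj * Cn[j, 2:3]) / (ni + nj)
        merged <- list(
            center = .denormHsv(rbind(c(hn, sv)))[1L, ],
            pixels = if (!is.null(ci$pixels) && !is.null(cj$pixels))
                rbind(ci$pixels, cj$pixels) else NULL,
            count = ci$count + cj$count,
            withinError = 0)
        clusters <- c(clusters[-c(i, j)], list(merged))
    }
    clusters
}

## ---------------------------------------------------------------------------
## Full extraction
## ---------------------------------------------------------------------------

#' Extract the dominant colors of an image
#'
#' The full dominant-color pipeline: convert to HSV, seed the palette from
#' the coarse HSV regions occupied by more than `areaThreshold` of the
#' pixels ([initialPalette()]), run Lloyd iterations (nearest-center
#' assignment / centroid update) to convergence, then alternate split
#' passes (clusters with within-error above `splitThreshold` are divided)
#' and merge passes (centers closer than `mergeThreshold` are united), each
#' followed by re-convergence, until the clustering is stable or
#' `maxRounds` is reached.
#'
#' @param image H x W x 3 RGB array in [0, 255].
#' @param params A [GlaParams-class] object.
#' @return A [MainColorDescriptor-class]; entries sorted by coverage
#'   fraction, fractions summing to 1. The attribute `objectiveTrace` holds
#'   one numeric vector of total within-cluster weighted squared error per
#'   Lloyd phase (each nonincreasing).
#' @examples
#' img <- array(0, c(16, 16, 3)); img[, , 1] <- 220; img[, , 3] <- 40
#' d <- extractMainColors(img)
#' numColors(d)          # 1 for a solid image
#' colorFractions(d)     # 1
#' @export
extractMainColors <- function(image, params = GlaParams()) {
    .checkRgbImage(image)
    hsv <- rgbToHsv(image)
    w <- params@weights
    P <- .normHsv(cbind(as.vector(hsv[, , 1L]), as.vector(hsv[, , 2L]),
                        as.vector(hsv[, , 3L])))
    init <- initialPalette(hsv, params)
    C <- .normHsv(rbind(init$centers))
    traces <- list()

    fit <- .lloyd(P, C, w, params@tol, params@maxIter)
    traces <- c(traces, list(fit$trace))
    C <- fit$centers; labels <- fit$labels

    for (round in seq_len(params@maxRounds)) {
        changed <- FALSE

        ## split pass
        errs <- vapply(seq_len(nrow(C)), function(i) {
            sel <- labels == i
            if (!any(sel)) 0 else
                mean(.wdist2(P[sel, , drop = FALSE], C[i, ], w))
        }, numeric(1L))
        if (any(errs > params@splitThreshold)) {
            newC <- NULL
            for (i in seq_len(nrow(C))) {
                if (errs[i] <= params@splitThreshold) {
                    newC <- rbind(newC, C[i, ])
                    next
                }
                sel <- labels == i
                dev <- P[sel, , drop = FALSE]
                dev <- cbind(((dev[, 1L] - C[i, 1L] + 0.5) %% 1) - 0.5,
                             dev[, 2L] - C[i, 2L], dev[, 3L] - C[i, 3L])
                wvar <- w * colMeans(dev^2)
                j <- which.max(wvar)
                off <- sqrt(mean(dev[, j]^2)) / 2
                c1 <- C[i, ]; c2 <- C[i, ]
                c1[j] <- c1[j] - off; c2[j] <- c2[j] + off
                if (j == 1L) { c1[1L] <- c1[1L] %% 1; c2[1L] <- c2[1L] %% 1 }
                newC <- rbind(newC, c1, c2)
            }
            C <- newC
            fit <- .lloyd(P, C, w, params@tol, params@maxIter)
            traces <- c(traces, list(fit$trace))
            C <- fit$centers; labels <- fit$labels
            changed <- TRUE
        }

        ## merge pass
        counts <- tabulate(labels, nbins = nrow(C))
        merged <- FALSE
        while (nrow(C) >= 2L) {
            k <- nrow(C)
            best <- NULL; bestd <- Inf
            for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
                dij <- sqrt(.wdist2Centers(C[i, ], C[j, ], w))
                if (dij < bestd) { bestd <- dij; best <- c(i, j) }
            }
            if (bestd >= params@mergeThreshold) break
            i <- best[1L]; j <- best[2L]
            ni <- counts[i]; nj <- counts[j]
            hn <- .circMean(c(C[i, 1L], C[j, 1L]), wts = c(ni, nj))
            sv <- (ni * C[i, 2:3] + nj * C[j, 2:3]) / (ni + nj)
            C <- rbind(C[-c(i, j), , drop = FALSE], c(hn, sv))
            counts <- c(counts[-c(i, j)], ni + nj)
            merged <- TRUE
        }
        if (merged) {
            fit <- .lloyd(P, C, w, params@tol, params@maxIter)
            traces <- c(traces, list(fit$trace))
            C <- fit$centers; labels <- fit$labels
            changed <- TRUE
        }

        if (!changed) break
    }

    counts <- tabulate(labels, nbins = nrow(C))
    frac <- counts / nrow(P)
    out <- MainColorDescriptor(.denormHsv(C), frac)
    attr(out, "objectiveTrace") <- traces
    out
}

#' Traditional occupancy-threshold main colors
#'
#' The classical main-color baseline: quantize every pixel to the nine
#' coarse HSV regions, keep the regions covering at least `minFraction` of
#' the pixels, represent each by its mean member color (circular mean on
#' hue), and renormalize the retained fractions to sum to 1.
#'
#' @param image H x W x 3 HSV array.
#' @param minFraction Minimum region coverage to keep (default 0.05).
#' @return A [MainColorDescriptor-class].
#' @export
traditionalMainColors <- function(image, minFraction = 0.05) {
    labels <- quantizeHsvImage(image)
    lv <- as.vector(labels)
    p <- tabulate(lv + 1L, nbins = 9L) / length(lv)
    keep <- which(p >= minFraction) - 1L
    if (length(keep) == 0L) keep <- which.max(p) - 1L
    P <- .normHsv(cbind(as.vector(image[, , 1L]), as.vector(image[, , 2L]),
                        as.vector(image[, , 3L])))
    centers <- t(vapply(keep, function(a) {
        Pa <- P[lv == a, , drop = FALSE]
        c(.circMean(Pa[, 1L]), mean(Pa[, 2L]), mean(Pa[, 3L]))
    }, numeric(3L)))
    MainColorDescriptor(.denormHsv(centers), p[keep + 1L] / sum(p[keep + 1L]))
}

#' Distance between two dominant-color descriptors
#'
#' Quadratic-form dominant-color matching:
#' D^2 = sum(mu1^2) + sum(mu2^2) - 2 * sum_ij a_ij mu1_i mu2_j with color
#' similarity a_ij = 1 - min(dist(c1_i, c2_j)/dmax, 1), where dist is the
#' weighted HSV distance (circular hue, normalized units) and `dmax` a
#' fixed normalizer beyond which colors count as fully dissimilar. The
#' alternative `method = "areahist"` compares the descriptors as 9-bin
#' coarse-region occupancy histograms by Euclidean distance.
#'
#' @param f1,f2 [MainColorDescriptor-class] objects.
#' @param weights Channel weights (h, s, v).
#' @param dmax Color-similarity normalizer (normalized weighted units).
#' @param method `"quadratic"` (default) or `"areahist"`.
#' @return Nonnegative distance; 0 for identical descriptors; symmetric.
#' @examples
#' a <- MainColorDescriptor(rbind(c(0, 1, 1)), 1)
#' b <- MainColorDescriptor(rbind(c(180, 1, 1)), 1)
#' dcdDistance(a, a)      # 0
#' dcdDistance(a, b)^2    # 2 (colors beyond dmax)
#' @export
dcdDistance <- function(f1, f2, weights = c(2, 1, 1), dmax = 0.1,
                        method = c("quadratic", "areahist")) {
    method <- match.arg(method)
    if (numColors(f1) < 1L || numColors(f2) < 1L)
        stop("empty descriptor")
    if (method == "areahist") {
        hist9 <- function(f) {
            a <- quantizeHsv(f@colors[, 1L], f@colors[, 2L], f@colors[, 3L])
            as.vector(tapply(f@fractions, factor(a, levels = 0:8), sum,
                             default = 0))
        }
        return(sqrt(sum((hist9(f1) - hist9(f2))^2)))
    }
    C1 <- .normHsv(f1@colors); C2 <- .normHsv(f2@colors)
    mu1 <- f1@fractions; mu2 <- f2@fractions
    A <- outer(seq_len(nrow(C1)), seq_len(nrow(C2)),
               Vectorize(function(i, j) {
                   d <- sqrt(.wdist2Centers(C1[i, ], C2[j, ], weights))
                   1 - min(d / dmax, 1)
               }))
    d2 <- sum(mu1^2) + sum(mu2^2) - 2 * sum(A * outer(mu1, mu2))
    sqrt(max(d2, 0))
}
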