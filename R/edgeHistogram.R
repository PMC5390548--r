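## Edge-histogram descriptor.
##
## Edge types, in fixed bin order: vertical, horizontal, 45 degree,
## 135 degree, nondirectional. Each image block is divided into 2 x 2
## macroblocks whose mean gray levels feed the five MPEG-7 edge filters:
##   vertical        ( 1, -1,  1, -1)
##   horizontal      ( 1,  1, -1, -1)
##   45 degree       (sqrt2, 0, 0, -sqrt2)
##   135 degree      (0, sqrt2, -sqrt2, 0)
##   nondirectional  ( 2, -2, -2,  2)
## in macroblock order top-left, top-right, bottom-left, bottom-right; the
## absolute response is compared against the edge threshold.

edgeTypeNames <- c("vertical", "horizontal", "diag45", "diag135",
                   "nondirectional")

.checkGrayImage <- function(image) {
    if (!is.matrix(image))
        stop("a gray image must be an H x W matrix")
    if (anyNA(image) || min(image) < 0 || max(image) > 255)
        stop("gray values must lie in [0, 255]")
    invisible(image)
}

## mean-pool an r*mh x c*mw matrix into an r x c matrix of tile means
.poolMean <- function(A, mh, mw) {
    r <- nrow(A) %/% mh
    cc <- ncol(A) %/% mw
    A1 <- colMeans(array(A, c(mh, r, ncol(A))))        # r x ncol
    t(colMeans(array(t(A1), c(mw, cc, r))))            # r x cc
}

## five absolute filter responses from the four macroblock-mean layers
.edgeResponses <- function(a0, a1, a2, a3) {
    list(abs(a0 - a1 + a2 - a3),
         abs(a0 + a1 - a2 - a3),
         sqrt(2) * abs(a0 - a3),
         sqrt(2) * abs(a1 - a2),
         2 * abs(a0 - a1 - a2 + a3))
}

#' Partition a gray image into the 4 x 4 subimage grid
#'
#' Subimage boundaries are integer floors of H/4 and W/4; remainder pixels
#' are attached to the last row and column of the grid.
#'
#' @param image H x W gray matrix, H and W at least 8.
#' @return List of 16 matrices, subimages in row-major order.
#' @examples
#' subs <- partitionSubimages(matrix(0, 16, 16))
#' dim(subs[[1]])   # 4 4
#' @export
partitionSubimages <- function(image) {
    .checkGrayImage(image)
    H <- nrow(image); W <- ncol(image)
    if (H < 8L || W < 8L) stop("image must be at least 8 x 8")
    bh <- H %/% 4L; bw <- W %/% 4L
    rowStart <- (0:3) * bh + 1L
    rowEnd <- c((1:3) * bh, H)
    colStart <- (0:3) * bw + 1L
    colEnd <- c((1:3) * bw, W)
    out <- vector("list", 16L)
    for (r in 1:4) for (cc in 1:4)
        out[[(r - 1L) * 4L + cc]] <-
            image[rowStart[r]:rowEnd[r], colStart[cc]:colEnd[cc],
                  drop = FALSE]
    out
}

#' Classify a single image block into an edge type
#'
#' The block is split into four equal macroblocks whose mean gray levels
#' are filtered by the five MPEG-7 edge operators. If the largest absolute
#' response strictly exceeds `threshold` the block takes that edge type
#' (ties resolved in the order vertical, horizontal, 45, 135,
#' nondirectional); otherwise it is a no-edge block.
#'
#' @param block Gray matrix with even side lengths >= 2.
#' @param threshold Edge threshold on the 0-255 gray scale.
#' @return List with `type` (one of `edgeTypeNames` or `"none"`) and
#'   `strength` (largest absolute filter response).
#' @examples
#' blk <- cbind(c(255, 255), c(0, 0))     # left bright, right dark
#' blockEdgeType(blk, 20)                  # vertical, strength 510
#' @export
blockEdgeType <- function(block, threshold = 20) {
    .checkGrayImage(block)
    if (nrow(block) < 2L || ncol(block) < 2L ||
        nrow(block) %% 2L != 0L || ncol(block) %% 2L != 0L)
        stop("block sides must be even and at least 2")
    mh <- nrow(block) %/% 2L; mw <- ncol(block) %/% 2L
    M <- .poolMean(block, mh, mw)
    E <- unlist(.edgeResponses(M[1L, 1L], M[1L, 2L], M[2L, 1L], M[2L, 2L]))
    i <- which.max(E)
    if (E[i] > threshold)
        list(type = edgeTypeNames[i], strength = E[i])
    else
        list(type = "none", strength = E[i])
}

#' Local edge histogram of a gray image
#'
#' Each of the 16 subimages is tiled by a g x g grid of blocks
#' (g = sqrt(blocksPerSubimage); block sides are the largest even numbers
#' not exceeding floor(subimage side / g), trailing pixels dropped). Every
#' block is classified by [blockEdgeType()] and per-type counts are divided
#' by the number of blocks, giving 16 x 5 bins in [0, 1].
#'
#' @param image H x W gray matrix. With the default 256 blocks per
#'   subimage the image must be at least 128 x 128; pass a smaller
#'   `blocksPerSubimage` for smaller images.
#' @param params An [EhdParams-class] object.
#' @return 16 x 5 numeric matrix; columns in `edgeTypeNames` order.
#' @export
localHistogram <- function(image, params = EhdParams()) {
    subs <- partitionSubimages(image)
    g <- as.integer(sqrt(params@blocksPerSubimage))
    thr <- params@edgeThreshold
    local <- matrix(0, 16L, 5L, dimnames = list(NULL, edgeTypeNames))
    for (si in seq_len(16L)) {
        A <- subs[[si]]
        bh <- ((nrow(A) %/% g) %/% 2L) * 2L
        bw <- ((ncol(A) %/% g) %/% 2L) * 2L
        if (bh < 2L || bw < 2L)
            stop("image too small: blocks of subimage ", si,
                 " would be under 2 x 2; reduce 'blocksPerSubimage'")
        A <- A[seq_len(g * bh), seq_len(g * bw), drop = FALSE]
        ## macroblock-mean grid, 2g x 2g; per-block layers by parity
        M <- .poolMean(A, bh %/% 2L, bw %/% 2L)
        odd <- seq(1L, 2L * g, by = 2L); even <- odd + 1L
        E <- .edgeResponses(M[odd, odd], M[odd, even],
                            M[even, odd], M[even, even])
        Earr <- array(unlist(E), c(g, g, 5L))
        flat <- matrix(Earr, g * g, 5L)
        mx <- do.call(pmax, E)
        amax <- max.col(flat, ties.method = "first")
        edge <- as.vector(mx) > thr
        local[si, ] <- tabulate(amax[edge], nbins = 5L) / (g * g)
    }
    local
}

#' Global edge histogram
#'
#' Arithmetic mean of the 16 local subimage histograms per edge type.
#'
#' @param local 16 x 5 local histogram matrix.
#' @return Numeric vector of 5 bins.
#' @export
globalHistogram <- function(local) {
    stopifnot(is.matrix(local), all(dim(local) == c(16L, 5L)))
    colMeans(local)
}

## row-major subimage indices (r, c in 0..3) for each of the 13 groups
.semiglobalGroups <- function() {
    idx <- function(r, cc) r * 4L + cc + 1L
    g <- vector("list", 13L)
    for (cc in 0:3) g[[cc + 1L]] <- idx(0:3, cc)            # 4 columns
    for (r in 0:3)  g[[r + 5L]] <- idx(r, 0:3)              # 4 rows
    quad <- list(c(0L, 1L), c(0L, 1L), c(2L, 3L), c(2L, 3L))
    quadc <- list(c(0L, 1L), c(2L, 3L), c(0L, 1L), c(2L, 3L))
    for (q in 1:4)                                          # corner quadrants
        g[[q + 8L]] <- as.vector(outer(quad[[q]], quadc[[q]], idx))
    g[[13L]] <- as.vector(outer(c(1L, 2L), c(1L, 2L), idx)) # center cluster
    g
}

#' Semiglobal edge histogram
#'
#' Means of the local histogram over 13 subimage groups of the 4 x 4 grid:
#' the four columns (groups 1-4), the four rows (5-8), the four corner
#' 2 x 2 quadrants (9-12) and the center 2 x 2 quadrant (13).
#'
#' @param local 16 x 5 local histogram matrix.
#' @return 13 x 5 numeric matrix.
#' @export
semiglobalHistogram <- function(local) {
    stopifnot(is.matrix(local), all(dim(local) == c(16L, 5L)))
    groups <- .semiglobalGroups()
    out <- t(vapply(groups, function(m) colMeans(local[m, , drop = FALSE]),
                    numeric(5L)))
    colnames(out) <- colnames(local)
    out
}

#' 3-bit uniform quantization of histogram bins
#'
#' Codes bin values in [0, 1] to 8 uniform levels:
#' code = min(floor(8 v), 7).
#'
#' @param values Numeric vector in [0, 1].
#' @return Integer codes in 0..7.
#' @seealso [dequantizeBins()]
#' @examples
#' quantizeBins(c(0, 0.30, 1))   # 0 2 7
#' @export
quantizeBins <- function(values) {
    if (anyNA(values) || any(values < 0 | values > 1))
        stop("bin values must lie in [0, 1]")
    pmin(as.integer(floor(values * 8)), 7L)
}

#' Reconstruction levels for 3-bit quantized bins
#'
#' @param codes Integer codes in 0..7.
#' @return Bin-center reconstruction values (code + 0.5)/8.
#' @export
dequantizeBins <- function(codes) {
    if (anyNA(codes) || any(codes < 0L | codes > 7L))
        stop("codes must lie in [0, 7]")
    (codes + 0.5) / 8
}

#' Extract the edge-histogram descriptor of an image
#'
#' Converts to gray ([rgbToGray()]), computes the 16 x 5 local histogram,
#' and derives the 5-bin global and 13 x 5 semiglobal histograms; when
#' `params@quantize` is set the 80 local bins are additionally 3-bit
#' encoded.
#'
#' @param image H x W x 3 RGB array in [0, 255].
#' @param params An [EhdParams-class] object.
#' @param coeffs Gray conversion coefficient set, see [rgbToGray()].
#' @return An [EdgeHistogramDescriptor-class].
#' @examples
#' img <- array(128, c(128, 128, 3))
#' d <- extractEdgeDescriptor(img)
#' sum(localHist(d))    # 0 for a uniform image
#' @export
extractEdgeDescriptor <- function(image, params = EhdParams(),
                                  coeffs = c("standard", "alt")) {
    .checkRgbImage(image)
    gray <- rgbToGray(image, coeffs = match.arg(coeffs))
    local <- localHistogram(gray, params)
    q <- if (params@quantize) quantizeBins(as.vector(t(local))) else integer(0)
    EdgeHistogramDescriptor(local, globalHistogram(local),
                            semiglobalHistogram(local), q)
}
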