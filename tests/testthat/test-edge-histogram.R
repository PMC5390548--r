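test_that("partitionSubimages floors the grid and attaches remainders", {
    subs <- partitionSubimages(matrix(0, 16, 16))
    expect_length(subs, 16L)
    expect_true(all(vapply(subs, function(s) all(dim(s) == c(4, 4)),
                           logical(1))))
    subs <- partitionSubimages(matrix(0, 100, 100))
    expect_true(all(vapply(subs, function(s) all(dim(s) == c(25, 25)),
                           logical(1))))
    ## 10 columns divide as 2, 2, 2, 4
    subs <- partitionSubimages(matrix(0, 10, 10))
    widths <- vapply(subs[1:4], ncol, integer(1))
    expect_equal(widths, c(2L, 2L, 2L, 4L))
    expect_error(partitionSubimages(matrix(0, 6, 6)), "8 x 8")
})

test_that("blockEdgeType applies the five MPEG-7 filters with a strict threshold", {
    expect_equal(blockEdgeType(matrix(100, 4, 4), 20)$type, "none")
    expect_equal(blockEdgeType(matrix(100, 4, 4), 20)$strength, 0)
    ## left half 255, right half 0: vertical response |255-0+255-0| = 510
    blk <- cbind(c(255, 255), c(0, 0))
    r <- blockEdgeType(blk, 20)
    expect_equal(r$type, "vertical")
    expect_equal(r$strength, 510)
    expect_equal(blockEdgeType(blk, 600)$type, "none")
    ## top/bottom split is horizontal; diagonal corners are nondirectional
    expect_equal(blockEdgeType(rbind(c(255, 255), c(0, 0)), 20)$type,
                 "horizontal")
    expect_equal(blockEdgeType(rbind(c(255, 0), c(0, 255)), 20)$type,
                 "nondirectional")
    ## smoothed diagonal steps: the sqrt(2)-weighted corner difference wins
    expect_equal(blockEdgeType(rbind(c(255, 127.5), c(127.5, 0)), 20)$type,
                 "diag45")
    expect_equal(blockEdgeType(rbind(c(127.5, 255), c(0, 127.5)), 20)$type,
                 "diag135")
    expect_error(blockEdgeType(matrix(0, 3, 4), 20), "even")
})

test_that("localHistogram bins edge blocks per subimage", {
    p <- EhdParams(blocksPerSubimage = 64L)
    expect_true(all(localHistogram(matrix(128, 64, 64), p) == 0))
    ## high-contrast vertical stripes: vertical bin is the strict maximum
    ## in every subimage
    img <- makePhantom(phantomSpec(rbind(c(10, 0.4, 0.8)),
                                   texture = "vstripes",
                                   textureContrast = 200,
                                   texturePeriod = 8, size = c(64, 64),
                                   seed = 1))
    loc <- localHistogram(rgbToGray(img), p)
    for (i in 1:16)
        expect_equal(which.max(loc[i, ]), c(vertical = 1L))
    ## threshold 0 on continuous noise: every block is classified
    set.seed(9)
    noisy <- matrix(runif(64 * 64, 0, 255), 64, 64)
    loc <- localHistogram(noisy, EhdParams(blocksPerSubimage = 64L,
                                           edgeThreshold = 0))
    expect_equal(unname(rowSums(loc)), rep(1, 16))
    expect_error(localHistogram(matrix(0, 20, 20), EhdParams()),
                 "too small")
})

test_that("globalHistogram is the mean over subimages", {
    expect_equal(globalHistogram(matrix(0, 16, 5)), rep(0, 5))
    loc <- matrix(0, 16, 5); loc[, 1] <- 0.5
    expect_equal(unname(globalHistogram(loc)), c(0.5, 0, 0, 0, 0))
    loc <- matrix(0, 16, 5); loc[1:4, 1] <- 1
    expect_equal(unname(globalHistogram(loc))[1], 0.25)
    ## independent summation oracle on random local bins
    set.seed(2)
    loc <- matrix(runif(80), 16, 5)
    oracle <- vapply(1:5, function(j) sum(loc[, j]) / 16, numeric(1))
    expect_equal(unname(globalHistogram(loc)), oracle, tolerance = 1e-12)
})

test_that("semiglobalHistogram groups columns, rows and quadrants", {
    expect_true(all(semiglobalHistogram(matrix(0, 16, 5)) == 0))
    ## value 1 in one bin of subimage (0,0) appears as 0.25 in its column,
    ## row and corner-quadrant groups only
    loc <- matrix(0, 16, 5); loc[1, 2] <- 1
    sg <- semiglobalHistogram(loc)
    expect_equal(unname(sg[, 2]),
                 c(0.25, 0, 0, 0, 0.25, 0, 0, 0, 0.25, 0, 0, 0, 0))
    expect_equal(sum(sg[, -2]), 0)
    ## constant local bins pass through unchanged
    loc <- matrix(0.3, 16, 5)
    expect_true(all(abs(semiglobalHistogram(loc) - 0.3) < 1e-12))
    ## the center group averages subimages (1,1), (1,2), (2,1), (2,2)
    loc <- matrix(0, 16, 5); loc[c(6, 7, 10, 11), 1] <- 1
    expect_equal(unname(semiglobalHistogram(loc)[13, 1]), 1)
})

test_that("quantizeBins codes to 3 bits with dequantization", {
    expect_equal(quantizeBins(0), 0L)
    expect_equal(quantizeBins(1), 7L)
    expect_equal(quantizeBins(0.30), 2L)
    expect_equal(quantizeBins(c(0.124, 0.125)), c(0L, 1L))
    expect_error(quantizeBins(1.2), "0, 1")
    expect_equal(dequantizeBins(0L), 1 / 16)
    expect_equal(dequantizeBins(quantizeBins(0.95)), 15 / 16)
})

test_that("extractEdgeDescriptor populates all three histograms", {
    img <- array(77, c(128, 128, 3))
    d <- extractEdgeDescriptor(img)
    expect_true(all(dim(localHist(d)) == c(16, 5)))
    expect_length(globalHist(d), 5L)
    expect_true(all(dim(semiglobalHist(d)) == c(13, 5)))
    expect_equal(sum(localHist(d)) + sum(globalHist(d)) +
                     sum(semiglobalHist(d)), 0)
    ## stripes dominate the global histogram; extraction is deterministic
    img <- makePhantom(phantomSpec(rbind(c(10, 0.4, 0.8)),
                                   texture = "vstripes",
                                   textureContrast = 200,
                                   texturePeriod = 32, size = c(128, 128),
                                   seed = 2))
    d1 <- extractEdgeDescriptor(img)
    expect_equal(which.max(globalHist(d1)), c(vertical = 1L))
    d2 <- extractEdgeDescriptor(img)
    expect_identical(localHist(d1), localHist(d2))
    ## quantized codes appear on request
    dq <- extractEdgeDescriptor(img, EhdParams(quantize = TRUE))
    expect_length(quantizedHist(dq), 80L)
    expect_equal(quantizedHist(dq),
                 quantizeBins(as.vector(t(localHist(dq)))))
})

test_that("rotating a stripe phantom by 90 degrees swaps the vertical and horizontal bins", {
    img <- makePhantom(phantomSpec(rbind(c(10, 0.4, 0.8)),
                                   texture = "vstripes",
                                   textureContrast = 200,
                                   texturePeriod = 8, size = c(128, 128),
                                   seed = 3))
    d <- extractEdgeDescriptor(img)
    dr <- extractEdgeDescriptor(rotateRgb90(img))
    ## axis-aligned stripes with block-aligned period: exact swap
    expect_equal(globalHist(dr)[2], globalHist(d)[1],
                 ignore_attr = TRUE)
    expect_equal(globalHist(dr)[1], globalHist(d)[2],
                 ignore_attr = TRUE)
})

test_that("raising the edge threshold never increases any local bin", {
    set.seed(4)
    img <- matrix(runif(64 * 64, 0, 255), 64, 64)
    thresholds <- c(0, 5, 20, 60, 200)
    prev <- NULL
    for (thr in thresholds) {
        loc <- localHistogram(img, EhdParams(blocksPerSubimage = 64L,
                                             edgeThreshold = thr))
        if (!is.null(prev)) expect_true(all(loc <= prev + 1e-12))
        prev <- loc
    }
})
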