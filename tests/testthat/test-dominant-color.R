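test_that("areaProbabilities counts coarse-region occupancy", {
    img <- solidHsv(0, 1, 1)                 # pure red
    p <- areaProbabilities(img)
    expect_equal(unname(p["red"]), 1)
    expect_equal(sum(p), 1)
    ## 2x2 image with pixels in regions {black, black, red, green}
    img <- array(0, c(2, 2, 3))
    img[1, 1, ] <- c(0, 0, 0.1); img[1, 2, ] <- c(200, 1, 0.05)
    img[2, 1, ] <- c(10, 0.9, 0.8); img[2, 2, ] <- c(100, 0.9, 0.8)
    expect_equal(unname(areaProbabilities(img)),
                 c(0.5, 0, 0, 0.25, 0, 0.25, 0, 0, 0))
})

test_that("initialPalette counts regions above the occupancy threshold", {
    p <- GlaParams(areaThreshold = 0.15)
    expect_equal(initialPalette(solidHsv(100, 0.8, 0.7), p)$k, 1L)
    ## 60% green / 40% blue
    img <- array(0, c(10, 10, 3))
    img[, , 1] <- c(rep(100, 60), rep(220, 40))
    img[, , 2] <- 0.8; img[, , 3] <- 0.7
    init <- initialPalette(img, p)
    expect_equal(init$k, 2L)
    expect_setequal(round(init$centers[, 1]), c(100, 220))
    ## occupancies (0.5, 0.3, 0.1, 0.1) -> only two exceed 15%
    img <- array(0, c(10, 10, 3))
    img[, , 1] <- c(rep(0, 50), rep(100, 30), rep(220, 10), rep(280, 10))
    img[, , 2] <- 0.8; img[, , 3] <- 0.7
    expect_equal(initialPalette(img, p)$k, 2L)
})

test_that("assignPixels uses circular hue distance with lowest-index ties", {
    img <- solidHsv(10, 0.5, 0.5, 1, 1)
    centers <- rbind(c(10, 0.5, 0.5), c(180, 0.5, 0.5))
    expect_equal(assignPixels(img, centers)[1, 1], 1L)
    ## pixel at 350 degrees: 20 degrees from center 10, 170 from center 180
    img <- solidHsv(350, 0.5, 0.5, 1, 1)
    expect_equal(assignPixels(img, centers)[1, 1], 1L)
    ## a single center labels everything
    img <- solidHsv(200, 0.3, 0.9, 3, 3)
    expect_true(all(assignPixels(img, rbind(c(0, 0, 0))) == 1L))
})

test_that("updateCenters averages members with circular hue", {
    img <- solidHsv(42, 0.3, 0.6, 2, 2)
    C <- updateCenters(img, matrix(1L, 2, 2))
    expect_equal(unname(C[1, ]), c(42, 0.3, 0.6))
    ## saturations 0.2 and 0.4 average to 0.3
    img <- solidHsv(42, 0.3, 0.6, 1, 2)
    img[1, 1, 2] <- 0.2; img[1, 2, 2] <- 0.4
    C <- updateCenters(img, matrix(1L, 1, 2))
    expect_equal(C[1, 2], 0.3)
    ## hues 350 and 10 have circular mean 0, matching the angular oracle
    img <- solidHsv(0, 0.5, 0.5, 1, 2)
    img[1, 1, 1] <- 350; img[1, 2, 1] <- 10
    C <- updateCenters(img, matrix(1L, 1, 2))
    dh <- abs(C[1, 1] - circMeanDegOracle(c(350, 10))) %% 360
    expect_lte(min(dh, 360 - dh), 1e-9)
    expect_equal(C[1, 1] %% 360, 0, tolerance = 1e-9)
    ## empty clusters are dropped
    img <- solidHsv(42, 0.3, 0.6, 1, 2)
    C <- updateCenters(img, matrix(c(1L, 3L), 1, 2))
    expect_equal(nrow(C), 2L)
    expect_equal(attr(C, "counts"), c(1L, 1L))
})

test_that("splitClusters divides only overdispersed clusters", {
    tight <- solidHsv(100, 0.5, 0.5, 4, 4)
    cl <- colorClusters(tight, rbind(c(100, 0.5, 0.5)))
    expect_equal(length(splitClusters(cl, 0.01)), 1L)
    expect_equal(splitClusters(cl, 0.01)[[1]]$center, cl[[1]]$center)
    ## one cluster holding two well-separated colors splits, and Lloyd
    ## iterations recover both planted colors
    img <- solidHsv(40, 0.8, 0.7, 2, 4)
    img[, 3:4, 1] <- 130
    cl <- colorClusters(img, rbind(c(85, 0.8, 0.7)))
    expect_gt(cl[[1]]$withinError, 0.01)
    split <- splitClusters(cl, 0.01)
    expect_equal(length(split), 2L)
    centers <- do.call(rbind, lapply(split, `[[`, "center"))
    for (it in 1:20) {
        lab <- assignPixels(img, centers)
        centers <- updateCenters(img, lab)
    }
    expect_equal(sort(centers[, 1]), c(40, 130), tolerance = 1e-6)
})

test_that("mergeClusters unites close centers by count-weighted means", {
    mk <- function(center, count)
        list(center = center, pixels = NULL, count = count, withinError = 0)
    ## identical centers, counts 30 and 10 -> one cluster of 40
    m <- mergeClusters(list(mk(c(50, 0.5, 0.5), 30L), mk(c(50, 0.5, 0.5), 10L)),
                       mergeThreshold = 0.1)
    expect_equal(length(m), 1L)
    expect_equal(m[[1]]$count, 40L)
    expect_equal(unname(m[[1]]$center), c(50, 0.5, 0.5), tolerance = 1e-9)
    ## distant centers stay apart
    far <- list(mk(c(0, 0.8, 0.8), 10L), mk(c(180, 0.8, 0.8), 10L))
    expect_equal(length(mergeClusters(far, 0.1)), 2L)
    ## counts (10, 30) at s = 0.2 / 0.6 merge to s = 0.5
    m <- mergeClusters(list(mk(c(50, 0.2, 0.5), 10L), mk(c(50, 0.6, 0.5), 30L)),
                       mergeThreshold = 0.5)
    expect_equal(length(m), 1L)
    expect_equal(m[[1]]$center[2], 0.5, tolerance = 1e-9)
})

test_that("extractMainColors recovers solid and planted palettes", {
    d <- extractMainColors(solidRgb(220, 40, 40, 16, 16))
    expect_equal(numColors(d), 1L)
    expect_equal(colorFractions(d), 1)
    ## three well-separated colors at 0.5 / 0.3 / 0.2
    spec <- phantomSpec(rbind(c(0, 0.8, 0.9), c(120, 0.8, 0.9),
                              c(240, 0.8, 0.9)),
                        fractions = c(0.5, 0.3, 0.2), size = c(48, 48),
                        seed = 3)
    d <- extractMainColors(makePhantom(spec))
    expect_equal(numColors(d), 3L)
    expect_equal(colorFractions(d), c(0.5, 0.3, 0.2), tolerance = 0.005)
    expect_equal(sort(mainColors(d)[, 1]), c(0, 120, 240), tolerance = 1)
    expect_equal(mainColors(d)[, 2], rep(0.8, 3), tolerance = 0.01)
    ## two planted colors closer than the merge threshold collapse to one
    spec <- phantomSpec(rbind(c(100, 0.80, 0.70), c(108, 0.80, 0.70)),
                        fractions = c(0.5, 0.5), size = c(32, 32), seed = 4)
    d <- extractMainColors(makePhantom(spec))
    expect_equal(numColors(d), 1L)
})

test_that("descriptor fractions always sum to one and the Lloyd objective is monotone", {
    set.seed(11)
    for (rep in 1:5) {
        k <- sample(1:3, 1)
        hues <- (runif(1, 0, 360) + (0:(k - 1)) * 115) %% 360
        fr <- as.vector(stats::rmultinom(1, 60, rep(1, k))) + 1
        fr <- fr / sum(fr)
        spec <- phantomSpec(cbind(hues, 0.7, 0.7), fractions = fr,
                            size = c(24, 24), noiseSigma = 4,
                            seed = rep)
        d <- extractMainColors(makePhantom(spec))
        expect_equal(sum(colorFractions(d)), 1, tolerance = 1e-12)
        for (tr in attr(d, "objectiveTrace"))
            if (length(tr) > 1L)
                expect_true(all(diff(tr) <= 1e-9))
    }
})

test_that("small-raster clustering attains the best two-center Lloyd objective", {
    w <- c(2, 1, 1)
    set.seed(21)
    for (rep in 1:3) {
        ## planted two-color 6x6 raster with mild jitter
        h1 <- runif(1, 0, 150); h2 <- h1 + 160
        hsv <- array(0, c(6, 6, 3))
        hsv[, , 1] <- c(rep(h1, 20), rep(h2, 16)) + runif(36, -3, 3)
        hsv[, , 2] <- 0.8 + runif(36, -0.05, 0.05)
        hsv[, , 3] <- 0.7 + runif(36, -0.05, 0.05)
        rgb <- hsvToRgbOracle(as.vector(hsv[, , 1]), as.vector(hsv[, , 2]),
                              as.vector(hsv[, , 3]))
        img <- array(rgb * 255, c(6, 6, 3))
        d <- extractMainColors(img)
        expect_equal(numColors(d), 2L)
        ## our final objective vs the exhaustive seeded-Lloyd oracle
        hsvBack <- rgbToHsv(img)
        P <- cbind(as.vector(hsvBack[, , 1]) / 360, as.vector(hsvBack[, , 2]),
                   as.vector(hsvBack[, , 3]))
        trace <- attr(d, "objectiveTrace")
        ours <- tail(trace[[length(trace)]], 1)
        best <- lloydObjectiveOracle(P, w)
        expect_lte(ours, best + 1e-9)
    }
})

test_that("traditionalMainColors keeps regions above the 5% coverage rule", {
    d <- traditionalMainColors(solidHsv(100, 0.8, 0.7, 8, 8))
    expect_equal(numColors(d), 1L)
    expect_equal(colorFractions(d), 1)
    ## coverages (0.9, 0.06, 0.04): two regions survive
    img <- array(0, c(10, 10, 3))
    img[, , 1] <- c(rep(100, 90), rep(220, 6), rep(0, 4))
    img[, , 2] <- 0.8; img[, , 3] <- 0.7
    d <- traditionalMainColors(img)
    expect_equal(numColors(d), 2L)
    expect_equal(colorFractions(d), c(0.9, 0.06) / 0.96, tolerance = 1e-12)
    ## nine regions at ~1/9 each all survive
    img <- array(0, c(3, 3, 3))
    img[, , 1] <- c(0, 0, 0, 30, 120, 170, 220, 280, 0)
    img[, , 2] <- c(0.5, 0.05, 0.05, rep(0.8, 6))
    img[, , 3] <- c(0.1, 0.5, 0.95, rep(0.6, 6))
    expect_equal(numColors(traditionalMainColors(img)), 9L)
})

test_that("dcdDistance is a symmetric premetric with the quadratic form", {
    a <- MainColorDescriptor(rbind(c(20, 0.6, 0.7), c(200, 0.4, 0.5)),
                             c(0.7, 0.3))
    expect_equal(dcdDistance(a, a), 0)
    ## single colors beyond dmax: squared distance 1 + 1 - 0
    b <- MainColorDescriptor(rbind(c(0, 1, 1)), 1)
    cc <- MainColorDescriptor(rbind(c(180, 1, 1)), 1)
    expect_equal(dcdDistance(b, cc)^2, 2)
    ## symmetry on random descriptors
    set.seed(5)
    for (i in 1:5) {
        mk <- function() {
            k <- sample(1:3, 1)
            fr <- runif(k); fr <- fr / sum(fr)
            MainColorDescriptor(cbind(runif(k, 0, 360), runif(k), runif(k)),
                                fr)
        }
        x <- mk(); y <- mk()
        expect_equal(dcdDistance(x, y), dcdDistance(y, x), tolerance = 1e-12)
        expect_gte(dcdDistance(x, y), 0)
    }
    ## the 9-region histogram mode is available and symmetric
    expect_equal(dcdDistance(b, cc, method = "areahist"),
                 dcdDistance(cc, b, method = "areahist"))
})
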