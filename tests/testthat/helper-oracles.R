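## Independent oracles and small fixture builders used across the suite.

## solid-color RGB image
solidRgb <- function(r, g, b, h = 16L, w = 16L) {
    img <- array(0, c(h, w, 3L))
    img[, , 1L] <- r; img[, , 2L] <- g; img[, , 3L] <- b
    img
}

## solid HSV image
solidHsv <- function(h, s, v, nr = 4L, nc = 4L) {
    img <- array(0, c(nr, nc, 3L))
    img[, , 1L] <- h; img[, , 2L] <- s; img[, , 3L] <- v
    img
}

## independent inverse hexcone conversion (sector formula), [0, 1] channels;
## deliberately a different code path from the package's forward conversion
hsvToRgbOracle <- function(h, s, v) {
    hh <- (h %% 360) / 60
    i <- floor(hh); f <- hh - i
    p <- v * (1 - s); q <- v * (1 - s * f); tt <- v * (1 - s * (1 - f))
    out <- matrix(0, length(h), 3L)
    for (j in seq_along(h)) {
        out[j, ] <- switch(as.character(i[j] %% 6),
                           "0" = c(v[j], tt[j], p[j]),
                           "1" = c(q[j], v[j], p[j]),
                           "2" = c(p[j], v[j], tt[j]),
                           "3" = c(p[j], q[j], v[j]),
                           "4" = c(tt[j], p[j], v[j]),
                           "5" = c(v[j], p[j], q[j]))
    }
    out
}

## brute-force weighted-L1 texture distance, term by term
textureDistanceOracle <- function(a, b) {
    tot <- 0
    la <- as.vector(t(localHist(a))); lb <- as.vector(t(localHist(b)))
    for (i in 1:80) tot <- tot + abs(la[i] - lb[i])
    for (i in 1:5) tot <- tot + 5 * abs(globalHist(a)[i] - globalHist(b)[i])
    sa <- as.vector(t(semiglobalHist(a))); sb <- as.vector(t(semiglobalHist(b)))
    for (i in 1:65) tot <- tot + abs(sa[i] - sb[i])
    tot
}

## a random but internally consistent edge descriptor
randomEdgeDescriptor <- function() {
    local <- matrix(runif(80, 0, 0.19), 16L, 5L)
    EdgeHistogramDescriptor(local)
}

## circular mean of hue angles in degrees (independent formulation)
circMeanDegOracle <- function(deg) {
    a <- deg * pi / 180
    (atan2(mean(sin(a)), mean(cos(a))) * 180 / pi) %% 360
}

## best 2-center Lloyd objective over all pairs of distinct pixel values as
## seeds (normalized HSV coordinates, weighted squared error, circular hue)
lloydObjectiveOracle <- function(P, w, k = 2L) {
    circd <- function(a, b) { d <- abs(a - b) %% 1; pmin(d, 1 - d) }
    wd2 <- function(P, cen)
        w[1] * circd(P[, 1], cen[1])^2 + w[2] * (P[, 2] - cen[2])^2 +
            w[3] * (P[, 3] - cen[3])^2
    obj <- function(C) {
        D <- sapply(seq_len(nrow(C)), function(i) wd2(P, C[i, ]))
        lab <- max.col(-D, ties.method = "first")
        tot <- 0
        for (i in seq_len(nrow(C))) {
            sel <- lab == i
            if (any(sel)) tot <- tot + sum(wd2(P[sel, , drop = FALSE], C[i, ]))
        }
        list(obj = tot, lab = lab)
    }
    cmean <- function(hn) {
        a <- 2 * pi * hn
        (atan2(mean(sin(a)), mean(cos(a))) / (2 * pi)) %% 1
    }
    uniq <- unique(P)
    best <- Inf
    if (nrow(uniq) < 2L) return(obj(uniq)$obj)
    for (i in seq_len(nrow(uniq) - 1L)) for (j in (i + 1L):nrow(uniq)) {
        C <- rbind(uniq[i, ], uniq[j, ])
        for (it in 1:60) {
            o <- obj(C)
            Cn <- t(sapply(sort(unique(o$lab)), function(l) {
                Pl <- P[o$lab == l, , drop = FALSE]
                c(cmean(Pl[, 1]), mean(Pl[, 2]), mean(Pl[, 3]))
            }))
            if (nrow(Cn) == nrow(C) && max(abs(Cn - C)) < 1e-12) break
            C <- Cn
        }
        best <- min(best, obj(C)$obj)
    }
    best
}

## rotate an H x W x 3 array 90 degrees counterclockwise
rotateRgb90 <- function(img) {
    d <- dim(img)
    out <- array(0, c(d[2L], d[1L], 3L))
    for (ch in 1:3) {
        m <- img[, , ch]
        out[, , ch] <- t(m)[d[2L]:1L, , drop = FALSE]
    }
    out
}
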