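## Rasters are plain base-R arrays:
##   RGB image: H x W x 3 array, channel values in [0, 255]
##   HSV image: H x W x 3 array, h in [0, 360) degrees, s and v in [0, 1]
##   gray image: H x W matrix, values in [0, 255]
## Row-major pixel semantics, origin at the top-left corner.

#' Names of the nine coarse HSV color regions
#'
#' The fixed label-to-name mapping of the coarse HSV quantizer: label 0 is
#' black, 1 gray, 2 white, and 3 through 8 the chromatic hue bands red,
#' yellow, green, cyan, blue, purple.
#'
#' @seealso [quantizeHsv()]
#' @export
colorAreaNames <- c("black", "gray", "white", "red", "yellow", "green",
                    "cyan", "blue", "purple")

.checkRgbImage <- function(image) {
    if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] != 3L)
        stop("an RGB image must be an H x W x 3 array")
    d <- dim(image)
    if (d[1L] < 1L || d[2L] < 1L)
        stop("image must have positive dimensions")
    if (anyNA(image) || min(image) < 0 || max(image) > 255)
        stop("RGB channel values must lie in [0, 255]")
    invisible(image)
}

.checkHsvImage <- function(image) {
    if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] != 3L)
        stop("an HSV image must be an H x W x 3 array")
    h <- image[, , 1L]; s <- image[, , 2L]; v <- image[, , 3L]
    if (anyNA(image) || min(h) < 0 || max(h) >= 360 ||
        min(s) < 0 || max(s) > 1 || min(v) < 0 || max(v) > 1)
        stop("HSV values out of range: h in [0, 360), s and v in [0, 1]")
    invisible(image)
}

#' Convert an RGB image to HSV
#'
#' Hexcone conversion: channels are scaled to [0, 1], then per pixel
#' V = max(R, G, B), S = (V - min)/V, and the hue sextant is chosen from
#' which channel attains the maximum and which the minimum, giving
#' H = 60 * H' wrapped into [0, 360) degrees. Achromatic pixels (V = min)
#' get H = 0, and S = 0 when V = 0.
#'
#' @param image H x W x 3 RGB array with channel values in [0, 255].
#' @return H x W x 3 HSV array: h in degrees [0, 360), s and v in [0, 1].
#' @examples
#' img <- array(0, c(2, 2, 3)); img[, , 1] <- 255      # solid red
#' rgbToHsv(img)[1, 1, ]                               # 0, 1, 1
#' @export
rgbToHsv <- function(image) {
    .checkRgbImage(image)
    d <- dim(image)
    r <- as.vector(image[, , 1L]) / 255
    g <- as.vector(image[, , 2L]) / 255
    b <- as.vector(image[, , 3L]) / 255
    V <- pmax(r, g, b)
    m <- pmin(r, g, b)
    C <- V - m
    S <- ifelse(V > 0, C / V, 0)

    ## sextant offsets; r', g', b' are distances from the max, scaled by C
    Hp <- numeric(length(V))
    chrom <- C > 0
    rp <- ifelse(chrom, (V - r) / ifelse(chrom, C, 1), 0)
    gp <- ifelse(chrom, (V - g) / ifelse(chrom, C, 1), 0)
    bp <- ifelse(chrom, (V - b) / ifelse(chrom, C, 1), 0)
    isR <- chrom & r >= g & r >= b
    isG <- chrom & !isR & g >= b
    isB <- chrom & !isR & !isG
    Hp[isR & g <= b] <- 5 + bp[isR & g <= b]       # R max, G min: magenta->red
    Hp[isR & g >  b] <- 1 - gp[isR & g >  b]       # R max, B min: red->yellow
    Hp[isG & b <= r] <- 1 + rp[isG & b <= r]       # G max, B min: yellow->green
    Hp[isG & b >  r] <- 3 - bp[isG & b >  r]       # G max, R min: green->cyan
    Hp[isB & r <= g] <- 3 + gp[isB & r <= g]       # B max, R min: cyan->blue
    Hp[isB & r >  g] <- 5 - rp[isB & r >  g]       # B max, G min: blue->magenta
    H <- (60 * Hp) %% 360
    H[!chrom] <- 0

    out <- array(0, d)
    out[, , 1L] <- H
    out[, , 2L] <- S
    out[, , 3L] <- V
    out
}

#' Convert an RGB image to gray
#'
#' Weighted channel sum g = 0.299 R + 0.587 G + 0.114 B (the standard
#' luminance weights, which sum to 1). `coeffs = "alt"` selects the variant
#' with blue coefficient 0.144; its weights sum to 1.030, so the output is
#' clipped to [0, 255].
#'
#' @param image H x W x 3 RGB array in [0, 255].
#' @param coeffs `"standard"` (blue weight 0.114) or `"alt"` (0.144).
#' @return H x W gray matrix in [0, 255].
#' @examples
#' img <- array(c(100, 150, 200), c(1, 1, 3))
#' rgbToGray(img)    # 140.75
#' @export
rgbToGray <- function(image, coeffs = c("standard", "alt")) {
    .checkRgbImage(image)
    coeffs <- match.arg(coeffs)
    wb <- if (coeffs == "standard") 0.114 else 0.144
    d <- dim(image)
    g <- 0.299 * as.vector(image[, , 1L]) +
        0.587 * as.vector(image[, , 2L]) + wb * as.vector(image[, , 3L])
    matrix(pmin(pmax(g, 0), 255), d[1L], d[2L])
}

#' Coarse nine-region HSV quantizer
#'
#' Maps HSV pixels to one of nine coarse color regions: dark pixels
#' (v <= 0.2) to black; desaturated pixels (s <= 0.1) to gray
#' (0.2 < v <= 0.9) or white (v > 0.9); all remaining pixels to one of six
#' hue bands -- red [315, 360) and [0, 20), yellow [20, 75), green
#' [75, 155), cyan [155, 190), blue [190, 260), purple [260, 315). Hue
#' intervals are half-open; the s and v cuts are closed on the upper side,
#' so every valid pixel receives exactly one label.
#'
#' @param h Hue in degrees, [0, 360); vectorized.
#' @param s,v Saturation and value in [0, 1]; vectorized.
#' @return Integer labels in 0..8 (see [colorAreaNames]).
#' @examples
#' quantizeHsv(90, 0.8, 0.6)    # 5, green
#' quantizeHsv(330, 0.5, 0.5)   # 3, red
#' @export
quantizeHsv <- function(h, s, v) {
    if (anyNA(c(h, s, v)) || any(h < 0 | h >= 360) ||
        any(s < 0 | s > 1) || any(v < 0 | v > 1))
        stop("quantizeHsv: h must be in [0, 360), s and v in [0, 1]")
    n <- max(length(h), length(s), length(v))
    h <- rep_len(h, n); s <- rep_len(s, n); v <- rep_len(v, n)
    ## chromatic hue bands; red wraps around 0
    hp <- integer(n)
    hp[h >= 20  & h < 75]  <- 1L
    hp[h >= 75  & h < 155] <- 2L
    hp[h >= 155 & h < 190] <- 3L
    hp[h >= 190 & h < 260] <- 4L
    hp[h >= 260 & h < 315] <- 5L
    area <- 3L + hp
    area[v <= 0.2] <- 0L
    achro <- v > 0.2 & s <= 0.1
    area[achro & v <= 0.9] <- 1L
    area[achro & v > 0.9] <- 2L
    area
}

#' Quantize every pixel of an HSV image
#'
#' @param image H x W x 3 HSV array.
#' @return H x W integer matrix of region labels in 0..8.
#' @seealso [quantizeHsv()]
#' @export
quantizeHsvImage <- function(image) {
    .checkHsvImage(image)
    d <- dim(image)
    matrix(quantizeHsv(as.vector(image[, , 1L]), as.vector(image[, , 2L]),
                       as.vector(image[, , 3L])),
           nrow = d[1L], ncol = d[2L])
}
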