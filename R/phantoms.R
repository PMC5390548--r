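## Seeded synthetic phantoms emulating tongue-image color and texture
## classes, so the whole pipeline (descriptors, retrieval, evaluation) runs
## without external data.

.hsvToRgb255 <- function(h, s, v) {
    ## standard sector formula; returns a length-3 RGB vector in [0, 255]
    h <- (h %% 360) / 60
    i <- floor(h)
    f <- h - i
    p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
    rgb <- switch(as.character(i %% 6),
                  "0" = c(v, t, p), "1" = c(q, v, p), "2" = c(p, v, t),
                  "3" = c(p, q, v), "4" = c(t, p, v), "5" = c(v, p, q))
    rgb * 255
}

#' Specify a synthetic phantom image
#'
#' A phantom is a flat-color image (1-3 palette colors in exact pixel
#' fractions, laid out as contiguous bands) with an optional gray-level
#' texture pattern superimposed and optional Gaussian channel noise.
#' Stripe and diagonal textures are triangular waves of peak-to-peak
#' amplitude `textureContrast` and period `texturePeriod` (pixels);
#' `checker` is a square-wave checkerboard with cells of `texturePeriod`
#' pixels; `cracks` darkens random-walk polylines by `textureContrast`.
#'
#' @param palette k x 3 matrix of HSV colors (h degrees, s and v in [0,1]).
#' @param fractions k coverage fractions summing to 1.
#' @param texture One of `"none"`, `"vstripes"`, `"hstripes"`, `"diag45"`,
#'   `"diag135"`, `"checker"`, `"cracks"`.
#' @param textureContrast Gray-level amplitude of the pattern (0-255 scale).
#' @param texturePeriod Pattern period in pixels.
#' @param noiseSigma Per-channel Gaussian noise standard deviation.
#' @param size Image size c(H, W).
#' @param shape `"full"` or `"ellipse"` (centered ellipse on a dark
#'   background, mimicking a tongue silhouette).
#' @param seed Integer seed; phantoms are fully reproducible.
#' @return A phantom spec (list) accepted by [makePhantom()].
#' @export
phantomSpec <- function(palette, fractions = rep(1 / nrow(rbind(palette)),
                                                 nrow(rbind(palette))),
                        texture = c("none", "vstripes", "hstripes", "diag45",
                                    "diag135", "checker", "cracks"),
                        textureContrast = 150, texturePeriod = 8,
                        noiseSigma = 0, size = c(128L, 128L),
                        shape = c("full", "ellipse"), seed = 1L) {
    palette <- rbind(palette)
    if (abs(sum(fractions) - 1) > 1e-9 || any(fractions < 0))
        stop("palette fractions must be nonnegative and sum to 1")
    if (length(fractions) != nrow(palette))
        stop("one fraction per palette color required")
    list(palette = palette, fractions = as.numeric(fractions),
         texture = match.arg(texture), textureContrast = textureContrast,
         texturePeriod = texturePeriod, noiseSigma = noiseSigma,
         size = as.integer(size), shape = match.arg(shape),
         seed = as.integer(seed))
}

.triWave <- function(pos, period, amplitude) {
    ph <- (pos %% period) / period
    amplitude * (abs(2 * ph - 1) - 0.5)
}

#' Render a phantom image
#'
#' Deterministic given the spec and its seed. Before noise, pixel counts
#' per palette color match the requested fractions to within one pixel.
#'
#' @param spec A spec from [phantomSpec()].
#' @return H x W x 3 RGB array in [0, 255].
#' @examples
#' spec <- phantomSpec(rbind(c(350, 0.5, 0.8)), texture = "vstripes",
#'                     size = c(64, 64))
#' img <- makePhantom(spec)
#' dim(img)
#' @export
makePhantom <- function(spec) {
    H <- spec$size[1L]; W <- spec$size[2L]
    n <- H * W
    if (exists(".Random.seed", envir = globalenv())) {
        oldSeed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    }
    set.seed(spec$seed)

    ## exact-count color bands over the column-major pixel scan
    bounds <- round(cumsum(spec$fractions) * n)
    counts <- diff(c(0L, bounds))
    colIdx <- rep.int(seq_along(counts), counts)
    rgbPal <- t(vapply(seq_len(nrow(spec$palette)), function(i)
        .hsvToRgb255(spec$palette[i, 1L], spec$palette[i, 2L],
                     spec$palette[i, 3L]), numeric(3L)))
    img <- array(0, c(H, W, 3L))
    for (ch in 1:3) img[, , ch] <- matrix(rgbPal[colIdx, ch], H, W)

    ## texture as gray-level modulation on all channels
    if (spec$texture != "none") {
        A <- spec$textureContrast
        p <- spec$texturePeriod
        row <- matrix(seq_len(H) - 1L, H, W)
        col <- matrix(seq_len(W) - 1L, H, W, byrow = TRUE)
        D <- switch(spec$texture,
            vstripes = .triWave(col, p, A),
            hstripes = .triWave(row, p, A),
            diag45 = .triWave(row + col, p, A),
            diag135 = .triWave(row - col, p, A),
            checker = A * (((row %/% p + col %/% p) %% 2) - 0.5),
            cracks = {
                D <- matrix(0, H, W)
                for (k in seq_len(max(3L, min(H, W) %/% 12L))) {
                    r <- sample.int(H, 1L); cc <- sample.int(W, 1L)
                    horiz <- runif(1) < 0.5
                    for (step in seq_len(min(H, W))) {
                        D[r, cc] <- -A
                        if (horiz) {
                            cc <- cc + 1L; r <- r + sample(c(-1L, 0L, 1L), 1L)
                        } else {
                            r <- r + 1L; cc <- cc + sample(c(-1L, 0L, 1L), 1L)
                        }
                        if (r < 1L || r > H || cc < 1L || cc > W) break
                    }
                }
                D
            })
        for (ch in 1:3) img[, , ch] <- img[, , ch] + D
    }

    if (spec$noiseSigma > 0)
        img <- img + array(stats::rnorm(3L * n, sd = spec$noiseSigma),
                           c(H, W, 3L))

    if (spec$shape == "ellipse") {
        row <- matrix(seq_len(H), H, W)
        col <- matrix(seq_len(W), H, W, byrow = TRUE)
        inside <- ((row - (H + 1) / 2) / (0.45 * H))^2 +
            ((col - (W + 1) / 2) / (0.45 * W))^2 <= 1
        for (ch in 1:3) {
            plane <- img[, , ch]
            plane[!inside] <- 25
            img[, , ch] <- plane
        }
    }

    pmin(pmax(img, 0), 255)
}

#' Default synthetic color-class templates
#'
#' Six phantom templates mimicking the hue ordering of clinical tongue
#' color classes (purple, purple-red, deep red, pink, pale, yellow-coated):
#' two-color palettes with distinct dominant hues spread across the
#' purple-red-yellow arc, no texture. Dominant hues are separated by at
#' least 25 degrees, so the classes stay separable under the default
#' +/-5 degree hue jitter of [makeFixtureDb()].
#'
#' @param size Image size c(H, W).
#' @param noiseSigma Per-channel noise of each template.
#' @return Named list of phantom specs.
#' @export
defaultColorTemplates <- function(size = c(128L, 128L), noiseSigma = 8) {
    mk <- function(h, s, v)
        phantomSpec(rbind(c(h, s, v), c(h, s * 0.8, min(1, v * 1.12))),
                    fractions = c(0.7, 0.3), size = size,
                    noiseSigma = noiseSigma)
    list(purple = mk(270, 0.55, 0.55),
         purple_red = mk(300, 0.65, 0.60),
         deep_red = mk(335, 0.60, 0.70),
         pink = mk(5, 0.45, 0.85),
         pale = mk(30, 0.25, 0.90),
         yellow_coat = mk(55, 0.50, 0.80))
}

#' Default synthetic texture-class templates
#'
#' Five phantom templates sharing one base color and differing only in
#' oriented edge structure: vertical stripes, horizontal stripes, the two
#' diagonal orientations, and a fine checkerboard (nondirectional edges).
#' The checker cell is one pixel, matching the macroblock size of
#' 2-pixel-wide edge blocks.
#'
#' @param size Image size c(H, W).
#' @param noiseSigma Per-channel noise of each template.
#' @return Named list of phantom specs.
#' @export
defaultTextureTemplates <- function(size = c(128L, 128L), noiseSigma = 4) {
    base <- c(10, 0.40, 0.80)
    mk <- function(tex, period = 8)
        phantomSpec(rbind(base), texture = tex, textureContrast = 150,
                    texturePeriod = period, size = size,
                    noiseSigma = noiseSigma)
    list(vertical = mk("vstripes"),
         horizontal = mk("hstripes"),
         diagonal45 = mk("diag45"),
         diagonal135 = mk("diag135"),
         nondirectional = mk("checker", period = 1))
}

#' Default combined color-by-texture templates
#'
#' Class templates in which neither color nor texture alone identifies the
#' class: each of the six classes pairs one of three dominant colors with
#' one of three textures so that every color and every texture is shared
#' between two classes. Retrieval must combine both features to separate
#' them, mirroring the structure of a fused-feature retrieval experiment.
#'
#' @param size Image size c(H, W).
#' @param noiseSigma Per-channel noise of each template.
#' @return Named list of phantom specs.
#' @export
defaultCombinedTemplates <- function(size = c(128L, 128L), noiseSigma = 6) {
    cols <- list(red = c(350, 0.55, 0.75),
                 pale = c(30, 0.25, 0.88),
                 purple = c(285, 0.55, 0.55))
    mk <- function(col, tex, period = 8)
        phantomSpec(rbind(col), texture = tex, textureContrast = 140,
                    texturePeriod = period, size = size,
                    noiseSigma = noiseSigma)
    list(red_vert = mk(cols$red, "vstripes"),
         red_check = mk(cols$red, "checker", period = 1),
         pale_vert = mk(cols$pale, "vstripes"),
         pale_horiz = mk(cols$pale, "hstripes"),
         purple_horiz = mk(cols$purple, "hstripes"),
         purple_check = mk(cols$purple, "checker", period = 1))
}

#' Generate a labeled synthetic image collection
#'
#' Renders `nPerClass` seeded variants of every template: the palette hues
#' are jittered uniformly within +/-`hueJitter` degrees, saturation and
#' value within +/-0.03, and the noise is resampled, each image from its
#' own derived seed.
#'
#' @param templates Named list of phantom specs (the class templates).
#' @param nPerClass Number of images per class.
#' @param seed Master seed; per-image seeds are derived from it.
#' @param hueJitter Half-width of the per-image hue jitter in degrees.
#' @return List with `images` (named list of RGB arrays), `labels`
#'   (character vector of class names) and `specs` (the jittered specs).
#' @examples
#' db <- makeFixtureDb(defaultColorTemplates(size = c(32, 32)),
#'                     nPerClass = 2, seed = 1)
#' table(db$labels)
#' @export
makeFixtureDb <- function(templates, nPerClass = 30L, seed = 1L,
                          hueJitter = 5) {
    stopifnot(nPerClass >= 1L, !is.null(names(templates)))
    images <- list(); labels <- character(); specs <- list()
    for (ci in seq_along(templates)) {
        tmpl <- templates[[ci]]
        for (j in seq_len(nPerClass)) {
            s <- ((seed - 1L) * 1009L + (ci - 1L) * 101L + j) %% 2147483647L
            spec <- tmpl
            spec$seed <- as.integer(s)
            ## jitter the palette with the image's own seed
            if (exists(".Random.seed", envir = globalenv())) {
                oldSeed <- get(".Random.seed", envir = globalenv())
            } else oldSeed <- NULL
            set.seed(spec$seed)
            k <- nrow(spec$palette)
            spec$palette[, 1L] <-
                (spec$palette[, 1L] + stats::runif(k, -hueJitter,
                                                   hueJitter)) %% 360
            spec$palette[, 2L] <- pmin(pmax(
                spec$palette[, 2L] + stats::runif(k, -0.03, 0.03), 0.02), 1)
            spec$palette[, 3L] <- pmin(pmax(
                spec$palette[, 3L] + stats::runif(k, -0.03, 0.03), 0.02), 1)
            if (!is.null(oldSeed))
                assign(".Random.seed", oldSeed, envir = globalenv())
            id <- sprintf("%s_%02d", names(templates)[ci], j)
            images[[id]] <- makePhantom(spec)
            labels <- c(labels, names(templates)[ci])
            specs[[id]] <- spec
        }
    }
    list(images = images, labels = labels, specs = specs)
}
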