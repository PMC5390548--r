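#' Read an image file as an RGB array
#'
#' Decodes PNG, JPEG or TIFF files via EBImage. Alpha channels are
#' dropped and grayscale sources are replicated to three channels.
#'
#' @param path Path to an existing image file.
#' @return H x W x 3 RGB array in [0, 255] (origin top-left).
#' @export
readImageRGB <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    img <- tryCatch(EBImage::readImage(path),
                    error = function(e)
                        stop("cannot decode '", path, "': ",
                             conditionMessage(e), call. = FALSE))
    a <- EBImage::imageData(img)     # x (columns) first in EBImage
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
    if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]
    if (dim(a)[3L] < 3L) a <- array(rep(a[, , 1L], 3L), c(dim(a)[1:2], 3L))
    out <- array(0, c(dim(a)[2L], dim(a)[1L], 3L))
    for (ch in 1:3) out[, , ch] <- t(a[, , ch])
    pmin(pmax(out * 255, 0), 255)
}

#' Write an RGB array as a PNG file
#'
#' @param image H x W x 3 RGB array in [0, 255].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeImagePng <- function(image, path) {
    .checkRgbImage(image)
    png::writePNG(image / 255, target = path)
    invisible(path)
}

## ---------------------------------------------------------------------------
## Descriptor serialization
## ---------------------------------------------------------------------------

.colorToList <- function(d) {
    list(k = nrow(d@colors),
         colors = lapply(seq_len(nrow(d@colors)), function(i)
             list(h = d@colors[i, 1L], s = d@colors[i, 2L],
                  v = d@colors[i, 3L], mu = d@fractions[i])))
}

.colorFromList <- function(x) {
    cols <- t(vapply(x$colors, function(cc)
        c(cc$h, cc$s, cc$v), numeric(3L)))
    MainColorDescriptor(cols, vapply(x$colors, `[[`, numeric(1L), "mu"))
}

.edgeToList <- function(d) {
    list(local = lapply(seq_len(16L), function(i) as.numeric(d@local[i, ])),
         global = as.numeric(d@global),
         semiglobal = lapply(seq_len(13L), function(i)
             as.numeric(d@semiglobal[i, ])),
         quantized = if (length(d@quantized)) as.integer(d@quantized)
                     else NULL)
}

.edgeFromList <- function(x) {
    loc <- do.call(rbind, lapply(x$local, as.numeric))
    sg <- do.call(rbind, lapply(x$semiglobal, as.numeric))
    q <- if (is.null(x$quantized)) integer(0) else as.integer(x$quantized)
    EdgeHistogramDescriptor(loc, as.numeric(x$global), sg, q)
}

#' Serialize a descriptor to JSON
#'
#' Dominant-color descriptors serialize as
#' `{"k": n, "colors": [{"h":..,"s":..,"v":..,"mu":..}, ...]}`; edge
#' descriptors as `{"local": [...], "global": [...], "semiglobal": [...],
#' "quantized": [...]|null}`. Numbers are written at full precision so
#' that [descriptorFromJson()] is an exact inverse.
#'
#' @param d A [MainColorDescriptor-class] or
#'   [EdgeHistogramDescriptor-class].
#' @return A JSON string.
#' @export
descriptorToJson <- function(d) {
    x <- if (is(d, "MainColorDescriptor")) .colorToList(d)
         else if (is(d, "EdgeHistogramDescriptor")) .edgeToList(d)
         else stop("unsupported descriptor class: ", class(d))
    as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                  null = "null"))
}

#' Deserialize a descriptor from JSON
#'
#' @param json A JSON string produced by [descriptorToJson()].
#' @return The descriptor object.
#' @export
descriptorFromJson <- function(json) {
    x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
    if (!is.null(x$k)) .colorFromList(x) else .edgeFromList(x)
}

## ---------------------------------------------------------------------------
## Index persistence: JSON-lines, one entry per image
## ---------------------------------------------------------------------------

#' Write a descriptor index as JSON lines
#'
#' One JSON object per line with fields `image_id`, `class_label` (null
#' when unlabeled), `color` and `edge`. Full-precision numbers make
#' [readIndexJsonl()] an exact inverse.
#'
#' @param index A [TongueIndex-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeIndexJsonl <- function(index, path) {
    lines <- vapply(seq_along(index@ids), function(i) {
        lab <- index@labels[i]
        entry <- list(image_id = index@ids[i],
                      class_label = if (is.na(lab)) NULL else lab,
                      color = .colorToList(index@colorDescriptors[[i]]),
                      edge = .edgeToList(index@edgeDescriptors[[i]]))
        as.character(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA,
                                      null = "null"))
    }, character(1L))
    writeLines(lines, path)
    invisible(path)
}

#' Read a descriptor index from JSON lines
#'
#' @param path Path written by [writeIndexJsonl()].
#' @param glaParams,ehdParams Parameters to record in the index (the file
#'   stores descriptors only).
#' @return A [TongueIndex-class].
#' @export
readIndexJsonl <- function(path, glaParams = GlaParams(),
                           ehdParams = EhdParams()) {
    lines <- readLines(path)
    ids <- character(); labels <- character()
    cds <- eds <- list()
    for (ln in lines) {
        x <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
        ids <- c(ids, x$image_id)
        labels <- c(labels,
                    if (is.null(x$class_label)) NA_character_
                    else x$class_label)
        cds <- c(cds, list(.colorFromList(x$color)))
        eds <- c(eds, list(.edgeFromList(x$edge)))
    }
    new("TongueIndex", ids = ids, labels = labels, colorDescriptors = cds,
        edgeDescriptors = eds, glaParams = glaParams, ehdParams = ehdParams)
}

## ---------------------------------------------------------------------------
## Configuration
## ---------------------------------------------------------------------------

#' Assemble a pipeline configuration
#'
#' Bundles every tunable of the pipeline into one list that round-trips
#' losslessly through [writeConfig()] / [readConfig()].
#'
#' @param glaParams A [GlaParams-class].
#' @param ehdParams An [EhdParams-class].
#' @param wColor,wTexture Fusion weights.
#' @param grayCoeffs `"standard"` or `"alt"`, see [rgbToGray()].
#' @param dcdDmax Color-similarity normalizer of [dcdDistance()].
#' @param seed Master seed.
#' @return A named configuration list.
#' @export
cbirConfig <- function(glaParams = GlaParams(), ehdParams = EhdParams(),
                       wColor = 0.6, wTexture = 0.4,
                       grayCoeffs = "standard", dcdDmax = 0.1, seed = 1L) {
    list(areaThreshold = glaParams@areaThreshold,
         splitThreshold = glaParams@splitThreshold,
         mergeThreshold = glaParams@mergeThreshold,
         weights = as.numeric(glaParams@weights),
         maxIter = glaParams@maxIter,
         maxRounds = glaParams@maxRounds,
         tol = glaParams@tol,
         blocksPerSubimage = ehdParams@blocksPerSubimage,
         edgeThreshold = ehdParams@edgeThreshold,
         quantize = ehdParams@quantize,
         wColor = wColor, wTexture = wTexture,
         grayCoeffs = grayCoeffs, dcdDmax = dcdDmax,
         seed = as.integer(seed))
}

#' Write a configuration to a YAML file
#'
#' @param config List from [cbirConfig()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeConfig <- function(config, path) {
    writeLines(yaml::as.yaml(config, precision = 15L), path)
    invisible(path)
}

#' Read a configuration file
#'
#' @param path YAML file written by [writeConfig()].
#' @return A configuration list; use [configParams()] to rebuild the
#'   parameter objects.
#' @export
readConfig <- function(path) {
    cfg <- yaml::yaml.load_file(path)
    cfg$maxIter <- as.integer(cfg$maxIter)
    cfg$maxRounds <- as.integer(cfg$maxRounds)
    cfg$blocksPerSubimage <- as.integer(cfg$blocksPerSubimage)
    cfg$seed <- as.integer(cfg$seed)
    cfg$weights <- as.numeric(cfg$weights)
    cfg
}

#' Rebuild parameter objects from a configuration list
#'
#' @param config List from [cbirConfig()] or [readConfig()].
#' @return List with elements `glaParams` and `ehdParams`.
#' @export
configParams <- function(config) {
    list(glaParams = GlaParams(areaThreshold = config$areaThreshold,
                               splitThreshold = config$splitThreshold,
                               mergeThreshold = config$mergeThreshold,
                               weights = config$weights,
                               maxIter = config$maxIter,
                               maxRounds = config$maxRounds,
                               tol = config$tol, seed = config$seed),
         ehdParams = EhdParams(blocksPerSubimage = config$blocksPerSubimage,
                               edgeThreshold = config$edgeThreshold,
                               quantize = config$quantize))
}
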