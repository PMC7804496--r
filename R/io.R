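#' @include stimgen.R
NULL

#' Read a grayscale image as a stimulus
#'
#' Reads an 8- or 16-bit PNG or TIFF, converts to a single grayscale
#' channel in [0, 1] (averaging channels if needed), and wraps it as a
#' [StimulusImage-class] so the contrast-energy metric can be evaluated
#' on arbitrary user images.
#'
#' @param path file path; format chosen by extension (.png/.tif/.tiff).
#' @param backgroundLevel declared background for convolution padding;
#'   defaults to the median pixel intensity.
#' @param eccentricity,geometry as in [stimulusImage()].
#' @return a [StimulusImage-class].
#' @export
readStimulus <- function(path, backgroundLevel = NULL, eccentricity = 0,
                         geometry = viewingGeometry(57)) {
    ext <- tolower(tools::file_ext(path))
    arr <- switch(ext,
        png = png::readPNG(path),
        tif = ,
        tiff = tiff::readTIFF(path),
        stop("unsupported image format: '", ext, "' (use png or tiff)"))
    if (length(dim(arr)) == 3L)
        arr <- apply(arr[, , seq_len(min(3L, dim(arr)[3])), drop = FALSE],
                     c(1, 2), mean)
    if (is.null(backgroundLevel))
        backgroundLevel <- stats::median(arr)
    stimulusImage(arr, backgroundLevel = backgroundLevel,
                  eccentricity = eccentricity, geometry = geometry)
}

#' Write a stimulus image as an 8-bit grayscale PNG
#'
#' @param image a [StimulusImage-class] or numeric matrix in [0, 1].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeStimulusPNG <- function(image, path) {
    im <- if (is(image, "StimulusImage")) intensities(image) else as.matrix(image)
    png::writePNG(im, path)
    invisible(path)
}

#' Write a filter-response map as a 32-bit float TIFF heat map
#'
#' Exports a convolution response map (which may be negative) as a
#' single-channel 32-bit floating point TIFF, min-max normalized into
#' [0, 1] (the TIFF writer's storage range).  The original value range is
#' returned so the normalization is invertible.
#'
#' @param responseMap numeric matrix, e.g. from [convolveMap()].
#' @param path output path.
#' @return invisibly, c(min, max) of the original responses.
#' @export
writeResponseTIFF <- function(responseMap, path) {
    rng <- range(responseMap)
    span <- if (diff(rng) > 0) diff(rng) else 1
    tiff::writeTIFF((responseMap - rng[1]) / span, path,
                    bits.per.sample = 32L, reduce = FALSE)
    invisible(rng)
}
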