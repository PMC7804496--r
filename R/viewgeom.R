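#' @include AllGenerics.R
NULL

#' Construct a viewing geometry
#'
#' @param distanceCm observer-to-screen distance in cm (> 0).
#' @param pixelPitchMm physical pixel size in mm (> 0); 0.282 mm is a
#'   common CRT/LCD pitch and the package-wide default.
#' @return a [ViewingGeometry-class].
#' @examples
#' g <- viewingGeometry(75, 0.282)
#' pixelsPerDegree(g)
#' @export
viewingGeometry <- function(distanceCm, pixelPitchMm = 0.282) {
    new("ViewingGeometry", viewingDistance = as.numeric(distanceCm),
        pixelPitch = as.numeric(pixelPitchMm))
}

.ppd <- function(distanceCm, pitchMm) {
    if (any(!is.finite(distanceCm)) || any(distanceCm <= 0))
        stop("viewing distance must be positive and finite")
    if (any(!is.finite(pitchMm)) || any(pitchMm <= 0))
        stop("pixel pitch must be positive and finite")
    # exact atan, not the small-angle approximation; one pixel subtends
    # atan(pitch / distance) with both lengths in mm
    degPerPx <- atan(pitchMm / (10 * distanceCm)) * 180 / pi
    1 / degPerPx
}

#' @describeIn pixelsPerDegree distance in cm as first argument, pixel
#'   pitch in mm as \code{pitch}.
#' @param pitch pixel pitch in mm (numeric method only).
#' @export
setMethod("pixelsPerDegree", "numeric", function(x, pitch = 0.282) {
    .ppd(x, pitch)
})

#' @describeIn pixelsPerDegree from a [ViewingGeometry-class].
#' @export
setMethod("pixelsPerDegree", "ViewingGeometry", function(x) {
    .ppd(x@viewingDistance, x@pixelPitch)
})

setMethod("show", "ViewingGeometry", function(object) {
    cat(sprintf("ViewingGeometry: %.4g cm distance, %.4g mm/px (%.4f px/deg)\n",
                object@viewingDistance, object@pixelPitch,
                pixelsPerDegree(object)))
})

#' Midget-cell dendritic field diameter at a retinal eccentricity
#'
#' Power-law fit of retinal midget ganglion cell dendritic field diameter
#' (micrometers) against retinal eccentricity (mm): \code{8.64 * x^1.04}.
#' The coefficients are taken as given from the anatomical fit; this
#' function is the anatomical anchor for the eccentricity scaling of the
#' foreground (center) Gaussian.
#'
#' @param eccMm retinal eccentricity in mm (>= 0), vectorized.
#' @param coefficient,exponent fit constants; defaults 8.64 and 1.04.
#' @return dendritic field diameter in micrometers.
#' @examples
#' dendriticDiameter(c(1, 2, 15))
#' @export
dendriticDiameter <- function(eccMm, coefficient = 8.64, exponent = 1.04) {
    if (any(!is.finite(eccMm)) || any(eccMm < 0))
        stop("retinal eccentricity must be nonnegative and finite")
    coefficient * eccMm^exponent
}

#' Construct a receptive-field profile at an eccentricity
#'
#' Two modes are supported.  In reproduction mode an explicit center sigma
#' in pixels (\code{sigmaPx}) is taken verbatim, as when reproducing a
#' tabulated experimental condition.  In model mode the sigma is derived
#' from the anatomical dendritic-diameter power law: eccentricity in
#' degrees is converted to retinal mm with a constant retinal
#' magnification, the dendritic diameter at that point is converted back
#' to degrees and then to pixels through the viewing geometry, and the
#' center sigma is a fixed fraction of that diameter.  The model-mode
#' constants are crude (see the package vignette) and are not validated
#' against tabulated sigmas; reproduction mode bypasses them.
#'
#' @param eccDeg eccentricity in degrees of visual angle (>= 0).
#' @param geometry a [ViewingGeometry-class]; required in model mode.
#' @param sigmaPx optional explicit center sigma in pixels.
#' @param K center-to-surround ratio (>= 1); default 5.
#' @param magnificationMmPerDeg retinal magnification, mm of retina per
#'   degree of visual angle (model mode; default 0.29).
#' @param diameterToSigma factor converting dendritic diameter to Gaussian
#'   sigma (model mode; default 0.5, i.e. sigma = diameter/2).
#' @param collectionWidthDeg width of the anatomical collection window
#'   around the region of interest, recorded for provenance only (a single
#'   sigma is used per image; the window does not modulate it).
#' @return a [ReceptiveFieldProfile-class].
#' @examples
#' rfProfile(5, sigmaPx = 10.8793)                     # reproduction mode
#' rfProfile(5, geometry = viewingGeometry(57))        # model mode
#' @export
rfProfile <- function(eccDeg, geometry = NULL, sigmaPx = NULL, K = 5,
                      magnificationMmPerDeg = 0.29, diameterToSigma = 0.5,
                      collectionWidthDeg = 17.2) {
    if (length(eccDeg) != 1L || !is.finite(eccDeg) || eccDeg < 0)
        stop("'eccDeg' must be a single nonnegative number")
    if (is.null(sigmaPx)) {
        if (is.null(geometry))
            stop("supply either an explicit 'sigmaPx' or a 'geometry' ",
                 "for model-mode sigma derivation")
        eccMm <- eccDeg * magnificationMmPerDeg
        diamUm <- dendriticDiameter(eccMm)
        diamDeg <- (diamUm / 1000) / magnificationMmPerDeg
        sigmaPx <- diameterToSigma * diamDeg * pixelsPerDegree(geometry)
    }
    new("ReceptiveFieldProfile", eccentricity = as.numeric(eccDeg),
        sigmaF = as.numeric(sigmaPx), surroundRatio = as.numeric(K))
}

#' @rdname accessors
#' @export
setMethod("sigmaF", "ReceptiveFieldProfile", function(object) object@sigmaF)

#' @rdname accessors
#' @export
setMethod("sigmaB", "ReceptiveFieldProfile",
    function(object) object@surroundRatio * object@sigmaF)

#' @rdname accessors
#' @export
setMethod("surroundRatio", "ReceptiveFieldProfile",
    function(object) object@surroundRatio)

#' @rdname accessors
#' @export
setMethod("eccentricity", "ReceptiveFieldProfile",
    function(object) object@eccentricity)

setMethod("show", "ReceptiveFieldProfile", function(object) {
    cat(sprintf(
        "ReceptiveFieldProfile at %.3g deg: sigmaF = %.5g px, K = %.3g (sigmaB = %.5g px)\n",
        object@eccentricity, object@sigmaF, object@surroundRatio,
        sigmaB(object)))
})
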