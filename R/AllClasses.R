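#' @import methods
NULL

#' Viewing geometry of a psychophysical display
#'
#' Couples the observer-to-screen distance with the physical pixel pitch of
#' the monitor, which together fix the angular subtense of one pixel and
#' hence the pixels-per-degree sampling rate of every rendered stimulus.
#'
#' @slot viewingDistance numeric(1), observer-to-screen distance in cm.
#' @slot pixelPitch numeric(1), physical size of one pixel in mm.
#'
#' @seealso [viewingGeometry()], [pixelsPerDegree()]
#' @export
setClass("ViewingGeometry",
    representation(viewingDistance = "numeric", pixelPitch = "numeric"))

setValidity("ViewingGeometry", function(object) {
    msg <- character()
    if (length(object@viewingDistance) != 1L ||
        !is.finite(object@viewingDistance) || object@viewingDistance <= 0)
        msg <- c(msg, "'viewingDistance' must be a single positive number (cm)")
    if (length(object@pixelPitch) != 1L ||
        !is.finite(object@pixelPitch) || object@pixelPitch <= 0)
        msg <- c(msg, "'pixelPitch' must be a single positive number (mm)")
    if (length(msg)) msg else TRUE
})

#' Center-surround receptive field profile at one eccentricity
#'
#' Holds the standard deviation of the foreground (center) Gaussian in
#' pixels, and the dimensionless center-to-surround ratio K.  The surround
#' standard deviation is defined as \code{sigmaB = K * sigmaF} and is
#' always derived, so the ratio invariant holds exactly.
#'
#' @slot eccentricity numeric(1), degrees of visual angle from fixation.
#' @slot sigmaF numeric(1), center Gaussian SD in pixels.
#' @slot surroundRatio numeric(1), K = sigmaB/sigmaF, at least 1.
#'
#' @seealso [rfProfile()], [dogKernel()]
#' @export
setClass("ReceptiveFieldProfile",
    representation(eccentricity = "numeric", sigmaF = "numeric",
                   surroundRatio = "numeric"))

setValidity("ReceptiveFieldProfile", function(object) {
    msg <- character()
    if (length(object@eccentricity) != 1L || object@eccentricity < 0)
        msg <- c(msg, "'eccentricity' must be a single nonnegative number (deg)")
    if (length(object@sigmaF) != 1L || !is.finite(object@sigmaF) ||
        object@sigmaF <= 0)
        msg <- c(msg, "'sigmaF' must be a single positive number (px)")
    if (length(object@surroundRatio) != 1L || object@surroundRatio < 1)
        msg <- c(msg, "'surroundRatio' (K) must be a single number >= 1")
    if (length(msg)) msg else TRUE
})

#' Discrete difference-of-Gaussians kernel
#'
#' A square, odd-sided weight array sampling the center-surround operator
#' (narrow Gaussian minus wide Gaussian) at integer pixel offsets,
#' truncated at a fixed multiple of the surround SD and mean-subtracted so
#' that the weights sum to exactly zero (the kernel annihilates constant
#' images).
#'
#' @slot weights numeric matrix, (2r+1) x (2r+1) kernel weights.
#' @slot sigmaF numeric(1), center SD in px.
#' @slot sigmaB numeric(1), surround SD in px.
#' @slot supportRadius integer(1), half-width r of the support in px.
#' @slot zeroSumAdjusted logical(1), TRUE once mean subtraction applied.
#'
#' @seealso [dogKernel()], [convolveMap()], [contrastEnergy()]
#' @export
setClass("DoGKernel",
    representation(weights = "matrix", sigmaF = "numeric", sigmaB = "numeric",
                   supportRadius = "integer", zeroSumAdjusted = "logical"))

setValidity("DoGKernel", function(object) {
    msg <- character()
    w <- object@weights
    r <- object@supportRadius
    if (nrow(w) != ncol(w) || nrow(w) != 2L * r + 1L)
        msg <- c(msg, "weights must be square with side 2*supportRadius + 1")
    if (nrow(w) %% 2L == 0L)
        msg <- c(msg, "kernel side length must be odd")
    if (isTRUE(object@zeroSumAdjusted) && abs(sum(w)) > 1e-12)
        msg <- c(msg, "zero-sum adjusted kernel must sum to 0 (within 1e-12)")
    if (max(abs(w - t(w))) > 1e-14 ||
        max(abs(w - w[nrow(w):1, ])) > 1e-14)
        msg <- c(msg, "kernel must be symmetric under reflection/transpose")
    if (length(msg)) msg else TRUE
})

#' A grayscale stimulus image
#'
#' Pixel intensities in [0, 1] plus the declared uniform background level
#' (used for boundary padding during convolution), the bounding box of the
#' target object, the retinal eccentricity at which the stimulus is
#' presented, and the viewing geometry that fixes its angular scale.
#'
#' @slot intensities numeric matrix in [0, 1]; rows are image rows
#'   (origin top-left).
#' @slot backgroundLevel numeric(1) in [0, 1].
#' @slot targetBox integer(4), c(row1, row2, col1, col2) of the target.
#' @slot eccentricity numeric(1), degrees of visual angle.
#' @slot geometry a [ViewingGeometry-class].
#'
#' @seealso [stimulusImage()], [renderStimulus()]
#' @export
setClass("StimulusImage",
    representation(intensities = "matrix", backgroundLevel = "numeric",
                   targetBox = "integer", eccentricity = "numeric",
                   geometry = "ViewingGeometry"))

setValidity("StimulusImage", function(object) {
    msg <- character()
    im <- object@intensities
    if (length(im) == 0L)
        msg <- c(msg, "image must contain at least one pixel")
    rng <- range(im)
    if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
        msg <- c(msg, "all intensities must lie in [0, 1]")
    if (length(object@backgroundLevel) != 1L ||
        object@backgroundLevel < 0 || object@backgroundLevel > 1)
        msg <- c(msg, "'backgroundLevel' must be a single value in [0, 1]")
    tb <- object@targetBox
    if (length(tb) != 4L ||
        tb[1] < 1L || tb[2] > nrow(im) || tb[3] < 1L || tb[4] > ncol(im) ||
        tb[1] > tb[2] || tb[3] > tb[4])
        msg <- c(msg, "'targetBox' must be c(row1, row2, col1, col2) inside the image")
    if (length(msg)) msg else TRUE
})

#' A contrast-energy value
#'
#' A nonnegative scalar in contrast-energy units, tagged with the
#' normalization convention under which it was computed: \code{"mean-square"}
#' (root of the per-pixel mean squared filter response; the default, under
#' which the degenerate kernel reduces to classical RMS contrast) or
#' \code{"sum-square"} (root of the total squared response).
#'
#' @slot value numeric(1), nonnegative.
#' @slot convention character(1), "mean-square" or "sum-square".
#'
#' @seealso [contrastEnergy()], [rmsContrast()]
#' @export
setClass("ContrastValue",
    representation(value = "numeric", convention = "character"))

setValidity("ContrastValue", function(object) {
    msg <- character()
    if (length(object@value) != 1L || !is.finite(object@value) ||
        object@value < 0)
        msg <- c(msg, "'value' must be a single nonnegative finite number")
    if (!object@convention %in% c("mean-square", "sum-square"))
        msg <- c(msg, "'convention' must be \"mean-square\" or \"sum-square\"")
    if (length(msg)) msg else TRUE
})

#' Contrast-to-behavior psychometric mapping model
#'
#' The single-parameter mapping from image contrast energy to predicted
#' proportion of correct target identifications.  Two Gaussians in
#' contrast-energy space share the target-alone mean \code{muT}: a narrow
#' one of SD \code{sigmaT} for the target presented alone (fixed by the
#' convention that a 10\% contrast change yields a 1\% identification
#' rate), and a wide one of SD \code{sigmaPhi = kPhi * sigmaT} for the
#' target among flankers, whose width is set by the sole experiment-derived
#' parameter \code{eAlpha} (the contrast energy at which flankers first
#' impede identification, i.e. where the flanked Gaussian has fallen to
#' 0.01).  Predictions are scaled by an empirical performance ceiling.
#'
#' @slot muT numeric(1), target-alone contrast energy (> 0).
#' @slot sigmaT numeric(1), target-alone Gaussian SD.
#' @slot eAlpha numeric(1), contrast energy of incipient flanker impediment.
#' @slot sigmaPhi numeric(1), flanked Gaussian SD.
#' @slot kPhi numeric(1), sigmaPhi/sigmaT, at least 1.
#' @slot ceiling numeric(1) in (0, 1], empirical performance ceiling.
#' @slot h numeric(1), the constant 2*log(0.01) (< 0).
#'
#' @seealso [mappingModel()], [proportionCorrect()]
#' @export
setClass("MappingModel",
    representation(muT = "numeric", sigmaT = "numeric", eAlpha = "numeric",
                   sigmaPhi = "numeric", kPhi = "numeric",
                   ceiling = "numeric", h = "numeric"))

setValidity("MappingModel", function(object) {
    msg <- character()
    if (object@muT <= 0) msg <- c(msg, "'muT' must be positive")
    if (object@sigmaT <= 0) msg <- c(msg, "'sigmaT' must be positive")
    if (object@kPhi < 1) msg <- c(msg, "'kPhi' must be >= 1")
    if (object@h >= 0) msg <- c(msg, "'h' must be negative")
    if (object@ceiling <= 0 || object@ceiling > 1)
        msg <- c(msg, "'ceiling' must lie in (0, 1]")
    if (abs(object@sigmaPhi - object@kPhi * object@sigmaT) >
        1e-12 * max(1, object@sigmaPhi))
        msg <- c(msg, "'sigmaPhi' must equal kPhi * sigmaT")
    if (length(msg)) msg else TRUE
})

#' Specification of a synthetic crowding stimulus
#'
#' A declarative description of one stimulus image from one of the four
#' supported families; [renderStimulus()] turns it into a
#' [StimulusImage-class] deterministically (identical specs give
#' bit-identical rasters).
#'
#' @slot family character(1), one of "letter_array", "landolt_bars",
#'   "vernier_lines", "concentric_cs".
#' @slot target named list of family-specific target geometry (sizes in
#'   deg or arcmin).
#' @slot flankers named list: count, spacing, size factors, orientations.
#' @slot intensity named list with targetLevel, flankerLevel,
#'   backgroundLevel, each in [0, 1].
#' @slot eccentricity numeric(1), degrees of visual angle.
#' @slot geometry a [ViewingGeometry-class].
#' @slot canvas named list with widthDeg/heightDeg (canvas size).
#'
#' @seealso [letterArraySpec()], [landoltBarsSpec()], [vernierSpec()],
#'   [concentricCsSpec()]
#' @export
setClass("StimulusSpec",
    representation(family = "character", target = "list", flankers = "list",
                   intensity = "list", eccentricity = "numeric",
                   geometry = "ViewingGeometry", canvas = "list"))

setValidity("StimulusSpec", function(object) {
    msg <- character()
    fams <- c("letter_array", "landolt_bars", "vernier_lines", "concentric_cs")
    if (length(object@family) != 1L || !object@family %in% fams)
        msg <- c(msg, paste0("'family' must be one of: ",
                             paste(fams, collapse = ", ")))
    lv <- object@intensity
    for (nm in c("targetLevel", "flankerLevel", "backgroundLevel")) {
        v <- lv[[nm]]
        if (is.null(v) || length(v) != 1L || v < 0 || v > 1)
            msg <- c(msg, sprintf("intensity$%s must be a single value in [0, 1]", nm))
    }
    cnt <- object@flankers$count
    if (!is.null(cnt) && (length(cnt) != 1L || cnt < 0))
        msg <- c(msg, "flankers$count must be a single nonnegative integer")
    sp <- object@flankers$spacing
    if (!is.null(sp) && any(sp <= 0))
        msg <- c(msg, "flankers$spacing must be positive")
    if (length(object@eccentricity) != 1L || object@eccentricity < 0)
        msg <- c(msg, "'eccentricity' must be a single nonnegative number")
    if (length(msg)) msg else TRUE
})

#' Configuration of one reproduced crowding experiment
#'
#' Bundles the tabulated constants of one experimental condition
#' (eccentricity, viewing distance, pixel pitch, center-Gaussian sigma,
#' target-alone contrast energy muT, flanker-impediment energy eAlpha) with
#' the stimulus family binding and the sweep (flank distances, flanker
#' counts, eccentricities) that the experiment runner iterates over.
#'
#' @slot id character(1), short experiment identifier (e.g. "HE", "KA").
#' @slot family character(1), stimulus family for [renderStimulus()].
#' @slot distanceCm numeric(1), viewing distance in cm.
#' @slot pixelPitchMm numeric(1), monitor pixel pitch in mm.
#' @slot eccentricities numeric vector, degrees.
#' @slot contrastSigma numeric vector parallel to eccentricities, center
#'   Gaussian SD in px at each eccentricity.
#' @slot K numeric(1), center-to-surround ratio.
#' @slot muT numeric(1), target-alone contrast energy.
#' @slot eAlpha numeric(1), flanker-impediment contrast energy.
#' @slot ceiling numeric(1), psychometric performance ceiling.
#' @slot sweep named list describing the swept variable(s).
#' @slot stimulus named list of family-specific geometry defaults.
#' @slot printed named list of tabulated derived values
#'   (pixelsPerDegree, sigmaT, kPhi) for cross-checking.
#'
#' @seealso [experimentConfig()], [runExperiment()], [reproduceTable1()]
#' @export
setClass("ExperimentConfig",
    representation(id = "character", family = "character",
                   distanceCm = "numeric", pixelPitchMm = "numeric",
                   eccentricities = "numeric", contrastSigma = "numeric",
                   K = "numeric", muT = "numeric", eAlpha = "numeric",
                   ceiling = "numeric", sweep = "list", stimulus = "list",
                   printed = "list"))

setValidity("ExperimentConfig", function(object) {
    msg <- character()
    if (length(object@eccentricities) < 1L)
        msg <- c(msg, "at least one eccentricity is required")
    if (length(object@contrastSigma) != length(object@eccentricities))
        msg <- c(msg, "'contrastSigma' must be parallel to 'eccentricities'")
    if (length(object@sweep) == 0L)
        msg <- c(msg, "'sweep' must be nonempty")
    if (length(msg)) msg else TRUE
})
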