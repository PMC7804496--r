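#' @include AllClasses.R
NULL

#' Pixels per degree of visual angle
#'
#' @param x a [ViewingGeometry-class], or a numeric viewing distance in cm.
#' @param ... for the numeric method, \code{pitch}: pixel pitch in mm.
#' @return numeric(1), pixels per degree of visual angle.
#' @export
setGeneric("pixelsPerDegree", function(x, ...) standardGeneric("pixelsPerDegree"))

#' Accessors for radialcontrast S4 objects
#'
#' Slot accessors for the package's S4 classes: receptive-field sigmas and
#' surround ratio, kernel weights and support radius, image intensities,
#' background level, target box, eccentricity, viewing geometry, and the
#' numeric value of a contrast energy.
#'
#' @param object an S4 object from this package.
#' @return the corresponding slot value (or derived quantity, for
#'   \code{sigmaB}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sigmaF", function(object) standardGeneric("sigmaF"))

#' @rdname accessors
#' @export
setGeneric("sigmaB", function(object) standardGeneric("sigmaB"))

#' @rdname accessors
#' @export
setGeneric("surroundRatio", function(object) standardGeneric("surroundRatio"))

#' @rdname accessors
#' @export
setGeneric("kernelWeights", function(object) standardGeneric("kernelWeights"))

#' @rdname accessors
#' @export
setGeneric("supportRadius", function(object) standardGeneric("supportRadius"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("backgroundLevel", function(object) standardGeneric("backgroundLevel"))

#' @rdname accessors
#' @export
setGeneric("targetBox", function(object) standardGeneric("targetBox"))

#' @rdname accessors
#' @export
setGeneric("eccentricity", function(object) standardGeneric("eccentricity"))

#' @rdname accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))

#' @rdname accessors
#' @export
setGeneric("energyValue", function(object) standardGeneric("energyValue"))

#' Convolve a stimulus with a difference-of-Gaussians kernel
#'
#' @param image a [StimulusImage-class] (or plain numeric matrix).
#' @param kernel a [DoGKernel-class].
#' @param ... further arguments (see methods), notably \code{method}.
#' @return numeric matrix of filter responses, same extent as the image.
#' @export
setGeneric("convolveMap", function(image, kernel, ...)
    standardGeneric("convolveMap"))

#' Radially generalized contrast energy of an image
#'
#' @param image a [StimulusImage-class] (or plain numeric matrix).
#' @param kernel a [DoGKernel-class].
#' @param ... further arguments, notably \code{convention}.
#' @return a [ContrastValue-class].
#' @export
setGeneric("contrastEnergy", function(image, kernel, ...)
    standardGeneric("contrastEnergy"))

#' Classical RMS contrast of an image
#'
#' @param image a [StimulusImage-class] or numeric matrix.
#' @param ... unused.
#' @return a [ContrastValue-class].
#' @export
setGeneric("rmsContrast", function(image, ...) standardGeneric("rmsContrast"))

#' Predicted proportion of correct identifications at a contrast energy
#'
#' @param C contrast energy: numeric vector or [ContrastValue-class].
#' @param model a [MappingModel-class].
#' @param ... unused.
#' @return numeric vector of predicted proportions correct in
#'   \code{[0, ceiling(model)]}.
#' @export
setGeneric("proportionCorrect", function(C, model, ...)
    standardGeneric("proportionCorrect"))

#' Rasterize a stimulus specification
#'
#' @param spec a [StimulusSpec-class].
#' @param ... unused.
#' @return a [StimulusImage-class]; identical specs give bit-identical
#'   rasters.
#' @export
setGeneric("renderStimulus", function(spec, ...)
    standardGeneric("renderStimulus"))

#' Run a configured crowding experiment end to end
#'
#' @param config an [ExperimentConfig-class].
#' @param ... further arguments (see method).
#' @return a data.frame of curve points.
#' @export
setGeneric("runExperiment", function(config, ...)
    standardGeneric("runExperiment"))

#' RMS-contrast confound report for a configured experiment
#'
#' @param config an [ExperimentConfig-class].
#' @param ... further arguments (see method).
#' @return a data.frame of RMS contrast per swept condition.
#' @export
setGeneric("rmsConfoundReport", function(config, ...)
    standardGeneric("rmsConfoundReport"))
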