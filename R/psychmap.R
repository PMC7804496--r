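#' @include dogfield.R
NULL

## calibration constants of the contrast-to-behavior mapping: a 10% change
## to the target-alone contrast is assumed to yield a 1% identification
## rate, and predictions are scaled by an empirical 85% performance ceiling.
.RC_DELTA <- 0.1
.RC_RATE <- 0.01
.RC_CEILING <- 0.85

#' The psychometric normalization constant h = 2 log(0.01)
#'
#' @param rate the identification rate reached at the calibration points
#'   of the psychometric Gaussians; default 0.01.
#' @return the (negative) constant \code{2 * log(rate)}.
#' @export
psychometricH <- function(rate = .RC_RATE) 2 * log(rate)

#' Target-alone psychometric width from the target contrast
#'
#' The SD of the target-alone Gaussian is fixed (not fitted) by the
#' convention that a 10\% change to the target-alone contrast energy
#' \code{muT} yields a 1\% identification rate:
#' \code{sigmaT = sqrt(-(0.1 muT)^2 / h)} with \code{h = 2 log(0.01)},
#' i.e. \code{0.1 * muT / sqrt(-h)}.
#'
#' @param muT target-alone contrast energy (>= 0), vectorized.
#' @param delta relative contrast change at which errors begin;
#'   default 0.1.
#' @param rate identification rate at that point; default 0.01.
#' @return sigmaT in the same units as \code{muT}.
#' @examples
#' sigmaTau(0.020228)
#' @export
sigmaTau <- function(muT, delta = .RC_DELTA, rate = .RC_RATE) {
    if (any(!is.finite(muT)) || any(muT < 0))
        stop("'muT' must be nonnegative and finite")
    delta * muT / sqrt(-psychometricH(rate))
}

#' Flanked-to-alone width ratio from the flanker-impediment energy
#'
#' The flanked Gaussian's SD is set so it falls to the calibration rate at
#' \code{eAlpha}, the contrast energy at which flankers first impede
#' identification: \code{sigmaPhi = |eAlpha - muT| / sqrt(-h)}, giving the
#' dimensionless ratio \code{kPhi = sigmaPhi / sigmaT =
#' |eAlpha - muT| / (0.1 muT)}.  The squared forms make the sign of
#' \code{eAlpha - muT} irrelevant, so the absolute difference is used.
#' A ratio below 1 would break the guarantee that predicted proportions
#' stay at or below the ceiling, and is rejected.
#'
#' @param eAlpha flanker-impediment contrast energy.
#' @param muT target-alone contrast energy (> 0).
#' @param delta,rate calibration constants as in [sigmaTau()].
#' @return the dimensionless ratio kPhi (>= 1).
#' @examples
#' kPhiFrom(0.032, 0.016057)
#' @export
kPhiFrom <- function(eAlpha, muT, delta = .RC_DELTA, rate = .RC_RATE) {
    if (any(!is.finite(muT)) || any(muT <= 0))
        stop("'muT' must be positive and finite")
    k <- abs(eAlpha - muT) / (delta * muT)
    if (any(k < 1 - 1e-9))
        stop("model violation: |eAlpha - muT| < ", delta, "*muT implies ",
             "kPhi < 1 (flanked Gaussian narrower than target-alone)")
    pmax(k, 1)   # guard against rounding exactly at the boundary
}

#' Assemble a contrast-to-behavior mapping model
#'
#' Builds a [MappingModel-class] from the target-alone contrast energy and
#' the sole experiment-derived parameter \code{eAlpha}, deriving
#' \code{sigmaT} via [sigmaTau()] and \code{kPhi} via [kPhiFrom()].
#'
#' @param muT target-alone contrast energy (> 0).
#' @param eAlpha flanker-impediment contrast energy.
#' @param ceiling empirical performance ceiling in (0, 1]; default 0.85.
#' @param delta,rate calibration constants as in [sigmaTau()].
#' @return a [MappingModel-class].
#' @examples
#' m <- mappingModel(0.016057, 0.032)
#' proportionCorrect(c(0.016057, 0.025, 0.032), m)
#' @export
mappingModel <- function(muT, eAlpha, ceiling = .RC_CEILING,
                         delta = .RC_DELTA, rate = .RC_RATE) {
    sT <- sigmaTau(muT, delta, rate)
    k <- kPhiFrom(eAlpha, muT, delta, rate)
    new("MappingModel", muT = as.numeric(muT), sigmaT = sT,
        eAlpha = as.numeric(eAlpha), sigmaPhi = k * sT, kPhi = k,
        ceiling = as.numeric(ceiling), h = psychometricH(rate))
}

setMethod("show", "MappingModel", function(object) {
    cat(sprintf(
        "MappingModel: muT = %.6g, sigmaT = %.4g, eAlpha = %.4g, kPhi = %.4f, ceiling = %.2f\n",
        object@muT, object@sigmaT, object@eAlpha, object@kPhi,
        object@ceiling))
})

.pcorrect <- function(C, model) {
    if (any(!is.finite(C)) || any(C < 0))
        stop("contrast energy 'C' must be nonnegative and finite")
    z2 <- (C - model@muT)^2 / (2 * model@sigmaT^2)
    gTau <- exp(-z2)
    gPhi <- exp(-z2 / model@kPhi^2)
    model@ceiling * (gTau + 1 - gPhi)
}

#' @describeIn proportionCorrect numeric contrast energies; returns
#'   \code{ceiling * (Gtau(C) + 1 - Gphi(C))} where \code{Gtau} and
#'   \code{Gphi} are the target-alone and flanked Gaussians.  With
#'   \code{kPhi >= 1} the result always lies in \code{[0, ceiling]}.
#' @export
setMethod("proportionCorrect", signature("numeric", "MappingModel"),
    function(C, model) .pcorrect(C, model))

#' @describeIn proportionCorrect a [ContrastValue-class] input.
#' @export
setMethod("proportionCorrect", signature("ContrastValue", "MappingModel"),
    function(C, model) .pcorrect(C@value, model))

#' @rdname accessors
#' @export
setGeneric("muT", function(object) standardGeneric("muT"))

#' @rdname accessors
#' @export
setMethod("muT", "MappingModel", function(object) object@muT)

#' @rdname accessors
#' @export
setGeneric("sigmaT", function(object) standardGeneric("sigmaT"))

#' @rdname accessors
#' @export
setMethod("sigmaT", "MappingModel", function(object) object@sigmaT)

#' @rdname accessors
#' @export
setGeneric("eAlpha", function(object) standardGeneric("eAlpha"))

#' @rdname accessors
#' @export
setMethod("eAlpha", "MappingModel", function(object) object@eAlpha)

#' @rdname accessors
#' @export
setGeneric("kPhi", function(object) standardGeneric("kPhi"))

#' @rdname accessors
#' @export
setMethod("kPhi", "MappingModel", function(object) object@kPhi)

#' Serialize a mapping model to a one-row data frame
#'
#' Lays out the model's primitive and derived parameters in the column
#' order of the package's experiment summary table (see
#' [reproduceTable1()]), convenient for CSV export.
#'
#' @param x a [MappingModel-class].
#' @param row.names,optional,... passed through (see
#'   [base::as.data.frame()]).
#' @return a one-row data.frame.
#' @export
as.data.frame.MappingModel <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
    data.frame(mu_t = x@muT, sigma_t = x@sigmaT, E_alpha = x@eAlpha,
               k_phi = x@kPhi, ceiling = x@ceiling,
               row.names = row.names, ...)
}
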