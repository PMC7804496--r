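#' @include psychmap.R
NULL

## Embedded fixed letter bitmaps (monochrome, 5 x 5).  System fonts are
## deliberately not used: identical specs must rasterize bit-identically
## on every platform, and pixel-count oracles must be exact.
.GLYPH_BITMAPS <- list(
    r = c("X.XX.",
          "XX..X",
          "X....",
          "X....",
          "X...."),
    a = c(".XXX.",
          "....X",
          ".XXXX",
          "X...X",
          ".XXXX"),
    n = c("X.XX.",
          "XX..X",
          "X...X",
          "X...X",
          "X...X"),
    o = c(".XXX.",
          "X...X",
          "X...X",
          "X...X",
          ".XXX."))

.glyphMatrix <- function(letter) {
    rows <- .GLYPH_BITMAPS[[letter]]
    if (is.null(rows))
        stop("no embedded bitmap for letter '", letter, "'; available: ",
             paste(names(.GLYPH_BITMAPS), collapse = ", "))
    do.call(rbind, lapply(strsplit(rows, ""), function(ch) as.integer(ch == "X")))
}

#' Rasterize an embedded letter glyph at a pixel height
#'
#' Nearest-neighbor upscaling of a fixed embedded monochrome bitmap;
#' deterministic, no anti-aliasing.
#'
#' @param letter one of the embedded letters (currently "r", "a", "n", "o").
#' @param heightPx target height in pixels (>= 3).
#' @return a 0/1 integer matrix of the requested height.
#' @export
letterGlyph <- function(letter, heightPx) {
    heightPx <- as.integer(round(heightPx))
    if (heightPx < 3L) stop("letter height below raster resolution (< 3 px)")
    g <- .glyphMatrix(letter)
    widthPx <- max(3L, as.integer(round(heightPx * ncol(g) / nrow(g))))
    ri <- pmin(nrow(g), ceiling(seq_len(heightPx) / heightPx * nrow(g)))
    ci <- pmin(ncol(g), ceiling(seq_len(widthPx) / widthPx * ncol(g)))
    g[ri, ci, drop = FALSE]
}

#' Rasterize a Landolt C (or full annulus)
#'
#' Annulus of outer diameter \code{diameterPx} with standard Landolt
#' proportions: stroke width and gap width both one fifth of the
#' diameter.  The gap is a square-cut band along the ray at
#' \code{gapOrientation} (0 = gap to the right, 90 = gap up, measured
#' counterclockwise); \code{gapless = TRUE} renders the full annulus.
#' Binary ink, no anti-aliasing.
#'
#' @param diameterPx outer diameter in pixels (>= 5).
#' @param gapOrientation gap direction in degrees.
#' @param gapless render an un-gapped circle.
#' @param strokePx stroke width in pixels; defaults to the standard
#'   \code{diameterPx / 5}.
#' @param gapWidthPx gap width in pixels; defaults to the standard
#'   \code{diameterPx / 5} (so the gap scales with the ring even when an
#'   explicit thinner stroke is requested).
#' @return a 0/1 integer matrix (odd side length, glyph centered).
#' @examples
#' sum(landoltC(50))              # ink area
#' sum(landoltC(50, gapless = TRUE))
#' @export
landoltC <- function(diameterPx, gapOrientation = 0, gapless = FALSE,
                     strokePx = diameterPx / 5,
                     gapWidthPx = diameterPx / 5) {
    if (diameterPx < 5)
        stop("Landolt C below raster resolution (diameter < 5 px)")
    R <- diameterPx / 2
    stroke <- strokePx
    half <- ceiling(R)
    off <- seq.int(-half, half)
    x <- matrix(off, length(off), length(off), byrow = TRUE)   # columns ->
    y <- -matrix(off, length(off), length(off))                # rows: up +
    r <- sqrt(x^2 + y^2)
    ink <- r <= R & r >= R - stroke
    if (!gapless) {
        # cospi/sinpi keep right-angle orientations exact on the grid
        cth <- cospi(gapOrientation / 180)
        sth <- sinpi(gapOrientation / 180)
        u <- x * cth + y * sth             # along gap direction
        v <- -x * sth + y * cth            # across it
        ink <- ink & !(u > 0 & abs(v) <= gapWidthPx / 2)
    }
    mode(ink) <- "integer"
    ink
}

## -- spec constructors ------------------------------------------------------

.mkSpec <- function(family, target, flankers, intensity, eccentricity,
                    geometry, canvas) {
    new("StimulusSpec", family = family, target = target,
        flankers = flankers, intensity = intensity,
        eccentricity = as.numeric(eccentricity), geometry = geometry,
        canvas = canvas)
}

#' Letter target with letter flankers
#'
#' A target letter optionally surrounded by flanker letters at the
#' cardinal positions (2 flankers: left/right; 4: plus above/below), the
#' classic crowded-letter arrangement.  Default rendering is gray letters
#' on a white background.
#'
#' @param letterHeightDeg letter height, degrees of visual angle.
#' @param targetLetter,flankerLetter embedded glyph names.
#' @param flankerCount 0, 2 or 4.
#' @param spacingDeg flanker spacing in degrees (see \code{spacingMode}).
#' @param spacingMode \code{"edge"} (default: empty gap between target and
#'   flanker edges) or \code{"center"} (center-to-center).
#' @param eccentricity presentation eccentricity in degrees.
#' @param geometry a [ViewingGeometry-class].
#' @param targetLevel,flankerLevel,backgroundLevel intensities in [0, 1].
#' @param canvasDeg c(width, height) of the canvas in degrees, or NULL to
#'   fit the content with \code{marginDeg} of margin.
#' @param marginDeg canvas margin when auto-sizing.
#' @return a [StimulusSpec-class].
#' @export
letterArraySpec <- function(letterHeightDeg = 0.4, targetLetter = "r",
                            flankerLetter = "a", flankerCount = 4,
                            spacingDeg = 0.2, spacingMode = c("edge", "center"),
                            eccentricity = 10,
                            geometry = viewingGeometry(55.88),
                            targetLevel = 0.5, flankerLevel = 0.5,
                            backgroundLevel = 1, canvasDeg = NULL,
                            marginDeg = 0.5) {
    spacingMode <- match.arg(spacingMode)
    if (!flankerCount %in% c(0, 2, 4))
        stop("'flankerCount' must be 0, 2 or 4 for letter arrays")
    .mkSpec("letter_array",
        target = list(heightDeg = letterHeightDeg, letter = targetLetter),
        flankers = list(count = flankerCount, spacing = spacingDeg,
                        spacingMode = spacingMode, letter = flankerLetter),
        intensity = list(targetLevel = targetLevel,
                         flankerLevel = flankerLevel,
                         backgroundLevel = backgroundLevel),
        eccentricity = eccentricity, geometry = geometry,
        canvas = list(canvasDeg = canvasDeg, marginDeg = marginDeg))
}

#' Landolt C target with four flanking bars
#'
#' A gapped annulus with tangential flanking bars above, below, left and
#' right, the classic bar-flanked acuity arrangement; distances are in
#' arcminutes and default rendering is black on a gray background.
#'
#' @param diameterArcmin target C outer diameter, arcmin.
#' @param gapOrientation target gap direction, degrees.
#' @param flankDistanceArcmin edge-to-edge gap between the C and each bar,
#'   arcmin (\code{spacingMode = "edge"}), or center-to-center distance
#'   (\code{"center"}).
#' @param flankerCount number of bars (0 or 4).
#' @param barLengthFactor bar length as a multiple of the C diameter.
#' @param spacingMode \code{"edge"} (default) or \code{"center"}.
#' @param eccentricity,geometry,targetLevel,flankerLevel,backgroundLevel,canvasDeg,marginDeg
#'   as in [letterArraySpec()].
#' @return a [StimulusSpec-class].
#' @export
landoltBarsSpec <- function(diameterArcmin = 1, gapOrientation = 0,
                            flankDistanceArcmin = 0.6, flankerCount = 4,
                            barLengthFactor = 1.5,
                            spacingMode = c("edge", "center"),
                            eccentricity = 5,
                            geometry = viewingGeometry(2300),
                            targetLevel = 0, flankerLevel = 0,
                            backgroundLevel = 0.5, canvasDeg = NULL,
                            marginDeg = NULL) {
    spacingMode <- match.arg(spacingMode)
    if (!flankerCount %in% c(0, 4))
        stop("'flankerCount' must be 0 or 4 for bar-flanked Landolt C")
    if (is.null(marginDeg)) marginDeg <- 2 * diameterArcmin / 60
    .mkSpec("landolt_bars",
        target = list(diameterArcmin = diameterArcmin,
                      gapOrientation = gapOrientation),
        flankers = list(count = flankerCount,
                        spacing = flankDistanceArcmin,
                        spacingMode = spacingMode,
                        barLengthFactor = barLengthFactor),
        intensity = list(targetLevel = targetLevel,
                         flankerLevel = flankerLevel,
                         backgroundLevel = backgroundLevel),
        eccentricity = eccentricity, geometry = geometry,
        canvas = list(canvasDeg = canvasDeg, marginDeg = marginDeg))
}

#' Vernier target with flanking lines
#'
#' Two nearly collinear vertical segments with a small horizontal offset
#' (the vernier), surrounded by an even number of full-height vertical
#' flanking lines placed symmetrically left and right at uniform spacing.
#'
#' @param segmentLengthDeg length of each vernier segment, degrees.
#' @param offsetDeg horizontal offset between the segments, degrees.
#' @param offsetDirection \code{"left"} (top segment left) or
#'   \code{"right"}.
#' @param gapDeg vertical gap between the segments, degrees.
#' @param lineWidthDeg stroke width of all lines, degrees.
#' @param flankerCount total number of flanking lines (even; 0-16).
#' @param spacingDeg center-to-center pitch between neighboring lines,
#'   degrees.
#' @param heightFactor flanker height as a multiple of the full vernier
#'   height (e.g. 0.5, 1, 2).
#' @param eccentricity,geometry,targetLevel,flankerLevel,backgroundLevel,canvasDeg,marginDeg
#'   as in [letterArraySpec()].
#' @return a [StimulusSpec-class].
#' @export
vernierSpec <- function(segmentLengthDeg = 0.3, offsetDeg = 0.05,
                        offsetDirection = c("left", "right"),
                        gapDeg = 0.02, lineWidthDeg = 0.025,
                        flankerCount = 0, spacingDeg = 0.2,
                        heightFactor = 1, eccentricity = 3.88,
                        geometry = viewingGeometry(75),
                        targetLevel = 0, flankerLevel = 0,
                        backgroundLevel = 0.5, canvasDeg = NULL,
                        marginDeg = 0.5) {
    offsetDirection <- match.arg(offsetDirection)
    if (flankerCount %% 2 != 0)
        stop("'flankerCount' must be even (flankers are placed in ",
             "left/right pairs)")
    .mkSpec("vernier_lines",
        target = list(segmentLengthDeg = segmentLengthDeg,
                      offsetDeg = offsetDeg,
                      offsetDirection = offsetDirection, gapDeg = gapDeg,
                      lineWidthDeg = lineWidthDeg),
        flankers = list(count = flankerCount, spacing = spacingDeg,
                        heightFactor = heightFactor),
        intensity = list(targetLevel = targetLevel,
                         flankerLevel = flankerLevel,
                         backgroundLevel = backgroundLevel),
        eccentricity = eccentricity, geometry = geometry,
        canvas = list(canvasDeg = canvasDeg, marginDeg = marginDeg))
}

#' Landolt C target with concentric C (or circle) flankers
#'
#' A small gapped annulus encircled by up to five concentric larger
#' annuli, each with its own gap orientation (or un-gapped full circles),
#' all sharing the target's center; flanker stroke scales with flanker
#' diameter (standard Landolt proportions throughout).
#'
#' @param diameterDeg target C outer diameter, degrees.
#' @param gapOrientation target gap direction, degrees.
#' @param flankerCount number of concentric flankers (0-5).
#' @param spacingDeg radial gap between successive ring edges, degrees.
#' @param gapless render flankers as full circles.
#' @param flankerStroke \code{"target"} (default): every flanker ring has
#'   the target's stroke width, the usual convention for these stimuli
#'   (and the one that keeps neighboring rings from fusing);
#'   \code{"scaled"}: stroke is one fifth of each ring's own diameter.
#' @param flankerOrientations gap directions for the flankers; a fixed
#'   deterministic default sequence is used when NULL.
#' @param eccentricity,geometry,targetLevel,flankerLevel,backgroundLevel,canvasDeg,marginDeg
#'   as in [letterArraySpec()].
#' @return a [StimulusSpec-class].
#' @export
concentricCsSpec <- function(diameterDeg = 1.25, gapOrientation = 0,
                             flankerCount = 1, spacingDeg = 0.35,
                             gapless = FALSE,
                             flankerStroke = c("target", "scaled"),
                             flankerOrientations = NULL,
                             eccentricity = 10,
                             geometry = viewingGeometry(58),
                             targetLevel = 0, flankerLevel = 0,
                             backgroundLevel = 0.5, canvasDeg = NULL,
                             marginDeg = 0.5) {
    flankerStroke <- match.arg(flankerStroke)
    if (flankerCount < 0 || flankerCount > 5)
        stop("'flankerCount' must be between 0 and 5")
    if (is.null(flankerOrientations))
        flankerOrientations <- c(90, 180, 0, 270, 45)[seq_len(flankerCount)]
    .mkSpec("concentric_cs",
        target = list(diameterDeg = diameterDeg,
                      gapOrientation = gapOrientation),
        flankers = list(count = flankerCount, spacing = spacingDeg,
                        gapless = gapless, stroke = flankerStroke,
                        orientations = flankerOrientations),
        intensity = list(targetLevel = targetLevel,
                         flankerLevel = flankerLevel,
                         backgroundLevel = backgroundLevel),
        eccentricity = eccentricity, geometry = geometry,
        canvas = list(canvasDeg = canvasDeg, marginDeg = marginDeg))
}

## -- rasterization ----------------------------------------------------------

## paint mask ink into canvas at a center position (row, col); returns the
## canvas and the bounding box of what was painted
.stamp <- function(canvas, mask, centerRow, centerCol, level) {
    r0 <- as.integer(round(centerRow - (nrow(mask) - 1) / 2))
    c0 <- as.integer(round(centerCol - (ncol(mask) - 1) / 2))
    r1 <- r0 + nrow(mask) - 1L
    c1 <- c0 + ncol(mask) - 1L
    if (r0 < 1L || c0 < 1L || r1 > nrow(canvas) || c1 > ncol(canvas))
        stop("stimulus exceeds the canvas; enlarge 'canvasDeg'")
    sub <- canvas[r0:r1, c0:c1]
    sub[mask == 1L] <- level
    canvas[r0:r1, c0:c1] <- sub
    list(canvas = canvas, box = c(r0, r1, c0, c1))
}

.oddCeil <- function(x) {
    n <- as.integer(ceiling(x))
    if (n %% 2L == 0L) n + 1L else n
}

.canvasFor <- function(spec, contentWpx, contentHpx, ppd) {
    cd <- spec@canvas$canvasDeg
    if (!is.null(cd)) {
        w <- .oddCeil(cd[1] * ppd)
        h <- .oddCeil(cd[length(cd)] * ppd)
    } else {
        m <- 2 * spec@canvas$marginDeg * ppd
        w <- .oddCeil(contentWpx + m)
        h <- .oddCeil(contentHpx + m)
    }
    matrix(spec@intensity$backgroundLevel, h, w)
}

.renderLetterArray <- function(spec, ppd) {
    hpx <- round(spec@target$heightDeg * ppd)
    tg <- letterGlyph(spec@target$letter, hpx)
    fg <- letterGlyph(spec@flankers$letter, hpx)
    spx <- spec@flankers$spacing * ppd
    edge <- spec@flankers$spacingMode == "edge"
    dx <- if (edge) ncol(tg) / 2 + spx + ncol(fg) / 2 else spx
    dy <- if (edge) nrow(tg) / 2 + spx + nrow(fg) / 2 else spx
    extentW <- ncol(tg) + 2 * (dx + ncol(fg))
    extentH <- nrow(tg) + 2 * (dy + nrow(fg))
    canvas <- .canvasFor(spec, extentW, extentH, ppd)
    cc <- (ncol(canvas) + 1) / 2
    cr <- (nrow(canvas) + 1) / 2
    st <- .stamp(canvas, tg, cr, cc, spec@intensity$targetLevel)
    canvas <- st$canvas
    n <- spec@flankers$count
    lv <- spec@intensity$flankerLevel
    if (n >= 2) {
        canvas <- .stamp(canvas, fg, cr, cc - dx, lv)$canvas
        canvas <- .stamp(canvas, fg, cr, cc + dx, lv)$canvas
    }
    if (n >= 4) {
        canvas <- .stamp(canvas, fg, cr - dy, cc, lv)$canvas
        canvas <- .stamp(canvas, fg, cr + dy, cc, lv)$canvas
    }
    list(canvas = canvas, box = st$box)
}

.renderLandoltBars <- function(spec, ppd) {
    dpx <- spec@target$diameterArcmin / 60 * ppd
    cglyph <- landoltC(dpx, spec@target$gapOrientation)
    stroke <- max(1L, as.integer(round(dpx / 5)))
    blen <- max(1L, as.integer(round(spec@flankers$barLengthFactor * dpx)))
    spx <- spec@flankers$spacing / 60 * ppd
    half <- (ncol(cglyph) - 1) / 2       # glyph half-side ~ outer radius
    d <- if (spec@flankers$spacingMode == "edge")
        half + spx + stroke / 2 else spx
    extent <- ncol(cglyph) + 2 * (d + stroke)
    canvas <- .canvasFor(spec, extent, extent, ppd)
    cc <- (ncol(canvas) + 1) / 2
    cr <- (nrow(canvas) + 1) / 2
    st <- .stamp(canvas, cglyph, cr, cc, spec@intensity$targetLevel)
    canvas <- st$canvas
    if (spec@flankers$count >= 4) {
        hbar <- matrix(1L, stroke, blen)   # tangential above/below
        vbar <- matrix(1L, blen, stroke)   # tangential left/right
        lv <- spec@intensity$flankerLevel
        canvas <- .stamp(canvas, vbar, cr, cc - d, lv)$canvas
        canvas <- .stamp(canvas, vbar, cr, cc + d, lv)$canvas
        canvas <- .stamp(canvas, hbar, cr - d, cc, lv)$canvas
        canvas <- .stamp(canvas, hbar, cr + d, cc, lv)$canvas
    }
    list(canvas = canvas, box = st$box)
}

.renderVernier <- function(spec, ppd) {
    seg <- max(2L, as.integer(round(spec@target$segmentLengthDeg * ppd)))
    gap <- as.integer(round(spec@target$gapDeg * ppd))
    wid <- max(1L, as.integer(round(spec@target$lineWidthDeg * ppd)))
    halfOff <- max(1L, as.integer(round(spec@target$offsetDeg * ppd / 2)))
    sgn <- if (spec@target$offsetDirection == "left") -1L else 1L
    totalH <- 2L * seg + gap
    n <- spec@flankers$count
    fh <- as.integer(round(spec@flankers$heightFactor * totalH))
    pitch <- spec@flankers$spacing * ppd
    maxOff <- if (n > 0) (n / 2) * pitch else 0
    extentW <- 2 * (maxOff + wid) + 4 * halfOff
    extentH <- max(totalH, fh)
    canvas <- .canvasFor(spec, extentW, extentH, ppd)
    cc <- (ncol(canvas) + 1) / 2
    cr <- (nrow(canvas) + 1) / 2
    lvT <- spec@intensity$targetLevel
    segm <- matrix(1L, seg, wid)
    topC <- cc + sgn * halfOff
    botC <- cc - sgn * halfOff
    st1 <- .stamp(canvas, segm, cr - (gap + seg) / 2 - 0.5, topC, lvT)
    st2 <- .stamp(st1$canvas, segm, cr + (gap + seg) / 2 + 0.5, botC, lvT)
    canvas <- st2$canvas
    box <- c(min(st1$box[1], st2$box[1]), max(st1$box[2], st2$box[2]),
             min(st1$box[3], st2$box[3]), max(st1$box[4], st2$box[4]))
    if (n > 0) {
        fl <- matrix(1L, fh, wid)
        lv <- spec@intensity$flankerLevel
        for (i in seq_len(n / 2)) {
            off <- i * pitch
            if (off - wid / 2 <= abs(halfOff) + wid / 2)
                stop("flanking lines overlap the vernier target; ",
                     "increase 'spacingDeg'")
            canvas <- .stamp(canvas, fl, cr, cc - off, lv)$canvas
            canvas <- .stamp(canvas, fl, cr, cc + off, lv)$canvas
        }
    }
    list(canvas = canvas, box = box)
}

.renderConcentricCs <- function(spec, ppd) {
    d0 <- spec@target$diameterDeg * ppd
    spx <- spec@flankers$spacing * ppd
    n <- spec@flankers$count
    diams <- if (n > 0) d0 + 2 * seq_len(n) * spx else numeric()
    extent <- if (n > 0) max(diams) + 2 else d0 + 2
    canvas <- .canvasFor(spec, extent, extent, ppd)
    cc <- (ncol(canvas) + 1) / 2
    cr <- (nrow(canvas) + 1) / 2
    tg <- landoltC(d0, spec@target$gapOrientation)
    st <- .stamp(canvas, tg, cr, cc, spec@intensity$targetLevel)
    canvas <- st$canvas
    lv <- spec@intensity$flankerLevel
    for (i in seq_len(n)) {
        strokePx <- if (identical(spec@flankers$stroke, "scaled"))
            diams[i] / 5 else d0 / 5
        ring <- landoltC(diams[i],
                         gapOrientation = spec@flankers$orientations[i],
                         gapless = isTRUE(spec@flankers$gapless),
                         strokePx = strokePx)
        canvas <- .stamp(canvas, ring, cr, cc, lv)$canvas
    }
    list(canvas = canvas, box = st$box)
}

#' @describeIn renderStimulus rasterize one of the four stimulus
#'   families.  All angular sizes are converted through the spec's
#'   viewing geometry; rendering is a pure function of the spec.
#' @export
setMethod("renderStimulus", "StimulusSpec", function(spec) {
    ppd <- pixelsPerDegree(spec@geometry)
    out <- switch(spec@family,
        letter_array = .renderLetterArray(spec, ppd),
        landolt_bars = .renderLandoltBars(spec, ppd),
        vernier_lines = .renderVernier(spec, ppd),
        concentric_cs = .renderConcentricCs(spec, ppd))
    stimulusImage(out$canvas,
                  backgroundLevel = spec@intensity$backgroundLevel,
                  targetBox = out$box,
                  eccentricity = spec@eccentricity,
                  geometry = spec@geometry)
})

setMethod("show", "StimulusSpec", function(object) {
    cat(sprintf("StimulusSpec (%s): %d flanker(s), eccentricity %.3g deg\n",
                object@family, object@flankers$count %||% 0L,
                object@eccentricity))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
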