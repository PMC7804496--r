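geomTest <- viewingGeometry(2300, 0.282)   # 1423.5 px/deg: arcmin-scale work

test_that("rendering is a pure function of the spec", {
    sp <- landoltBarsSpec(diameterArcmin = 6, flankDistanceArcmin = 0.6,
                          geometry = geomTest, canvasDeg = c(0.3, 0.3))
    a <- renderStimulus(sp)
    b <- renderStimulus(sp)
    expect_identical(intensities(a), intensities(b))
})

test_that("an unflanked letter image contains only the target glyph", {
    sp <- letterArraySpec(flankerCount = 0, canvasDeg = c(2, 2))
    img <- renderStimulus(sp)
    lv <- sort(unique(as.vector(intensities(img))))
    expect_identical(lv, c(0.5, 1))        # ink and background only
    tb <- targetBox(img)
    outside <- intensities(img)
    outside[tb[1]:tb[2], tb[3]:tb[4]] <- 1
    expect_true(all(outside == 1))         # no ink outside the target box
})

test_that("letter flankers add exactly four glyphs' worth of ink", {
    sp0 <- letterArraySpec(flankerCount = 0, flankerLetter = "r",
                           canvasDeg = c(3, 3))
    sp4 <- letterArraySpec(flankerCount = 4, flankerLetter = "r",
                           canvasDeg = c(3, 3))
    ink <- function(s) sum(intensities(renderStimulus(s)) != 1)
    expect_identical(ink(sp4), 5L * ink(sp0))
})

test_that("Landolt rasters obey the annulus geometry", {
    gapped <- landoltC(50)
    gapless <- landoltC(50, gapless = TRUE)
    expect_lt(sum(gapped), sum(gapless))
    # analytic annulus-minus-gap area oracle (10% raster tolerance)
    R <- 25; r <- 15; stroke <- 10
    analytic <- pi * (R^2 - r^2) - stroke * (R - r)
    expect_lt(abs(sum(gapped) - analytic) / analytic, 0.1)
    # right-angle gap rotations preserve ink area exactly on the grid
    expect_identical(sum(landoltC(50, 0)), sum(landoltC(50, 90)))
    expect_identical(sum(landoltC(50, 90)), sum(landoltC(50, 180)))
    expect_error(landoltC(4), "resolution")
})

test_that("bar-flanked Landolt stimuli keep a clear gap at close distances", {
    # at ~23.7 px/arcmin a 3-arcmin flank gap spans many background pixels
    sp <- landoltBarsSpec(diameterArcmin = 6, flankDistanceArcmin = 3,
                          geometry = geomTest, canvasDeg = c(0.4, 0.4))
    img <- intensities(renderStimulus(sp))
    mid <- (nrow(img) + 1) / 2
    run <- rle(img[mid, ])
    # along the horizontal midline: bar, gap, C ring, ..., ring, gap, bar
    gaps <- run$lengths[run$values == 0.5]
    expect_gte(length(gaps), 2)
    expect_true(any(gaps >= 1))
})

test_that("vernier mirror symmetry and flanker-count / height scaling hold", {
    base <- function(dir, n = 0, hf = 1)
        vernierSpec(offsetDirection = dir, flankerCount = n,
                    heightFactor = hf, canvasDeg = c(5, 2.5))
    L <- intensities(renderStimulus(base("left")))
    R <- intensities(renderStimulus(base("right")))
    expect_identical(L, R[, ncol(R):1])
    ink <- function(n, hf = 1)
        sum(intensities(renderStimulus(base("left", n, hf))) == 0)
    counts <- vapply(c(2, 4, 8, 16), ink, numeric(1))
    expect_true(all(diff(counts) > 0))
    # doubling flanker height exactly doubles flanker ink
    flankInk1 <- ink(2, 1) - ink(0, 1)
    flankInk2 <- ink(2, 2) - ink(0, 2)
    expect_identical(flankInk2, 2L * flankInk1)
    expect_error(vernierSpec(flankerCount = 3), "even")
    expect_error(renderStimulus(
        vernierSpec(flankerCount = 2, spacingDeg = 0.01,
                    canvasDeg = c(5, 2.5))), "overlap")
})

test_that("concentric flankers nest without fusing and add ink monotonically", {
    dark <- function(n, gapless = FALSE)
        sum(intensities(renderStimulus(concentricCsSpec(
            flankerCount = n, gapless = gapless,
            canvasDeg = c(6, 6)))) == 0)
    expect_gt(dark(5), dark(1))
    expect_gt(dark(1), dark(0))
    expect_gt(dark(1, gapless = TRUE), dark(1))
    expect_error(concentricCsSpec(flankerCount = 6), "between 0 and 5")
})

test_that("stimuli exceeding the canvas are rejected", {
    sp <- concentricCsSpec(flankerCount = 5, spacingDeg = 0.5,
                           canvasDeg = c(2, 2))
    expect_error(renderStimulus(sp), "canvas")
})
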