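test_that("pixels per degree matches the tabulated viewing configurations", {
    # (distance cm, expected px/deg) for the four distinct conditions
    cases <- rbind(c(75.00, 46.4177),
                   c(2300.00, 1423.4770),
                   c(58.00, 35.8963),
                   c(55.88, 34.5843))
    for (i in seq_len(nrow(cases))) {
        got <- pixelsPerDegree(cases[i, 1], pitch = 0.282)
        expect_lt(abs(got - cases[i, 2]) / cases[i, 2], 1e-4)
    }
    expect_equal(pixelsPerDegree(viewingGeometry(75, 0.282)),
                 pixelsPerDegree(75, 0.282))
})

test_that("pixels per degree is nearly linear in distance and validates inputs", {
    for (D in c(50, 75, 500, 2300)) {
        ratio <- pixelsPerDegree(2 * D) / pixelsPerDegree(D)
        expect_lt(abs(ratio - 2), 2e-6)
    }
    d <- seq(20, 3000, length.out = 25)
    expect_true(all(diff(pixelsPerDegree(d)) > 0))
    expect_error(pixelsPerDegree(0), "positive")
    expect_error(pixelsPerDegree(75, pitch = -1), "positive")
    expect_error(viewingGeometry(-5), "positive")
})

test_that("dendritic field diameter follows the anatomical power law", {
    expect_equal(dendriticDiameter(1), 8.64)
    expect_equal(dendriticDiameter(0), 0)
    # independent evaluation through logs
    oracle <- exp(log(8.64) + 1.04 * log(2))
    expect_equal(dendriticDiameter(2), oracle, tolerance = 1e-12)
    expect_equal(round(dendriticDiameter(2), 3), 17.766)
    x <- seq(0.1, 16, length.out = 40)
    expect_true(all(diff(dendriticDiameter(x)) > 0))
    expect_error(dendriticDiameter(-1), "nonnegative")
})

test_that("receptive-field profiles honor the explicit-sigma (reproduction) mode", {
    p <- rfProfile(5, sigmaPx = 10.8793, K = 5)
    expect_identical(sigmaF(p), 10.8793)
    expect_equal(sigmaB(p), 54.3965)
    expect_identical(sigmaB(p), 5 * sigmaF(p))   # ratio invariant is exact
    p1 <- rfProfile(0, sigmaPx = 0.5541, K = 1)
    expect_identical(sigmaB(p1), 0.5541)
})

test_that("model-mode sigma grows with eccentricity and requires a geometry", {
    g <- viewingGeometry(57)
    s5 <- sigmaF(rfProfile(5, geometry = g))
    s10 <- sigmaF(rfProfile(10, geometry = g))
    expect_gt(s10, s5)
    expect_gt(s5, 0)
    expect_error(rfProfile(5), "sigmaPx")
    expect_error(rfProfile(-1, geometry = g), "nonnegative")
})

test_that("surround-to-center ratio below 1 is rejected", {
    expect_error(rfProfile(5, sigmaPx = 2, K = 0.5), "must be")
})
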