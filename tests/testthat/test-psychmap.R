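test_that("target-alone width follows the 10%-change / 1%-rate calibration", {
    # sigmaT = 0.1 * muT / sqrt(-2 log(0.01)), frozen to 4 significant figures
    expect_equal(signif(sigmaTau(0.020228), 4), 0.0006665)
    expect_equal(signif(sigmaTau(0.016057), 4), 0.0005291)
    expect_identical(sigmaTau(0), 0)
    expect_error(sigmaTau(-1), "nonnegative")
})

test_that("flanked-width ratio reproduces tabulated values and rejects kPhi < 1", {
    expect_lt(abs(kPhiFrom(0.032, 0.016057) - 9.9290) / 9.9290, 1e-3)
    expect_lt(abs(kPhiFrom(0.080, 0.020228) - 29.5499) / 29.5499, 1e-3)
    mu <- 0.02
    expect_equal(kPhiFrom(1.1 * mu, mu), 1)
    expect_error(kPhiFrom(1.05 * mu, mu), "model violation")
    expect_error(kPhiFrom(0.03, 0), "positive")
})

test_that("assembled models reproduce tabulated kPhi and the sigmaPhi identity", {
    m1 <- mappingModel(0.011640, 0.030)
    expect_lt(abs(kPhi(m1) - 15.7745) / 15.7745, 1e-3)
    m5 <- mappingModel(0.011640, 0.080)
    expect_lt(abs(kPhi(m5) - 58.7319) / 58.7319, 1e-3)
    mu <- 0.012
    mEq <- mappingModel(mu, 1.1 * mu)
    expect_equal(mEq@sigmaPhi, sigmaT(mEq))
    # eAlpha below muT is legitimate (the squared forms ignore sign)
    mBelow <- mappingModel(0.012, 0.006)
    expect_equal(kPhi(mBelow), 5)
})

test_that("proportion correct has the right anchors, ceiling and shape", {
    m <- mappingModel(0.016057, 0.032)
    expect_equal(proportionCorrect(muT(m), m), 0.85)
    # at eAlpha the flanked Gaussian is 0.01 by construction and the
    # target-alone Gaussian is negligible at this kPhi
    expect_equal(proportionCorrect(eAlpha(m), m), 0.85 * 0.99,
                 tolerance = 1e-4 / 0.8415)
    expect_equal(proportionCorrect(100, m), 0.85, tolerance = 1e-12)
    # bounded in [0, ceiling] and symmetric about muT
    C <- seq(0, 0.1, length.out = 2001)
    p <- proportionCorrect(C, m)
    expect_true(all(p >= 0 & p <= 0.85 + 1e-12))
    d <- 0.004
    expect_equal(proportionCorrect(muT(m) + d, m),
                 proportionCorrect(muT(m) - d, m), tolerance = 1e-12)
    # one local minimum on each side of muT (unimodal dip per side)
    side <- p[C > muT(m)]
    sgn <- sign(diff(side))
    expect_equal(sum(diff(sgn[sgn != 0]) != 0), 1)
})

test_that("the flanked Gaussian equals the calibration rate at eAlpha exactly", {
    for (pars in list(c(0.020228, 0.080), c(0.016057, 0.032),
                      c(0.011640, 0.030))) {
        m <- mappingModel(pars[1], pars[2])
        gPhi <- exp(-(eAlpha(m) - muT(m))^2 / (2 * m@kPhi^2 * sigmaT(m)^2))
        expect_equal(gPhi, 0.01, tolerance = 1e-12)
    }
})

test_that("model serialization carries the derived columns", {
    df <- as.data.frame(mappingModel(0.012, 0.025))
    expect_identical(names(df),
                     c("mu_t", "sigma_t", "E_alpha", "k_phi", "ceiling"))
    expect_equal(df$k_phi, kPhiFrom(0.025, 0.012))
})
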