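test_that("gaussian masks are normalized, radially symmetric and peak-scaled", {
    m <- gaussianMask(1, 4)
    expect_lt(abs(sum(m) - 1), 2e-4)   # mass outside the 4-sigma support
    # reflection / transpose symmetry at a few offsets
    c0 <- 5
    expect_identical(m[c0 + 2, c0 + 1], m[c0 - 2, c0 + 1])
    expect_identical(m[c0 + 2, c0 + 1], m[c0 + 1, c0 + 2])
    m2 <- gaussianMask(2, 8)
    expect_lt(m2[9, 9], m[5, 5])       # peak ~ sigma^-2
    expect_error(gaussianMask(2, 4), "supportRadius")
    expect_error(gaussianMask(-1, 4), "positive")
})

test_that("difference-of-Gaussians kernel is zero-sum and vanishes when K = 1", {
    k <- dogKernel(rfProfile(0, sigmaPx = 2, K = 5))
    expect_lt(abs(sum(kernelWeights(k))), 1e-12)
    expect_true(k@zeroSumAdjusted)
    expect_identical(nrow(kernelWeights(k)), 2L * supportRadius(k) + 1L)
    k1 <- dogKernel(rfProfile(0, sigmaPx = 2, K = 1))
    expect_true(all(kernelWeights(k1) == 0))
})

test_that("kernel spectrum is bandpass: zero DC, one radial peak, closed-form match", {
    for (K in c(2, 5, 10)) {
        k <- dogKernel(rfProfile(0, sigmaPx = 2, K = K))
        sp <- kernelSpectrum(k)
        expect_lt(sp$axial[1], 1e-12)                   # DC gain
        err <- max(abs(sp$axial - sp$closedForm))
        expect_lt(err, 1e-6)
        # unimodal along the radial frequency axis: rises to a single
        # maximum then decays
        ax <- sp$axial
        pk <- which.max(ax)
        expect_gt(pk, 1)
        expect_lt(pk, length(ax))
        expect_true(all(diff(ax[1:pk]) > 0))
        expect_true(all(diff(ax[pk:length(ax)]) < 0))
    }
})

test_that("convolution annihilates constants, is linear, and reproduces impulses", {
    k <- smallKernel()
    const <- stimulusImage(matrix(0.7, 20, 20), backgroundLevel = 0.7)
    expect_true(all(convolveMap(const, k) == 0))
    # linearity about the background level
    img <- randomImage(20, seed = 7, bg = 0.5)
    a <- 0.37
    scaled <- stimulusImage(a * (intensities(img) - 0.5) + 0.5,
                            backgroundLevel = 0.5)
    expect_equal(convolveMap(scaled, k), a * convolveMap(img, k),
                 tolerance = 1e-12)
    # impulse response: single bright pixel reproduces the kernel
    n <- 2L * supportRadius(k) + 21L
    im <- matrix(0.5, n, n)
    ctr <- (n + 1L) / 2L
    im[ctr, ctr] <- 1
    resp <- convolveMap(stimulusImage(im, backgroundLevel = 0.5), k)
    half <- supportRadius(k)
    got <- resp[(ctr - half):(ctr + half), (ctr - half):(ctr + half)]
    expect_equal(got, 0.5 * kernelWeights(k), tolerance = 1e-12,
                 ignore_attr = TRUE)
})

test_that("spatial and frequency-domain convolution agree", {
    k <- smallKernel(sigmaF = 1.2, K = 5)
    img <- randomImage(40, seed = 11)
    a <- convolveMap(img, k, method = "spatial")
    b <- convolveMap(img, k, method = "fft")
    expect_lt(max(abs(a - b)), 1e-8)
})

test_that("contrast energy is a semi-norm with the advertised conventions", {
    k <- smallKernel()
    img <- randomImage(16, seed = 3)
    v <- energyValue(contrastEnergy(img, k))
    expect_gte(v, 0)
    vs <- energyValue(contrastEnergy(img, k, convention = "sum-square"))
    expect_equal(vs, v * sqrt(length(intensities(img))), tolerance = 1e-12)
    # constant at its own background level maps to exactly zero
    const <- stimulusImage(matrix(0.25, 16, 16), backgroundLevel = 0.25)
    expect_identical(energyValue(contrastEnergy(const, k)), 0)
})

test_that("RMS contrast matches the direct formula and the degenerate mask", {
    two <- matrix(c(0, 1), 1, 2)
    expect_equal(energyValue(rmsContrast(two)), 0.5)
    expect_identical(energyValue(rmsContrast(matrix(0.4, 5, 5))), 0)
    set.seed(42)
    for (i in 1:5) {
        m <- matrix(runif(64), 8, 8)
        oracle <- sqrt(sum((m - sum(m) / 64)^2) / 64)   # textbook RMS
        expect_equal(energyValue(rmsContrast(m)), oracle, tolerance = 1e-12)
        expect_equal(energyValue(degenerateContrastEnergy(m)), oracle,
                     tolerance = 1e-12)
    }
})

test_that("the radial metric separates light-flanked steps more than dark-flanked", {
    # three adjacent pixels on a mid-gray field; the center steps by the
    # same amount in both images, so Euclidean distances are equal, but
    # the center-surround metric weights the step by its flanks
    k <- smallKernel(sigmaF = 1.5, K = 5)
    strip <- function(flank, center) {
        im <- matrix(0.5, 15, 15)
        im[8, 7] <- flank; im[8, 9] <- flank; im[8, 8] <- center
        stimulusImage(im, backgroundLevel = 0.5)
    }
    CE <- function(im) energyValue(contrastEnergy(im, k))
    dark <- abs(CE(strip(0, 0.6)) - CE(strip(0, 0.5)))
    light <- abs(CE(strip(1, 0.6)) - CE(strip(1, 0.5)))
    euclid <- function(a, b) sqrt(sum((intensities(a) - intensities(b))^2))
    expect_equal(euclid(strip(0, 0.6), strip(0, 0.5)),
                 euclid(strip(1, 0.6), strip(1, 0.5)))
    expect_gt(light, dark)
})
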