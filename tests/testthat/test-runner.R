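test_that("all shipped experiment configurations load and validate", {
    ids <- experimentIds()
    expect_setequal(ids, c("HE", "KA", "PA1", "PA5", "PL", "PS"))
    for (id in ids) {
        cfg <- experimentConfig(id)
        expect_s4_class(cfg, "ExperimentConfig")
        expect_gt(length(cfg@sweep), 0)
    }
    expect_error(experimentConfig("XX"), "unknown experiment")
})

test_that("experiment runs are deterministic and respect the ceiling", {
    r1 <- runExperiment(experimentConfig("PA1"))
    r2 <- runExperiment(experimentConfig("PA1"))
    expect_identical(r1, r2)
    for (id in c("HE", "KA", "PA1", "PA5", "PL", "PS")) {
        p <- cachedRun(id)$proportion_correct
        expect_true(all(p >= 0 & p <= 0.85 + 1e-12))
    }
})

test_that("the anchored target-alone condition predicts the performance ceiling", {
    he <- cachedRun("HE")
    alone <- he[he$flanker_count == 0, ]
    expect_equal(alone$contrast_energy, rep(0.020228, nrow(alone)),
                 tolerance = 1e-12)
    expect_equal(alone$proportion_correct, rep(0.85, nrow(alone)),
                 tolerance = 1e-12)
})

test_that("derived-column recomputation flags the known PL/PS inconsistency", {
    tab <- suppressMessages(reproduceTable1())
    expect_true(all(tab$consistent[tab$id %in% c("HE", "KA", "PA1", "PA5")]))
    expect_false(any(tab$consistent[tab$id %in% c("PL", "PS")]))
    expect_true(all(tab$consistent_exchanged))
    tabEx <- reproduceTable1(exchangePLPS = TRUE)
    expect_true(all(tabEx$consistent))
})

test_that("RMS contrast rises with flanker count and with ring spacing", {
    he <- rmsConfoundReport(experimentConfig("HE"))
    sub <- he[he$height_factor == 1 & he$flanker_count > 0, ]
    sub <- sub[order(sub$flanker_count), ]
    expect_true(all(diff(sub$rms_contrast) > 0))
    pa <- rmsConfoundReport(experimentConfig("PA5"))
    sub <- pa[!pa$gapless, ]
    sub <- sub[order(sub$spacing_deg), ]
    expect_true(all(diff(sub$rms_contrast) > 0))
    # no flankers: the report reduces to the target-alone RMS
    cfg <- experimentConfig("PA1")
    cfg@sweep <- list(flanker_count = c(0), gapless = FALSE,
                      spacing_deg = 0.35)
    r0 <- rmsConfoundReport(cfg)
    alone <- renderStimulus(concentricCsSpec(
        flankerCount = 0, spacingDeg = 0.35, diameterDeg = 1.25,
        geometry = viewingGeometry(58, 0.282), eccentricity = 10,
        canvasDeg = c(7, 7)))
    expect_equal(r0$rms_contrast, energyValue(rmsContrast(alone)),
                 tolerance = 1e-12)
})
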