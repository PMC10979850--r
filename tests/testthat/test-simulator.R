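test_that("molecule conservation holds on every simulated dataset", {
    for (tb in c(0.3, 0.5, 0.65, 0.8)) {
        cfg <- simConfig(nTranscripts = 800L, totalMolecules = 4e4,
                         targetBeta = tb, depthPerFraction = 1e5,
                         seed = round(100 * tb))
        sim <- simulateDataset(cfg)
        tr <- sim$truth
        expect_identical(tr@mN + tr@mC, tr@mW)
        expect_true(all(tr@mC >= 0 & tr@mN >= 0))
        expect_equal(realizedBeta(tr),
                     sum(tr@mC * tr@lengths) / sum(tr@mW * tr@lengths))
    }
})

test_that("split calibration lands within 0.005 of the target volume fraction", {
    for (tb in c(0.5, 0.6, 0.7, 0.8)) {
        cfg <- simConfig(nTranscripts = 2000L, totalMolecules = 1e5,
                         targetBeta = tb, seed = 17L)
        wc <- simulateWholeCell(cfg)
        tr <- splitFractions(wc$mW, wc$lengths, cfg)
        expect_lt(abs(realizedBeta(tr) - tb), 0.005)
        ## per-transcript cytosolic fractions are spread, not pinned to
        ## the boundaries (the split must emulate graded localization)
        tf <- trueCytoFraction(tr)
        tf <- tf[!is.na(tf)]
        expect_gt(mean(tf > 0.05 & tf < 0.95), 0.3)
    }
})

test_that("explicitly forced splits reproduce the worked volume fractions", {
    ## balanced cell state: equal RNA volume in nucleus and cytosol
    t1 <- SimTruth(mW = c(100, 200), mC = c(60, 90), lengths = c(1000, 1000))
    expect_equal(realizedBeta(t1), 0.5)
    ## 80% of the RNA volume in the cytosol
    t2 <- SimTruth(mW = c(100, 200), mC = c(60, 180), lengths = c(1000, 1000))
    expect_equal(realizedBeta(t2), 0.8)
    expect_equal(trueCytoFraction(t2), c(0.6, 0.9))
    expect_error(SimTruth(mW = c(1, 1), mC = c(2, 0), lengths = c(1, 1)),
                 "exceed")
})

test_that("whole-cell expression is heavy-tailed with the configured exponent", {
    cfg <- simConfig(nTranscripts = 10000L, totalMolecules = 5e5, seed = 4L)
    wc <- simulateWholeCell(cfg)
    expect_equal(sum(wc$mW), 5e5)
    srt <- sort(wc$mW, decreasing = TRUE)
    fit <- stats::lm(log(srt[1:100]) ~ log(1:100))
    expect_lt(abs(unname(coef(fit)[2]) + 1), 0.15)
    ## single transcript gets everything
    one <- simulateWholeCell(simConfig(nTranscripts = 1L,
                                       totalMolecules = 100, seed = 1L))
    expect_equal(one$mW, 100)
    ## exponent 0 is a uniform allocation: no rank trend
    flat <- simulateWholeCell(simConfig(nTranscripts = 2000L,
                                        totalMolecules = 1e6,
                                        expressionTailExponent = 0,
                                        seed = 2L))
    expect_lt(max(flat$mW) / min(flat$mW), 1.5)  # no heavy tail remains
})

test_that("expected-mode counts equal the length-weighted formula", {
    got <- simulateCounts(c(60, 180), c(1000, 1000), 1000, mode = "expected")
    expect_equal(got, c(250, 750))
    expect_error(simulateCounts(c(0, 0), c(1, 1), 10, "expected"),
                 "domain error")
})

test_that("multinomial counts conserve depth and track expectations", {
    set.seed(31)
    m <- rpois(500, 10); l <- runif(500, 200, 5000)
    cnt <- simulateCounts(m, l, 1e6, mode = "multinomial", seed = 77L)
    expect_equal(sum(cnt), 1e6)
    exp_ <- expectedFractionCounts(m, l, 1e6)
    p <- m * l / sum(m * l)
    sdv <- sqrt(1e6 * p * (1 - p))
    expect_true(all(abs(cnt - exp_) <= 5 * pmax(sdv, 1)))
})

test_that("identical configurations give byte-identical datasets", {
    cfg <- simConfig(nTranscripts = 300L, totalMolecules = 2e4,
                     targetBeta = 0.7, depthPerFraction = 5e4, seed = 12L)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    s1 <- simulateDataset(cfg); s2 <- simulateDataset(cfg)
    expect_identical(s1$truth@mC, s2$truth@mC)
    expect_identical(quantData(s1$samples$whole)$expected_count,
                     quantData(s2$samples$whole)$expected_count)
    emitDataset(s1$truth, cfg, d1)
    emitDataset(s2$truth, cfg, d2)
    for (f in list.files(d1))
        expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                         readBin(file.path(d2, f), "raw", 1e6))
})

test_that("emitted datasets round-trip through the quantification reader", {
    cfg <- simConfig(nTranscripts = 200L, totalMolecules = 1e4,
                     targetBeta = 0.6, depthPerFraction = 3e4, seed = 6L)
    sim <- simulateDataset(cfg)
    d <- withr::local_tempdir()
    paths <- emitDataset(sim$truth, cfg, d)
    for (f in c("whole", "nuclear", "cytosolic")) {
        back <- readQuantTable(paths[[f]], fraction = f)
        orig <- quantData(sim$samples[[f]])
        got <- quantData(back)
        expect_identical(got$transcript_id, orig$transcript_id)
        expect_identical(got$expected_count, orig$expected_count)
    }
    ## truth table reproduces the realized beta from its own columns
    tr <- readTruthTable(paths[["truth"]])
    expect_equal(realizedBeta(tr), realizedBeta(sim$truth), tolerance = 1e-12)
    expect_identical(tr@mC, sim$truth@mC)
})

test_that("degenerate simulator inputs are rejected", {
    expect_error(simConfig(targetBeta = 0), "targetBeta")
    expect_error(simConfig(nTranscripts = 0L), "nTranscripts")
    cfg <- simConfig(nTranscripts = 5L, totalMolecules = 10)
    expect_error(splitFractions(rep(0, 5), rep(1000, 5), cfg),
                 "at least one molecule")
})

test_that("binomial-thinning split also calibrates to the target", {
    cfg <- simConfig(nTranscripts = 2000L, totalMolecules = 1e5,
                     targetBeta = 0.7, splitMethod = "binomial", seed = 19L)
    wc <- simulateWholeCell(cfg)
    tr <- splitFractions(wc$mW, wc$lengths, cfg)
    expect_lt(abs(realizedBeta(tr) - 0.7), 0.005)
    expect_identical(tr@mN + tr@mC, tr@mW)
})

test_that("noiseless pipeline recovers beta and the exact localization", {
    cfg <- simConfig(nTranscripts = 600L, totalMolecules = 5e4,
                     targetBeta = 0.75, depthPerFraction = 2e5,
                     countMode = "expected", seed = 23L)
    sim <- simulateDataset(cfg)
    ret <- filterExpression(sim$samples$whole, sim$samples$nuclear,
                            sim$samples$cytosolic)
    tri <- buildTriplet(sim$samples$whole, sim$samples$nuclear,
                        sim$samples$cytosolic, ret)
    fit <- optimizeMap(tri)
    expect_lt(abs(fit$beta - realizedBeta(sim$truth)), 1e-3)
    ## with the realized beta, LI equals the true molecule fraction
    li <- localizationIndex(fpkmNuclear(tri), fpkmCytosolic(tri),
                            realizedBeta(sim$truth))
    tf <- trueCytoFraction(sim$truth)[match(rownames(assay(tri, "fpkm")),
                                            sim$truth@transcriptIds)]
    expect_lt(max(abs(li - tf)), 1e-9)
    ## naive index underestimates localization when beta > 0.5
    naive <- naiveLocalizationIndex(fpkmNuclear(tri), fpkmCytosolic(tri))
    expect_lt(median(naive - tf), -0.05)
})
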