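test_that("the two-gene conceptual example reproduces the published indices", {
    fx <- twoGeneSetup()
    ## cell type 2: nuclear library [40, 20] molecules, cytosolic [60, 180]
    rn <- expectedFractionCounts(fx$type2$nuclear, fx$lengths, fx$depth)
    rc <- expectedFractionCounts(fx$type2$cytosolic, fx$lengths, fx$depth)
    expect_equal(rn, c(A = 666.67, B = 333.33), tolerance = 1e-4)
    expect_equal(rc, c(A = 250, B = 750))
    expect_equal(round(naiveLocalizationIndex(rn[["A"]], rc[["A"]]), 2), 0.27)
    expect_equal(round(naiveLocalizationIndex(rn[["B"]], rc[["B"]]), 2), 0.69)
    expect_equal(localizationIndex(rn[["A"]], rc[["A"]], beta = 0.8), 0.6)
    expect_equal(localizationIndex(rn[["B"]], rc[["B"]], beta = 0.8), 0.9)
    ## cell type 1 is volume-balanced: the naive index is already correct
    rn1 <- expectedFractionCounts(fx$type1$nuclear, fx$lengths, fx$depth)
    rc1 <- expectedFractionCounts(fx$type1$cytosolic, fx$lengths, fx$depth)
    expect_equal(round(naiveLocalizationIndex(rn1[["B"]], rc1[["B"]]), 2), 0.45)
})

test_that("expected counts are length-weighted and conserve depth", {
    expect_equal(expectedFractionCounts(5, 300, 1234), 1234)
    expect_equal(expectedFractionCounts(c(10, 10), c(1, 3), 1000), c(250, 750))
    set.seed(8)
    m <- rpois(20, 5); l <- runif(20, 200, 2000)
    expect_equal(sum(expectedFractionCounts(m, l, 5e4)), 5e4)
    expect_error(expectedFractionCounts(c(0, 0), c(1, 1), 10), "domain error")
})

test_that("localization index properties hold on random inputs", {
    set.seed(99)
    for (i in 1:50) {
        fn <- rexp(1, 0.1); fc <- rexp(1, 0.1); b <- runif(1, 0.05, 0.95)
        ## beta = 0.5 reduces to the naive index
        expect_equal(localizationIndex(fn, fc, 0.5),
                     naiveLocalizationIndex(fn, fc))
        ## invariance to joint rescaling of the fraction FPKMs
        k <- runif(1, 0.1, 50)
        expect_equal(localizationIndex(k * fn, k * fc, b),
                     localizationIndex(fn, fc, b))
        ## complementarity: swap fractions and beta
        expect_equal(localizationIndex(fn, fc, b) +
                     localizationIndex(fc, fn, 1 - b), 1)
        ## strictly increasing in beta when both FPKMs are positive
        expect_gt(localizationIndex(fn, fc, min(b + 0.02, 0.99)),
                  localizationIndex(fn, fc, b))
    }
    expect_equal(localizationIndex(5, 5, 0.5), 0.5)
    expect_equal(localizationIndex(3, 0, 0.7), 0)
})

test_that("undefined indices are signaled, not silently zeroed", {
    expect_warning(v <- localizationIndex(c(0, 2), c(0, 2), 0.5), "undefined")
    expect_true(is.na(v[1]) && v[2] == 0.5)
    expect_error(localizationIndex(1, 1, 1.5), "beta")
})

test_that("compartment classification uses the published thresholds", {
    expect_identical(classifyLocalization(c(0.39, 0.61, 0.5, NA, 0.4, 0.6)),
                     c("nuclear", "cytosolic", "intermediate", "undefined",
                       "intermediate", "intermediate"))
})

test_that("localization tables label every transcript of a triplet", {
    tri <- matchedTriplet(c(5, 5, 5), c(9, 1, 5), c(1, 9, 5),
                          c("nuc", "cyt", "mid"))
    tab <- localizationTable(tri, beta = 0.5, sampleId = "demo")
    r <- locRecords(tab)
    expect_identical(setNames(r$label, r$transcript_id),
                     c(nuc = "nuclear", cyt = "cytosolic", mid = "intermediate"))
    expect_equal(r$li, r$naive_li)  # beta = 0.5
    expect_equal(betaUsed(tab), 0.5)
})

test_that("consistency summary bins by presence and counts unanimity", {
    tabs <- list(
        c1 = locTableFromLI(c(A = 0.7, B = 0.7, C = 0.2)),
        c2 = locTableFromLI(c(A = 0.8, B = 0.3, C = 0.1)),
        c3 = locTableFromLI(c(A = 0.9, B = 0.8))
    )
    cs <- consistencySummary(tabs)
    k3 <- cs[cs$k == 3, ]
    expect_equal(k3$n_expressed, 2)          # A and B in all three
    expect_equal(k3$n_always_cytosolic, 1)   # A only (B dips to 0.3)
    expect_equal(k3$n_always_nuclear, 0)
    k2 <- cs[cs$k == 2, ]
    expect_equal(k2$n_always_nuclear, 1)     # C: 0.2 and 0.1
})

test_that("a constructed 72%-unanimous bin is reported exactly", {
    ## 100 transcripts present in all 10 conditions; 72 always >= 0.5
    K <- 10; n <- 100
    ids <- sprintf("t%03d", 1:n)
    tabs <- lapply(1:K, function(k) {
        li <- c(rep(0.8, 72), rep(NA_real_, 0),
                ifelse(seq_len(n - 72) %% 2 == 0, 0.3, 0.6))
        ## non-unanimous tail: alternate low/high across conditions
        li[73:n] <- ifelse((seq(73, n) + k) %% 2 == 0, 0.3, 0.7)
        locTableFromLI(setNames(li, ids))
    })
    cs <- consistencySummary(tabs)
    row <- cs[cs$k == K, ]
    expect_equal(row$n_expressed, 100)
    expect_equal(row$n_always_cytosolic, 72)
    expect_equal(row$prop_always_cytosolic, 0.72)
})

test_that("threshold ties are tallied in both camps and reported", {
    tabs <- list(locTableFromLI(c(A = 0.5)), locTableFromLI(c(A = 0.5)))
    cs <- consistencySummary(tabs)
    row <- cs[cs$k == 2, ]
    expect_equal(row$n_always_cytosolic, 1)
    expect_equal(row$n_always_nuclear, 1)
    expect_equal(row$n_ties, 1)
})

test_that("strong localizers require presence in enough conditions", {
    mk <- function(...) locTableFromLI(c(...))
    tabs <- list(
        mk(A = 0.95, B = 0.92, C = 0.99, D = 0.2),
        mk(A = 0.92, B = 0.89, C = 0.95, D = 0.1),
        mk(A = 0.99, B = 0.95, C = 0.97, D = 0.25),
        mk(A = 0.96, B = 0.93, C = 0.98, D = 0.28),
        mk(A = 0.94, B = 0.95, C = 0.91, D = 0.22),
        mk(A = 0.98, B = 0.97, D = 0.15)
    )
    got <- strongLocalizers(tabs, minConditions = 5)
    expect_setequal(got$cytosolic, c("A", "C"))  # B dips to 0.89 once
    expect_setequal(got$nuclear, "D")            # all below 0.3
    ## C is only present in 5 conditions: dropped at a stricter minimum
    gotC <- strongLocalizers(tabs, minConditions = 6)
    expect_setequal(gotC$cytosolic, "A")
})

test_that("enrichment ratios and hypergeometric tails are exact", {
    g <- rep(c(TRUE, FALSE), c(100, 900))
    s <- rep(c(TRUE, FALSE), c(20, 80))
    res <- enrichmentRatio(s, g)
    expect_equal(res$ratio, 2)
    ## identical sets: no enrichment, certain tail
    res2 <- enrichmentRatio(g, g)
    expect_equal(res2$ratio, 1)
    expect_equal(res2$p_value, 1)
    ## small population: match exhaustive subset enumeration
    gl <- rep(c(TRUE, FALSE), c(4, 6))
    sp <- rep(c(TRUE, FALSE), c(3, 2))
    res3 <- enrichmentRatio(sp, gl)
    expect_equal(res3$p_value, enumTailProb(gl, 5, 3), tolerance = 1e-12)
    expect_error(enrichmentRatio(logical(), gl), "empty")
})

test_that("hypergeometric tails match enumeration across random small cases", {
    set.seed(123)
    for (i in 1:20) {
        N <- sample(5:15, 1)
        gl <- sample(c(TRUE, FALSE), N, replace = TRUE)
        nS <- sample(1:N, 1)
        x <- sum(gl[sample(N, nS)])
        sp <- rep(c(TRUE, FALSE), c(x, nS - x))
        expect_equal(enrichmentRatio(sp, gl)$p_value,
                     enumTailProb(gl, nS, x), tolerance = 1e-12)
    }
})
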