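test_that("quantification tables are read with depth derived from counts", {
    p <- withr::local_tempfile(fileext = ".tsv")
    writeQuantFixture(p, c("A", "B", "C"), c(1000, 2000, 500), c(10, 30, 60))
    fs <- readQuantTable(p, fraction = "whole")
    expect_s4_class(fs, "FractionSample")
    expect_equal(sampleDepth(fs), 100)
    expect_equal(nrow(quantData(fs)), 3L)
    expect_equal(quantData(fs)$expected_count, c(10, 30, 60))
})

test_that("reader accepts case-insensitive RSEM-style aliases", {
    p <- withr::local_tempfile(fileext = ".tsv")
    df <- data.frame(Transcript_ID = c("A", "B"), Gene_ID = c("g1", "g1"),
                     Length = c(100, 200), Effective_Length = c(80, 180),
                     Expected_Count = c(5, 5), TPM = 0, FPKM = 0)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    fs <- readQuantTable(p, fraction = "nuclear")
    expect_equal(quantData(fs)$effective_length, c(80, 180))
})

test_that("reader rejects malformed tables", {
    p <- withr::local_tempfile(fileext = ".tsv")
    writeQuantFixture(p, c("A", "B"), c(100, 200), c(1, 2),
                      countsName = "some_other_column")
    expect_error(readQuantTable(p, "whole"), "missing required column")

    p2 <- withr::local_tempfile(fileext = ".tsv")
    writeQuantFixture(p2, c("A", "A"), c(100, 200), c(1, 2))
    expect_error(readQuantTable(p2, "whole"), "duplicate transcript_id")

    expect_error(readQuantTable(tempfile(), "whole"), "not found")
})

test_that("an empty table yields zero records that fail downstream", {
    p <- withr::local_tempfile(fileext = ".tsv")
    writeQuantFixture(p, character(), numeric(), numeric())
    fs <- readQuantTable(p, "whole")
    expect_equal(nrow(quantData(fs)), 0L)
    expect_true(is.na(sampleDepth(fs)))
    expect_error(buildTriplet(fs, fs, fs, retained = character()), "data error")
})

test_that("FPKM and CPM follow their definitions", {
    expect_equal(computeFPKM(10, 1000, 1e6), 10)
    expect_equal(computeFPKM(0, 500, 1e6), 0)
    expect_equal(computeFPKM(50, 2000, 5e6), 5)
    expect_equal(computeCPM(c(1, 100, 3), 1e6), c(1, 100, 3))
    expect_equal(computeCPM(3, 3e6), 1)
    expect_error(computeFPKM(1, 0, 1e6), "length")
    expect_error(computeCPM(1, 0), "depth")
})

test_that("FPKM and CPM are invariant to joint count/depth rescaling", {
    set.seed(11)
    counts <- rpois(50, 20); lens <- runif(50, 200, 5000); depth <- sum(counts)
    for (k in c(2, 10)) {
        expect_equal(computeFPKM(k * counts, lens, k * depth),
                     computeFPKM(counts, lens, depth))
        expect_equal(computeCPM(k * counts, k * depth),
                     computeCPM(counts, depth))
    }
})

test_that("expression filter implements the whole-AND-one-fraction rule", {
    ## per-sample depth 1e6 so CPM equals the raw count
    mk <- function(counts, fr) quickSample(counts, fr, depth = 1e6)
    w <- mk(c(A = 2, B = 0.5, C = 2, D = 0), "whole")
    n <- mk(c(A = 0, B = 10, C = 2, D = 5), "nuclear")
    c_ <- mk(c(A = 3, B = 10, C = 2, D = 5), "cytosolic")
    expect_setequal(filterExpression(w, n, c_), c("A", "C"))
    ## mitochondrial exclusion overrides expression
    expect_setequal(filterExpression(w, n, c_, excludedIds = "C"), "A")
    ## missing transcript counts as zero, not an error
    w2 <- mk(c(A = 2), "whole")
    expect_setequal(filterExpression(w2, n, c_), "A")
})

test_that("expression filter is idempotent", {
    set.seed(3)
    ids <- sprintf("t%02d", 1:40)
    mk <- function(fr) quickSample(setNames(rpois(40, 2), ids), fr, depth = 1e6)
    w <- mk("whole"); n <- mk("nuclear"); c_ <- mk("cytosolic")
    r1 <- filterExpression(w, n, c_)
    sub <- function(s) {
        q <- quantData(s)
        keep <- q$transcript_id %in% r1
        fractionSample(q$transcript_id[keep], q$length[keep],
                       q$expected_count[keep], fractionType(s),
                       depth = sampleDepth(s))
    }
    r2 <- filterExpression(sub(w), sub(n), sub(c_))
    expect_setequal(r2, r1)
})

test_that("triplets are aligned lexicographically with recomputed FPKM", {
    w <- quickSample(c(B = 40, A = 10, C = 50), "whole")
    n <- quickSample(c(A = 5, B = 20), "nuclear")
    c_ <- quickSample(c(B = 30, A = 10), "cytosolic")
    suppressWarnings(tri <- buildTriplet(w, n, c_, retained = c("B", "A")))
    m <- assay(tri, "fpkm")
    expect_identical(rownames(m), c("A", "B"))
    expect_equal(m["A", "whole"], computeFPKM(10, 1000, 100))
    expect_equal(m["B", "nuclear"], computeFPKM(20, 1000, 25))
    ## id missing from the whole-cell sample is an error
    expect_error(suppressWarnings(buildTriplet(w, n, c_, c("A", "Z"))),
                 "whole-cell")
    ## tiny triplets work but warn about identifiability
    expect_warning(buildTriplet(w, n, c_, "A"), "recommended minimum")
})

test_that("pseudo-bulk pooling is additive, order-invariant, label-safe", {
    s1 <- quickSample(c(A = 1, B = 2), "nuclear", replicateId = "cell1")
    s2 <- quickSample(c(A = 3, B = 0), "nuclear", replicateId = "cell2")
    pooled <- poolPseudobulk(list(s1, s2))
    q <- quantData(pooled)
    expect_equal(setNames(q$expected_count, q$transcript_id),
                 c(A = 4, B = 2))
    expect_equal(sampleDepth(pooled), 6)
    ## single input is the identity on counts and depth
    solo <- poolPseudobulk(list(s1))
    expect_equal(quantData(solo)$expected_count, quantData(s1)$expected_count)
    expect_equal(sampleDepth(solo), sampleDepth(s1))
    ## order invariance
    rev <- poolPseudobulk(list(s2, s1))
    expect_equal(quantData(rev)$expected_count, q$expected_count)
    expect_error(poolPseudobulk(list()), "usage error")
    s3 <- quickSample(c(A = 1), "cytosolic")
    expect_error(poolPseudobulk(list(s1, s3)), "mix")
})

test_that("replicate consensus intersects ids and averages the indices", {
    t1 <- locTableFromLI(c(A = 0.6, B = 0.2), sampleId = "r1")
    t2 <- locTableFromLI(c(A = 0.8, C = 0.9), sampleId = "r2")
    cons <- replicateConsensus(list(t1, t2))
    r <- locRecords(cons)
    expect_identical(r$transcript_id, "A")
    expect_equal(r$li, 0.7)
    ## one table passes through unchanged
    expect_identical(replicateConsensus(list(t1)), t1)
    ## ids {A,B} and {B,C} intersect to {B}
    t3 <- locTableFromLI(c(B = 0.4, C = 0.5))
    r2 <- locRecords(replicateConsensus(list(t1, t3)))
    expect_identical(r2$transcript_id, "B")
    expect_equal(r2$li, 0.3)
    ## disjoint replicates are an error
    t4 <- locTableFromLI(c(Z = 0.5))
    expect_error(replicateConsensus(list(t1, t4)), "data error")
})

test_that("detection filter keeps transcripts seen in every sample", {
    s1 <- quickSample(c(A = 1, B = 0, C = 4), "whole")
    s2 <- quickSample(c(A = 2, B = 3, C = 1), "nuclear")
    s3 <- quickSample(c(A = 5, B = 1, C = 0), "cytosolic")
    expect_setequal(filterDetected(list(s1, s2, s3)), "A")
})

test_that("mitochondrial ids are picked up from chrM/MT chromosome labels", {
    md <- data.frame(transcript_id = c("A", "B", "C", "D"),
                     chromosome = c("chr1", "chrM", "MT", "chrX"))
    expect_setequal(mitochondrialIds(md), c("B", "C"))
})
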