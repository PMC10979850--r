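## Shared fixtures: all built in code, nothing on disk.

## Two-gene conceptual setup: equal transcript lengths, two cell states.
## Cell type 1: gene A 40 nuclear / 60 cytosolic, gene B 110 / 90.
## Cell type 2: gene A 40 / 60, gene B 20 / 180.  Depth 1000 per fraction.
twoGeneSetup <- function() {
    list(
        lengths = c(A = 1000, B = 1000),
        type1 = list(nuclear = c(A = 40, B = 110), cytosolic = c(A = 60, B = 90)),
        type2 = list(nuclear = c(A = 40, B = 20), cytosolic = c(A = 60, B = 180)),
        depth = 1000
    )
}

## FractionSample from bare counts (equal unit lengths by default)
quickSample <- function(counts, fraction, ids = names(counts),
                        lengths = rep(1000, length(counts)),
                        replicateId = "rep1", depth = NULL) {
    if (is.null(ids)) ids <- sprintf("tx_%d", seq_along(counts))
    fractionSample(transcript_id = ids, length = lengths,
                   expected_count = counts, fraction = fraction,
                   replicateId = replicateId, depth = depth)
}

## Noiseless triplet satisfying fpkm_w = (1-beta0) fpkm_n + beta0 fpkm_c
noiselessTriplet <- function(beta0, n = 100, seed = 1) {
    set.seed(seed)
    fn <- rexp(n, rate = 0.1)
    fc <- rexp(n, rate = 0.05)
    matchedTriplet((1 - beta0) * fn + beta0 * fc, fn, fc)
}

## LocalizationTable straight from index values (for consistency summaries)
locTableFromLI <- function(li, ids = names(li), sampleId = "s",
                           betaUsed = 0.7) {
    if (is.null(ids)) ids <- sprintf("tx_%d", seq_along(li))
    rec <- S4Vectors::DataFrame(
        transcript_id = ids, li = li, naive_li = li,
        label = classifyLocalization(li))
    methods::new("LocalizationTable", sampleId = sampleId,
                 betaUsed = betaUsed, records = rec)
}

## Independent term-by-term log-posterior oracle built from stats d* calls
oracleLogPosterior <- function(beta, nu, sigma, w, n, c, s,
                               shape = 2, rate = 0.1, a = 2, b = 2) {
    total <- 0
    for (i in seq_along(w)) {
        r <- w[i] - ((1 - beta) * n[i] + beta * c[i])
        total <- total + stats::dt(r / sigma, df = nu, log = TRUE) - log(sigma)
    }
    total +
        stats::dgamma(nu, shape = shape, rate = rate, log = TRUE) +
        stats::dexp(sigma, rate = 1 / s, log = TRUE) +
        stats::dbeta(beta, a, b, log = TRUE)
}

## Exhaustive hypergeometric tail by enumerating all subsets of the
## population (feasible for populations of <= 15 items)
enumTailProb <- function(flagsGlobal, nSpecific, xObserved) {
    N <- length(flagsGlobal)
    idx <- utils::combn(N, nSpecific)
    hits <- apply(idx, 2, function(j) sum(flagsGlobal[j]) >= xObserved)
    mean(hits)
}

## Small RSEM-style table on disk for reader tests
writeQuantFixture <- function(path, ids, lengths, counts,
                              countsName = "expected_count") {
    z <- rep(0, length(ids))
    df <- data.frame(transcript_id = ids,
                     gene_id = if (length(ids)) paste0("g", ids) else character(),
                     length = lengths, effective_length = lengths,
                     X = counts, TPM = z, FPKM = z)
    names(df)[names(df) == "X"] <- countsName
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}
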