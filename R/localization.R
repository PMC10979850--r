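#' @importFrom stats phyper
NULL

#' Per-transcript localization index
#'
#' The fraction of a transcript's RNA molecules residing in the cytosol,
#' computed from its nuclear and cytosolic FPKM and the cytosolic volume
#' fraction beta:
#' \deqn{LI = \frac{\beta\,FPKM_c}{(1-\beta)\,FPKM_n + \beta\,FPKM_c}}
#' Reduces to the naive index when \eqn{\beta = 0.5}.  Vectorized over the
#' FPKM arguments; elements where both FPKMs are zero are undefined and
#' returned as \code{NA} with a warning.
#'
#' @param fpkm_n,fpkm_c non-negative nuclear and cytosolic FPKM values.
#' @param beta cytosolic volume fraction, in (0,1).
#' @return localization index values in [0,1] (\code{NA} where undefined).
#' @seealso [naiveLocalizationIndex()], [localizationTable()]
#' @export
localizationIndex <- function(fpkm_n, fpkm_c, beta) {
    if (length(beta) != 1L || beta <= 0 || beta >= 1)
        stop("beta must lie in (0,1)")
    if (any(fpkm_n < 0) || any(fpkm_c < 0))
        stop("FPKM values must be non-negative")
    denom <- (1 - beta) * fpkm_n + beta * fpkm_c
    und <- denom == 0
    if (any(und))
        warning(sum(und), " transcript(s) with zero FPKM in both fractions: ",
                "localization index undefined (NA)")
    ifelse(und, NA_real_, beta * fpkm_c / denom)
}

#' Naive localization index
#'
#' \eqn{FPKM_c / (FPKM_n + FPKM_c)}: the commonly used FPKM ratio, which
#' equals the true cytosolic molecule fraction only when the cellular RNA
#' volume is equally split between nucleus and cytosol (\eqn{\beta = 0.5});
#' it underestimates localization when \eqn{\beta > 0.5} and overestimates
#' it when \eqn{\beta < 0.5}.
#'
#' @inheritParams localizationIndex
#' @return values in [0,1] (\code{NA} where both FPKMs are zero).
#' @export
naiveLocalizationIndex <- function(fpkm_n, fpkm_c) {
    localizationIndex(fpkm_n, fpkm_c, beta = 0.5)
}

#' Expected read counts under length-weighted sampling
#'
#' The expected number of reads assigned to each transcript in a library of
#' a given depth is proportional to the product of molecule count and
#' transcript length:
#' \deqn{r(i) = D \cdot \frac{m_i l_i}{\sum_j m_j l_j}}
#'
#' @param molecules non-negative molecule counts.
#' @param lengths positive transcript lengths, nucleotides.
#' @param depth total sequenced reads.
#' @return expected read counts (sum to \code{depth}).
#' @export
expectedFractionCounts <- function(molecules, lengths, depth) {
    if (length(molecules) != length(lengths))
        stop("molecules and lengths must have equal length")
    if (any(lengths <= 0)) stop("lengths must be positive")
    if (any(molecules < 0)) stop("molecule counts must be non-negative")
    vol <- sum(molecules * lengths)
    if (vol <= 0) stop("domain error: no molecules to sequence")
    depth * molecules * lengths / vol
}

#' Classify a localization index into a compartment label
#'
#' @param li localization index values (NA allowed).
#' @param lower nuclear threshold: \code{li < lower} is nuclear (default 0.4).
#' @param upper cytosolic threshold: \code{li > upper} is cytosolic
#'   (default 0.6).
#' @return character vector with levels \code{nuclear}, \code{intermediate},
#'   \code{cytosolic}, \code{undefined}.
#' @export
classifyLocalization <- function(li, lower = 0.4, upper = 0.6) {
    stopifnot(lower >= 0, upper <= 1, lower < upper)
    out <- ifelse(is.na(li), "undefined",
           ifelse(li < lower, "nuclear",
           ifelse(li > upper, "cytosolic", "intermediate")))
    out
}

#' Build a localization table from a matched triplet
#'
#' Computes the localization index, the naive index and a compartment label
#' for every transcript of a \linkS4class{MatchedTriplet}, given an
#' estimated cytosolic volume fraction.
#'
#' @param triplet a \linkS4class{MatchedTriplet}.
#' @param beta cytosolic volume fraction (e.g. [betaMap()] of a fitted
#'   posterior).
#' @param sampleId sample/condition label.
#' @param lower,upper classification thresholds, see
#'   [classifyLocalization()].
#' @return a \linkS4class{LocalizationTable}.
#' @export
localizationTable <- function(triplet, beta, sampleId = "sample",
                              lower = 0.4, upper = 0.6) {
    stopifnot(is(triplet, "MatchedTriplet"))
    n <- fpkmNuclear(triplet); c <- fpkmCytosolic(triplet)
    li <- suppressWarnings(localizationIndex(n, c, beta))
    naive <- suppressWarnings(naiveLocalizationIndex(n, c))
    rec <- DataFrame(
        transcript_id = rownames(assay(triplet, "fpkm")),
        li = li, naive_li = naive,
        label = classifyLocalization(li, lower, upper)
    )
    new("LocalizationTable", sampleId = sampleId, betaUsed = beta,
        records = rec)
}

#' Average localization across replicates
#'
#' Keeps only the transcripts present in every replicate table and averages
#' their localization and naive indices arithmetically; labels are
#' reassigned from the averaged index.  Beta itself is never averaged
#' before index computation: each replicate's table is computed with its
#' own beta, and only the per-transcript indices are combined.
#'
#' @param tables non-empty list of \linkS4class{LocalizationTable}s.
#' @param sampleId label of the consensus table; defaults to the first
#'   table's label.
#' @param lower,upper classification thresholds for the re-labeling.
#' @return a \linkS4class{LocalizationTable} over the id intersection.
#' @export
replicateConsensus <- function(tables, sampleId = NULL,
                               lower = 0.4, upper = 0.6) {
    stopifnot(length(tables) >= 1L)
    if (length(tables) == 1L) return(tables[[1]])
    ids <- Reduce(intersect, lapply(tables, function(t) locRecords(t)$transcript_id))
    if (!length(ids))
        stop("data error: no transcript is present in all replicates")
    ids <- sort(ids)
    liM <- matrix(unlist(lapply(tables, function(t) {
        r <- locRecords(t)
        r$li[match(ids, r$transcript_id)]
    })), nrow = length(ids))
    naiveM <- matrix(unlist(lapply(tables, function(t) {
        r <- locRecords(t)
        r$naive_li[match(ids, r$transcript_id)]
    })), nrow = length(ids))
    li <- rowMeans(liM)
    naive <- rowMeans(naiveM)
    rec <- DataFrame(transcript_id = ids, li = li, naive_li = naive,
                     label = classifyLocalization(li, lower, upper))
    if (is.null(sampleId)) sampleId <- sampleId(tables[[1]])
    new("LocalizationTable", sampleId = sampleId,
        betaUsed = mean(vapply(tables, betaUsed, numeric(1))),
        records = rec)
}

#' Cross-condition localization consistency
#'
#' For every transcript, counts the conditions (e.g. cell lines) in which
#' it appears, bins transcripts by that count k, and within each bin
#' counts those that are cytosolic (\code{LI >= threshold}) in \emph{all}
#' their conditions and those that are nuclear (\code{LI <= threshold}) in
#' all of them.  A transcript sitting exactly at the threshold everywhere
#' satisfies both definitions; such ties are counted in both tallies and
#' reported separately in \code{n_ties} so the overlap is explicit.
#' Transcripts with undefined LI in a condition are dropped from that
#' condition's tally and counted in \code{n_undefined}.
#'
#' @param tables named list of \linkS4class{LocalizationTable}s, one per
#'   condition.
#' @param threshold the split point (default 0.5).
#' @return data.frame with one row per k: \code{n_expressed},
#'   \code{n_always_cytosolic}, \code{n_always_nuclear}, \code{n_ties},
#'   \code{prop_always_cytosolic}, \code{prop_always_nuclear},
#'   \code{n_undefined}.
#' @export
consistencySummary <- function(tables, threshold = 0.5) {
    stopifnot(length(tables) >= 1L)
    li <- lapply(tables, function(t) {
        r <- locRecords(t)
        setNames(r$li, r$transcript_id)
    })
    allIds <- unique(unlist(lapply(li, names)))
    K <- length(tables)
    ## presence = the transcript appears in that condition's table
    present <- vapply(allIds, function(id)
        sum(vapply(li, function(x) id %in% names(x), logical(1))), integer(1))
    nUndef <- 0L
    rows <- lapply(seq_len(K), function(k) {
        sel <- allIds[present == k]
        nCyt <- 0L; nNuc <- 0L; nTie <- 0L; nExp <- 0L
        for (id in sel) {
            v <- unlist(lapply(li, function(x)
                if (id %in% names(x)) x[[id]] else NULL))
            if (anyNA(v)) { nUndef <<- nUndef + 1L; next }
            nExp <- nExp + 1L
            cyt <- all(v >= threshold); nuc <- all(v <= threshold)
            if (cyt) nCyt <- nCyt + 1L
            if (nuc) nNuc <- nNuc + 1L
            if (cyt && nuc) nTie <- nTie + 1L
        }
        data.frame(k = k, n_expressed = nExp,
                   n_always_cytosolic = nCyt, n_always_nuclear = nNuc,
                   n_ties = nTie,
                   prop_always_cytosolic = if (nExp) nCyt / nExp else NA_real_,
                   prop_always_nuclear = if (nExp) nNuc / nExp else NA_real_)
    })
    out <- do.call(rbind, rows)
    attr(out, "n_undefined") <- nUndef
    out
}

#' Strongly localized transcripts across conditions
#'
#' Transcripts expressed in at least \code{minConditions} conditions whose
#' localization index exceeds \code{cytoCut} in every condition where they
#' are expressed (strong cytosolic), or stays below \code{nucCut}
#' everywhere (strong nuclear).
#'
#' @param tables named list of \linkS4class{LocalizationTable}s.
#' @param minConditions minimum number of conditions (default 5).
#' @param cytoCut strong-cytosolic threshold (default 0.9).
#' @param nucCut strong-nuclear threshold (default 0.3).
#' @return list with character vectors \code{cytosolic} and \code{nuclear}.
#' @export
strongLocalizers <- function(tables, minConditions = 5L,
                             cytoCut = 0.9, nucCut = 0.3) {
    stopifnot(minConditions >= 1L, cytoCut > 0, cytoCut < 1,
              nucCut > 0, nucCut < 1)
    li <- lapply(tables, function(t) {
        r <- locRecords(t)
        setNames(r$li, r$transcript_id)
    })
    allIds <- unique(unlist(lapply(li, names)))
    cyt <- character(); nuc <- character()
    for (id in allIds) {
        v <- unlist(lapply(li, function(x)
            if (id %in% names(x)) x[[id]] else NULL))
        if (length(v) < minConditions || anyNA(v)) next
        if (all(v > cytoCut)) cyt <- c(cyt, id)
        if (all(v < nucCut)) nuc <- c(nuc, id)
    }
    list(cytosolic = cyt, nuclear = nuc)
}

#' Enrichment of a feature in a localization-specific set
#'
#' Ratio of the frequency of flagged items (e.g. high intron-retention
#' introns, low inclusion exons) in a localization-specific subset over
#' their frequency in the global set, with a hypergeometric upper-tail
#' p-value (probability of observing at least the flagged count when
#' drawing the subset at random from the global population).  When testing
#' several conditions, apply a Bonferroni correction to the returned
#' p-values (e.g. \code{p.adjust(p, "bonferroni")}).
#'
#' @param flagsSpecific logical vector: flag status of the items in the
#'   localization-specific subset.
#' @param flagsGlobal logical vector: flag status of all items (the subset
#'   must be drawn from this population).
#' @return list with \code{ratio}, \code{p_value}, and the underlying
#'   counts.
#' @export
enrichmentRatio <- function(flagsSpecific, flagsGlobal) {
    if (!length(flagsGlobal)) stop("global set must be non-empty")
    if (!length(flagsSpecific))
        stop("undefined ratio: empty localization-specific set")
    if (length(flagsSpecific) > length(flagsGlobal))
        stop("specific set cannot exceed the global set")
    x <- sum(flagsSpecific)           # flagged in subset
    nS <- length(flagsSpecific)       # subset size
    K <- sum(flagsGlobal)             # flagged in population
    N <- length(flagsGlobal)          # population size
    freqGlobal <- K / N
    ratio <- if (freqGlobal > 0) (x / nS) / freqGlobal else NA_real_
    p <- phyper(x - 1, K, N - K, nS, lower.tail = FALSE)
    list(ratio = ratio, p_value = p,
         n_flagged_specific = x, n_specific = nS,
         n_flagged_global = K, n_global = N)
}
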