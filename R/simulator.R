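#' @importFrom stats rmultinom qnbinom qbinom
NULL

#' Create a simulator configuration
#'
#' See \linkS4class{SimConfig} for the meaning of every field.  Defaults
#' describe the benchmark conditions: 10,000 transcripts, 5e5 whole-cell
#' molecules under a rank power law with exponent 1 (most transcripts
#' lowly expressed, few highly expressed), transcript lengths log-uniform
#' on 200-10,000 nt, multinomial sequencing at 1e6 reads per fraction.
#'
#' @param nTranscripts,totalMolecules transcriptome size and molecule
#'   budget.
#' @param expressionTailExponent rank power-law exponent (1 = Zipf).
#' @param lengthMin,lengthMax transcript length range, nucleotides.
#' @param targetBeta target cytosolic volume fraction.
#' @param nbMean NB mean of the split-difference magnitude (NA = calibrate).
#' @param nbDispersion NB dispersion.
#' @param depthPerFraction reads per fraction.
#' @param countMode \code{"expected"} or \code{"multinomial"}.
#' @param splitMethod \code{"nb"} or \code{"binomial"}.
#' @param seed integer RNG seed.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(nTranscripts = 10000L, totalMolecules = 5e5,
                      expressionTailExponent = 1.0,
                      lengthMin = 200L, lengthMax = 10000L,
                      targetBeta = 0.5, nbMean = NA_real_, nbDispersion = 1.0,
                      depthPerFraction = 1e6, countMode = "multinomial",
                      splitMethod = "nb", seed = 1L) {
    new("SimConfig", nTranscripts = as.integer(nTranscripts),
        totalMolecules = as.numeric(totalMolecules),
        expressionTailExponent = expressionTailExponent,
        lengthMin = as.integer(lengthMin), lengthMax = as.integer(lengthMax),
        targetBeta = targetBeta, nbMean = nbMean,
        nbDispersion = nbDispersion,
        depthPerFraction = as.numeric(depthPerFraction),
        countMode = countMode, splitMethod = splitMethod,
        seed = as.integer(seed))
}

## derived per-stage seeds so stages can be rerun independently
.stageSeed <- function(seed, stage) {
    offs <- c(whole_cell = 11L, split = 23L, counts_whole = 37L,
              counts_nuclear = 41L, counts_cytosolic = 43L)
    as.integer((abs(as.numeric(seed)) * 7919 + offs[[stage]]) %% 2147483647)
}

#' Simulate whole-cell molecule counts
#'
#' Assigns \code{totalMolecules} molecules to \code{nTranscripts}
#' transcripts by a single multinomial draw with rank-based probabilities
#' proportional to \eqn{rank^{-a}} (heavy-tailed: most transcripts lowly
#' expressed, very few highly expressed; \eqn{a = 0} gives a uniform
#' allocation).  Transcript lengths are drawn log-uniformly from the
#' configured range.  Deterministic given \code{config@seed}; zero-molecule
#' transcripts are allowed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with numeric \code{mW} and \code{lengths}.
#' @export
simulateWholeCell <- function(config) {
    validObject(config)
    n <- config@nTranscripts
    set.seed(.stageSeed(config@seed, "whole_cell"))
    lengths <- round(exp(runif(n, log(config@lengthMin),
                               log(config@lengthMax))))
    probs <- seq_len(n)^(-config@expressionTailExponent)
    probs <- probs / sum(probs)
    mW <- as.numeric(rmultinom(1L, size = config@totalMolecules, prob = probs))
    list(mW = mW, lengths = as.numeric(lengths))
}

## cytosolic counts for a candidate split, NB scheme: |d_i| quantile-coupled
## NB with per-transcript mean scale*max(mW,1), shared dispersion; signs fixed
.nbSplit <- function(mW, u, sign, scale, dispersion) {
    d <- if (scale <= 0) numeric(length(mW))
         else qnbinom(u, mu = scale * pmax(mW, 1), size = 1 / dispersion)
    pmin(pmax(round((mW + sign * d) / 2), 0), mW)
}

#' Split whole-cell molecules into nuclear and cytosolic fractions
#'
#' For each transcript a signed nucleo-cytosolic difference is drawn: its
#' magnitude follows a negative binomial with dispersion
#' \code{nbDispersion} and a mean proportional to the transcript's
#' expression (\code{nbMean * mW}, so that highly and lowly expressed
#' transcripts shift by comparable fractions of their molecules), and its
#' sign points to the cytosol with a probability set by the target.  The
#' cytosolic count is \code{clamp(round((mW + d)/2), 0, mW)} (round half
#' to even) and the nuclear count is the exact complement, so conservation
#' holds by construction.  Calibration (differences quantile-coupled to
#' fixed uniforms, so realized beta is a deterministic monotone function
#' of the knobs): the mean scale is doubled until the all-nuclear /
#' all-cytosolic sign extremes bracket the target, then the sign
#' probability is bisected until the realized length-weighted cytosolic
#' fraction is within 0.005 of \code{targetBeta}.  When \code{nbMean} is
#' set, only the sign probability is calibrated.  The realized beta
#' stored in the result is the authoritative ground truth, not the
#' target.
#'
#' With \code{splitMethod = "binomial"}, \code{mC ~ Binomial(mW, p)} with
#' p calibrated the same way (sensitivity alternative).
#'
#' @param mW whole-cell molecule counts.
#' @param lengths transcript lengths, nucleotides.
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{SimTruth}.
#' @export
splitFractions <- function(mW, lengths, config) {
    validObject(config)
    if (sum(mW) < 1) stop("at least one molecule is required")
    n <- length(mW)
    stopifnot(length(lengths) == n)
    target <- config@targetBeta
    tol <- 0.005
    vol <- sum(mW * lengths)
    set.seed(.stageSeed(config@seed, "split"))
    u <- runif(n)
    if (config@splitMethod == "binomial") {
        realized <- function(p) sum(qbinom(u, mW, p) * lengths) / vol
        lo <- 0; hi <- 1; mid <- 0.5
        for (i in seq_len(200L)) {
            mid <- (lo + hi) / 2
            if (abs(realized(mid) - target) <= tol) break
            if (realized(mid) < target) lo <- mid else hi <- mid
        }
        mC <- qbinom(u, mW, mid)
        return(SimTruth(mW = mW, mC = mC, lengths = lengths))
    }
    ## NB scheme.  Two knobs (the magnitudes are quantile-coupled to fixed
    ## uniforms, so realized beta is a deterministic function of each): the
    ## difference-magnitude scale sc (NB mean = sc * m_w per transcript)
    ## and the cytosolic sign share q.  Signs are assigned by a
    ## deterministic largest-first volume-balancing rule -- walking the
    ## transcripts in decreasing volume order, a transcript's difference
    ## points to the cytosol when the running cytosolic volume share is
    ## still below q -- so the realized beta moves quasi-continuously in q
    ## instead of jumping by whole heavy transcripts.  The scale is grown
    ## until the sign extremes (q = 0: all nuclear; q = 1: all cytosolic)
    ## bracket the target with margin; q is then bisected, along which
    ## realized beta is monotone non-decreasing.
    v <- mW * lengths
    ord <- order(v, decreasing = TRUE)
    vOrd <- v[ord]
    cumV <- cumsum(vOrd)
    signFor <- function(q) {
        s <- numeric(n)
        plus <- 0
        for (i in seq_len(n)) {
            if (plus + vOrd[i] / 2 <= q * cumV[i]) {
                s[i] <- 1; plus <- plus + vOrd[i]
            } else s[i] <- -1
        }
        out <- numeric(n)
        out[ord] <- s
        out
    }
    realized <- function(sc, q)
        sum(.nbSplit(mW, u, signFor(q), sc, config@nbDispersion) * lengths) / vol
    if (!is.na(config@nbMean)) {
        sc <- config@nbMean
    } else {
        sc <- 1
        nDouble <- 0L
        while ((realized(sc, 0) > target - 0.01 ||
                realized(sc, 1) < target + 0.01) && nDouble < 25L) {
            sc <- sc * 2; nDouble <- nDouble + 1L
        }
        if (nDouble >= 25L)
            stop("parameter error: split calibration failed to bracket the ",
                 "target beta; widen the nb_mean search range or adjust ",
                 "nbDispersion")
    }
    lo <- 0; hi <- 1; q <- 0.5
    if (abs(realized(sc, q) - target) > tol) {
        for (i in seq_len(60L)) {
            q <- (lo + hi) / 2
            fm <- realized(sc, q)
            if (abs(fm - target) <= tol) break
            if (fm < target) lo <- q else hi <- q
        }
    }
    ## The sign walk moves whole transcripts at once, so the q-bisection can
    ## stall one flip away from the target.  Polish on the magnitude scale,
    ## along which the quantile-coupled counts move one molecule at a time:
    ## scan a scale grid at both bracket endpoints of q, accept the first
    ## point inside the tolerance, otherwise bisect a straddling pair.
    if (abs(realized(sc, q) - target) > tol && is.na(config@nbMean)) {
        found <- FALSE
        for (qTry in unique(c(q, lo, hi))) {
            grid <- sc * 2^seq(-14, 4, by = 0.5)
            fg <- vapply(grid, function(s) realized(s, qTry), numeric(1))
            best <- which.min(abs(fg - target))
            if (abs(fg[best] - target) <= tol) {
                sc <- grid[best]; q <- qTry; found <- TRUE; break
            }
            cross <- which(diff(sign(fg - target)) != 0)
            if (length(cross)) {
                sLo <- grid[cross[1]]; sHi <- grid[cross[1] + 1]
                dirUp <- fg[cross[1]] < target
                for (i in seq_len(80L)) {
                    scMid <- (sLo + sHi) / 2
                    fm <- realized(scMid, qTry)
                    if (abs(fm - target) <= tol) {
                        sc <- scMid; q <- qTry; found <- TRUE; break
                    }
                    if ((fm < target) == dirUp) sLo <- scMid else sHi <- scMid
                }
                if (found) break
            }
        }
    }
    mC <- .nbSplit(mW, u, signFor(q), sc, config@nbDispersion)
    truth <- SimTruth(mW = mW, mC = mC, lengths = lengths)
    if (is.na(config@nbMean) && abs(truth@realizedBeta - target) > tol)
        stop("parameter error: calibration did not reach the target beta ",
             sprintf("(realized %.4f, target %.4f)", truth@realizedBeta, target))
    truth
}

#' Simulate sequencing counts from molecule counts
#'
#' Either the exact length-weighted expected read counts
#' (\code{mode = "expected"}) or a single multinomial draw of \code{depth}
#' reads with probabilities proportional to molecules times length
#' (\code{mode = "multinomial"}; counts then sum to \code{depth} exactly).
#'
#' @param molecules non-negative molecule counts.
#' @param lengths positive transcript lengths.
#' @param depth sequencing depth.
#' @param mode \code{"expected"} or \code{"multinomial"}.
#' @param seed RNG seed (multinomial mode).
#' @return numeric count vector.
#' @export
simulateCounts <- function(molecules, lengths, depth,
                           mode = c("expected", "multinomial"), seed = 1L) {
    mode <- match.arg(mode)
    vol <- sum(molecules * lengths)
    if (vol <= 0) stop("domain error: all molecule-length products are zero")
    if (mode == "expected")
        return(expectedFractionCounts(molecules, lengths, depth))
    set.seed(as.integer(seed))
    as.numeric(rmultinom(1L, size = depth, prob = molecules * lengths / vol))
}

## counts for the three fractions of a truth object (shared by the
## in-memory dataset builder and the table writer, so they agree exactly)
.datasetCounts <- function(truth, config) {
    mk <- function(mol, stage)
        simulateCounts(mol, truth@lengths, config@depthPerFraction,
                       mode = config@countMode,
                       seed = .stageSeed(config@seed, stage))
    list(whole = mk(truth@mW, "counts_whole"),
         nuclear = mk(truth@mN, "counts_nuclear"),
         cytosolic = mk(truth@mC, "counts_cytosolic"))
}

#' Simulate a complete matched fractionation dataset
#'
#' Generates whole-cell molecule counts, splits them into nuclear and
#' cytosolic fractions at the target cytosolic volume fraction, sequences
#' each fraction, and returns the three \linkS4class{FractionSample}s
#' together with the ground truth.  Fully deterministic given
#' \code{config@seed}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with elements \code{truth} (\linkS4class{SimTruth}) and
#'   \code{samples} (named list of \linkS4class{FractionSample}s:
#'   \code{whole}, \code{nuclear}, \code{cytosolic}).
#' @export
simulateDataset <- function(config) {
    wc <- simulateWholeCell(config)
    truth <- splitFractions(wc$mW, wc$lengths, config)
    counts <- .datasetCounts(truth, config)
    ids <- truth@transcriptIds
    samples <- lapply(names(counts), function(f)
        fractionSample(transcript_id = ids, length = truth@lengths,
                       expected_count = counts[[f]],
                       effective_length = truth@lengths,
                       fraction = f, replicateId = "sim"))
    names(samples) <- names(counts)
    list(truth = truth, samples = samples)
}

#' Write a simulated dataset as quantification tables
#'
#' Emits one tab-separated RSEM-style quantification table per fraction
#' (columns \code{transcript_id}, \code{gene_id}, \code{length},
#' \code{effective_length}, \code{expected_count}, \code{TPM},
#' \code{FPKM}; effective length equals length) plus a ground-truth table
#' \code{truth.tsv} (\code{transcript_id}, \code{length}, \code{m_w},
#' \code{m_n}, \code{m_c}, \code{true_cyto_fraction},
#' \code{realized_beta}) whose \code{#}-prefixed header records the full
#' configuration.  Reading the tables back with [readQuantTable()]
#' reproduces the counts exactly.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param config the \linkS4class{SimConfig} used to generate it.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
emitDataset <- function(truth, config, dir) {
    stopifnot(is(truth, "SimTruth"))
    if (length(truth@mW) == 0L) stop("parameter error: empty truth")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    counts <- .datasetCounts(truth, config)
    paths <- c()
    for (f in names(counts)) {
        cnt <- counts[[f]]
        depth <- sum(cnt)
        tpmDen <- sum(cnt / truth@lengths)
        tab <- data.table::data.table(
            transcript_id = truth@transcriptIds,
            gene_id = truth@transcriptIds,
            length = truth@lengths,
            effective_length = truth@lengths,
            expected_count = cnt,
            TPM = if (tpmDen > 0) 1e6 * (cnt / truth@lengths) / tpmDen else 0,
            FPKM = computeFPKM(cnt, truth@lengths, max(depth, 1))
        )
        p <- file.path(dir, sprintf("%s.isoforms.results", f))
        data.table::fwrite(tab, p, sep = "\t")
        paths[f] <- p
    }
    tp <- file.path(dir, "truth.tsv")
    hdr <- c("# locindex simulated ground truth",
             sprintf("# n_transcripts=%d total_molecules=%g tail_exponent=%g",
                     config@nTranscripts, config@totalMolecules,
                     config@expressionTailExponent),
             sprintf("# target_beta=%g realized_beta=%.10f", config@targetBeta,
                     truth@realizedBeta),
             sprintf("# depth_per_fraction=%g count_mode=%s split_method=%s seed=%d",
                     config@depthPerFraction, config@countMode,
                     config@splitMethod, config@seed))
    writeLines(hdr, tp)
    data.table::fwrite(data.table::data.table(
        transcript_id = truth@transcriptIds, length = truth@lengths,
        m_w = truth@mW, m_n = truth@mN, m_c = truth@mC,
        true_cyto_fraction = truth@trueCytoFraction,
        realized_beta = truth@realizedBeta
    ), tp, sep = "\t", append = TRUE, col.names = TRUE)
    paths["truth"] <- tp
    invisible(paths)
}

#' Read a simulated ground-truth table
#'
#' @param path path to a \code{truth.tsv} written by [emitDataset()].
#' @return a \linkS4class{SimTruth}.
#' @export
readTruthTable <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, skip = "transcript_id")
    SimTruth(mW = dt$m_w, mC = dt$m_c, lengths = dt$length,
             transcriptIds = dt$transcript_id)
}
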