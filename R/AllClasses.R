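#' @importFrom methods new validObject is show slot callNextMethod setValidity
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

.FRACTIONS <- c("whole", "nuclear", "cytosolic")

#' Per-fraction transcript quantification sample
#'
#' Holds one RNA-seq quantification of a cellular fraction (whole cell,
#' nucleus or cytosol): per-transcript read counts, lengths and derived
#' FPKM/CPM values, together with the library depth used for normalization.
#'
#' @slot fraction character(1), one of \code{"whole"}, \code{"nuclear"},
#'   \code{"cytosolic"}.
#' @slot replicateId character(1) replicate label.
#' @slot depth numeric(1), total assigned reads; by convention the sum of
#'   \code{expected_count} over all transcripts before any filtering.
#' @slot quant \linkS4class{DataFrame} with columns \code{transcript_id},
#'   \code{gene_id}, \code{length}, \code{effective_length},
#'   \code{expected_count}, \code{fpkm}, \code{cpm}.
#'
#' @seealso [readQuantTable()], [poolPseudobulk()], [buildTriplet()]
#' @exportClass FractionSample
setClass("FractionSample",
    representation(
        fraction = "character",
        replicateId = "character",
        depth = "numeric",
        quant = "DataFrame"
    )
)

setValidity("FractionSample", function(object) {
    msg <- character()
    if (length(object@fraction) != 1L || !object@fraction %in% .FRACTIONS)
        msg <- c(msg, sprintf("'fraction' must be one of %s",
                              paste(.FRACTIONS, collapse = ", ")))
    q <- object@quant
    needed <- c("transcript_id", "length", "effective_length",
                "expected_count", "fpkm", "cpm")
    miss <- setdiff(needed, colnames(q))
    if (length(miss))
        msg <- c(msg, paste("quant lacks column(s):", paste(miss, collapse = ", ")))
    if (nrow(q) > 0L && length(miss) == 0L) {
        if (anyDuplicated(q$transcript_id))
            msg <- c(msg, "duplicate transcript_id in quant")
        if (any(q$length < 1))
            msg <- c(msg, "transcript length must be >= 1")
        if (any(q$expected_count > 0 & q$effective_length <= 0))
            msg <- c(msg, "effective_length must be > 0 where expected_count > 0")
        if (any(!is.finite(q$fpkm)) || any(q$fpkm < 0) ||
            any(!is.finite(q$cpm)) || any(q$cpm < 0))
            msg <- c(msg, "fpkm/cpm must be finite and non-negative")
        if (length(object@depth) != 1L || (!is.na(object@depth) && object@depth <= 0))
            msg <- c(msg, "depth must be a single positive number")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn FractionSample-class display a short summary
#' @param object a \code{FractionSample}
#' @export
setMethod("show", "FractionSample", function(object) {
    cat(sprintf("FractionSample [%s] replicate '%s'\n",
                object@fraction, object@replicateId))
    cat(sprintf("  %d transcripts, depth %.6g\n",
                nrow(object@quant), object@depth))
})

#' Matched whole/nuclear/cytosolic FPKM triplet
#'
#' A \linkS4class{SummarizedExperiment} carrying a single assay \code{"fpkm"}
#' with exactly three columns (\code{whole}, \code{nuclear},
#' \code{cytosolic}) aligned over a common transcript set.  This is the
#' input of the cytosolic volume-fraction regression: the model states that
#' whole-cell FPKM of every transcript is the convex combination
#' \eqn{(1-\beta)\,FPKM_n + \beta\,FPKM_c} plus heavy-tailed noise.
#'
#' Rows are transcripts (rownames are transcript ids); no row may be zero in
#' all three fractions.
#'
#' @seealso [buildTriplet()], [samplePosterior()], [localizationTable()]
#' @exportClass MatchedTriplet
setClass("MatchedTriplet", contains = "SummarizedExperiment")

setValidity("MatchedTriplet", function(object) {
    msg <- character()
    if (!"fpkm" %in% names(assays(object)))
        return("assay 'fpkm' is required")
    m <- assay(object, "fpkm")
    if (ncol(m) != 3L || !identical(colnames(m), .FRACTIONS))
        msg <- c(msg, "assay 'fpkm' must have columns whole, nuclear, cytosolic")
    if (nrow(m) < 1L)
        msg <- c(msg, "at least one transcript is required")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
        msg <- c(msg, "rownames must be unique transcript ids")
    if (any(!is.finite(m)) || any(m < 0))
        msg <- c(msg, "FPKM values must be finite and non-negative")
    else if (any(rowSums(m) == 0))
        msg <- c(msg, "no transcript may have zero FPKM in all three fractions")
    if (length(msg)) msg else TRUE
})

#' @describeIn MatchedTriplet-class display a short summary
#' @param object a \code{MatchedTriplet}
#' @export
setMethod("show", "MatchedTriplet", function(object) {
    m <- assay(object, "fpkm")
    cat(sprintf("MatchedTriplet with %d transcripts\n", nrow(m)))
    cat(sprintf("  mean FPKM  whole %.4g | nuclear %.4g | cytosolic %.4g\n",
                mean(m[, "whole"]), mean(m[, "nuclear"]), mean(m[, "cytosolic"])))
})

#' Configuration of the Bayesian beta regression
#'
#' Priors and sampler settings for the Student-t regression of whole-cell
#' FPKM on nuclear and cytosolic FPKM.  Defaults follow the model as
#' published: \eqn{\nu \sim \Gamma(2, 0.1)} (shape/rate) on the degrees of
#' freedom, \eqn{\sigma \sim Exp(mean = s)} on the error scale with
#' \eqn{s = sd(FPKM_w)} computed from the data, \eqn{\beta \sim Beta(2,2)},
#' 4 chains of 6000 iterations with the first 2000 as warm-up.
#'
#' @slot nuPriorShape,nuPriorRate Gamma prior on the Student-t degrees of
#'   freedom (shape 2, rate 0.1).
#' @slot sigmaPriorMean mean of the exponential prior on the error scale;
#'   \code{NA} (default) means "compute as sd of whole-cell FPKM at fit time".
#' @slot betaPriorA,betaPriorB Beta prior on the cytosolic volume fraction.
#' @slot chains,iterations,warmup MCMC layout; \code{warmup < iterations}.
#' @slot targetAccept target acceptance rate of the warm-up step-size
#'   adaptation.
#' @slot maxTreeDepth retained for interface compatibility with
#'   tree-based Hamiltonian samplers; unused by the random-walk kernel.
#' @slot seed integer RNG seed.
#' @slot errorModel \code{"student_t"} (default) or \code{"normal"}; the
#'   normal model is provided for robustness comparisons only.
#' @seealso [betaModelConfig()], [samplePosterior()]
#' @exportClass BetaModelConfig
setClass("BetaModelConfig",
    representation(
        nuPriorShape = "numeric", nuPriorRate = "numeric",
        sigmaPriorMean = "numeric",
        betaPriorA = "numeric", betaPriorB = "numeric",
        chains = "integer", iterations = "integer", warmup = "integer",
        targetAccept = "numeric", maxTreeDepth = "integer",
        seed = "integer", errorModel = "character"
    ),
    prototype(
        nuPriorShape = 2, nuPriorRate = 0.1,
        sigmaPriorMean = NA_real_,
        betaPriorA = 2, betaPriorB = 2,
        chains = 4L, iterations = 6000L, warmup = 2000L,
        targetAccept = 0.9, maxTreeDepth = 10L,
        seed = 1L, errorModel = "student_t"
    )
)

setValidity("BetaModelConfig", function(object) {
    msg <- character()
    pos <- c(nuPriorShape = object@nuPriorShape, nuPriorRate = object@nuPriorRate,
             betaPriorA = object@betaPriorA, betaPriorB = object@betaPriorB)
    if (any(pos <= 0))
        msg <- c(msg, "all prior hyperparameters must be > 0")
    if (!is.na(object@sigmaPriorMean) && object@sigmaPriorMean <= 0)
        msg <- c(msg, "sigmaPriorMean must be > 0 when set")
    if (object@warmup >= object@iterations)
        msg <- c(msg, "warmup must be smaller than iterations")
    if (object@chains < 1L || object@iterations < 1L || object@warmup < 0L)
        msg <- c(msg, "chains/iterations/warmup must be positive")
    if (object@targetAccept <= 0 || object@targetAccept >= 1)
        msg <- c(msg, "targetAccept must lie in (0, 1)")
    if (!object@errorModel %in% c("student_t", "normal"))
        msg <- c(msg, "errorModel must be 'student_t' or 'normal'")
    if (length(msg)) msg else TRUE
})

#' Posterior sample of the cytosolic volume fraction
#'
#' Pooled MCMC draws of \eqn{(\beta, \nu, \sigma)} with the MAP estimate of
#' \eqn{\beta} (kernel-density mode of the pooled draws) and convergence
#' diagnostics.
#'
#' @slot draws numeric matrix with columns \code{beta}, \code{nu},
#'   \code{sigma}; post-warmup draws from all chains, stacked.
#' @slot chain integer vector mapping each draw to its chain.
#' @slot betaMap numeric(1) maximum a posteriori estimate of beta.
#' @slot rhatBeta,essBeta potential scale reduction factor and effective
#'   sample size of the beta draws.
#' @slot nTranscripts number of transcripts in the regression.
#' @slot config the \linkS4class{BetaModelConfig} used (with the realized
#'   \code{sigmaPriorMean} filled in).
#' @seealso [samplePosterior()], [estimateBetaMap()], [qcBeta()]
#' @exportClass BetaPosterior
setClass("BetaPosterior",
    representation(
        draws = "matrix", chain = "integer",
        betaMap = "numeric", rhatBeta = "numeric", essBeta = "numeric",
        nTranscripts = "integer", config = "BetaModelConfig"
    )
)

setValidity("BetaPosterior", function(object) {
    msg <- character()
    d <- object@draws
    if (!identical(colnames(d), c("beta", "nu", "sigma")))
        msg <- c(msg, "draws must have columns beta, nu, sigma")
    else {
        if (any(d[, "beta"] <= 0 | d[, "beta"] >= 1))
            msg <- c(msg, "beta draws must lie in (0,1)")
        if (any(d[, "nu"] <= 0) || any(d[, "sigma"] <= 0))
            msg <- c(msg, "nu and sigma draws must be positive")
    }
    if (length(object@chain) != nrow(d))
        msg <- c(msg, "chain index must match draws")
    if (!is.na(object@betaMap) && (object@betaMap <= 0 || object@betaMap >= 1))
        msg <- c(msg, "betaMap must lie in (0,1)")
    if (length(msg)) msg else TRUE
})

#' @describeIn BetaPosterior-class display a short summary
#' @param object a \code{BetaPosterior}
#' @export
setMethod("show", "BetaPosterior", function(object) {
    b <- object@draws[, "beta"]
    ci <- stats::quantile(b, c(0.05, 0.95), names = FALSE)
    cat(sprintf("BetaPosterior: %d draws over %d chains (%d transcripts)\n",
                nrow(object@draws), length(unique(object@chain)),
                object@nTranscripts))
    cat(sprintf("  beta MAP %.4f | mean %.4f | 90%% CI [%.4f, %.4f]\n",
                object@betaMap, mean(b), ci[1], ci[2]))
    cat(sprintf("  Rhat %.4f | ESS %.0f\n", object@rhatBeta, object@essBeta))
})

#' Per-transcript localization table
#'
#' One row per transcript with the localization index (fraction of the
#' transcript's molecules in the cytosol), the naive index
#' \eqn{FPKM_c/(FPKM_n + FPKM_c)}, and a compartment label.
#'
#' @slot sampleId character(1) sample/condition label.
#' @slot betaUsed numeric(1) cytosolic volume fraction used to compute LI.
#' @slot records \linkS4class{DataFrame} with columns \code{transcript_id},
#'   \code{li}, \code{naive_li}, \code{label}.  \code{label} is one of
#'   \code{nuclear}, \code{cytosolic}, \code{intermediate},
#'   \code{undefined}; \code{undefined} rows (both fraction FPKMs zero)
#'   carry \code{NA} indices.
#' @seealso [localizationTable()], [replicateConsensus()],
#'   [consistencySummary()]
#' @exportClass LocalizationTable
setClass("LocalizationTable",
    representation(
        sampleId = "character", betaUsed = "numeric", records = "DataFrame"
    )
)

setValidity("LocalizationTable", function(object) {
    msg <- character()
    r <- object@records
    needed <- c("transcript_id", "li", "naive_li", "label")
    if (!all(needed %in% colnames(r)))
        return(paste("records needs columns:", paste(needed, collapse = ", ")))
    if (anyDuplicated(r$transcript_id))
        msg <- c(msg, "duplicate transcript_id")
    if (length(object@betaUsed) != 1L ||
        object@betaUsed <= 0 || object@betaUsed >= 1)
        msg <- c(msg, "betaUsed must lie in (0,1)")
    ok <- is.na(r$li) | (r$li >= 0 & r$li <= 1)
    if (!all(ok))
        msg <- c(msg, "li must lie in [0,1] or be NA (undefined)")
    und <- r$label == "undefined"
    if (any(und != is.na(r$li)))
        msg <- c(msg, "label 'undefined' must coincide with NA indices")
    if (!all(r$label %in% c("nuclear", "cytosolic", "intermediate", "undefined")))
        msg <- c(msg, "invalid label value")
    if (length(msg)) msg else TRUE
})

#' @describeIn LocalizationTable-class display a short summary
#' @param object a \code{LocalizationTable}
#' @export
setMethod("show", "LocalizationTable", function(object) {
    r <- object@records
    cat(sprintf("LocalizationTable '%s' (beta = %.3f): %d transcripts\n",
                object@sampleId, object@betaUsed, nrow(r)))
    print(table(factor(r$label,
        levels = c("nuclear", "intermediate", "cytosolic", "undefined"))))
})

#' Configuration of the fractionation simulator
#'
#' Settings for generating matched whole-cell / nuclear / cytosolic
#' quantification data with known ground truth.  Whole-cell molecule counts
#' follow a heavy-tailed rank power law (most transcripts lowly expressed,
#' few highly expressed); each transcript's molecules are then split between
#' nucleus and cytosol so that the length-weighted (volume) cytosolic
#' fraction hits \code{targetBeta}; sequencing is emulated by
#' length-weighted read assignment at \code{depthPerFraction} reads.
#'
#' @slot nTranscripts,totalMolecules transcriptome size and molecule budget.
#' @slot expressionTailExponent exponent of the rank power law (1 = Zipf).
#' @slot lengthMin,lengthMax transcript length range, nucleotides
#'   (log-uniform).
#' @slot targetBeta target cytosolic volume fraction in (0,1).
#' @slot nbMean scale of the negative-binomial mean of the per-transcript
#'   nucleo-cytosolic difference magnitude (mean = \code{nbMean * mW});
#'   \code{NA} (default) means "calibrate by bisection so the realized
#'   beta is within 0.005 of target".
#' @slot nbDispersion negative-binomial dispersion (variance
#'   \eqn{\mu + \phi \mu^2}).
#' @slot depthPerFraction sequencing depth per fraction.
#' @slot countMode \code{"expected"} (exact length-weighted expectations) or
#'   \code{"multinomial"} (one multinomial draw per fraction).
#' @slot splitMethod \code{"nb"} (signed negative-binomial difference,
#'   default) or \code{"binomial"} (binomial thinning) fraction split.
#' @slot seed integer RNG seed.
#' @seealso [simConfig()], [simulateDataset()]
#' @exportClass SimConfig
setClass("SimConfig",
    representation(
        nTranscripts = "integer", totalMolecules = "numeric",
        expressionTailExponent = "numeric",
        lengthMin = "integer", lengthMax = "integer",
        targetBeta = "numeric", nbMean = "numeric", nbDispersion = "numeric",
        depthPerFraction = "numeric", countMode = "character",
        splitMethod = "character", seed = "integer"
    ),
    prototype(
        nTranscripts = 10000L, totalMolecules = 5e5,
        expressionTailExponent = 1.0,
        lengthMin = 200L, lengthMax = 10000L,
        targetBeta = 0.5, nbMean = NA_real_, nbDispersion = 1.0,
        depthPerFraction = 1e6, countMode = "multinomial",
        splitMethod = "nb", seed = 1L
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nTranscripts < 1L) msg <- c(msg, "nTranscripts must be >= 1")
    if (object@totalMolecules < 1) msg <- c(msg, "totalMolecules must be >= 1")
    if (object@expressionTailExponent < 0)
        msg <- c(msg, "expressionTailExponent must be >= 0")
    if (object@lengthMin < 1L || object@lengthMax < object@lengthMin)
        msg <- c(msg, "length range must satisfy 1 <= lengthMin <= lengthMax")
    if (object@targetBeta <= 0 || object@targetBeta >= 1)
        msg <- c(msg, "targetBeta must lie in (0,1)")
    if (!is.na(object@nbMean) && object@nbMean < 0)
        msg <- c(msg, "nbMean must be >= 0 when set")
    if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be > 0")
    if (object@depthPerFraction < 1) msg <- c(msg, "depthPerFraction must be >= 1")
    if (!object@countMode %in% c("expected", "multinomial"))
        msg <- c(msg, "countMode must be 'expected' or 'multinomial'")
    if (!object@splitMethod %in% c("nb", "binomial"))
        msg <- c(msg, "splitMethod must be 'nb' or 'binomial'")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated fractionation experiment
#'
#' Molecule counts per compartment with the realized cytosolic volume
#' fraction.  Conservation holds exactly: \code{mN + mC == mW} per
#' transcript, and \code{realizedBeta} equals
#' \eqn{\sum m_c l / \sum m_w l} computed from the stored columns.
#'
#' @slot transcriptIds transcript identifiers.
#' @slot mW,mN,mC whole-cell, nuclear, cytosolic molecule counts.
#' @slot lengths transcript lengths, nucleotides.
#' @slot realizedBeta realized cytosolic volume fraction (ground truth).
#' @slot trueCytoFraction per-transcript \code{mC/mW} (\code{NA} where
#'   \code{mW == 0}).
#' @seealso [SimTruth()], [splitFractions()], [emitDataset()]
#' @exportClass SimTruth
setClass("SimTruth",
    representation(
        transcriptIds = "character",
        mW = "numeric", mN = "numeric", mC = "numeric",
        lengths = "numeric",
        realizedBeta = "numeric", trueCytoFraction = "numeric"
    )
)

setValidity("SimTruth", function(object) {
    msg <- character()
    n <- length(object@mW)
    if (length(object@mN) != n || length(object@mC) != n ||
        length(object@lengths) != n || length(object@transcriptIds) != n ||
        length(object@trueCytoFraction) != n)
        return("all per-transcript vectors must have equal length")
    if (any(object@mW < 0) || any(object@mN < 0) || any(object@mC < 0))
        msg <- c(msg, "molecule counts must be non-negative")
    if (any(object@mN + object@mC != object@mW))
        msg <- c(msg, "conservation violated: mN + mC must equal mW")
    if (any(object@lengths < 1))
        msg <- c(msg, "lengths must be >= 1")
    vol <- sum(object@mW * object@lengths)
    if (vol <= 0)
        msg <- c(msg, "at least one molecule is required")
    else if (abs(object@realizedBeta -
                 sum(object@mC * object@lengths) / vol) > 1e-12)
        msg <- c(msg, "realizedBeta inconsistent with molecule counts")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimTruth-class display a short summary
#' @param object a \code{SimTruth}
#' @export
setMethod("show", "SimTruth", function(object) {
    cat(sprintf("SimTruth: %d transcripts, %.6g molecules, realized beta %.4f\n",
                length(object@mW), sum(object@mW), object@realizedBeta))
})

#' Construct a SimTruth from explicit molecule counts
#'
#' Builds the ground-truth object directly from whole-cell and cytosolic
#' molecule counts (nuclear counts are the exact complement), computing the
#' realized cytosolic volume fraction
#' \eqn{\beta = \sum_i m_c(i) l(i) / \sum_i m_w(i) l(i)}.
#'
#' @param mW whole-cell molecule counts (non-negative).
#' @param mC cytosolic molecule counts, elementwise \code{<= mW}.
#' @param lengths transcript lengths in nucleotides.
#' @param transcriptIds optional ids; defaults to \code{tx_1 ... tx_n}.
#' @return a \linkS4class{SimTruth}.
#' @examples
#' ## two genes of equal length, preferentially cytosolic cell state
#' tr <- SimTruth(mW = c(100, 200), mC = c(60, 180), lengths = c(1000, 1000))
#' realizedBeta(tr)   # 0.8
#' @export
SimTruth <- function(mW, mC, lengths, transcriptIds = NULL) {
    if (length(mW) != length(mC) || length(mW) != length(lengths))
        stop("mW, mC and lengths must have equal length")
    if (any(mC > mW))
        stop("cytosolic counts cannot exceed whole-cell counts")
    if (is.null(transcriptIds))
        transcriptIds <- sprintf("tx_%d", seq_along(mW))
    mN <- mW - mC
    vol <- sum(mW * lengths)
    if (vol <= 0) stop("at least one molecule is required")
    frac <- ifelse(mW > 0, mC / mW, NA_real_)
    new("SimTruth", transcriptIds = as.character(transcriptIds),
        mW = as.numeric(mW), mN = as.numeric(mN), mC = as.numeric(mC),
        lengths = as.numeric(lengths),
        realizedBeta = sum(mC * lengths) / vol,
        trueCytoFraction = frac)
}
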