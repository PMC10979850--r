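#' @importFrom data.table fread fwrite setnames as.data.table
#' @importFrom stats setNames
NULL

## Column aliases accepted (case-insensitive) when reading quantification
## tables; RSEM isoform.results headers are covered.
.QUANT_ALIASES <- list(
    transcript_id   = c("transcript_id", "transcript", "tx_id", "isoform_id"),
    gene_id         = c("gene_id", "gene"),
    length          = c("length", "len"),
    effective_length = c("effective_length", "eff_length", "efflength"),
    expected_count  = c("expected_count", "count", "counts", "est_counts"),
    tpm             = c("tpm"),
    fpkm            = c("fpkm")
)

#' Fragments per kilobase per million mapped fragments
#'
#' \code{FPKM(i) = count(i) / (length(i)/10^3) / (depth/10^6)}.  A zero
#' count yields a zero FPKM regardless of length.
#'
#' @param counts non-negative read/fragment counts.
#' @param lengths positive transcript (effective) lengths in nucleotides.
#' @param depth total mapped fragments of the library.
#' @return numeric vector of FPKM values.
#' @examples
#' computeFPKM(50, 2000, 5e6)   # 5
#' @export
computeFPKM <- function(counts, lengths, depth) {
    if (length(counts) != length(lengths))
        stop("counts and lengths must have equal length")
    if (any(lengths <= 0)) stop("all lengths must be > 0")
    if (length(depth) != 1L || depth <= 0) stop("depth must be a single positive number")
    counts / (lengths / 1e3) / (depth / 1e6)
}

#' Counts per million mapped reads
#'
#' @param counts non-negative read counts.
#' @param depth total mapped reads of the library.
#' @return numeric vector of CPM values.
#' @export
computeCPM <- function(counts, depth) {
    if (length(depth) != 1L || depth <= 0) stop("depth must be a single positive number")
    counts / (depth / 1e6)
}

## length used for FPKM: effective length when positive, else annotated
.fpkmLength <- function(length, effective_length) {
    ifelse(is.finite(effective_length) & effective_length > 0,
           effective_length, length)
}

#' Build a FractionSample from per-transcript quantifications
#'
#' Library depth defaults to the sum of \code{expected_count} over all
#' transcripts (computed before any filtering); FPKM and CPM are derived
#' from the counts.  FPKM uses the effective length where positive, the
#' annotated length otherwise.
#'
#' @param transcript_id character transcript ids (unique).
#' @param length transcript lengths, nucleotides.
#' @param expected_count expected read/fragment counts.
#' @param fraction \code{"whole"}, \code{"nuclear"} or \code{"cytosolic"}.
#' @param effective_length effective lengths; defaults to \code{length}.
#' @param gene_id optional gene ids.
#' @param replicateId replicate label.
#' @param depth total assigned reads; derived from the counts when omitted.
#' @return a \linkS4class{FractionSample}.
#' @export
fractionSample <- function(transcript_id, length, expected_count, fraction,
                           effective_length = length, gene_id = NA_character_,
                           replicateId = "rep1", depth = NULL) {
    n <- length(transcript_id)
    if (n == 0L) {
        q <- DataFrame(transcript_id = character(), gene_id = character(),
                       length = numeric(), effective_length = numeric(),
                       expected_count = numeric(), fpkm = numeric(),
                       cpm = numeric())
        return(new("FractionSample", fraction = fraction,
                   replicateId = replicateId, depth = NA_real_, quant = q))
    }
    derived <- is.null(depth)
    if (derived) depth <- sum(expected_count)
    if (is.na(depth) || depth <= 0)
        stop("data error: library depth is zero or undefined (no reads)")
    if (derived && abs(depth - sum(expected_count)) > 1e-6 * max(depth, 1))
        stop("derived depth inconsistent with counts")  # unreachable guard
    lenF <- .fpkmLength(length, effective_length)
    q <- DataFrame(
        transcript_id = as.character(transcript_id),
        gene_id = rep_len(as.character(gene_id), n),
        length = as.numeric(length),
        effective_length = as.numeric(effective_length),
        expected_count = as.numeric(expected_count),
        fpkm = computeFPKM(expected_count, lenF, depth),
        cpm = computeCPM(expected_count, depth)
    )
    new("FractionSample", fraction = fraction, replicateId = replicateId,
        depth = as.numeric(depth), quant = q)
}

#' Read an RSEM-style quantification table
#'
#' Reads a tab-separated transcript quantification table (header row;
#' case-insensitive column aliases accepted) into a
#' \linkS4class{FractionSample}.  Requires at least transcript id, length,
#' effective length and expected count columns; TPM/FPKM columns are
#' ignored since FPKM and CPM are recomputed from the counts for
#' consistency across fractions.
#'
#' @param path path to the table (e.g. an RSEM \code{isoforms.results} file).
#' @param fraction \code{"whole"}, \code{"nuclear"} or \code{"cytosolic"}.
#' @param replicateId replicate label.
#' @param depth override the library depth; by default the sum of
#'   expected counts.
#' @return a \linkS4class{FractionSample}.
#' @seealso [fractionSample()], [emitDataset()]
#' @export
readQuantTable <- function(path, fraction, replicateId = "rep1", depth = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    dt <- fread(path, sep = "\t", header = TRUE, data.table = TRUE)
    lc <- tolower(names(dt))
    col <- function(canon) {
        hit <- which(lc %in% .QUANT_ALIASES[[canon]])
        if (length(hit)) hit[1] else NA_integer_
    }
    required <- c("transcript_id", "length", "effective_length", "expected_count")
    idx <- vapply(required, col, integer(1))
    if (anyNA(idx)) {
        miss <- required[is.na(idx)]
        stop("format error: missing required column(s): ",
             paste(miss, collapse = ", "))
    }
    ids <- as.character(dt[[idx["transcript_id"]]])
    if (anyDuplicated(ids))
        stop("data error: duplicate transcript_id in ", path)
    gidx <- col("gene_id")
    fractionSample(
        transcript_id = ids,
        length = as.numeric(dt[[idx["length"]]]),
        expected_count = as.numeric(dt[[idx["expected_count"]]]),
        effective_length = as.numeric(dt[[idx["effective_length"]]]),
        gene_id = if (is.na(gidx)) NA_character_ else as.character(dt[[gidx]]),
        fraction = fraction, replicateId = replicateId, depth = depth
    )
}

## counts of a sample over an id universe, absent ids = 0
.countsOver <- function(sample, ids) {
    q <- quantData(sample)
    out <- setNames(numeric(length(ids)), ids)
    out[q$transcript_id[q$transcript_id %in% ids]] <-
        q$expected_count[q$transcript_id %in% ids]
    out
}

#' Expression filter over a matched whole/nuclear/cytosolic set
#'
#' Retains transcripts whose whole-cell expression is at least
#' \code{cpmThreshold} CPM \emph{and} whose expression in at least one of
#' the two fractions (nucleus or cytosol) also reaches the threshold.
#' Transcripts on an exclusion list (typically the mitochondrial
#' transcripts, which do not partition between nucleus and cytosol) are
#' dropped.  Missing transcripts in a fraction count as zero; CPM is
#' computed against each sample's full (pre-filter) depth, so filtering
#' does not change normalization.
#'
#' @param w,n,c \linkS4class{FractionSample}s of the whole-cell, nuclear and
#'   cytosolic libraries.
#' @param cpmThreshold detection threshold in CPM (default 1).
#' @param excludedIds character vector of transcript ids to drop
#'   unconditionally (e.g. chrM-encoded transcripts).
#' @return character vector of retained transcript ids (may be empty).
#' @export
filterExpression <- function(w, n, c, cpmThreshold = 1, excludedIds = character()) {
    stopifnot(is(w, "FractionSample"), is(n, "FractionSample"),
              is(c, "FractionSample"))
    ids <- sort(unique(c(quantData(w)$transcript_id,
                         quantData(n)$transcript_id,
                         quantData(c)$transcript_id)))
    if (!length(ids)) return(character())
    cpm1 <- function(s) computeCPM(.countsOver(s, ids), sampleDepth(s))
    keep <- cpm1(w) >= cpmThreshold &
        (cpm1(n) >= cpmThreshold | cpm1(c) >= cpmThreshold) &
        !(ids %in% excludedIds)
    ids[keep]
}

#' Mitochondrial transcript ids from a metadata table
#'
#' Convenience helper: given a transcript metadata data.frame with a
#' chromosome column, returns the ids on the mitochondrial chromosome
#' (named \code{"chrM"} or \code{"MT"}).
#'
#' @param metadata data.frame with columns \code{transcript_id} and
#'   \code{chromosome}.
#' @return character vector of mitochondrial transcript ids.
#' @export
mitochondrialIds <- function(metadata) {
    stopifnot(all(c("transcript_id", "chromosome") %in% colnames(metadata)))
    as.character(metadata$transcript_id[metadata$chromosome %in% c("chrM", "MT")])
}

#' Detection-based replicate reproducibility filter
#'
#' Optional substitute for a replicate-reproducibility step: keeps the
#' transcripts detected (expected count > 0) in \emph{every} supplied
#' sample, i.e. in all replicates of all three fractions.
#'
#' @param samples list of \linkS4class{FractionSample}s.
#' @return character vector of transcript ids detected throughout.
#' @export
filterDetected <- function(samples) {
    stopifnot(length(samples) >= 1L)
    detected <- lapply(samples, function(s) {
        q <- quantData(s)
        q$transcript_id[q$expected_count > 0]
    })
    Reduce(intersect, detected)
}

#' Assemble a matched FPKM triplet
#'
#' Aligns the three fraction samples over the retained transcript ids in
#' lexicographic order and recomputes FPKM from counts, lengths and the
#' pre-filter depths.  Transcripts absent from the nuclear or cytosolic
#' sample get zero FPKM there; every retained id must be present in the
#' whole-cell sample.
#'
#' @param w,n,c \linkS4class{FractionSample}s (whole, nuclear, cytosolic).
#' @param retained character vector of transcript ids to keep, typically
#'   from [filterExpression()].
#' @return a \linkS4class{MatchedTriplet}.
#' @export
buildTriplet <- function(w, n, c, retained) {
    if (!length(retained))
        stop("data error: empty retained set")
    ids <- sort(unique(as.character(retained)))
    qw <- quantData(w)
    if (!all(ids %in% qw$transcript_id))
        stop("data error: retained transcript(s) absent from the whole-cell sample: ",
             paste(utils::head(setdiff(ids, qw$transcript_id), 5), collapse = ", "))
    if (length(ids) < 50L)
        warning("triplet has ", length(ids),
                " transcripts; fewer than the recommended minimum of 50 for ",
                "a stable beta estimate")
    fpkmOver <- function(s) {
        q <- quantData(s)
        hit <- match(ids, q$transcript_id)
        counts <- ifelse(is.na(hit), 0, q$expected_count[hit])
        lenF <- ifelse(is.na(hit), 1,
                       .fpkmLength(q$length[hit], q$effective_length[hit]))
        computeFPKM(counts, lenF, sampleDepth(s))
    }
    m <- cbind(whole = fpkmOver(w), nuclear = fpkmOver(n),
               cytosolic = fpkmOver(c))
    rownames(m) <- ids
    se <- SummarizedExperiment(assays = list(fpkm = m))
    new("MatchedTriplet", se)
}

#' Construct a MatchedTriplet from FPKM vectors
#'
#' Low-level constructor used when FPKM values are already available (e.g.
#' in tests or from external quantifications).
#'
#' @param fpkm_w,fpkm_n,fpkm_c aligned non-negative FPKM vectors.
#' @param transcriptIds transcript ids; defaults to \code{tx_1 ... tx_n}.
#' @return a \linkS4class{MatchedTriplet}.
#' @export
matchedTriplet <- function(fpkm_w, fpkm_n, fpkm_c, transcriptIds = NULL) {
    t <- length(fpkm_w)
    if (length(fpkm_n) != t || length(fpkm_c) != t)
        stop("FPKM vectors must have equal length")
    if (is.null(transcriptIds)) transcriptIds <- sprintf("tx_%d", seq_len(t))
    m <- cbind(whole = as.numeric(fpkm_w), nuclear = as.numeric(fpkm_n),
               cytosolic = as.numeric(fpkm_c))
    rownames(m) <- as.character(transcriptIds)
    new("MatchedTriplet", SummarizedExperiment(assays = list(fpkm = m)))
}

#' Write a matched triplet as a tab-separated table
#'
#' Columns: \code{transcript_id}, \code{fpkm_w}, \code{fpkm_n},
#' \code{fpkm_c}.
#'
#' @param triplet a \linkS4class{MatchedTriplet}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTriplet <- function(triplet, path) {
    stopifnot(is(triplet, "MatchedTriplet"))
    m <- assay(triplet, "fpkm")
    fwrite(data.table::data.table(transcript_id = rownames(m),
                                  fpkm_w = m[, "whole"],
                                  fpkm_n = m[, "nuclear"],
                                  fpkm_c = m[, "cytosolic"]),
           path, sep = "\t")
    invisible(path)
}

#' Pool fraction samples into a pseudo-bulk sample
#'
#' Sums per-transcript counts and depths over samples of the same fraction
#' (e.g. single cells) and recomputes FPKM/CPM, producing one bulk-like
#' library per fraction.
#'
#' @param samples non-empty list of \linkS4class{FractionSample}s sharing
#'   the same fraction label.
#' @param replicateId label of the pooled sample.
#' @return a \linkS4class{FractionSample}.
#' @export
poolPseudobulk <- function(samples, replicateId = "pseudobulk") {
    if (!length(samples))
        stop("usage error: empty sample list")
    fr <- unique(vapply(samples, fractionType, character(1)))
    if (length(fr) != 1L)
        stop("usage error: samples mix fraction labels: ",
             paste(fr, collapse = ", "))
    ids <- sort(unique(unlist(lapply(samples,
        function(s) quantData(s)$transcript_id))))
    counts <- numeric(length(ids))
    len <- rep(NA_real_, length(ids))
    efflen <- rep(NA_real_, length(ids))
    gene <- rep(NA_character_, length(ids))
    for (s in samples) {
        q <- quantData(s)
        hit <- match(q$transcript_id, ids)
        counts[hit] <- counts[hit] + q$expected_count
        fill <- is.na(len[hit])
        len[hit][fill] <- q$length[fill]
        efflen[hit][fill] <- q$effective_length[fill]
        gene[hit][fill] <- q$gene_id[fill]
    }
    fractionSample(transcript_id = ids, length = len, expected_count = counts,
                   effective_length = efflen, gene_id = gene,
                   fraction = fr, replicateId = replicateId)
}
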