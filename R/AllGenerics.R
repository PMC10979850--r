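#' Accessors for locindex classes
#'
#' Small accessor generics exposing the slots of the package's S4 classes.
#'
#' @param x an object of the documented class.
#' @return the corresponding slot value.
#' @name locindex-accessors
NULL

#' @rdname locindex-accessors
#' @export
setGeneric("fractionType", function(x) standardGeneric("fractionType"))
#' @rdname locindex-accessors
#' @export
setMethod("fractionType", "FractionSample", function(x) x@fraction)

#' @rdname locindex-accessors
#' @export
setGeneric("replicateId", function(x) standardGeneric("replicateId"))
#' @rdname locindex-accessors
#' @export
setMethod("replicateId", "FractionSample", function(x) x@replicateId)

#' @rdname locindex-accessors
#' @export
setGeneric("sampleDepth", function(x) standardGeneric("sampleDepth"))
#' @rdname locindex-accessors
#' @export
setMethod("sampleDepth", "FractionSample", function(x) x@depth)

#' @rdname locindex-accessors
#' @export
setGeneric("quantData", function(x) standardGeneric("quantData"))
#' @rdname locindex-accessors
#' @export
setMethod("quantData", "FractionSample", function(x) x@quant)

#' @rdname locindex-accessors
#' @export
setGeneric("fpkmWhole", function(x) standardGeneric("fpkmWhole"))
#' @rdname locindex-accessors
#' @export
setMethod("fpkmWhole", "MatchedTriplet",
    function(x) assay(x, "fpkm")[, "whole"])

#' @rdname locindex-accessors
#' @export
setGeneric("fpkmNuclear", function(x) standardGeneric("fpkmNuclear"))
#' @rdname locindex-accessors
#' @export
setMethod("fpkmNuclear", "MatchedTriplet",
    function(x) assay(x, "fpkm")[, "nuclear"])

#' @rdname locindex-accessors
#' @export
setGeneric("fpkmCytosolic", function(x) standardGeneric("fpkmCytosolic"))
#' @rdname locindex-accessors
#' @export
setMethod("fpkmCytosolic", "MatchedTriplet",
    function(x) assay(x, "fpkm")[, "cytosolic"])

#' @rdname locindex-accessors
#' @export
setGeneric("betaDraws", function(x) standardGeneric("betaDraws"))
#' @rdname locindex-accessors
#' @export
setMethod("betaDraws", "BetaPosterior", function(x) x@draws[, "beta"])

#' @rdname locindex-accessors
#' @export
setGeneric("betaMap", function(x) standardGeneric("betaMap"))
#' @rdname locindex-accessors
#' @export
setMethod("betaMap", "BetaPosterior", function(x) x@betaMap)

#' @rdname locindex-accessors
#' @export
setGeneric("rhatBeta", function(x) standardGeneric("rhatBeta"))
#' @rdname locindex-accessors
#' @export
setMethod("rhatBeta", "BetaPosterior", function(x) x@rhatBeta)

#' @rdname locindex-accessors
#' @export
setGeneric("essBeta", function(x) standardGeneric("essBeta"))
#' @rdname locindex-accessors
#' @export
setMethod("essBeta", "BetaPosterior", function(x) x@essBeta)

#' @rdname locindex-accessors
#' @export
setGeneric("locRecords", function(x) standardGeneric("locRecords"))
#' @rdname locindex-accessors
#' @export
setMethod("locRecords", "LocalizationTable", function(x) x@records)

#' @rdname locindex-accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname locindex-accessors
#' @export
setMethod("sampleId", "LocalizationTable", function(x) x@sampleId)

#' @rdname locindex-accessors
#' @export
setGeneric("betaUsed", function(x) standardGeneric("betaUsed"))
#' @rdname locindex-accessors
#' @export
setMethod("betaUsed", "LocalizationTable", function(x) x@betaUsed)

#' @rdname locindex-accessors
#' @export
setGeneric("realizedBeta", function(x) standardGeneric("realizedBeta"))
#' @rdname locindex-accessors
#' @export
setMethod("realizedBeta", "SimTruth", function(x) x@realizedBeta)

#' @rdname locindex-accessors
#' @export
setGeneric("trueCytoFraction", function(x) standardGeneric("trueCytoFraction"))
#' @rdname locindex-accessors
#' @export
setMethod("trueCytoFraction", "SimTruth", function(x) x@trueCytoFraction)

#' @rdname locindex-accessors
#' @export
setGeneric("moleculeCounts", function(x) standardGeneric("moleculeCounts"))
#' @rdname locindex-accessors
#' @export
setMethod("moleculeCounts", "SimTruth", function(x) {
    data.frame(transcript_id = x@transcriptIds, m_w = x@mW, m_n = x@mN,
               m_c = x@mC, length = x@lengths, stringsAsFactors = FALSE)
})
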