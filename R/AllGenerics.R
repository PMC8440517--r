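#' Accessors for famcond classes
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("traitLabel", function(x) standardGeneric("traitLabel"))
#' @rdname accessors
#' @export
setMethod("traitLabel", "SumstatsTable", function(x) x@traitLabel)

#' @rdname accessors
#' @export
setGeneric("variantData", function(x) standardGeneric("variantData"))
#' @rdname accessors
#' @export
setMethod("variantData", "SumstatsTable", function(x) x@variants)

#' @rdname accessors
#' @export
setGeneric("phenotypeVariance", function(x) standardGeneric("phenotypeVariance"))
#' @rdname accessors
#' @export
setMethod("phenotypeVariance", "SumstatsTable", function(x) x@phenotypeVariance)

#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setMethod("nVariants", "SumstatsTable", function(x) nrow(x@variants))
#' @rdname accessors
#' @export
setMethod("nVariants", "HarmonizedSet", function(x) nrow(x@tables[[1]]@variants))
#' @rdname accessors
#' @export
setMethod("nVariants", "LDScorePanel", function(x) nrow(x@scores))

#' @rdname accessors
#' @export
setGeneric("harmonizedTables", function(x) standardGeneric("harmonizedTables"))
#' @rdname accessors
#' @export
setMethod("harmonizedTables", "HarmonizedSet", function(x) x@tables)

#' @rdname accessors
#' @export
setGeneric("droppedLog", function(x) standardGeneric("droppedLog"))
#' @rdname accessors
#' @export
setMethod("droppedLog", "HarmonizedSet", function(x) x@droppedLog)

#' @rdname accessors
#' @export
setGeneric("ldScores", function(x) standardGeneric("ldScores"))
#' @rdname accessors
#' @export
setMethod("ldScores", "LDScorePanel", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("mSnps", function(x) standardGeneric("mSnps"))
#' @rdname accessors
#' @export
setMethod("mSnps", "LDScorePanel", function(x) x@mSnps)

#' @rdname accessors
#' @export
setGeneric("effectLabels", function(x) standardGeneric("effectLabels"))
#' @rdname accessors
#' @export
setMethod("effectLabels", "PathModelSpec", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("effectLabels", "ConditionalEstimate", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("coefMatrix", function(x) standardGeneric("coefMatrix"))
#' @rdname accessors
#' @export
setMethod("coefMatrix", "PathModelSpec", function(x) x@A)

#' @rdname accessors
#' @export
setGeneric("intercept", function(x) standardGeneric("intercept"))
#' @rdname accessors
#' @export
setMethod("intercept", "InterceptEstimate", function(x) x@intercept)

#' @rdname accessors
#' @export
setGeneric("interceptSE", function(x) standardGeneric("interceptSE"))
#' @rdname accessors
#' @export
setMethod("interceptSE", "InterceptEstimate", function(x) x@interceptSE)

#' @rdname accessors
#' @export
setGeneric("ldscSlope", function(x) standardGeneric("ldscSlope"))
#' @rdname accessors
#' @export
setMethod("ldscSlope", "InterceptEstimate", function(x) x@slope)

#' @rdname accessors
#' @export
setGeneric("ldscSlopeSE", function(x) standardGeneric("ldscSlopeSE"))
#' @rdname accessors
#' @export
setMethod("ldscSlopeSE", "InterceptEstimate", function(x) x@slopeSE)

#' @rdname accessors
#' @export
setGeneric("nOverlap", function(x) standardGeneric("nOverlap"))
#' @rdname accessors
#' @export
setMethod("nOverlap", "OverlapEstimate", function(x) x@nOverlap)

#' @rdname accessors
#' @export
setGeneric("nOverlapRaw", function(x) standardGeneric("nOverlapRaw"))
#' @rdname accessors
#' @export
setMethod("nOverlapRaw", "OverlapEstimate", function(x) x@nOverlapRaw)

#' @rdname accessors
#' @export
setGeneric("rgEstimate", function(x) standardGeneric("rgEstimate"))
#' @rdname accessors
#' @export
setMethod("rgEstimate", "GeneticCorrelation", function(x) x@rg)

#' @rdname accessors
#' @export
setGeneric("rgSE", function(x) standardGeneric("rgSE"))
#' @rdname accessors
#' @export
setMethod("rgSE", "GeneticCorrelation", function(x) x@rgSE)

#' @rdname accessors
#' @export
setGeneric("betaAdj", function(x) standardGeneric("betaAdj"))
#' @rdname accessors
#' @export
setMethod("betaAdj", "ConditionalEstimate", function(x) x@betaAdj)

#' @rdname accessors
#' @export
setGeneric("covAdj", function(x) standardGeneric("covAdj"))
#' @rdname accessors
#' @export
setMethod("covAdj", "ConditionalEstimate", function(x) x@covAdj)

#' @rdname accessors
#' @export
setGeneric("seAdj", function(x) standardGeneric("seAdj"))
#' @rdname accessors
#' @export
setMethod("seAdj", "ConditionalEstimate", function(x)
  setNames(sqrt(diag(x@covAdj)), x@labels))

#' @rdname accessors
#' @export
setGeneric("waldP", function(x) standardGeneric("waldP"))
#' @rdname accessors
#' @export
setMethod("waldP", "ConditionalEstimate", function(x) x@waldP)
#' @rdname accessors
#' @export
setMethod("waldP", "SemFit", function(x) x@waldP)

#' @rdname accessors
#' @export
setGeneric("semTheta", function(x) standardGeneric("semTheta"))
#' @rdname accessors
#' @export
setMethod("semTheta", "SemFit", function(x) x@theta)

#' @rdname accessors
#' @export
setGeneric("semCov", function(x) standardGeneric("semCov"))
#' @rdname accessors
#' @export
setMethod("semCov", "SemFit", function(x) x@covTheta)

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setMethod("isConverged", "SemFit", function(x) x@converged)

#' @rdname accessors
#' @export
setGeneric("sentinels", function(x) standardGeneric("sentinels"))
#' @rdname accessors
#' @export
setMethod("sentinels", "LocusSet", function(x) x@sentinels)

#' @rdname accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @rdname accessors
#' @export
setMethod("nLoci", "LocusSet", function(x) nrow(x@sentinels))

#' @rdname accessors
#' @export
setGeneric("familyGenotypes", function(x) standardGeneric("familyGenotypes"))
#' @rdname accessors
#' @export
setMethod("familyGenotypes", "FamilyDataset", function(x) x@genotypes)

#' @rdname accessors
#' @export
setGeneric("familyPhenotypes", function(x) standardGeneric("familyPhenotypes"))
#' @rdname accessors
#' @export
setMethod("familyPhenotypes", "FamilyDataset", function(x) x@phenotypes)

#' @rdname accessors
#' @export
setGeneric("trueEffects", function(x) standardGeneric("trueEffects"))
#' @rdname accessors
#' @export
setMethod("trueEffects", "FamilyDataset", function(x) x@trueEffects)

#' @rdname accessors
#' @export
setGeneric("sampleMasks", function(x) standardGeneric("sampleMasks"))
#' @rdname accessors
#' @export
setMethod("sampleMasks", "FamilyDataset", function(x) x@masks)
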