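#' @rdname AminoAcidIndex-class
#' @param object,x An object.
#' @export
setGeneric("accession", function(object) standardGeneric("accession"))

#' @rdname AminoAcidIndex-class
#' @export
setGeneric("indexValues", function(object) standardGeneric("indexValues"))

#' @rdname Structure-class
#' @export
setGeneric("structureId", function(object) standardGeneric("structureId"))

#' @rdname Structure-class
#' @export
setGeneric("atomTable", function(object) standardGeneric("atomTable"))

#' @rdname Structure-class
#' @export
setGeneric("chainIds", function(object) standardGeneric("chainIds"))

#' @rdname Structure-class
#' @export
setGeneric("residueTable", function(object) standardGeneric("residueTable"))

#' @rdname Structure-class
#' @export
setGeneric("chainSequences", function(object) standardGeneric("chainSequences"))

#' @rdname PpirMap-class
#' @export
setGeneric("residueMap", function(object) standardGeneric("residueMap"))

#' @rdname PpirMap-class
#' @export
setGeneric("contactPairs", function(object) standardGeneric("contactPairs"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureInfo", function(object) standardGeneric("featureInfo"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureData", function(object) standardGeneric("featureData"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("windowLabels", function(object) standardGeneric("windowLabels"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("indexAccessions", function(object) standardGeneric("indexAccessions"))

#' @rdname FeatureMatrix-class
#' @param accessions Character vector of index accessions to keep.
#' @export
setGeneric("indexBlock", function(object, accessions) standardGeneric("indexBlock"))
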