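#' @name accessors
#' @title Accessors for TrackPheno classes
#' @description Small accessor generics; prefer these over direct slot
#'   access.
#' @param object a TrackPheno object.
NULL

#' @rdname accessors
#' @export
setGeneric("trackData", function(object) standardGeneric("trackData"))

#' @rdname accessors
#' @export
setGeneric("trackIds", function(object) standardGeneric("trackIds"))

#' @rdname accessors
#' @export
setGeneric("nTracks", function(object) standardGeneric("nTracks"))

#' @rdname accessors
#' @export
setGeneric("timeGrid", function(object) standardGeneric("timeGrid"))

#' @rdname accessors
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))

#' @rdname accessors
#' @export
setGeneric("tensorValues", function(object) standardGeneric("tensorValues"))

#' @rdname accessors
#' @export
setGeneric("explainedVariance",
           function(object) standardGeneric("explainedVariance"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("clusterEmbedding",
           function(object) standardGeneric("clusterEmbedding"))

#' @rdname accessors
#' @export
setGeneric("clusterSummary",
           function(object) standardGeneric("clusterSummary"))

#' @rdname accessors
#' @export
setGeneric("componentPoints",
           function(object) standardGeneric("componentPoints"))
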