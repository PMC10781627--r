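#' @rdname GenomeMap-class
#' @param x a GenomeMap
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))

#' @rdname GenomeMap-class
#' @export
setGeneric("chromLengthsBp", function(x) standardGeneric("chromLengthsBp"))

#' @rdname GenomeMap-class
#' @export
setGeneric("chromLengthsCm", function(x) standardGeneric("chromLengthsCm"))

#' @rdname GenomeMap-class
#' @export
setGeneric("totalCm", function(x) standardGeneric("totalCm"))

#' @rdname IBDSegments-class
#' @param x an IBDSegments object
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' @rdname SharingMatrix-class
#' @param x a SharingMatrix
#' @export
setGeneric("sharingValues", function(x) standardGeneric("sharingValues"))

#' @rdname ClusterHierarchy-class
#' @param x a ClusterHierarchy
#' @export
setGeneric("leafLabels", function(x) standardGeneric("leafLabels"))

#' @rdname ClusterHierarchy-class
#' @export
setGeneric("leaves", function(x) standardGeneric("leaves"))
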