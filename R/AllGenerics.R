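#' @include AllClasses.R
NULL

#' Accessors for karyoDosage classes
#'
#' Small accessor generics in the Bioconductor style: slot access stays
#' behind functions.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @rdname accessors
#' @export
setGeneric("centromeres", function(x) standardGeneric("centromeres"))
#' @rdname accessors
#' @export
setGeneric("relativeSizes", function(x) standardGeneric("relativeSizes"))
#' @rdname accessors
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))
#' @rdname accessors
#' @export
setGeneric("geneCounts", function(x) standardGeneric("geneCounts"))
#' @rdname accessors
#' @export
setGeneric("linkCounts", function(x) standardGeneric("linkCounts"))

#' @rdname accessors
#' @export
setGeneric("wholeDelta", function(x) standardGeneric("wholeDelta"))
#' @rdname accessors
#' @export
setGeneric("shortArmDelta", function(x) standardGeneric("shortArmDelta"))
#' @rdname accessors
#' @export
setGeneric("longArmDelta", function(x) standardGeneric("longArmDelta"))
#' @rdname accessors
#' @export
setGeneric("isEuploid", function(x) standardGeneric("isEuploid"))

#' @rdname accessors
#' @export
setGeneric("individualId", function(x) standardGeneric("individualId"))
#' @rdname accessors
#' @export
setGeneric("depthWindows", function(x) standardGeneric("depthWindows"))
#' @rdname accessors
#' @export
setGeneric("totalCount", function(x) standardGeneric("totalCount"))
#' @rdname accessors
#' @export
setGeneric("chromCounts", function(x) standardGeneric("chromCounts"))

#' @rdname accessors
#' @export
setGeneric("coverageValues", function(x) standardGeneric("coverageValues"))
#' @rdname accessors
#' @export
setGeneric("meanDepth", function(x) standardGeneric("meanDepth"))

#' @rdname accessors
#' @export
setGeneric("gainThresholds", function(x) standardGeneric("gainThresholds"))
#' @rdname accessors
#' @export
setGeneric("lossThresholds", function(x) standardGeneric("lossThresholds"))

#' @rdname accessors
#' @export
setGeneric("calledKaryotype", function(x) standardGeneric("calledKaryotype"))
#' @rdname accessors
#' @export
setGeneric("classification", function(x) standardGeneric("classification"))
#' @rdname accessors
#' @export
setGeneric("callEvents", function(x) standardGeneric("callEvents"))

#' @rdname accessors
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))
#' @rdname accessors
#' @export
setGeneric("trueKaryotypes", function(x) standardGeneric("trueKaryotypes"))
#' @rdname accessors
#' @export
setGeneric("karyotypeLabels", function(x) standardGeneric("karyotypeLabels"))
#' @rdname accessors
#' @export
setGeneric("traitMatrix", function(x) standardGeneric("traitMatrix"))
#' @rdname accessors
#' @export
setGeneric("crossDirection", function(x) standardGeneric("crossDirection"))
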