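#' @rdname GermlineReference-class
#' @param object,x a `GermlineReference` or `TagGroupSet`.
#' @export
setGeneric("segmentNames", function(object) standardGeneric("segmentNames"))

#' @rdname GermlineReference-class
#' @export
setGeneric("segmentKind", function(object) standardGeneric("segmentKind"))

#' @rdname GermlineReference-class
#' @export
setGeneric("anchorPos", function(object) standardGeneric("anchorPos"))

#' @rdname GermlineReference-class
#' @param kind optional kind filter (`"V"`, `"J"` or `"C"`).
#' @export
setGeneric("segmentSeqs", function(object, kind = NULL) standardGeneric("segmentSeqs"))

#' @rdname TagGroupSet-class
#' @export
setGeneric("tags", function(object) standardGeneric("tags"))

#' @rdname TagGroupSet-class
#' @export
setGeneric("readCounts", function(object) standardGeneric("readCounts"))

#' @rdname TagGroupSet-class
#' @export
setGeneric("derivativeOf", function(object) standardGeneric("derivativeOf"))

#' @rdname TagGroupSet-class
#' @export
setGeneric("tagReads", function(object) standardGeneric("tagReads"))

#' @rdname TagLengthReport-class
#' @param object a `TagLengthReport`.
#' @export
setGeneric("readThreshold", function(object) standardGeneric("readThreshold"))
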