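#' Generic positions carried by an object
#'
#' For a [ContactSet-class] the positions within the cutoff; for a
#' [SiteProfile-class] every profiled position.
#' @param object a `ContactSet` or `SiteProfile`.
#' @return character vector of generic positions.
#' @export
setGeneric("sitePositions", function(object) standardGeneric("sitePositions"))

#' Receptor identifier of an object
#' @param object an object carrying a receptor id.
#' @export
setGeneric("receptorId", function(object) standardGeneric("receptorId"))

#' Segment table of an annotation
#' @param object a [ReceptorAnnotation-class].
#' @export
setGeneric("segments", function(object) standardGeneric("segments"))

#' Amino-acid sequence of an annotation
#' @param object a [ReceptorAnnotation-class].
#' @export
setGeneric("receptorSequence", function(object) standardGeneric("receptorSequence"))

#' Contact table of a ContactSet
#' @param object a [ContactSet-class].
#' @export
setGeneric("contactTable", function(object) standardGeneric("contactTable"))

#' Evidence table of a SiteProfile
#' @param object a [SiteProfile-class].
#' @export
setGeneric("profileTable", function(object) standardGeneric("profileTable"))
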