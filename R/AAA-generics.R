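#' Accessor generics
#'
#' Small accessor generics shared by the fuseAE container classes:
#' `modality()` returns the modality tag of an [OmicsMatrix] or
#' [HiddenFeatures] object, `sampleIds()`/`featureIds()` the sample and
#' feature identifiers, `omicsValues()` the samples x features value
#' matrix, `survTimes()`/`eventIndicator()` the survival fields,
#' `latentMatrix()` the samples x latent-dim matrix of hidden features
#' and `foldValues()` the per-fold metric values of a [MetricsReport].
#'
#' @param x an object of the documented class
#' @return the corresponding slot value (see Description)
#' @name accessors
#' @aliases modality sampleIds featureIds omicsValues survTimes
#'   eventIndicator latentMatrix foldValues
#' @examples
#' om <- OmicsMatrix(matrix(1:6, 2, 3), modality = "GeneExp")
#' modality(om)
#' dim(omicsValues(om))
NULL

#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname accessors
#' @export
setGeneric("omicsValues", function(x) standardGeneric("omicsValues"))

#' @rdname accessors
#' @export
setGeneric("survTimes", function(x) standardGeneric("survTimes"))

#' @rdname accessors
#' @export
setGeneric("eventIndicator", function(x) standardGeneric("eventIndicator"))

#' @rdname accessors
#' @export
setGeneric("latentMatrix", function(x) standardGeneric("latentMatrix"))

#' @rdname accessors
#' @export
setGeneric("foldValues", function(x) standardGeneric("foldValues"))
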