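#' @rdname standardize
#' @export
setGeneric("standardize", function(x, ...) standardGeneric("standardize"))

#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("isStandardized", function(x) standardGeneric("isStandardized"))

#' @rdname assocMatrix
#' @export
setGeneric("assocMatrix", function(object) standardGeneric("assocMatrix"))

#' @rdname assocMatrix
#' @export
setGeneric("groupAssoc", function(object) standardGeneric("groupAssoc"))

#' @rdname assocMatrix
#' @export
setGeneric("indivAssoc", function(object) standardGeneric("indivAssoc"))

#' @rdname assocMatrix
#' @export
setGeneric("confounders", function(object) standardGeneric("confounders"))

#' @rdname assocMatrix
#' @export
setGeneric("objectiveTrace", function(object) standardGeneric("objectiveTrace"))

#' @rdname geqtlObjective
#' @export
setGeneric("geqtlObjective", function(object, X, Z, ...)
  standardGeneric("geqtlObjective"))

#' @rdname snr
#' @export
setGeneric("snr", function(object, ...) standardGeneric("snr"))
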