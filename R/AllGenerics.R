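#' @title Generics for screen-data accessors
#' @description Accessor generics shared by the plate/screen classes.
#' @param x an object
#' @param ... further arguments for methods
#' @name crispa-generics
NULL

#' @rdname crispa-generics
#' @export
setGeneric("plateId", function(x) standardGeneric("plateId"))

#' @rdname crispa-generics
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname crispa-generics
#' @export
setGeneric("plateFormat", function(x) standardGeneric("plateFormat"))

#' @rdname crispa-generics
#' @export
setGeneric("layoutEntries", function(x) standardGeneric("layoutEntries"))

#' @rdname crispa-generics
#' @export
setGeneric("geneEffects", function(x) standardGeneric("geneEffects"))

#' @rdname crispa-generics
#' @export
setGeneric("screenId", function(x) standardGeneric("screenId"))

#' @rdname crispa-generics
#' @export
setGeneric("screenRecords", function(x) standardGeneric("screenRecords"))

#' @rdname crispa-generics
#' @export
setGeneric("normState", function(x) standardGeneric("normState"))

#' @rdname crispa-generics
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))

#' @rdname crispa-generics
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))

#' @rdname crispa-generics
#' @export
setGeneric("termInfo", function(x) standardGeneric("termInfo"))

#' @rdname crispa-generics
#' @export
setGeneric("termGenes", function(x, ...) standardGeneric("termGenes"))

#' @rdname crispa-generics
#' @export
setGeneric("termParents", function(x) standardGeneric("termParents"))
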