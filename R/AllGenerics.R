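#' @include AllClasses.R
NULL

#' @rdname registerCompound
#' @export
setGeneric("registerCompound", function(registry, input, ...)
  standardGeneric("registerCompound"))

#' @rdname bulkRegister
#' @export
setGeneric("bulkRegister", function(registry, inputs, ...)
  standardGeneric("bulkRegister"))

#' @rdname queryCompound
#' @export
setGeneric("queryCompound", function(registry, input, ...)
  standardGeneric("queryCompound"))

#' @rdname queryConformers
#' @export
setGeneric("queryConformers", function(registry, molregnos, ...)
  standardGeneric("queryConformers"))

#' @rdname retrieveCompound
#' @export
setGeneric("retrieveCompound", function(registry, ids, ...)
  standardGeneric("retrieveCompound"))
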