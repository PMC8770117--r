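#' @rdname computeCPM
#' @export
setGeneric("computeCPM", function(x, ...) standardGeneric("computeCPM"))

#' @rdname logTransform
#' @export
setGeneric("logTransform", function(x, ...) standardGeneric("logTransform"))

#' @rdname applyCorrection
#' @export
setGeneric("applyCorrection",
           function(model, x, ...) standardGeneric("applyCorrection"))
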