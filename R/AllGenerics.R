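#' @title Generics for camix containers
#' @description Accessor generics for the core S4 containers.
#' @param x an object
#' @param object an object
#' @name camix-generics
#' @keywords internal
NULL

#' @rdname camix-generics
#' @export
setGeneric("curveDist", function(x) standardGeneric("curveDist"))

#' @rdname camix-generics
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))

#' @rdname camix-generics
#' @export
setGeneric("pairCounts", function(x) standardGeneric("pairCounts"))

#' @rdname camix-generics
#' @export
setGeneric("admixtureProportion", function(x) standardGeneric("admixtureProportion"))

#' @rdname camix-generics
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))

#' @rdname camix-generics
#' @export
setGeneric("timeWindow", function(x) standardGeneric("timeWindow"))

#' @rdname camix-generics
#' @export
setGeneric("bestModels", function(x) standardGeneric("bestModels"))

#' @rdname camix-generics
#' @export
setGeneric("isUndetermined", function(x) standardGeneric("isUndetermined"))

#' @rdname camix-generics
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname camix-generics
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))
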