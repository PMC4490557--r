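#' @name riboFRET-generics
#' @title Accessor generics
#' @description Accessors for the core riboFRET classes.
#' @param x,object an riboFRET object
#' @param ... further arguments for methods
NULL

#' @rdname riboFRET-generics
#' @export
setGeneric("stateNames", function(x) standardGeneric("stateNames"))

#' @rdname riboFRET-generics
#' @export
setGeneric("fretMean", function(x) standardGeneric("fretMean"))

#' @rdname riboFRET-generics
#' @export
setGeneric("fretSd", function(x) standardGeneric("fretSd"))

#' @rdname riboFRET-generics
#' @export
setGeneric("rateMatrix", function(x) standardGeneric("rateMatrix"))

#' @rdname riboFRET-generics
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' Stationary distribution of a kinetic scheme
#'
#' Solves pi Q = 0 with sum(pi) = 1 for the continuous-time generator Q built
#' from the off-diagonal rate matrix (diagonal = negative row sums). States
#' that are unreachable sinks of mass are handled by the linear solve itself.
#'
#' @param x a [KineticScheme-class]
#' @return named numeric vector of stationary occupancies
#' @export
setGeneric("stationaryDistribution",
           function(x) standardGeneric("stationaryDistribution"))

#' @rdname riboFRET-generics
#' @export
setGeneric("traceIDs", function(x) standardGeneric("traceIDs"))

#' @rdname riboFRET-generics
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname riboFRET-generics
#' @export
setGeneric("traceData", function(x) standardGeneric("traceData"))

#' @rdname riboFRET-generics
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname riboFRET-generics
#' @export
setGeneric("modelSummary", function(x) standardGeneric("modelSummary"))
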