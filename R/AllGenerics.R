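#' @rdname NetworkGeometry-class
#' @param object,x an object
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname NetworkGeometry-class
#' @export
setGeneric("areas", function(x) standardGeneric("areas"))

#' @rdname NetworkGeometry-class
#' @export
setGeneric("isExcitatory", function(x) standardGeneric("isExcitatory"))

#' @rdname SimulationResult-class
#' @export
setGeneric("voltageTraces", function(x) standardGeneric("voltageTraces"))

#' @rdname SimulationResult-class
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @rdname SimulationResult-class
#' @export
setGeneric("diseaseClass", function(x) standardGeneric("diseaseClass"))

#' @rdname SimulationResult-class
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname SimulationResult-class
#' @export
setGeneric("firingRates", function(x, ...) standardGeneric("firingRates"))
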