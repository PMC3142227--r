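#' @rdname speciesNames
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname speciesNames
#' @export
setGeneric("variableSpecies", function(x) standardGeneric("variableSpecies"))

#' @rdname speciesNames
#' @export
setGeneric("constantSpecies", function(x) standardGeneric("constantSpecies"))

#' @rdname speciesNames
#' @export
setGeneric("initConc", function(x) standardGeneric("initConc"))

#' @rdname stoichiometricMatrix
#' @export
setGeneric("stoichiometricMatrix",
           function(net) standardGeneric("stoichiometricMatrix"))

#' @rdname sampleTrace
#' @export
setGeneric("sampleTrace", function(trace, species, T, N, dt)
  standardGeneric("sampleTrace"))

#' @rdname signal-accessors
#' @export
setGeneric("samplingFrequency", function(x) standardGeneric("samplingFrequency"))
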