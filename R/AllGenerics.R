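#' @rdname bodyWeight
#' @export
setGeneric("bodyWeight", function(phys, age) standardGeneric("bodyWeight"))

#' @rdname organVolume
#' @export
setGeneric("organVolume", function(phys, tissue, age) standardGeneric("organVolume"))

#' @rdname gfr
#' @export
setGeneric("gfr", function(phys, age, ...) standardGeneric("gfr"))

#' @rdname boneRates
#' @export
setGeneric("boneRates", function(phys, age) standardGeneric("boneRates"))

#' @rdname scheduleTotals
#' @export
setGeneric("scheduleTotals", function(schedule, window = NULL)
  standardGeneric("scheduleTotals"))

#' @rdname writeSchedule
#' @export
setGeneric("writeSchedule", function(schedule, path) standardGeneric("writeSchedule"))

#' @rdname simulateIndividual
#' @export
setGeneric("simulateIndividual", function(individual, scenario, ...)
  standardGeneric("simulateIndividual"))

#' @rdname simulatePopulation
#' @export
setGeneric("simulatePopulation", function(population, scenario, ...)
  standardGeneric("simulatePopulation"))

#' @rdname bodyBurden
#' @export
setGeneric("bodyBurden", function(x, age, ...) standardGeneric("bodyBurden"))

#' @rdname populationQuantiles
#' @export
setGeneric("populationQuantiles", function(x, tissue, ...)
  standardGeneric("populationQuantiles"))
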