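#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

COMPARTMENT_ASSAYS <- c("plasma", "liver", "brain", "bone", "rest",
                        "urine", "oralAbsorbed", "depotReleased")

#' Simulate a virtual population under a scenario
#'
#' Runs [simulateIndividual()] for every individual on the shared readout grid
#' and assembles an [AlExposureExperiment-class] (rows = readout times,
#' columns = individuals, one assay of amounts per compartment).
#'
#' @param population a [VirtualPopulation-class].
#' @param scenario an [ExposureScenario-class].
#' @param params a [ModelParams-class].
#' @param phys a [Physiology-class].
#' @param tEnd horizon in years.
#' @param atol,rtol solver tolerances.
#' @param readoutDays readout interval in days.
#' @param checkBalance mass-balance tolerance applied to every individual
#'   (set \code{NULL} to skip).
#' @param ... unused.
#' @return an [AlExposureExperiment-class].
#' @rdname simulatePopulation
#' @export
setMethod("simulatePopulation", "VirtualPopulation",
  function(population, scenario, params = ModelParams(),
           phys = defaultPhysiology(), tEnd = 50, atol = 1e-9, rtol = 1e-6,
           readoutDays = 7, checkBalance = 1e-3, ...) {
  pp <- population@params
  trajs <- lapply(seq_len(nrow(pp)), function(i) {
    traj <- simulateIndividual(pp[i, , drop = FALSE], scenario,
                               params = params, phys = phys, tEnd = tEnd,
                               atol = atol, rtol = rtol,
                               readoutDays = readoutDays)
    if (!is.null(checkBalance)) {
      err <- massBalance(traj, tol = Inf)
      if (err > checkBalance)
        stop(sprintf("mass-balance violation (%.3g) for individual %d", err,
                     pp$id[i]))
    }
    traj
  })
  ref <- trajs[[1L]]
  assayList <- lapply(COMPARTMENT_ASSAYS, function(a)
    vapply(trajs, function(tr) tr[[a]], numeric(nrow(ref))))
  names(assayList) <- COMPARTMENT_ASSAYS
  se <- SummarizedExperiment(
    assays = assayList,
    rowData = DataFrame(time_days = ref$time_days, age_years = ref$age_years),
    colData = DataFrame(pp, row.names = paste0("ind", pp$id)),
    metadata = list(scenario = scenario, params = params, phys = phys,
                    seed = population@seed,
                    solver = list(atol = atol, rtol = rtol,
                                  readoutDays = readoutDays, tEnd = tEnd)))
  new("AlExposureExperiment", se)
})

#' Readout ages of an experiment
#' @param x an [AlExposureExperiment-class].
#' @return numeric vector of ages in years.
#' @export
readoutAges <- function(x) rowData(x)$age_years

#' Concentration matrix for a tissue
#'
#' Amounts divided by the age-dependent organ volume (plasma: ug/L; tissues:
#' ug/g ww at density 1 g/mL).
#'
#' @param x an [AlExposureExperiment-class].
#' @param tissue one of plasma, liver, brain, bone, rest.
#' @return matrix (readout times x individuals).
#' @export
concentrations <- function(x, tissue) {
  tissue <- match.arg(tissue, MODEL_TISSUES)
  phys <- metadata(x)$phys
  vol <- organVolume(phys, tissue, readoutAges(x))
  if (tissue != "plasma") vol <- vol * 1000
  assay(x, tissue) / vol
}

setMethod("show", "AlExposureExperiment", function(object) {
  cat("AlExposureExperiment: scenario '", metadata(object)$scenario@name,
      "', ", ncol(object), " individuals, ", nrow(object),
      " readouts to ", max(readoutAges(object)), " y\n", sep = "")
})
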