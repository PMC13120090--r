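#' Construct a VariabilitySpec
#'
#' @param cvOralF,cvGfr,cvDist,cvKabs,cvInit coefficients of variation
#'   (fractions) for the lognormal inter-individual factors; the single
#'   literature-anchored value 0.5 is the default throughout.
#' @return a [VariabilitySpec-class].
#' @export
VariabilitySpec <- function(cvOralF = 0.5, cvGfr = 0.5, cvDist = 0.5,
                            cvKabs = 0.5, cvInit = 0.5) {
  new("VariabilitySpec", cvOralF = cvOralF, cvGfr = cvGfr, cvDist = cvDist,
      cvKabs = cvKabs, cvInit = cvInit)
}

# sdlog of a median-1 lognormal with the given coefficient of variation
cvToSdlog <- function(cv) sqrt(log(1 + cv^2))

# counter-based per-individual substream seed; keeps the i-th individual's
# draws independent of n and of scenario content
individualSeed <- function(seed, id) {
  as.integer((as.double(seed) * 48271 + as.double(id) * 16807) %% 2147483647)
}

#' Sample a virtual population
#'
#' Draws \code{n} female virtual individuals. Every parameter factor is
#' lognormal with median 1 and \code{sdlog = sqrt(log(1 + CV^2))}; initial
#' organ concentrations at birth are lognormal around the medians in
#' \code{params@initLevels} (plasma median 2.2 ug/L by default). Each
#' individual is drawn from its own counter-based substream of the master
#' seed, so the population is bit-identical across scenario runs and the first
#' k individuals of a larger population equal the population of size k.
#'
#' @param n number of individuals (the study cohort size is 500).
#' @param seed master seed (integer).
#' @param spec a [VariabilitySpec-class].
#' @param params a [ModelParams-class] supplying the initial-level medians.
#' @return a [VirtualPopulation-class].
#' @examples
#' pop <- samplePopulation(5, seed = 1)
#' @export
samplePopulation <- function(n, seed = 1L, spec = VariabilitySpec(),
                             params = ModelParams()) {
  if (n < 1) stop("n must be at least 1")
  sdF <- cvToSdlog(spec@cvOralF); sdG <- cvToSdlog(spec@cvGfr)
  sdD <- cvToSdlog(spec@cvDist); sdK <- cvToSdlog(spec@cvKabs)
  sdI <- cvToSdlog(spec@cvInit)
  med <- params@initLevels
  z <- vapply(seq_len(n), function(i) {
    set.seed(individualSeed(seed, i))
    stats::rnorm(11)
  }, numeric(11))
  sds <- c(sdF, sdG, sdD, sdK, sdK, sdK, rep(sdI, 5))
  fac <- exp(z * sds)                      # 11 x n, sds recycled column-wise
  meds <- c(rep(1, 6), med[c("plasma", "liver", "brain", "bone", "rest")])
  p <- data.frame(seq_len(n), t(fac * meds))
  names(p) <- c("id", "fOral", "fGfr", "fDist", "fKabsAH", "fKabsAP",
                "fKabsAAHS", "initPlasma", "initLiver", "initBrain",
                "initBone", "initRest")
  new("VirtualPopulation", params = p, seed = as.integer(seed), spec = spec)
}

#' The median ("typical") individual
#'
#' All factors exactly 1 and initial levels at their medians; the deterministic
#' reference subject of the population.
#'
#' @param params a [ModelParams-class].
#' @return one-row individual parameter data.frame.
#' @export
typicalIndividual <- function(params = ModelParams()) {
  med <- params@initLevels
  data.frame(id = 0L, fOral = 1, fGfr = 1, fDist = 1,
             fKabsAH = 1, fKabsAP = 1, fKabsAAHS = 1,
             initPlasma = med[["plasma"]], initLiver = med[["liver"]],
             initBrain = med[["brain"]], initBone = med[["bone"]],
             initRest = med[["rest"]])
}

#' Initial compartment amounts at birth
#'
#' Converts an individual's sampled initial concentrations into compartment
#' amounts using the age-0 physiology: plasma amount = concentration (ug/L) x
#' central volume (L); tissue amounts = concentration (ug/g ww) x tissue mass
#' (g, density 1 g/mL).
#'
#' @param individual one row of [VirtualPopulation-class] params (or
#'   [typicalIndividual()]).
#' @param phys a [Physiology-class].
#' @return named numeric amounts in ug for plasma, liver, brain, bone, rest.
#' @export
initialAmounts <- function(individual, phys) {
  v <- vapply(MODEL_TISSUES, function(tt) organVolume(phys, tt, 0), numeric(1))
  c(plasma = individual$initPlasma * v[["plasma"]],
    liver = individual$initLiver * v[["liver"]] * 1000,
    brain = individual$initBrain * v[["brain"]] * 1000,
    bone = individual$initBone * v[["bone"]] * 1000,
    rest = individual$initRest * v[["rest"]] * 1000)
}

setMethod("show", "VirtualPopulation", function(object) {
  cat("VirtualPopulation:", nrow(object@params), "individuals, seed",
      object@seed, "\n")
})

#' Write a population audit dump
#'
#' @param population a [VirtualPopulation-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writePopulation <- function(population, path) {
  utils::write.csv(population@params, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
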