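#' @import methods
#' @importFrom stats approxfun quantile setNames median
NULL

DAYS_PER_YEAR <- 365.25
WEEKS_PER_YEAR <- 365.25 / 7
PMA_AT_TERM_BIRTH <- 40           # postmenstrual age at full-term birth, weeks
MODEL_TISSUES <- c("plasma", "liver", "brain", "bone", "rest")
PH_EUR_DOSE_LIMIT_MG <- 1.25      # Ph. Eur. cap on Al per vaccine dose

#' Age-dependent female reference physiology
#'
#' Holds the growth/organ-volume table, the calcium kinetic table driving the
#' bone submodel, and the renal (GFR maturation) model. Tables span ages 0-50
#' years; lookups outside that range are errors, never extrapolated.
#'
#' @slot growth data.frame with columns \code{age_years}, \code{bw_kg} and
#'   volume fractions \code{frac_plasma}, \code{frac_liver}, \code{frac_brain},
#'   \code{frac_bone}, \code{frac_rest} (unitless, density 1 kg/L). The
#'   "plasma" fraction is the central (plasma-equivalent extracellular)
#'   distribution volume; see the package vignette.
#' @slot ca data.frame with columns \code{age_years}, \code{v_acc_mg_d}
#'   (calcium accretion flux, mg Ca/day), \code{v_res_mg_d} (calcium
#'   resorption flux, mg Ca/day), \code{m_ca_g} (exchangeable bone calcium
#'   mass, g).
#' @slot renal list with \code{gfrAdult} (L/day for the reference adult),
#'   \code{pma50} (weeks postmenstrual age at half-maturation), \code{gamma}
#'   (Hill exponent), \code{sizeExp} (allometric exponent), \code{refBw}
#'   (reference adult body weight, kg).
#' @export
setClass("Physiology",
  slots = c(growth = "data.frame", ca = "data.frame", renal = "list"))

setValidity("Physiology", function(object) {
  g <- object@growth
  need <- c("age_years", "bw_kg", paste0("frac_", MODEL_TISSUES))
  if (!all(need %in% names(g)))
    return(paste("growth table must have columns:", paste(need, collapse = ", ")))
  if (is.unsorted(g$age_years, strictly = TRUE))
    return("growth ages must be strictly increasing")
  if (any(g$bw_kg <= 0) || is.unsorted(g$bw_kg))
    return("body weight must be positive and non-decreasing")
  fr <- as.matrix(g[paste0("frac_", MODEL_TISSUES)])
  if (any(fr <= 0) || any(fr >= 1))
    return("organ volume fractions must lie in (0, 1)")
  if (any(rowSums(fr) > 1))
    return("sum of modelled organ fractions exceeds 1")
  ca <- object@ca
  needCa <- c("age_years", "v_acc_mg_d", "v_res_mg_d", "m_ca_g")
  if (!all(needCa %in% names(ca)))
    return(paste("ca table must have columns:", paste(needCa, collapse = ", ")))
  if (any(as.matrix(ca[-1]) < 0)) return("Ca kinetic quantities must be non-negative")
  if (any(ca$m_ca_g == 0)) return("degenerate Ca table: m_ca_g = 0")
  if (is.unsorted(ca$m_ca_g)) return("exchangeable bone Ca mass must be non-decreasing")
  r <- object@renal
  needR <- c("gfrAdult", "pma50", "gamma", "sizeExp", "refBw")
  if (!all(needR %in% names(r))) return("renal model incomplete")
  if (r$gfrAdult <= 0 || r$pma50 <= 0 || r$gamma <= 0 || r$refBw <= 0)
    return("renal model parameters must be positive")
  TRUE
})

#' An ordered vaccination schedule
#'
#' Dose events (age, label, adjuvant kind, Al mass in mg) sorted by age with
#' stable order for ties. Combination products appear as one row per adjuvant
#' component so that depot kinetics stay adjuvant-specific.
#'
#' @slot name scenario label.
#' @slot doses data.frame with columns \code{age_months}, \code{age_years},
#'   \code{label}, \code{adjuvant} (one of AH, AP, AAHS), \code{al_mg}.
#' @export
setClass("VaccinationSchedule",
  slots = c(name = "character", doses = "data.frame"))

setValidity("VaccinationSchedule", function(object) {
  d <- object@doses
  need <- c("age_months", "age_years", "label", "adjuvant", "al_mg")
  if (!all(need %in% names(d)))
    return(paste("doses must have columns:", paste(need, collapse = ", ")))
  if (nrow(d) == 0L) return(TRUE)
  if (!all(d$adjuvant %in% names(adjuvantAbsorptionRates())))
    return("unknown adjuvant kind in schedule")
  if (any(d$age_months < 0)) return("dose ages must be non-negative")
  if (any(d$al_mg <= 0)) return("dose Al masses must be positive")
  if (is.unsorted(d$age_months)) return("doses must be sorted by age")
  TRUE
})

#' Piecewise-constant age-staged dietary aluminium regimen
#'
#' @slot name regimen label.
#' @slot stages data.frame with columns \code{age_start_y}, \code{age_end_y},
#'   \code{mg_per_kg_week}: contiguous, non-overlapping stages covering
#'   0-50 years.
#' @slot oralF oral bioavailability (fraction absorbed; default 0.0017).
#' @export
setClass("DietaryRegimen",
  slots = c(name = "character", stages = "data.frame", oralF = "numeric"))

setValidity("DietaryRegimen", function(object) {
  s <- object@stages
  need <- c("age_start_y", "age_end_y", "mg_per_kg_week")
  if (!all(need %in% names(s)))
    return(paste("stages must have columns:", paste(need, collapse = ", ")))
  if (nrow(s) == 0L) return("regimen needs at least one stage")
  if (any(s$mg_per_kg_week < 0)) return("intake rates must be non-negative")
  if (s$age_start_y[1] != 0 || s$age_end_y[nrow(s)] < 50)
    return("stages must cover [0, 50] years")
  if (any(abs(s$age_start_y[-1] - s$age_end_y[-nrow(s)]) > 1e-12))
    return("stages must be contiguous and non-overlapping")
  if (length(object@oralF) != 1L || object@oralF <= 0 || object@oralF >= 1)
    return("oral bioavailability must lie in (0, 1)")
  TRUE
})

#' A complete exposure scenario
#'
#' Pairs a vaccination schedule with a dietary regimen plus the sensitivity
#' switches (brain intrusion multiplier for early infancy).
#'
#' @slot name scenario name.
#' @slot schedule a [VaccinationSchedule-class].
#' @slot diet a [DietaryRegimen-class].
#' @slot brainMultiplier multiplier on the brain intrusion clearance (default
#'   1; the blood-brain-barrier sensitivity scenario uses 20).
#' @slot brainMultiplierMaxAge age (years) below which the multiplier applies.
#' @export
setClass("ExposureScenario",
  slots = c(name = "character", schedule = "VaccinationSchedule",
            diet = "DietaryRegimen", brainMultiplier = "numeric",
            brainMultiplierMaxAge = "numeric"))

setValidity("ExposureScenario", function(object) {
  if (object@brainMultiplier < 0) return("brain multiplier must be >= 0")
  if (object@brainMultiplierMaxAge < 0) return("brain multiplier age bound must be >= 0")
  TRUE
})

#' Kinetic parameters of the aluminium PBTK model
#'
#' All rate parameters refer to the reference adult; uptake clearances are
#' scaled allometrically with body weight at run time. Amount unit inside the
#' model is ug, volume L, time days.
#'
#' @slot clupLiver,clupBrain,clupRest plasma-to-tissue uptake clearances
#'   (L/day, reference adult).
#' @slot koutLiver,koutRest tissue efflux rate constants (1/day). Brain has no
#'   efflux: it is modelled as a sink.
#' @slot kappaBone bone coupling constant: Al uptake clearance per unit calcium
#'   accretion flux (L per mg Ca).
#' @slot fu filterable (non-protein-bound) plasma fraction driving renal
#'   elimination, in (0, 1].
#' @slot kAbs named numeric: zero-order intramuscular absorption rate per
#'   adjuvant kind (fraction of deposited dose per day).
#' @slot initLevels named numeric medians of initial levels at birth: plasma
#'   in ug/L, liver/brain/bone/rest in ug/g wet weight.
#' @export
setClass("ModelParams",
  slots = c(clupLiver = "numeric", clupBrain = "numeric", clupRest = "numeric",
            koutLiver = "numeric", koutRest = "numeric", kappaBone = "numeric",
            fu = "numeric", kAbs = "numeric", initLevels = "numeric"))

setValidity("ModelParams", function(object) {
  for (s in c("clupLiver", "clupBrain", "clupRest", "koutLiver", "koutRest",
              "kappaBone", "fu")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      return(paste(s, "must be a single non-negative number"))
  }
  if (object@fu <= 0 || object@fu > 1) return("fu must lie in (0, 1]")
  if (!all(c("AH", "AP", "AAHS") %in% names(object@kAbs)))
    return("kAbs must name AH, AP and AAHS")
  if (any(object@kAbs <= 0)) return("absorption rates must be positive")
  if (!all(MODEL_TISSUES %in% names(object@initLevels)))
    return("initLevels must name all modelled tissues")
  if (any(object@initLevels < 0)) return("initial levels must be non-negative")
  TRUE
})

#' Inter-individual variability settings
#'
#' Coefficients of variation (as fractions) of the multiplicative lognormal
#' factors applied per individual. Factors have median 1 and
#' sdlog = sqrt(log(1 + CV^2)).
#'
#' @slot cvOralF,cvGfr,cvDist,cvKabs,cvInit CVs for oral bioavailability, GFR,
#'   tissue distribution (one shared factor across all uptake clearances and
#'   the bone coupling), intramuscular absorption rates (per adjuvant), and
#'   initial organ levels. Defaults all 0.5.
#' @export
setClass("VariabilitySpec",
  slots = c(cvOralF = "numeric", cvGfr = "numeric", cvDist = "numeric",
            cvKabs = "numeric", cvInit = "numeric"))

setValidity("VariabilitySpec", function(object) {
  cvs <- c(object@cvOralF, object@cvGfr, object@cvDist, object@cvKabs, object@cvInit)
  if (any(cvs < 0)) return("CVs must be non-negative")
  TRUE
})

#' A sampled virtual population
#'
#' One row per individual: multiplicative lognormal factors plus sampled
#' initial organ concentrations at birth. Reproducible from (seed, id) via
#' counter-based substreams, so the same seed yields the identical population
#' in every scenario and the first k individuals do not depend on n.
#'
#' @slot params data.frame with columns \code{id}, \code{fOral}, \code{fGfr},
#'   \code{fDist}, \code{fKabsAH}, \code{fKabsAP}, \code{fKabsAAHS}, and
#'   initial concentrations \code{initPlasma} (ug/L), \code{initLiver},
#'   \code{initBrain}, \code{initBone}, \code{initRest} (ug/g ww).
#' @slot seed master seed the population was drawn from.
#' @slot spec the [VariabilitySpec-class] used.
#' @export
setClass("VirtualPopulation",
  slots = c(params = "data.frame", seed = "integer", spec = "VariabilitySpec"))

setValidity("VirtualPopulation", function(object) {
  p <- object@params
  need <- c("id", "fOral", "fGfr", "fDist", "fKabsAH", "fKabsAP", "fKabsAAHS",
            "initPlasma", "initLiver", "initBrain", "initBone", "initRest")
  if (!all(need %in% names(p)))
    return(paste("params must have columns:", paste(need, collapse = ", ")))
  if (nrow(p) < 1L) return("population must contain at least one individual")
  if (any(as.matrix(p[c("fOral", "fGfr", "fDist", "fKabsAH", "fKabsAP",
                        "fKabsAAHS")]) <= 0))
    return("all variability factors must be positive")
  TRUE
})

#' Population simulation results
#'
#' Extends \linkS4class{SummarizedExperiment}: rows are readout times, columns
#' individuals. One assay of compartment amounts (ug) per model compartment
#' (\code{plasma}, \code{liver}, \code{brain}, \code{bone}, \code{rest}),
#' cumulative urinary excretion (\code{urine}), cumulative absorbed oral input
#' (\code{oralAbsorbed}) and cumulative depot release (\code{depotReleased}).
#' \code{rowData} holds the age grid; \code{colData} the individual parameters;
#' \code{metadata} the scenario, model parameters, physiology and solver
#' settings.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("AlExposureExperiment", contains = "SummarizedExperiment")
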