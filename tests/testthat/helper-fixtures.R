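# Shared fixtures built in code.

# age-independent physiology: constant body weight and organ fractions,
# fully matured GFR (half-maturation point pushed to ~0 PMA), stationary
# adult calcium turnover -- reduces the model to constant coefficients
flatPhysiology <- function(bw = 60, fracPlasma = 0.2, gfrAdult = 148.3) {
  growth <- data.frame(age_years = c(0, 50), bw_kg = bw,
                       frac_plasma = fracPlasma, frac_liver = 0.026,
                       frac_brain = 0.022, frac_bone = 0.113, frac_rest = 0.6)
  ca <- data.frame(age_years = c(0, 50), v_acc_mg_d = 400, v_res_mg_d = 400,
                   m_ca_g = 1000)
  Physiology(growth, ca,
             renal = list(gfrAdult = gfrAdult, pma50 = 1e-6, refBw = bw))
}

# constant dietary intake (adult stage everywhere), or no intake at all
flatDiet <- function(rate = 0.8, oralF = 0.0017) {
  DietaryRegimen(data.frame(age_start_y = 0, age_end_y = 50,
                            mg_per_kg_week = rate), oralF = oralF)
}

zeroDiet <- function() flatDiet(rate = 0)

foodOnlyScenario <- function(diet = zeroDiet(), ...) {
  ExposureScenario(emptySchedule(), diet, name = "none", ...)
}

emptySchedule <- function() {
  VaccinationSchedule(data.frame(age_months = numeric(0),
                                 label = character(0),
                                 adjuvant = character(0),
                                 al_mg = numeric(0)), name = "empty")
}

zeroAmounts <- c(plasma = 0, liver = 0, brain = 0, bone = 0, rest = 0)

# minimal population experiment wrapping a given plasma concentration matrix
# (rows = ages), for quantile tests against analytic distributions
concExperiment <- function(concMatrix, ages, phys = defaultPhysiology()) {
  vol <- organVolume(phys, "plasma", ages)
  n <- ncol(concMatrix)
  zero <- matrix(0, nrow = length(ages), ncol = n)
  pop <- do.call(rbind, replicate(n, typicalIndividual(), simplify = FALSE))
  pop$id <- seq_len(n)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(plasma = concMatrix * vol, liver = zero, brain = zero,
                  bone = zero, rest = zero, urine = zero, oralAbsorbed = zero,
                  depotReleased = zero),
    rowData = S4Vectors::DataFrame(time_days = ages * 365.25,
                                   age_years = ages),
    colData = S4Vectors::DataFrame(pop),
    metadata = list(phys = phys,
                    scenario = foodOnlyScenario()))
  new("AlExposureExperiment", se)
}
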