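#' Zero-order intramuscular absorption rates per adjuvant kind
#'
#' Fractions of the deposited dose released per day: aluminium hydroxide (AH)
#' 0.002784/day, aluminium phosphate (AP) 0.01098/day, and amorphous aluminium
#' hydroxyphosphate sulfate (AAHS) treated identically to AP given its similar
#' physicochemical and dissolution properties.
#'
#' @return named numeric vector (1/day).
#' @examples
#' 1 / adjuvantAbsorptionRates()  # depot depletion times in days
#' @export
adjuvantAbsorptionRates <- function() {
  c(AH = 0.002784, AP = 0.01098, AAHS = 0.01098)
}

#' Time to complete depletion of an adjuvant depot
#'
#' Under zero-order release the depot is exhausted after \code{1 / kAbs} days:
#' about 3 months for AP/AAHS and about 1 year for AH.
#'
#' @param kind adjuvant kind: \code{"AH"}, \code{"AP"} or \code{"AAHS"}.
#' @return depletion time in days.
#' @export
depotDepletionTime <- function(kind) {
  kind <- match.arg(kind, names(adjuvantAbsorptionRates()), several.ok = TRUE)
  unname(1 / adjuvantAbsorptionRates()[kind])
}

# round-half-up to `digits`, matching the printed dose-total convention
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Construct a VaccinationSchedule
#'
#' @param doses data.frame with columns \code{age_months}, \code{label},
#'   \code{adjuvant}, \code{al_mg}. Adjuvant strings are case-insensitive.
#'   Rows are sorted by age (stable for ties). Doses above the Ph. Eur. limit
#'   of 1.25 mg Al trigger a warning, not an error, so hypothetical scenarios
#'   remain explorable.
#' @param name schedule label.
#' @return a validated [VaccinationSchedule-class].
#' @export
VaccinationSchedule <- function(doses, name = "schedule") {
  doses <- as.data.frame(doses)
  if (nrow(doses) > 0L) {
    doses$adjuvant <- toupper(trimws(as.character(doses$adjuvant)))
    bad <- which(!doses$adjuvant %in% names(adjuvantAbsorptionRates()))
    if (length(bad))
      stop("unknown adjuvant '", doses$adjuvant[bad[1]], "' in row ", bad[1])
    bad <- which(!is.finite(doses$al_mg) | doses$al_mg <= 0)
    if (length(bad))
      stop("invalid Al mass '", doses$al_mg[bad[1]], "' in row ", bad[1])
    doses <- doses[order(doses$age_months), , drop = FALSE]
    rownames(doses) <- NULL
    if (any(doses$al_mg > PH_EUR_DOSE_LIMIT_MG))
      warning("dose exceeds the Ph. Eur. limit of ", PH_EUR_DOSE_LIMIT_MG,
              " mg Al per dose")
  }
  doses$age_years <- if (nrow(doses)) doses$age_months / 12 else numeric(0)
  doses <- doses[, c("age_months", "age_years", "label", "adjuvant", "al_mg"),
                 drop = FALSE]
  new("VaccinationSchedule", name = name, doses = doses)
}

#' Read a vaccination schedule from CSV
#'
#' Expected header: \code{age_months,label,adjuvant,al_mg}. Malformed rows
#' raise an error naming the offending line.
#'
#' @param path CSV file path.
#' @param name schedule label (defaults to the file name).
#' @return a [VaccinationSchedule-class].
#' @export
loadSchedule <- function(path, name = sub("\\.csv$", "", basename(path))) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_months", "label", "adjuvant", "al_mg")
  if (!all(need %in% names(d)))
    stop("schedule CSV must have header: ", paste(need, collapse = ","))
  if (nrow(d) > 0L) {
    d$age_months <- suppressWarnings(as.numeric(d$age_months))
    d$al_mg <- suppressWarnings(as.numeric(d$al_mg))
    bad <- which(!is.finite(d$age_months) | d$age_months < 0)
    if (length(bad))
      stop("malformed age in ", basename(path), " line ", bad[1] + 1L)
    bad <- which(!is.finite(d$al_mg))
    if (length(bad))
      stop("malformed Al mass in ", basename(path), " line ", bad[1] + 1L)
    adj <- toupper(trimws(d$adjuvant))
    bad <- which(!adj %in% names(adjuvantAbsorptionRates()))
    if (length(bad))
      stop("unknown adjuvant '", d$adjuvant[bad[1]], "' in ", basename(path),
           " line ", bad[1] + 1L)
  }
  VaccinationSchedule(d, name = name)
}

#' Write a vaccination schedule to CSV
#'
#' Round-trips with [loadSchedule()] field-for-field.
#'
#' @param schedule a [VaccinationSchedule-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @rdname writeSchedule
#' @export
setMethod("writeSchedule", "VaccinationSchedule", function(schedule, path) {
  utils::write.csv(schedule@doses[, c("age_months", "label", "adjuvant", "al_mg")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
})

#' Aluminium dose totals of a schedule
#'
#' Exact per-adjuvant and grand totals, optionally restricted to an age window
#' \code{[from, to)} in years; reported values are additionally rounded
#' half-up to 1 decimal, the convention used for printed schedule totals.
#'
#' @param schedule a [VaccinationSchedule-class].
#' @param window optional numeric \code{c(from, to)} in years (half-open).
#' @return list with \code{raw} and \code{reported} named vectors
#'   (AH, AP, AAHS, total; mg).
#' @examples
#' s <- builtinScenario("GERMANY_2025")
#' scheduleTotals(s@schedule)$reported          # total 8.8 mg
#' scheduleTotals(s@schedule, c(0, 2))$reported # first two years: 4.8 mg
#' @rdname scheduleTotals
#' @export
setMethod("scheduleTotals", "VaccinationSchedule", function(schedule, window = NULL) {
  d <- schedule@doses
  if (!is.null(window)) {
    if (length(window) != 2L || window[1] > window[2])
      stop("window must be c(from, to) with from <= to")
    d <- d[d$age_years >= window[1] & d$age_years < window[2], , drop = FALSE]
  }
  kinds <- names(adjuvantAbsorptionRates())
  raw <- vapply(kinds, function(k) sum(d$al_mg[d$adjuvant == k]), numeric(1))
  raw <- c(raw, total = sum(raw))
  list(raw = raw, reported = roundHalfUp(raw, 1))
})

setMethod("show", "VaccinationSchedule", function(object) {
  t <- scheduleTotals(object)$reported
  cat("VaccinationSchedule '", object@name, "': ", nrow(object@doses),
      " doses, total ", t[["total"]], " mg Al (AH ", t[["AH"]], ", AP ",
      t[["AP"]], ", AAHS ", t[["AAHS"]], ")\n", sep = "")
})

#' Construct a DietaryRegimen
#'
#' @param stages data.frame with columns \code{age_start_y}, \code{age_end_y},
#'   \code{mg_per_kg_week}, contiguous and covering 0-50 years.
#' @param oralF oral bioavailability (default 0.0017, i.e. 0.17 %).
#' @param name regimen label.
#' @return a validated [DietaryRegimen-class].
#' @export
DietaryRegimen <- function(stages, oralF = 0.0017, name = "diet") {
  new("DietaryRegimen", name = name, stages = as.data.frame(stages),
      oralF = oralF)
}

#' Dietary intake rate at a given age
#'
#' Piecewise-constant stage lookup, right-continuous at stage boundaries.
#'
#' @param diet a [DietaryRegimen-class].
#' @param age age in years (vectorised).
#' @return intake in mg Al/kg/week.
#' @export
dietIntakeRate <- function(diet, age) {
  s <- diet@stages
  if (any(age < s$age_start_y[1] | age > s$age_end_y[nrow(s)]))
    stop("age outside dietary regimen coverage")
  i <- findInterval(age, s$age_start_y)
  s$mg_per_kg_week[i]
}

setMethod("show", "DietaryRegimen", function(object) {
  cat("DietaryRegimen '", object@name, "': ", nrow(object@stages),
      " stages, F = ", object@oralF, "\n", sep = "")
})

euAverageDiet <- function(maxFormula = FALSE) {
  stages <- data.frame(age_start_y = c(0, 0.25, 0.5, 0.75),
                       age_end_y = c(0.25, 0.5, 0.75, 50),
                       mg_per_kg_week = c(0.1, 0.2, 0.4, 0.8))
  name <- "EU_AVERAGE"
  if (maxFormula) {
    # worst-case soy-based / hypoallergenic formula intake for the first 6 months
    stages <- data.frame(age_start_y = c(0, 0.5, 0.75),
                         age_end_y = c(0.5, 0.75, 50),
                         mg_per_kg_week = c(2.0, 0.4, 0.8))
    name <- "MAX_FORMULA"
  }
  DietaryRegimen(stages, name = name)
}

#' Construct a custom exposure scenario
#'
#' @param schedule a [VaccinationSchedule-class].
#' @param diet a [DietaryRegimen-class].
#' @param name scenario label.
#' @param brainMultiplier,brainMultiplierMaxAge brain intrusion sensitivity
#'   switch (multiplier applied below the given age in years).
#' @return an [ExposureScenario-class].
#' @export
ExposureScenario <- function(schedule, diet, name = "custom",
                             brainMultiplier = 1, brainMultiplierMaxAge = 0.5) {
  new("ExposureScenario", name = name, schedule = schedule, diet = diet,
      brainMultiplier = brainMultiplier,
      brainMultiplierMaxAge = brainMultiplierMaxAge)
}

BUILTIN_SCENARIOS <- c("FOOD_ONLY", "GERMANY_2025", "GERMANY_2025_HEPB")

#' Built-in exposure scenarios
#'
#' Frozen study scenarios: \code{FOOD_ONLY} (empty vaccination schedule on the
#' EU-average diet), \code{GERMANY_2025} (the recommended German 2025 schedule
#' of Al-adjuvanted vaccinations, 8.8 mg total Al), and
#' \code{GERMANY_2025_HEPB} (additionally hepatitis B at birth and 1 month,
#' 0.25 mg AAHS each; 9.3 mg total). Sensitivity switches: \code{maxFormula}
#' raises dietary intake to 2 mg/kg/week for ages 0-6 months;
#' \code{brain20x} multiplies the brain intrusion clearance by 20 for ages
#' below 6 months while keeping brain efflux at zero.
#'
#' @param name scenario name (see above).
#' @param maxFormula logical sensitivity switch.
#' @param brain20x logical sensitivity switch.
#' @return an [ExposureScenario-class].
#' @examples
#' builtinScenario("GERMANY_2025_HEPB")
#' @export
builtinScenario <- function(name, maxFormula = FALSE, brain20x = FALSE) {
  if (!name %in% BUILTIN_SCENARIOS)
    stop("unknown scenario '", name, "'; valid names: ",
         paste(BUILTIN_SCENARIOS, collapse = ", "))
  schedule <- switch(name,
    FOOD_ONLY = VaccinationSchedule(
      data.frame(age_months = numeric(0), label = character(0),
                 adjuvant = character(0), al_mg = numeric(0)),
      name = "none"),
    GERMANY_2025 = loadSchedule(
      system.file("extdata", "schedule_germany2025.csv",
                  package = "aluPBTK", mustWork = TRUE),
      name = "GERMANY_2025"),
    GERMANY_2025_HEPB = loadSchedule(
      system.file("extdata", "schedule_germany2025_hepb.csv",
                  package = "aluPBTK", mustWork = TRUE),
      name = "GERMANY_2025_HEPB"))
  fullName <- paste0(name,
                     if (maxFormula) "+MAX_FORMULA" else "",
                     if (brain20x) "+BRAIN_20X" else "")
  new("ExposureScenario", name = fullName, schedule = schedule,
      diet = euAverageDiet(maxFormula = maxFormula),
      brainMultiplier = if (brain20x) 20 else 1,
      brainMultiplierMaxAge = 0.5)
}

setMethod("show", "ExposureScenario", function(object) {
  cat("ExposureScenario '", object@name, "': ", nrow(object@schedule@doses),
      " vaccine doses on diet '", object@diet@name, "'",
      if (object@brainMultiplier != 1)
        paste0("; brain intrusion x", object@brainMultiplier, " below ",
               object@brainMultiplierMaxAge, " y"),
      "\n", sep = "")
})
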