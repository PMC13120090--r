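#' Construct a Physiology object
#'
#' @param growth growth/organ-fraction table (see [Physiology-class]).
#' @param ca calcium kinetic table.
#' @param renal list of renal maturation parameters; missing entries are filled
#'   with the defaults (adult GFR 148.3 L/day for the 60 kg reference female,
#'   i.e. ~103 mL/min absolute; half-maturation at 47.7 weeks postmenstrual
#'   age; Hill exponent 3.4; allometric exponent 0.75).
#' @return a validated [Physiology-class] object.
#' @export
Physiology <- function(growth, ca, renal = list()) {
  def <- list(gfrAdult = 148.3, pma50 = 47.7, gamma = 3.4,
              sizeExp = 0.75, refBw = 60)
  renal <- utils::modifyList(def, renal)
  new("Physiology", growth = as.data.frame(growth), ca = as.data.frame(ca),
      renal = renal)
}

#' Default female reference physiology
#'
#' Loads the shipped reference tables (full-term female, birth weight 3.5 kg,
#' adult plateau 60 kg, ICRP-style organ growth; calcium accretion/resorption
#' with infancy and pubertal peaks and a stationary adult turnover plateau).
#' Users can substitute their own tables via [Physiology()].
#'
#' @param growthPath,caPath optional CSV paths overriding the shipped tables.
#' @return a [Physiology-class] object.
#' @examples
#' phys <- defaultPhysiology()
#' bodyWeight(phys, 0)    # 3.5 kg at birth
#' @export
defaultPhysiology <- function(growthPath = NULL, caPath = NULL) {
  if (is.null(growthPath))
    growthPath <- system.file("extdata", "physiology_female_default.csv",
                              package = "aluPBTK", mustWork = TRUE)
  if (is.null(caPath))
    caPath <- system.file("extdata", "ca_kinetics_default.csv",
                          package = "aluPBTK", mustWork = TRUE)
  Physiology(utils::read.csv(growthPath), utils::read.csv(caPath))
}

checkAgeRange <- function(phys, age) {
  rng <- range(phys@growth$age_years)
  if (any(age < rng[1] | age > rng[2]))
    stop("age outside the physiology table range [", rng[1], ", ", rng[2], "]")
}

#' Body weight at a given age
#'
#' Piecewise-linear interpolation on the growth table; exact at grid nodes.
#'
#' @param phys a [Physiology-class] object.
#' @param age age in years (vectorised), within the table range.
#' @return body weight in kg.
#' @rdname bodyWeight
#' @export
setMethod("bodyWeight", "Physiology", function(phys, age) {
  checkAgeRange(phys, age)
  stats::approx(phys@growth$age_years, phys@growth$bw_kg, xout = age)$y
})

#' Organ volume at a given age
#'
#' Volume = fraction(tissue, age) x body weight(age) / density, with density
#' 1 kg/L by convention. Fractions are interpolated piecewise-linearly.
#'
#' @param phys a [Physiology-class] object.
#' @param tissue one of \code{"plasma"}, \code{"liver"}, \code{"brain"},
#'   \code{"bone"}, \code{"rest"}.
#' @param age age in years (vectorised).
#' @return volume in L (numerically equal to mass in kg).
#' @rdname organVolume
#' @export
setMethod("organVolume", "Physiology", function(phys, tissue, age) {
  tissue <- match.arg(tissue, MODEL_TISSUES)
  checkAgeRange(phys, age)
  g <- phys@growth
  frac <- stats::approx(g$age_years, g[[paste0("frac_", tissue)]], xout = age)$y
  frac * bodyWeight(phys, age)
})

#' GFR maturation fraction
#'
#' Sigmoid Hill function of postmenstrual age (PMA):
#' \code{PMA^gamma / (PMA^gamma + pma50^gamma)}. Monotone non-decreasing in
#' PMA, 0.5 at \code{pma50} and tending to 1.
#'
#' @param pmaWeeks postmenstrual age in weeks.
#' @param pma50 half-maturation PMA (weeks).
#' @param gamma Hill exponent.
#' @return maturation fraction in (0, 1).
#' @export
gfrMaturation <- function(pmaWeeks, pma50 = 47.7, gamma = 3.4) {
  1 / (1 + (pma50 / pmaWeeks)^gamma)
}

#' Glomerular filtration rate at a given age
#'
#' Adult size-scaled GFR times the maturation fraction:
#' \code{gfrAdult * (BW/refBw)^sizeExp * maturation(PMA)} with
#' \code{PMA = 40 weeks + postnatal age} (full-term birth).
#'
#' @param phys a [Physiology-class] object.
#' @param age age in years (vectorised).
#' @param bw optional body weight override (kg); defaults to the growth table.
#' @param ... unused.
#' @return GFR in L/day, strictly positive.
#' @rdname gfr
#' @export
setMethod("gfr", "Physiology", function(phys, age, bw = NULL, ...) {
  if (any(age < 0)) stop("age must be non-negative")
  r <- phys@renal
  if (is.null(bw)) bw <- bodyWeight(phys, age)
  pma <- PMA_AT_TERM_BIRTH + age * WEEKS_PER_YEAR
  r$gfrAdult * (bw / r$refBw)^r$sizeExp * gfrMaturation(pma, r$pma50, r$gamma)
})

#' Calcium-coupled bone exchange rates
#'
#' Al uptake into bone is proportional to the calcium accretion flux; release
#' from bone follows the fractional calcium resorption rate:
#' \code{uptakeScale = V_acc(age)} (mg Ca/day) and
#' \code{releaseRate = V_res(age) / (M_Ca(age) * 1000)} (1/day).
#'
#' @param phys a [Physiology-class] object.
#' @param age age in years (vectorised), within the Ca table range.
#' @return list with \code{uptakeScale} (mg Ca/day) and \code{releaseRate}
#'   (1/day), both non-negative.
#' @rdname boneRates
#' @export
setMethod("boneRates", "Physiology", function(phys, age) {
  ca <- phys@ca
  rng <- range(ca$age_years)
  if (any(age < rng[1] | age > rng[2]))
    stop("age outside the Ca table range [", rng[1], ", ", rng[2], "]")
  vAcc <- stats::approx(ca$age_years, ca$v_acc_mg_d, xout = age)$y
  vRes <- stats::approx(ca$age_years, ca$v_res_mg_d, xout = age)$y
  mCa <- stats::approx(ca$age_years, ca$m_ca_g, xout = age)$y
  if (any(mCa <= 0)) stop("degenerate Ca table: exchangeable bone Ca mass is zero")
  list(uptakeScale = vAcc, releaseRate = vRes / (mCa * 1000))
})

setMethod("show", "Physiology", function(object) {
  g <- object@growth
  cat("Physiology: ages", min(g$age_years), "-", max(g$age_years), "y;",
      "BW", g$bw_kg[1], "->", g$bw_kg[nrow(g)], "kg;",
      "adult GFR", object@renal$gfrAdult, "L/day\n")
})
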