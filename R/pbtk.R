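#' Construct kinetic model parameters
#'
#' The defaults are the package's documented reference calibration: they place
#' the adult food-only plasma median inside the normal range (1-10 ug/L) and
#' give adult food-only tissue levels of the order reported for bone
#' (~0.5 ug/g ww) and liver (~0.07 ug/g ww), with the brain treated as a sink.
#' Every value is overridable, so an externally estimated calibration can be
#' dropped in. See the package vignette for the derivation.
#'
#' @param clupLiver,clupBrain,clupRest uptake clearances (L/day, reference
#'   adult; scaled with (BW/refBw)^0.75 at run time).
#' @param koutLiver,koutRest tissue efflux rate constants (1/day).
#' @param kappaBone bone Al uptake clearance per unit Ca accretion flux
#'   (L per mg Ca): uptake clearance = kappaBone x V_acc(age).
#' @param fu filterable plasma fraction; renal elimination = fu x GFR x C_p.
#' @param kAbs named zero-order depot absorption rates (1/day).
#' @param initLevels named medians of initial levels at birth (plasma ug/L,
#'   tissues ug/g ww), chosen near equilibrium with the 2.2 ug/L plasma median
#'   at birth physiology.
#' @return a validated [ModelParams-class].
#' @export
ModelParams <- function(clupLiver = 0.8, clupBrain = 0.02, clupRest = 120,
                        koutLiver = 0.01, koutRest = 0.02,
                        kappaBone = 0.0027, fu = 0.06,
                        kAbs = adjuvantAbsorptionRates(),
                        initLevels = c(plasma = 2.2, liver = 0.16,
                                       brain = 0.08, bone = 1.0, rest = 1.0)) {
  new("ModelParams", clupLiver = clupLiver, clupBrain = clupBrain,
      clupRest = clupRest, koutLiver = koutLiver, koutRest = koutRest,
      kappaBone = kappaBone, fu = fu, kAbs = kAbs, initLevels = initLevels)
}

setMethod("show", "ModelParams", function(object) {
  cat("ModelParams: CLup(liver/brain/rest) =", object@clupLiver, "/",
      object@clupBrain, "/", object@clupRest, "L/d; kout(liver/rest) =",
      object@koutLiver, "/", object@koutRest, "/d; kappaBone =",
      object@kappaBone, "L/mg; fu =", object@fu, "\n")
})

#' Oral aluminium input rate into plasma
#'
#' \code{rate = intake(age) [mg/kg/week] x bw / 7 x F x fOral x 1000}, in
#' ug absorbed Al per day.
#'
#' @param age age in years.
#' @param diet a [DietaryRegimen-class].
#' @param bw body weight in kg.
#' @param fOral individual multiplicative factor on oral bioavailability.
#' @return absorbed input rate in ug/day.
#' @examples
#' oralInputRate(20, euAverage <- builtinScenario("FOOD_ONLY")@diet, bw = 60)
#' @export
oralInputRate <- function(age, diet, bw, fOral = 1) {
  dietIntakeRate(diet, age) * bw / 7 * diet@oralF * fOral * 1000
}

#' Build the depot table for an individual
#'
#' One zero-order depot per schedule row: release rate
#' \code{kAbs(kind) x fKabs x D0 x 1000} ug/day from the administration age
#' until the deposited mass is exhausted (duration \code{1 / (kAbs x fKabs)}
#' days).
#'
#' @param schedule a [VaccinationSchedule-class].
#' @param params a [ModelParams-class].
#' @param individual one-row individual data.frame (per-adjuvant kAbs factors).
#' @return data.frame with \code{start_day}, \code{end_day}, \code{rate_ug_d},
#'   \code{d0_mg}, \code{adjuvant}.
#' @export
buildDepots <- function(schedule, params = ModelParams(),
                        individual = typicalIndividual(params)) {
  d <- schedule@doses
  if (nrow(d) == 0L)
    return(data.frame(start_day = numeric(0), end_day = numeric(0),
                      rate_ug_d = numeric(0), d0_mg = numeric(0),
                      adjuvant = character(0)))
  fk <- c(AH = individual$fKabsAH, AP = individual$fKabsAP,
          AAHS = individual$fKabsAAHS)
  k <- unname(params@kAbs[d$adjuvant] * fk[d$adjuvant])
  start <- d$age_years * DAYS_PER_YEAR
  data.frame(start_day = start, end_day = start + 1 / k,
             rate_ug_d = k * d$al_mg * 1000, d0_mg = d$al_mg,
             adjuvant = d$adjuvant)
}

#' Total depot release rate at a time point
#'
#' Sum of the zero-order release rates of all depots still holding unreleased
#' mass at time \code{t}; a depot contributes its constant rate on
#' \code{[start, start + 1/kAbs)} and 0 afterwards.
#'
#' @param depots depot table from [buildDepots()].
#' @param t time in days (vectorised).
#' @return release rate in ug/day.
#' @export
depotReleaseRate <- function(depots, t) {
  vapply(t, function(tt)
    sum(depots$rate_ug_d[depots$start_day <= tt & tt < depots$end_day]),
    numeric(1))
}

# cumulative mass released by all depots up to time t (ug), closed form
depotReleasedCumulative <- function(depots, t) {
  out <- numeric(length(t))
  for (d in seq_len(nrow(depots)))
    out <- out + depots$rate_ug_d[d] *
      pmax(pmin(t, depots$end_day[d]) - depots$start_day[d], 0)
  out
}

#' Precompute the simulation context for one individual
#'
#' Bundles interpolators of the age-dependent physiology (central volume,
#' allometric scale, GFR including the individual factor, Ca accretion flux,
#' bone release rate constant), the diet lookup, the individual's depot table
#' and the solver breakpoints (dose events, depot exhaustions, diet stage
#' switches, the brain-multiplier age bound) into one environment used by
#' [alDerivatives()].
#'
#' @param individual one-row individual data.frame.
#' @param scenario an [ExposureScenario-class].
#' @param params a [ModelParams-class].
#' @param phys a [Physiology-class].
#' @param tEnd simulation horizon in years.
#' @return an environment (simulation context).
#' @export
buildSimContext <- function(individual, scenario, params = ModelParams(),
                            phys = defaultPhysiology(), tEnd = 50) {
  tEndDay <- tEnd * DAYS_PER_YEAR
  # daily grid, one spare node past the horizon so indexed interpolation in
  # the right-hand side never reads past the end
  grid <- seq(0, ceiling(tEndDay) + 1, by = 1)
  age <- pmin(grid / DAYS_PER_YEAR, max(phys@growth$age_years))
  bw <- bodyWeight(phys, age)
  br <- boneRates(phys, pmin(age, max(phys@ca$age_years)))
  ctx <- new.env(parent = emptyenv())
  ctx$params <- params
  ctx$ind <- individual
  ctx$phys <- phys
  ctx$scenario <- scenario
  ctx$tEndDay <- tEndDay
  ctx$tGridMax <- grid[length(grid)] - 1
  ctx$vBw <- bw
  ctx$vVp <- organVolume(phys, "plasma", age)
  ctx$vScale <- (bw / phys@renal$refBw)^phys@renal$sizeExp * individual$fDist
  ctx$vGfrFu <- gfr(phys, age) * individual$fGfr * params@fu
  ctx$vBoneUp <- br$uptakeScale * params@kappaBone * individual$fDist
  ctx$vKrel <- br$releaseRate
  # scalar kinetic constants, fetched once per derivative call
  ctx$pClLi <- params@clupLiver
  ctx$pClBr <- params@clupBrain
  ctx$pClR <- params@clupRest
  ctx$pKoLi <- params@koutLiver
  ctx$pKoR <- params@koutRest
  # diet stages in days for fast lookup
  st <- scenario@diet@stages
  ctx$dietStartDays <- st$age_start_y * DAYS_PER_YEAR
  ctx$dietRate <- st$mg_per_kg_week
  ctx$oralF <- scenario@diet@oralF * individual$fOral
  ctx$depots <- buildDepots(scenario@schedule, params, individual)
  ctx$mBrainBoundaryDay <- scenario@brainMultiplierMaxAge * DAYS_PER_YEAR
  ctx$mBrainEarly <- scenario@brainMultiplier
  bp <- c(0, tEndDay, ctx$depots$start_day, ctx$depots$end_day,
          ctx$dietStartDays)
  if (ctx$mBrainEarly != 1) bp <- c(bp, ctx$mBrainBoundaryDay)
  bp <- sort(unique(bp[bp >= 0 & bp <= tEndDay]))
  ctx$breakpoints <- bp
  # segment-level constants, set by the integrator before each segment
  ctx$segDepotRate <- 0
  ctx$segMBrain <- 1
  ctx
}

# oral absorbed input rate (ug/day) at time t days, using the context
ctxOralRate <- function(ctx, t) {
  i <- findInterval(t, ctx$dietStartDays)
  j <- floor(t); w <- t - j
  bw <- ctx$vBw[j + 1L] * (1 - w) + ctx$vBw[j + 2L] * w
  ctx$dietRate[i] * bw / 7 * ctx$oralF * 1000
}

#' Right-hand side of the aluminium PBTK ODE system
#'
#' State (amounts in ug): central/plasma \code{Ap}, liver \code{Ali}, brain
#' \code{Abr}, bone \code{Abo}, rest-of-body \code{Ar}, cumulative urine
#' \code{U}, cumulative absorbed oral input \code{O}. With
#' \code{Cp = Ap / Vp(age)}:
#' \deqn{dAp/dt = oral + depots + kout_li Ali + kout_r Ar + krel(age) Abo -
#'   [CLup_li + m_br CLup_br + CLup_r + kappa V_acc(age) + fu GFR(age)] Cp}
#' \deqn{dA_T/dt = CLup_T Cp - kout_T A_T \quad (T = liver, rest)}
#' \deqn{dAbr/dt = m_br CLup_br Cp \quad (sink: no efflux)}
#' \deqn{dAbo/dt = kappa V_acc(age) Cp - krel(age) Abo}
#' \deqn{dU/dt = fu GFR(age) Cp, \qquad dO/dt = oral}
#' The system is linear in state and inputs, so scenario responses
#' superimpose. Uptake clearances carry the individual's shared distribution
#' factor and the allometric size scale.
#'
#' @param t time in days.
#' @param state named numeric state vector (ug).
#' @param ctx simulation context from [buildSimContext()].
#' @return list with the derivative vector (deSolve convention).
#' @export
alDerivatives <- function(t, state, ctx) {
  if (any(!is.finite(state))) stop("non-finite state at t = ", t)
  if (t < 0) t <- 0
  if (t > ctx$tGridMax) t <- ctx$tGridMax
  j <- floor(t); w <- t - j; j <- j + 1L; j2 <- j + 1L
  vp <- ctx$vVp[j] * (1 - w) + ctx$vVp[j2] * w
  if (!is.finite(vp) || vp <= 0) stop("non-positive central volume at t = ", t)
  sc <- ctx$vScale[j] * (1 - w) + ctx$vScale[j2] * w
  clBone <- ctx$vBoneUp[j] * (1 - w) + ctx$vBoneUp[j2] * w
  krel <- ctx$vKrel[j] * (1 - w) + ctx$vKrel[j2] * w
  elim <- ctx$vGfrFu[j] * (1 - w) + ctx$vGfrFu[j2] * w
  cp <- state[[1L]] / vp
  clLi <- ctx$pClLi * sc
  clBr <- ctx$pClBr * sc * ctx$segMBrain
  clR <- ctx$pClR * sc
  bw <- ctx$vBw[j] * (1 - w) + ctx$vBw[j2] * w
  oral <- ctx$dietRate[findInterval(t, ctx$dietStartDays)] * bw / 7 *
    ctx$oralF * 1000
  dAp <- oral + ctx$segDepotRate + ctx$pKoLi * state[[2L]] +
    ctx$pKoR * state[[5L]] + krel * state[[4L]] -
    (clLi + clBr + clR + clBone + elim) * cp
  list(c(dAp,
         clLi * cp - ctx$pKoLi * state[[2L]],
         clBr * cp,
         clBone * cp - krel * state[[4L]],
         clR * cp - ctx$pKoR * state[[5L]],
         elim * cp,
         oral))
}

#' Simulate one individual
#'
#' Integrates the PBTK system with \code{deSolve::lsoda} (stiff-capable,
#' adaptive step; defaults atol 1e-9, rtol 1e-6), restarting the solver at
#' every dose event, depot exhaustion, diet-stage switch and
#' brain-multiplier boundary. Readouts are weekly by default.
#'
#' @param individual one-row individual data.frame (from a
#'   [VirtualPopulation-class] or [typicalIndividual()]).
#' @param scenario an [ExposureScenario-class].
#' @param params a [ModelParams-class].
#' @param phys a [Physiology-class].
#' @param tEnd horizon in years (at most the physiology table range).
#' @param atol,rtol solver tolerances.
#' @param readoutDays readout interval in days (7 = weekly).
#' @param initialAmounts optional named amounts (ug) overriding the
#'   individual's sampled initial levels (e.g. zero for a vaccines-only
#'   superposition run).
#' @param ... unused.
#' @return a trajectory data.frame: \code{time_days}, \code{age_years},
#'   compartment amounts (ug): \code{plasma}, \code{liver}, \code{brain},
#'   \code{bone}, \code{rest}, \code{urine}, \code{oralAbsorbed},
#'   \code{depotReleased}; concentrations \code{conc_plasma} (ug/L) and
#'   \code{conc_liver}, \code{conc_brain}, \code{conc_bone}, \code{conc_rest}
#'   (ug/g ww).
#' @examples
#' traj <- simulateIndividual(typicalIndividual(),
#'                            builtinScenario("FOOD_ONLY"), tEnd = 1)
#' max(traj$conc_plasma)
#' @rdname simulateIndividual
#' @export
setMethod("simulateIndividual", "data.frame",
  function(individual, scenario, params = ModelParams(),
           phys = defaultPhysiology(), tEnd = 50, atol = 1e-9, rtol = 1e-6,
           readoutDays = 7, initialAmounts = NULL, ...) {
  stopifnot(nrow(individual) == 1L)
  if (tEnd > max(phys@growth$age_years))
    stop("tEnd exceeds the physiology table range")
  ctx <- buildSimContext(individual, scenario, params, phys, tEnd)
  if (is.null(initialAmounts))
    initialAmounts <- aluPBTK::initialAmounts(individual, phys)
  y <- c(plasma = unname(initialAmounts[["plasma"]]),
         liver = unname(initialAmounts[["liver"]]),
         brain = unname(initialAmounts[["brain"]]),
         bone = unname(initialAmounts[["bone"]]),
         rest = unname(initialAmounts[["rest"]]),
         urine = 0, oralAbsorbed = 0)
  readout <- seq(0, ctx$tEndDay, by = readoutDays)
  if (readout[length(readout)] < ctx$tEndDay)
    readout <- c(readout, ctx$tEndDay)
  bp <- ctx$breakpoints
  out <- matrix(NA_real_, nrow = length(readout), ncol = 7,
                dimnames = list(NULL, names(y)))
  out[1, ] <- y
  for (s in seq_len(length(bp) - 1L)) {
    t0 <- bp[s]; t1 <- bp[s + 1L]
    ctx$segDepotRate <- sum(ctx$depots$rate_ug_d[
      ctx$depots$start_day <= t0 & t0 < ctx$depots$end_day])
    ctx$segMBrain <- if (ctx$mBrainEarly != 1 && t0 < ctx$mBrainBoundaryDay)
      ctx$mBrainEarly else 1
    inside <- readout[readout > t0 & readout <= t1]
    times <- unique(c(t0, inside, t1))
    sol <- deSolve::lsoda(y, times, alDerivatives, ctx, tcrit = t1,
                          atol = atol, rtol = rtol, maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0)
      stop("solver failure in segment [", t0, ", ", t1, "] days of scenario '",
           scenario@name, "'")
    y <- sol[nrow(sol), -1]
    if (length(inside))
      out[match(inside, readout), ] <- sol[match(inside, sol[, 1]), -1,
                                           drop = FALSE]
  }
  age <- readout / DAYS_PER_YEAR
  traj <- data.frame(time_days = readout, age_years = age, out,
                     depotReleased = depotReleasedCumulative(ctx$depots, readout))
  attr(traj, "depots") <- ctx$depots
  traj$conc_plasma <- traj$plasma / organVolume(phys, "plasma", age)
  for (tt in c("liver", "brain", "bone", "rest"))
    traj[[paste0("conc_", tt)]] <-
      traj[[tt]] / (organVolume(phys, tt, age) * 1000)
  traj
})

#' Mass-balance check of a trajectory
#'
#' The implemented system conserves mass:
#' \code{initial body + absorbed oral + released depot = body amounts + urine}
#' at every readout. Returns the worst relative error (relative to total
#' input); errors reflect solver accuracy only.
#'
#' @param traj trajectory from [simulateIndividual()].
#' @param tol diagnostic threshold; violations above it are reported (with the
#'   worst timepoint) via a warning.
#' @return maximum relative error (numeric).
#' @export
massBalance <- function(traj, tol = 1e-3) {
  body <- traj$plasma + traj$liver + traj$brain + traj$bone + traj$rest
  init <- body[1]
  input <- init + traj$oralAbsorbed + traj$depotReleased
  err <- abs(input - (body + traj$urine)) / pmax(input, .Machine$double.eps)
  if (max(err) > tol) {
    w <- which.max(err)
    warning(sprintf("mass-balance violation %.3g at age %.3f y",
                    max(err), traj$age_years[w]))
  }
  max(err)
}
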