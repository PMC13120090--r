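# Independent fixed-step RK4 oracle. The right-hand side is re-derived here
# from the documented model equations and evaluated through the physiology
# accessors (not through the solver's precomputed context), and the integrator
# is a plain classical Runge-Kutta loop -- an integration path fully
# independent of deSolve.
rk4Oracle <- function(individual, scenario, params, phys, tEnd, h = 0.1,
                      init = initialAmounts(individual, phys)) {
  tEndDay <- tEnd * 365.25
  grid <- seq(0, tEndDay + 1, by = 0.25)
  age <- pmin(grid / 365.25, max(phys@growth$age_years))
  fVp <- approxfun(grid, organVolume(phys, "plasma", age))
  fBw <- approxfun(grid, bodyWeight(phys, age))
  fGfr <- approxfun(grid, gfr(phys, age))
  br <- boneRates(phys, age)
  fVacc <- approxfun(grid, br$uptakeScale)
  fKrel <- approxfun(grid, br$releaseRate)
  refBw <- phys@renal$refBw; sizeExp <- phys@renal$sizeExp
  depots <- buildDepots(scenario@schedule, params, individual)
  st <- scenario@diet@stages

  deriv <- function(t, y) {
    a <- t / 365.25
    vp <- fVp(t)
    cp <- y[1] / vp
    sc <- (fBw(t) / refBw)^sizeExp * individual$fDist
    mbr <- if (a < scenario@brainMultiplierMaxAge) scenario@brainMultiplier else 1
    clLi <- params@clupLiver * sc
    clBr <- params@clupBrain * sc * mbr
    clR <- params@clupRest * sc
    clBone <- params@kappaBone * individual$fDist * fVacc(t)
    krel <- fKrel(t)
    elim <- params@fu * fGfr(t) * individual$fGfr
    stage <- findInterval(a, st$age_start_y)
    oral <- st$mg_per_kg_week[stage] * fBw(t) / 7 * scenario@diet@oralF *
      individual$fOral * 1000
    depot <- sum(depots$rate_ug_d[depots$start_day <= t & t < depots$end_day])
    c(oral + depot + params@koutLiver * y[2] + params@koutRest * y[5] +
        krel * y[4] - (clLi + clBr + clR + clBone + elim) * cp,
      clLi * cp - params@koutLiver * y[2],
      clBr * cp,
      clBone * cp - krel * y[4],
      clR * cp - params@koutRest * y[5],
      elim * cp,
      oral)
  }

  bp <- sort(unique(c(0, tEndDay, depots$start_day, depots$end_day,
                      st$age_start_y * 365.25,
                      scenario@brainMultiplierMaxAge * 365.25)))
  bp <- bp[bp >= 0 & bp <= tEndDay]
  y <- c(unname(init[c("plasma", "liver", "brain", "bone", "rest")]), 0, 0)
  for (s in seq_len(length(bp) - 1L)) {
    len <- bp[s + 1L] - bp[s]
    nStep <- max(1L, ceiling(len / h))
    hh <- len / nStep
    t <- bp[s]
    # evaluate inputs strictly inside the segment so step inputs stay constant
    for (k in seq_len(nStep)) {
      k1 <- deriv(t + 1e-9, y)
      k2 <- deriv(t + hh / 2, y + hh / 2 * k1)
      k3 <- deriv(t + hh / 2, y + hh / 2 * k2)
      k4 <- deriv(min(t + hh, bp[s + 1L] - 1e-9), y + hh * k3)
      y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + hh
    }
  }
  names(y) <- c("plasma", "liver", "brain", "bone", "rest", "urine",
                "oralAbsorbed")
  y
}
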