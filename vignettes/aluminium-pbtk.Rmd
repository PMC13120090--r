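---
title: "Modelling aluminium toxicokinetics of vaccination and diet"
author: "aluPBTK"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling aluminium toxicokinetics of vaccination and diet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aluPBTK)
```

## The model

aluPBTK simulates aluminium disposition in a growing female body from birth
to age 50 with a linear, time-varying compartment system. The state is a
vector of aluminium *amounts* (µg): a central ("plasma") compartment, liver,
brain, bone, rest-of-body, plus the cumulative urinary output and the
cumulative absorbed oral input used for bookkeeping. With
$C_p = A_p / V_p(\mathrm{age})$,

$$
\begin{aligned}
\dot A_p &= R_\mathrm{oral}(t) + R_\mathrm{depot}(t)
  + k_\mathrm{out,li} A_\mathrm{li} + k_\mathrm{out,r} A_\mathrm{r}
  + k_\mathrm{rel}(a) A_\mathrm{bo} \\
&\quad - \bigl[\mathrm{CL}_\mathrm{li} + m_\mathrm{br}\mathrm{CL}_\mathrm{br}
  + \mathrm{CL}_\mathrm{r} + \kappa_\mathrm{bone} V_\mathrm{acc}(a)
  + f_u\,\mathrm{GFR}(a)\bigr] C_p,\\
\dot A_T &= \mathrm{CL}_T C_p - k_{\mathrm{out},T} A_T
  \qquad (T = \text{liver, rest}),\\
\dot A_\mathrm{br} &= m_\mathrm{br}\,\mathrm{CL}_\mathrm{br} C_p
  \qquad \text{(sink: no efflux)},\\
\dot A_\mathrm{bo} &= \kappa_\mathrm{bone} V_\mathrm{acc}(a)\, C_p
  - k_\mathrm{rel}(a) A_\mathrm{bo},
  \qquad k_\mathrm{rel}(a) = \frac{V_\mathrm{res}(a)}{M_\mathrm{Ca}(a)},\\
\dot U &= f_u\,\mathrm{GFR}(a)\, C_p .
\end{aligned}
$$

The structural assumptions, in words:

* **Zero-order depots.** Each vaccine dose deposits its aluminium mass
  $D_0$ intramuscularly; the depot releases $k_\mathrm{abs} D_0$ per day
  until exhausted after $1/k_\mathrm{abs}$ days (AH 0.002784/day ≈ 1 year;
  AP 0.01098/day ≈ 3 months; AAHS is treated as AP, with which it shares
  physicochemical and dissolution behaviour). Absorbed aluminium is 100 %
  systemically available.
* **Brain is a sink.** Uptake is a small clearance; efflux is identically
  zero, so brain content is monotone non-decreasing. This is deliberately
  conservative for a retention-prone organ.
* **Bone follows calcium.** Uptake is proportional to the age-dependent
  calcium accretion flux $V_\mathrm{acc}$ (mg Ca/day), release uses the
  fractional calcium resorption rate $V_\mathrm{res}/M_\mathrm{Ca}$. During
  growth $M_\mathrm{Ca}$ is small and rising, so bone is a slowly recycling
  buffer in infancy and approaches stationary turnover in adulthood.
* **Renal elimination is GFR-driven.** Only the filterable fraction $f_u$
  of plasma aluminium is cleared: $f_u\,\mathrm{GFR}(a)\,C_p$. GFR matures
  as a Hill sigmoid of postmenstrual age,
  $\mathrm{PMA}^{\gamma}/(\mathrm{PMA}^{\gamma}+\mathrm{PMA}_{50}^{\gamma})$,
  on top of allometric size scaling $(\mathrm{BW}/60\,\mathrm{kg})^{0.75}$.
* **Growth dilution is implicit.** Amounts are the conserved quantities;
  concentrations are amounts divided by growing volumes, so the dilution of
  a fixed store by growth emerges without an artificial dilution term.
* **Linearity.** No saturable binding or transport is modelled, so
  superposition holds exactly: the food + vaccines trajectory equals the
  food-only trajectory plus the vaccines-only trajectory. All
  scenario-difference readouts rest on this property, and the test suite
  asserts it numerically.

### The central compartment

The "plasma" compartment is assigned a *plasma-equivalent central
distribution volume* — roughly the extracellular water, 35 % of body weight
at birth declining to 20 % in adults — rather than the anatomical plasma
volume of ~4–5 % of body weight. Reported plasma concentrations are central
amount over central volume, the usual central-compartment reading under
rapid plasma–interstitial equilibration. Two reasons: first, aluminium
equilibrates quickly with interstitial fluid compared with the weekly
readout scale; second, a literal plasma volume gives the central compartment
an eigenvalue of order 40/day in infants, making the system needlessly stiff
without changing any steady state or any clearance-determined increment
(both are invariant to the choice of $V_p$). With the central volume used
here the system is mildly stiff at most, which is also what makes the
fixed-step Runge–Kutta cross-check in the test suite meaningful.

## Age-dependent physiology

`defaultPhysiology()` ships a full-term female reference: body weight
3.5 kg at birth rising to a 60 kg adult plateau, organ masses (liver, brain,
wet marrow-including cartilage-free bone, central volume, rest) specified at
13 grid ages and interpolated piecewise-linearly as fractions of body
weight. Fractions were derived from target organ masses, which guarantees
that interpolated organ volumes are monotone during growth (the product of a
decreasing linear fraction and an increasing linear weight is concave, so it
cannot dip below its endpoints). The calcium table carries accretion and
resorption fluxes with an infancy level around 160 mg/day, a pubertal
accretion peak of 500 mg/day near age 13, and a stationary adult turnover of
400 mg/day against 1000 g of exchangeable bone calcium; adult stationarity
($V_\mathrm{acc} \approx V_\mathrm{res}$ within 5 % beyond age 30) is
asserted by the tests. Ages outside 0–50 years are rejected, never
extrapolated. Both tables are plain CSV and replaceable via `Physiology()`.

Renal defaults: adult GFR 148.3 L/day for the 60-kg reference female
(~103 mL/min absolute), $\mathrm{PMA}_{50} = 47.7$ weeks, $\gamma = 3.4$,
allometric exponent 0.75. At term birth (PMA 40 weeks) the maturation
fraction is ≈ 0.355.

## The default calibration

The mechanisms above fix the model structure but not its rate
constants, which published aluminium PBTK models estimate from animal and
human kinetic data. The `ModelParams()` defaults are the package's own
reference calibration, chosen once against three anchors: (i) the adult
food-only plasma median must sit inside the normal adult range 1–10 µg/L;
(ii) the infant plasma fold-increase from the first-year vaccinations should
be a moderate transient (the 2–5 fold band); (iii) single boosters in adults
should be marginal (fold ≤ 1.1). Secondary anchors were the adult food-only
tissue levels: steady-state ratios give
$A_\mathrm{li}/C_p = \mathrm{CL}_\mathrm{li}/k_\mathrm{out,li}$ and
$A_\mathrm{bo} = \kappa_\mathrm{bone} V_\mathrm{acc} C_p / k_\mathrm{rel}$,
which with the defaults put adult bone near 0.4–0.5 µg/g ww and adult liver
near 0.06–0.07 µg/g ww — the order of magnitude of published normal levels
(bone ULN 5, liver ULN 4 µg/g ww).

| parameter | default | unit | role |
|---|---|---|---|
| `clupLiver` | 0.8 | L/day | liver uptake clearance (reference adult) |
| `clupBrain` | 0.02 | L/day | brain intrusion clearance (sink) |
| `clupRest` | 120 | L/day | rest-of-body uptake (fast distribution buffer) |
| `koutLiver` | 0.01 | 1/day | liver return rate |
| `koutRest` | 0.02 | 1/day | rest return rate |
| `kappaBone` | 0.0027 | L/mg Ca | bone uptake per unit Ca accretion |
| `fu` | 0.06 | – | filterable plasma fraction |
| `kAbs` | 0.002784 / 0.01098 | 1/day | AH / AP(=AAHS) depot release |

On $f_u$: with ~90 % of plasma aluminium bound to transferrin, 0.1 is an
upper bound on the filterable fraction. The default 0.06 stays inside that
bound and, with the physiological adult GFR, places the adult food-only
steady state $R/(f_u\,\mathrm{GFR}) \approx 1.3$ µg/L — mid normal range —
whereas $f_u = 0.1$ would land just below 1 µg/L. Incomplete filterability
of the citrate-bound fraction makes a value below the bound defensible.

Initial levels at birth (fetal exposure) are sampled around medians of
plasma 2.2 µg/L, liver 0.16, brain 0.08, bone 1.0 and rest 1.0 µg/g ww.
Apart from the plasma median, these were chosen to be near equilibrium with
a 2.2 µg/L plasma level under birth physiology, so the food-only newborn
starts in quasi-steady state and early trajectories decline smoothly as the
low infant dietary intake takes over.

What this calibration is *not*: a fit to measured kinetics. Absolute
concentrations, the exact timing of the maximum median difference inside the
infancy window, and the absolute body burden at 50 years (of order 10 mg
here, between isotope-retention estimates of 2–7 mg and whole-body
chemical-analysis estimates of 35–40 mg) all depend on it and should be
re-derived from an externally estimated parameter set for quantitative use —
every constant is an argument to `ModelParams()` and every table a CSV.

## The virtual population

`samplePopulation()` emulates the study cohort: $N = 500$ female
individuals (any $n$ is allowed; the tests and the acceptance script run
paired cohorts of 50, and the sampling checks use $10^5$ — sizes chosen to
keep the default runs fast while leaving the Monte-Carlo error far below the
asserted tolerances). Inter-individual variability is multiplicative
lognormal with median 1 and $\sigma^2 = \ln(1+\mathrm{CV}^2)$ on oral
bioavailability, GFR, tissue distribution (one shared factor across all
uptake clearances and the bone coupling), and the per-adjuvant absorption
rates; initial organ levels are lognormal around their medians. The only
variability value anchored in the source material is the 50 % CV of the
absorption rates; the same CV is used as default everywhere else, and each
CV is a `VariabilitySpec` field.

Individuals are drawn from counter-based substreams of the master seed
(`seed`, `id` → substream), so the population is *structurally* identical
across scenarios — the pairing needed for median-difference contrasts — and
the first $k$ individuals of a large population equal the population of
size $k$.

What the generator does not emulate: correlation between an individual's
initial organ levels (sampled independently), covariate coupling between
body size and parameter variability (body weight is the reference growth
curve for everyone), male physiology, and preterm birth. Passing tests
therefore demonstrate correctness of the machinery and plausibility of the
population spread, not agreement with any measured cohort.

## Numerical choices

* **Integration.** `deSolve::lsoda` (adaptive, stiff-capable), absolute
  tolerance $10^{-9}$, relative $10^{-6}$. The solver is restarted at every
  discontinuity of the inputs: dose administrations, depot exhaustion times
  (individual-specific, since $k_\mathrm{abs}$ carries a lognormal factor),
  diet-stage switches, and the brain-multiplier age bound. `tcrit` pins each
  segment so the solver never evaluates beyond it.
* **Coefficient interpolation.** Physiology is pre-evaluated on a daily grid
  per simulation and linearly interpolated by direct indexing inside the
  right-hand side; the readout grid is weekly (per run configuration).
* **Verification.** Mass balance (initial + absorbed oral + released depot =
  body + urine) holds to ~10⁻¹³ relative; an independently coded fixed-step
  classical Runge–Kutta oracle (0.1-day steps) agrees within 0.5 % over a
  2-year horizon; a single-compartment reduction reproduces the closed form
  $C_{ss} = R/(f_u\,\mathrm{GFR})$ within 0.1 %.
* **Quantiles.** Pointwise empirical quantiles with linear interpolation of
  order statistics (`quantile` type 7).
* **Max-median-difference.** The argmax of the median difference over
  readouts inside a closed window; ties resolve to the earliest readout; the
  ratio is reported at the max-difference timepoint (not the max-ratio
  timepoint), and the p95 values are taken at that same timepoint.
* **Rounding of reported dose totals.** Half-up to one decimal
  (8.835 → 8.8, 9.335 → 9.3, 1.935 → 1.9), matching the printed convention;
  raw sums are always available.
* **Degenerate inputs.** Empty schedules are valid (food-only); a zero
  exchangeable bone calcium mass, non-contiguous diet stages, unknown
  adjuvants or tissues, inverted windows and off-grid readout ages are
  errors. Doses above the 1.25 mg pharmacopoeial limit warn but run, so
  hypothetical scenarios remain explorable. A value exactly at a reference
  level is *not* an exceedance.

## Design choices where the ground was open

* **Bone uptake as clearance-from-plasma.** "Proportional to calcium
  uptake" admits two readings: a clearance $\kappa V_\mathrm{acc} C_p$ or a
  fixed fraction of the Ca flux. The clearance form is adopted — it keeps
  the system linear in state, makes bone uptake respond to plasma levels,
  and has a well-defined zero-exposure limit.
* **Bone volume.** Model bone is wet, marrow-including and cartilage-free;
  concentrations use that volume, and the 0.497 dry-to-wet conversion of
  literature bone values compares against it.
* **HPV two-dose scheme** at 9 and 10 years; "at birth" means age exactly 0;
  dose ages in months convert as months/12.
* **Depot remainder in body burden.** `bodyBurden()` reports body
  compartments and the unreleased depot remainder separately. At median
  kinetics the remainder at age 50 is zero (the last dose at 49 years
  depletes within a year); individuals with a slow sampled absorption factor
  can carry a small remainder past 50, which is why it is reported rather
  than silently added.
* **Sensitivity switches as flags.** The maximum infant-formula diet
  (2 mg/kg/week below 6 months) and the 20× brain intrusion (below 6
  months, efflux kept at zero) are orthogonal switches on any scenario
  rather than separate scenario names.

## Known limitations

The calibration caveats above are the main ones. In addition: the infancy
maximum median difference falls late in the 0–2-year window here (after the
11/12-month dose cluster) while the clearest transient *peak* of the
food + vacc curve sits near the 4-month doses — which of the two dose
clusters dominates the windowed difference is calibration-dependent.
Plasma protein binding is a constant fraction, not a binding model;
lymph-node/particle kinetics, lactational and transplacental transfer are
not modelled (initial levels stand in for gestational exposure); tissue
concentrations are whole-organ averages. Population spread reflects the
default 50 % CVs and is narrower than some published p5–p95 ranges.
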