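---
title: "Methods: ship emission scenarios, PM2.5 health burden and aerosol forcing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ship emission scenarios, PM2.5 health burden and aerosol forcing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shipimpact)
```

## What the package models

Marine fuel-sulphur policy trades off two consequences of ship exhaust:
sulphate aerosol formed from SO~x~ raises ambient PM~2.5~ and with it
premature cardiovascular and lung-cancer mortality and childhood asthma, but
the same aerosol scatters sunlight and brightens clouds, cooling the planet.
`shipimpact` implements that whole causal chain as a desk-scale pipeline:

1. **Activity-based emissions.** AIS-style vessel movement records are
   combined with registry-style technical data into gridded emission
   inventories per fuel-sulphur scenario.
2. **Exposure surrogate.** A steady-state, lifetime-based dispersion model
   turns emissions into PM~2.5~ component concentration fields.
3. **Health burden.** Concentration-response (C-R) functions convert
   scenario concentration pairs into gridded excess mortality and morbidity
   with confidence bounds.
4. **Aerosol forcing.** Single-band box expressions estimate the direct and
   first-indirect (Twomey) radiative forcing of the ship aerosol.

Three scenarios are compared on one shared synthetic world: `NO_SHIPPING`
(the counterfactual), `BAU` (business as usual, 2.7% residual fuel sulphur
outside control areas) and `ACTION_2020` (a 0.5% global cap). All randomness
lives in the world generator; every downstream stage is a pure transform, so
fixed seeds make whole runs bit-reproducible.

## Emission model

Per activity record, propulsion power follows the cubic propeller law
$L = \min\{\max[(v/v_d)^3, 0.02], 1\}$: load scales with the cube of the
speed ratio, floored at 2% to represent auxiliary (hotelling) demand and
capped at full power. A full resistance calculation would need hull-form
data the synthetic registry does not carry; the cubic law preserves the
load dependence the emission factors actually consume.

Specific fuel-oil consumption is defined at 80% load and penalised off
design with the normalised quadratic $q(L) = 0.455L^2 - 0.71L + 1.28$,
$\mathrm{SFOC}(L) = \mathrm{SFOC}_{80}\, q(L)/q(0.8)$. The curve reproduces
both published low-load extremes (165 to 186 g kWh^-1^ for heavy fuel oil,
250 to 282 g kWh^-1^ for distillate) to the printed integer.

Species factors (g kWh^-1^):

* **NO~x~** follows the MARPOL Annex VI Regulation 13 curves by engine
  class and crankshaft speed (Tier I 17 / $45n^{-0.2}$ / 9.8, Tier II
  14.4 / $44n^{-0.23}$ / 7.7, Tier III 3.4 / $9n^{-0.2}$ / 2.0 for
  slow/medium/high-speed diesels), with pre-regulation Tier 0 engines at
  110% of Tier I.
* **SO~x~** comes from fuel sulphur content times fuel burned. A
  fuel-family fraction of the fuel sulphur leaves the stack bound in
  primary sulphate (0.04 distillate, 0.063 heavy fuel oil — the values
  implied by the published gaseous-SO2 factors, adopted to close the
  sulphur mass balance exactly); the remainder is emitted as SO~2~
  (factor 2 from S to SO~2~ mass). The identity
  $s\cdot\mathrm{SFOC} = \mathrm{EF_{SO_2}}/2 + \mathrm{EF_{SO_4\!-\!S}}$
  holds to machine precision and is enforced by tests.
* **PM** interpolates piecewise-linearly between the 0.1/0.5/2.7% S anchors
  at the 80% and 25% load points, linearly in load between them, clamped
  outside. The non-sulphate residual (PM minus sulphate mass) is carried as
  elemental/organic carbon and ash.
* **CO~2~** is proportional to SFOC with table-implied carbon factors
  515/165 (HFO) and 803/250 (distillate).

The effective fuel sulphur at a position and date is the minimum of the
scenario's global content (2.7% BAU, 0.5% Action) and every control-area
cap whose polygon contains the position and whose effective date has
passed (emission control areas 0.1% S; EU-directive and Chinese domestic
areas 0.5% S). Inventories are projected from the 2015-style base year to
2020 with per-ship-type compound annual growth (dry bulk +1.74%, liquid
bulk -1.90%, unitised +2.79%, passenger -0.55%, miscellaneous 0.00%).
Masses are accumulated in grams and reported in tonnes to avoid unit
drift; cell membership is half-open [lower, upper) in both coordinates.

## Exposure surrogate

A chemical-transport model is out of scope; the health and forcing stages
consume concentration fields, not chemistry internals, so the package uses
a steady-state lifetime surrogate that preserves the two properties the
downstream maths relies on — linearity in emissions and spatial decay away
from the source:

$$C = \frac{Q\,\tau}{A\,h_{mix}}$$

per cell, where $Q$ is the emission rate, $\tau$ the species lifetime,
$A$ the cell area and $h_{mix}$ the mixing height, after spreading the
column mass with an isotropic exponential kernel of e-folding length
$\ell = u\,\tau$ (wind speed times lifetime). The kernel is normalised
over the closed domain, so spreading conserves total mass to numerical
precision (a regression-guarded invariant). Species lifetimes default to
1.5 d for SO~2~ (primary sink: oxidation to sulphate), 2.8 d for sulphate,
2.0 d for nitrate and 2.5 d for primary particles. Half of the emitted
SO~2~ sulphur is routed to sulphate (oxidation and deposition sinks of
comparable strength; configurable), a 10% share of NO~x~ nitrogen forms
aerosol nitrate, and ammonium accompanies both at neutralisation
stoichiometry. At steady state the atmospheric sulphur burden equals
emission rate times lifetime per species, and the mean sulphur lifetime is
the sink-flux-weighted average of 1.5 and 2.8 d — both identities are
asserted in tests.

When the Action scenario lowers sulphate relative to BAU, freed ammonia
forms some ammonium nitrate. The surrogate offsets 1% of the local
sulphate reduction by default, up to 15% in designated high-ammonia cells
and never more, capped by available ammonia equivalent — mimicking the
reported magnitude bounds of that compensation without the full
equilibrium chemistry.

## Health burden

For endpoint incidence rate $B$ (per 100,000 cohort persons per year) and
exposed cohort population $P$:

$$E = \mathrm{AF}\cdot B\cdot P,\qquad
\mathrm{AF} = \frac{\mathrm{RR}-1}{\mathrm{RR}},\qquad
\mathrm{RR} = e^{\beta\,(C_1-C_0)}$$

so that $E = [1 - e^{\beta (C_0 - C_1)}]\,B\,P$ per grid cell. Default
coefficients (per µg m^-3^ PM~2.5~): cardiovascular mortality
$\beta = 0.023111$ (95% CI 0.013103–0.033647) and lung-cancer mortality
$\beta = 0.031481$ (95% CI 0.006766–0.055962), both attributed wholly to
the 30+ cohort; childhood asthma $\beta = 0.002469$ (95% CI
0.001291–0.003633) for the 14-and-under cohort. Confidence bounds are
propagated by recomputing $E$ at the CI ends of $\beta$; ordering
low ≤ central ≤ high is guaranteed for $\Delta C \ge 0$.

The field calls $RR = e^{\beta\Delta C}$ the *linear* form although it is
exponential in $\Delta C$; the package keeps that naming. A *log-linear*
alternative $RR = ((C_1+1)/(C_0+1))^\beta$ (Ostro-2004 convention) is also
provided. Published log-linear coefficients for these endpoints live in
supplementary literature and are not bundled; requesting the log-linear
form with default coefficients therefore reuses the linear-form betas with
a warning. Note an algebraic consequence: at *equal* $\beta$ the concave
log form can never exceed the exponential form for $\Delta C > 0$ (since
$\ln\frac{C_1+1}{C_0+1} < C_1 - C_0$); the often-quoted "log-linear is
higher at low background" behaviour appears only with the larger
log-scale coefficients those studies fit, and the tests demonstrate the
crossover with a coefficient of that magnitude.

Scenario burdens are computed against the no-shipping counterfactual;
avoided burden between scenarios is the difference of those totals
(additive by construction, exact before rounding). Report rounding follows
the conventions of the field's summary tables: mortality to the nearest
100 cases, asthma to the nearest 100,000. Age-standardised incidence rates
convert to crude rates via a population-structure ratio
(`crude = ASR × ratio`); countries missing from an incidence table fall
back to the mean over reporting countries.

## Aerosol forcing

**Direct effect.** A single-band clear-sky box expression
(Haywood–Shine type):

$$F = -\frac{S_0}{4} T_{atm}^2 (1-f_c)\,\omega\,\bar\beta\,\Delta\mathrm{AOD}
\left[(1-R_s)^2 - \frac{2R_s}{\bar\beta}\Big(\frac{1}{\omega}-1\Big)\right]$$

with solar constant $S_0 = 1361$ W m^-2^, transmittance $T_{atm} = 0.76$,
cloud fraction $f_c$, single-scattering albedo $\omega$, upscatter
fraction $\bar\beta = 0.29$ and surface albedo $R_s$. $\Delta$AOD comes
from the sulphate-plus-nitrate column mass at a fixed mass extinction
efficiency (8.5 m² g^-1^, a standard dry-sulphate value). The bracket has
exactly one root in $\omega$ for $R_s > 0$,
$\omega^* = [1 + \bar\beta(1-R_s)^2/(2R_s)]^{-1}$, increasing in $R_s$:
partially absorbing aerosol tips from cooling to warming over bright
surfaces, which is why the direct-effect sign hinges on the assumed SSA.
`ssa_sensitivity()` tabulates this. Full spectral radiative transfer is
deliberately replaced by this box form: it retains every sensitivity of
interest (SSA, cloud fraction, surface albedo) at desk scale, but absolute
global mW m^-2^ values are not reproduction targets.

**First-indirect (Twomey) effect.** Cloud droplet number follows the
empirical multi-component relation $D_n = a + b\,C_{NSS} + c\,C_{SSLT}$
with $a = 31$, $b = 93.5$ per µg m^-3^ non-sea-salt sulphate and $c = 16.5$
per µg m^-3^ sea salt — a form with a physically meaningful pristine
asymptote $a$. With these constants the package reads $D_n$ in cm^-3^ (the
per-m^3^ unit sometimes printed alongside them is implausible for cloud
droplets); only the ratio $D_{n,1}/D_{n,0}$ enters the albedo change, so
the unit choice cancels. Cloud albedo responds with the susceptibility
form $\Delta A = \frac{A_0(1-A_0)}{3}\ln(D_{n,1}/D_{n,0})$ and the flux
change is $F = -I\,f_c\,\Delta A\,T_{atm}^2$, area-weighted to a global
mean. Two vertical-mixing end-members bracket the uncertainty: `well_mixed`
exposes the cloud to the full sulphate perturbation; `detached` assumes
convection does not lift sulphates into the upper cloud and scales the
in-cloud sulphate by a detachment factor $d = 0.25$ before the droplet
relation — a value tuned so the detached/well-mixed forcing ratio matches
the roughly fourfold weakening reported for that assumption (it is the
ratio, not the absolute values, that the factor controls). Detached-mode
magnitude is provably at most the well-mixed magnitude for any $d \le 1$.

## The synthetic world

No deposited input data exist for this pipeline, so a generator supplies
every input with the statistical structure the analysis assumes:

* **Land/sea and countries** — a threshold on smoothed Gaussian noise
  (35% land by default) partitioned into countries by nearest-seed
  assignment. Procedural masks keep the package download-free; coastline
  geometry is not realistic and is not meant to be.
* **Population** — a multinomial draw over land cells (total conserved
  exactly in integer persons) with a lognormal texture and a coastal
  multiplier (default 3; coastal cells are land cells bordering sea). Age
  cohort fractions (30+ between 0.35 and 0.60; 14-and-under between 0.15
  and 0.35, jointly ≤ 1) are uniform within a country, matching the
  simplification of applying national cohort fractions uniformly in space.
* **Traffic** — vessels shuttle along straight lane corridors between sea
  cells with Gaussian cross-track scatter (0.4 cells), hourly records,
  cruise speeds 60–95% of design speed with occasional near-zero
  manoeuvring. Hourly granularity is finer than a typical 3-h output step,
  so temporal aggregation is genuinely exercised.
* **Incidence** — cardiovascular 400–900 and lung-cancer 20–80 deaths per
  100,000 aged 30+, childhood wheeze 5,000–15,000 per 100,000 children:
  magnitudes chosen once to bracket typical national statistics. A quarter
  of countries report only ASR values plus a crude:ASR ratio, exercising
  the conversion path.
* **Meteorology and background PM** — smooth fields within physical
  bounds: cloud fraction 0.15–0.85, insolation 120–340 W m^-2^, wind
  2–12 m s^-1^, mixing height 300–1500 m, sea salt 2–15 µg m^-3^ over sea
  and zero over land, albedo 0.06 over sea and 0.15–0.40 over land. The
  background PM~2.5~ field has a lognormal long tail over land decaying
  seaward, so that sea salt is the majority background component over the
  open sea — the regime in which marine PM is mostly natural.

What the generator does **not** emulate: seasonal cycles, demographic
pyramids, real shorelines or trade-route geography, correlated
multi-species chemistry. Passing tests therefore demonstrate the internal
correctness and the qualitative response structure of the method — policy
monotonicity, closed-form sulphur arithmetic, sign and ordering of forcing
responses — not agreement with any real region's absolute burden.

## Numerical choices and degenerate inputs

* Problem sizes: unit tests run on 20×20-cell worlds with 10–60 vessels;
  the structural end-to-end suite uses a 50×50 world, 200 vessels, 72 h of
  traffic and all three scenarios. These sizes were chosen to exercise the
  full pipeline in seconds while keeping every cell count large enough for
  the rank tests (≥ 1000 cells for the coastal-bias test).
* The open-ocean SO~2~ reduction from 2.7% to 0.5% S is the closed form
  $(2.7-0.5)/2.7 = 81.48\%$, independent of fleet composition because the
  gaseous split is linear in sulphur content; any traffic share inside a
  control area (already capped in both scenarios) pulls the global
  reduction strictly below that value.
* Empty record lists, zero-vessel fleets and zero-emission inventories
  produce exact zeros, not NaNs; records outside the grid are counted and
  excluded; a zero mixing height, a land-based lane endpoint, an unknown
  fuel family or ship type, and negative concentrations or rates all raise
  configuration/input errors naming the offending quantity.
* Rounding only happens at the reporting edge (`report_round`,
  `rounded = TRUE` in `compare_scenarios()`); all internal arithmetic is
  double precision, and the spread kernel conserves mass to 1e-9 relative.

## Known limitations

The exposure surrogate has no vertical structure, no deposition fields and
no nonlinear chemistry, so it cannot reproduce absolute concentration
magnitudes of a chemical-transport model — only linear-response structure.
The forcing box formulas are single-band and clear-sky/cloud-fraction
weighted; second-indirect (cloud lifetime) effects are excluded by design.
Auxiliary engines and boilers are not modelled as separate machinery, and
scrubber-equivalence compliance options are out of scope. Global totals of
the kind printed in full-scale assessments (hundreds of thousands of
deaths, tens of mW m^-2^) require global traffic, meteorology and
population data and are deliberately not targets of the synthetic runs.
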