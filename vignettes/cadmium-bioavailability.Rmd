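---
title: "Modelling cadmium bioavailability in soils: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cadmium bioavailability in soils: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cadsoil` estimates how vulnerable a soil is to cadmium contamination from
properties of the *intact* (uncontaminated) soil.  The chain of reasoning
it implements is: (i) the ecologically relevant quantity is not total Cd
but the labile fraction, measured here by the diffusive gradients in
thin-films (DGT) technique; (ii) among the many correlated physicochemical
properties of a soil, cation exchange capacity (CEC) and pH are sufficient
proxies for the two independent axes of variation; (iii) a log-linear
regression with a pH-by-dose interaction predicts the DGT-measured
concentration from CEC, pH and the added Cd; and (iv) a biotic ligand
model (BLM) — mass-action competition of Cd²⁺, Ca²⁺, Mg²⁺ and H⁺ for a
single soil ligand — gives that regression a mechanistic interpretation.

This vignette records the models, their assumptions, and the design
decisions taken where the methodology left genuine latitude.  It states no
empirical result that the package's tests do not themselves compute.

## 1. DGT concentration calculation

A DGT sampler accumulates metal in a resin gel behind a diffusive layer.
From the eluate concentration $C_\mathrm{Cd}$ (µg/L) the accumulated mass
per area and the time-averaged concentration at the sampler face are

$$M_\mathrm{DGT} = \frac{C_\mathrm{Cd}\,(V_\mathrm{HNO_3}+V_\mathrm{gel})}{A\,f_e},
\qquad
[\mathrm{Cd_{DGT}}] = \frac{M_\mathrm{DGT}\,\Delta g}{D\,t},$$

with defaults $\Delta g = 0.082 + 0.014$ cm (gel + filter),
$D = 6.09\times10^{-6}$ cm²/s, $t = 86400$ s, $V_\mathrm{HNO_3} = 1$ mL,
$V_\mathrm{gel} = 0.16$ mL, $A = 3.14$ cm², $f_e = 0.8$.  These formulas
are dimensionally sloppy as usually written (µg/cm³ vs µg/L), so
`cadsoil` fixes the unit convention: volumes are entered in mL and
converted internally, and the final ×1000 step from µg/cm³ to µg/L is
explicit and tested.  End to end the computation is linear,
$[\mathrm{Cd_{DGT}}] = k\,C_\mathrm{Cd}$ with $k = 8.43\times10^{-2}$ at
the defaults.

No correction by the soil-specific ratio $R_\mathrm{diff}$ is applied or
offered: a defensible $R_\mathrm{diff}$ needs a concentration-independent
distribution coefficient, which spiked soils do not have.  This is a
deliberate non-goal, not a missing default.

## 2. Choosing proxy variables: correlations and factor analysis

Soil properties are strongly interdependent, which makes a regression on
all of them collinear.  `property_correlations()` computes the Pearson
matrix (pairwise-complete by default, complete-case on request;
zero-variance properties are flagged `NA` rather than letting `NaN`
propagate).  `soil_factor_analysis()` standardizes the nine numeric
properties (sand, silt, clay, CEC, specific surface area, WHC, pH, total
C, ignition loss), extracts two factors by maximum likelihood, applies the
promax rotation and estimates regression-method scores.

Decisions worth recording:

* **Variance proportions come from the unrotated ML solution.**  After an
  oblique rotation, per-factor "variance explained" is not additive; the
  unrotated sums of squared loadings are the quantities whose cumulative
  sum is meaningful.  The output labels this basis.
* **Missing data.**  The packaged property table has no surface-area value
  for the OECD artificial soil.  The default drops that sample (n = 16),
  an option mean-imputes instead; the choice moves the factor-1 proportion
  by about a percentage point.
* **Sign convention.**  Each factor is flipped so its largest-magnitude
  loading is positive.
* **Proxy selection rule.**  `select_proxies()` groups properties by their
  dominant factor and takes the highest-loading member, *except* that a
  property on the preference list (`cec`, then `ph`) supersedes it when
  its loading is within 0.5 of the group maximum.  The preference encodes
  domain convention rather than statistics: CEC and pH are the routinely
  measured, mechanistically interpretable drivers of metal sorption, and
  on the packaged data they are statistically interchangeable with the
  properties that top their groups (total C and clay respectively).  The
  0.5 margin is deliberately wide — it expresses "member of the same
  strongly co-loading group", not a near-tie; genuine near-ties between
  non-preferred candidates (loading difference < 0.05) are reported, not
  silently broken.

## 3. Regression models for log₁₀[Cd_DGT]

Two OLS models, both in log₁₀ (the response is in µg/L, so only the
intercept depends on the unit):

* per dose level: $\log_{10}[\mathrm{Cd_{DGT}}] = b_1\,\mathrm{CEC} + b_2\,\mathrm{pH} + c$;
* pooled, with interaction:
  $\log_{10}[\mathrm{Cd_{DGT}}] = b_1\,\mathrm{CEC} + b_2\,\mathrm{pH} +
  b_3 \log_{10}[\mathrm{Cd_{Add}}] + b_4\,(\mathrm{pH}\times\log_{10}[\mathrm{Cd_{Add}}]) + c$.

The interaction term is the scientific point: the pH effect weakens as the
dose grows, which the BLM later rationalizes as protons being displaced
from the ligand by added Cd.  Zero-addition control rows are excluded by
the caller (the log dose is undefined); `standardize = TRUE` z-scores the
regressors (denominator $n-1$) for per-SD effect sizes; significance
stars use two-sided t tests at 5/1/0.1% with no multiplicity correction
(presentation only).  `predict_cd_dgt()` returns $10^{\hat y}$ with an
interval formed on the log scale and back-transformed.  Fits are
validated against closed-form normal-equations oracles in the tests, and
rank deficiency raises a singular-design error instead of silently
dropping a column.

## 4. The biotic ligand model

One ligand L binds each cation M ∈ {Cd, Ca, Mg, H} by
$\mathrm{M + L \leftrightarrow ML}$ with affinity constant
$K_M = [\mathrm{ML}]/([\mathrm{M}][\mathrm{L}])$ (1/M).  The ligand site
is divalent; two protons occupy one site, so every proton term carries a
stoichiometric factor 2.  All solution concentrations are carried in mM on
a 100%-WHC volume basis: measured concentrations from the 200%-WHC slurry
are doubled, $[\mathrm{H^+}] = 2\times10^{-\mathrm{pH}}$, and the dose
conversion is $[\mathrm{Cd_{Add\text{-}s}}] = \mathrm{Cd_{Add}}/(\mathrm{WHC}\times 2)$
mg/L assuming complete dissolution of the added CdCl₂, followed by the
molar conversion with the Cd atomic weight 112.41 g/mol (overridable; the
choice is the standard atomic weight).

**Forward solver.**  `speciate()` reduces the equilibrium to one unknown,
the free ligand $[\mathrm{L}]$, via the ligand balance
$L^0 = [\mathrm{L}]\,(1 + \sum_i s_i K_i [\mathrm{M}_i])$ with
$[\mathrm{M}_i] = M_i^0/(1 + s_i K_i [\mathrm{L}])$ and $s_H = 2$.  The
balance is strictly increasing in $[\mathrm{L}]$, vanishes at 0 and is
$\ge L^0$ at $L^0$, so the root is bracketed in $(0, L^0]$ and found by
Brent's method to a relative tolerance of $10^{-12}$.  Tests close every
mass balance to $10^{-8}$ and check the root against an independent
grid-refinement oracle.

**Stage 1.**  For each competing cation the isotherm linearizes to
$$\frac{1}{[\mathrm{M}]} = \frac{1}{M^0}\left(1 + s_M\frac{K_M}{K_{Cd}}\cdot
\frac{[\mathrm{Cd}]^0-[\mathrm{Cd}]}{[\mathrm{Cd}]}\right),$$
an OLS line in $x = ([\mathrm{Cd}]^0-[\mathrm{Cd}])/[\mathrm{Cd}]$ giving
the total $M^0$ (1/intercept) and the affinity ratio $K_M/K_{Cd}$
(slope/intercept, divided by $s_M$ — for the proton the raw slope
estimates $2K_H/K_{Cd}$, and omitting the division makes the
forward/inverse round trip recover $K_H$ twice too large).  The free Cd
is taken to be the DGT-measured concentration; that equivalence is an
approximation, since DGT integrates all labile species.  Fits with
non-positive slope or intercept have no physical reading and are returned
flagged inadmissible rather than raised.

**Stage 2.**  With the ratios fixed, the bound Cd
$[\mathrm{CdL}] = [\mathrm{Cd}]^0 - [\mathrm{Cd}]$ is fitted by least
squares against
$$[\mathrm{CdL}] = \frac{[\mathrm{Cd}]\,L^0}
{1/K_{Cd} + [\mathrm{Cd}] + \tfrac{K_{Ca}}{K_{Cd}}[\mathrm{Ca}]
 + \tfrac{K_{Mg}}{K_{Cd}}[\mathrm{Mg}] + 2\tfrac{K_{H}}{K_{Cd}}[\mathrm{H}]},$$
leaving two free parameters, $L^0$ and $K_{Cd}$.  Positivity is enforced
by optimizing their log₁₀; a coarse deterministic grid scan (60 × 60 over
$L^0 \in [10^{-3}, 10^{3}]$ mM, $K_{Cd} \in [10^{0}, 10^{7}]$ 1/M) seeds
a Nelder–Mead refinement, so the optimum is reproducible without random
restarts.  Three residual weightings are offered: unweighted (the default,
matching the plain squared-sum objective of the original procedure),
relative (residual/[CdL]), and `inverse_cd` (residual/[Cd]).  The spiked
levels span four orders of magnitude, so the unweighted objective is
dominated by the top level and leaves $K_{Cd}$ weakly identified; when
measurement noise is multiplicative on the measured free ion — as it is
for the instrument noise the simulator emulates — the standard deviation
of $[\mathrm{CdL}]$ is proportional to $[\mathrm{Cd}]$, making
`inverse_cd` the inverse-variance estimator.  The recovery tests use it
for that reason; the default stays unweighted.

**What the fits can and cannot pin down.**  Four spiked levels carry
little information per parameter.  The noiseless round trip is exact to
$10^{-6}$, but at 5% multiplicative noise the median relative errors over
100 replicates are a few percent for the cation totals, around 10% for
the affinity ratios and $K_{Cd}$, and parameter sets estimated from only
three usable levels (as in the packaged cation table) should be read as
order-of-magnitude values.  For the same reason the packaged
published-scale parameter table is treated as an input to the forward
solver, not as a target the fitters are expected to reproduce from the
three printed points.  Observed-vs-predicted comparisons use the
conventional factor-of-2 band (`predict_free_cd()`); model-data agreement
is expected to degrade below ~0.01 µM, where DGT-labile and free-ion
concentrations diverge most.

## 5. The synthetic-data generator

`generate_soil_table()` draws each soil from a two-latent-factor model —
a sorption/organic axis and a coarseness axis — with type-specific factor
means (5 sandy, 4 andosol, 3 brown-forest, 5 cohesive soils by default),
then clips to physical ranges and renormalizes texture to 100%.  This
reproduces the field table's qualitative structure: CEC–WHC–total
C–ignition loss–surface area strongly positively correlated, pH aligned
with sand, and clear type separation — it does *not* reproduce sampling
idiosyncrasies (the field table's one texture row summing to 88.9, the
missing surface-area cell) or any spatial/pedological realism, so passing
tests speak to the statistical machinery, not to soil genesis.

`generate_regression_dataset()` applies the interaction model forward
with additive Gaussian noise on the log₁₀ scale (matching the log-linear
model; default σ = 0.2).  `generate_blm_dataset()` converts doses to
total solution Cd, solves the true equilibrium with `speciate()`, and
perturbs the observed free concentrations with mean-one multiplicative
lognormal noise (default CV 5%, respecting non-negativity).  Because the
same forward solver also appears inside the fitters' round trip, the
solver itself is cross-checked against an independent brute-force grid
oracle, so recovery tests are not a function testing itself.  Per-type
BLM truth presets live in a reviewable YAML file
(`inst/extdata/blm_type_presets.yaml`).  Defaults mirror the study
conditions (17 soils, four doses 1.5/15/150/1000 mg/kg, WHC 0.232 for
the dose conversion); all generators are deterministic given
`sim_config(seed = ...)`.

## 6. Test problem sizes

The suite's stochastic checks use: 100 replicates of the 4-level BLM
round trip at 5% CV (median-error acceptance), a 200-replicate
Monte-Carlo calibration of the interaction regression at n = 68 and
σ = 0.2 (bias within 2 Monte-Carlo SEs, 95% CI coverage in [0.90,
0.99]), 50-seed checks of the generator's correlation targets, and
10⁵–10⁶-point grid oracles for the speciation root.  These sizes make the
Monte-Carlo standard errors small relative to the tolerances they guard
while keeping the default `testthat` run under a minute.

## 7. Known limitations

* Single ligand class, concentration-based (no activity corrections), no
  electrostatic or multi-site extensions (WHAM/NICA-Donnan are out of
  scope), no toxicity endpoint.
* The DGT-equals-free-ion reading understates speciation at low
  concentrations.
* Aging of the contaminated soil is not modelled (held negligible by the
  underlying experimental design).
* The per-level regression needs ≥ 4 observations and errors below that;
  saturated designs elsewhere are flagged by a zero-residual-df warning
  rather than refused.
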