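---
title: "From flashlet trains to chlorophyll budgets: the cyanophys analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From flashlet trains to chlorophyll budgets: the cyanophys analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanophys)
```

cyanophys implements the quantitative chain used to characterise the
photophysiology of cyanobacteria undergoing iron depletion: from raw
single-turnover fluorescence transients and immunoblot band volumes to
electron-transport light-response parameters, photosystem
stoichiometries and a chlorophyll-allocation budget. This vignette
explains the models behind each stage, the parameters that matter, the
numerical choices made, and what the synthetic-data generators do and
do not emulate.

## Single-turnover fluorescence induction

A fast repetition rate (FRR) measurement fires a train of microsecond
excitation flashlets — by default 40 flashlets of 2 µs separated by
2 µs of darkness — at a dilute cell suspension. Each flashlet deposits
a photon dose

$$\Delta D = I \cdot c \cdot \Delta t,$$

where $I$ is the flash intensity (µmol photons m⁻² s⁻¹), $\Delta t$
the flash duration, and $c = 6.02214076\times10^{-3}$ converts
µmol photons m⁻² s⁻¹ to photons Å⁻² s⁻¹ (Avogadro's number
$\times 10^{-6}$ mol/µmol $\times 10^{-20}$ m²/Å²). Defaults are
30,000 µmol photons m⁻² s⁻¹ at 625 nm (phycobilisome-absorbed
red-orange light) and 100,000 at 455 nm (chlorophyll-absorbed blue
light). The whole train lasts 160 µs, far less than the ~1000 µs a
closed PSII centre needs to pass its electron onward, so centres close
progressively and never re-open within a measurement; the protocol
constructor rejects any train reaching 1000 µs for this reason, and
re-opening is deliberately not modelled.

With no excitonic connectivity between centres ($p = 0$), closure
follows the cumulative one-hit Poisson law

$$C(D) = 1 - e^{-\sigma_{PSII} D},$$

with $\sigma_{PSII}$ the functional absorption cross-section
(Å² quanta⁻¹). With connectivity $p > 0$, excitation arriving at a
closed centre can migrate to an open neighbour, and the closed
fraction solves

$$\frac{dC}{dD} = \sigma \frac{1-C}{1-pC},$$

which `closure_fraction()` integrates with 100 fourth-order
Runge-Kutta sub-steps per flashlet (the test suite checks this against
an adaptive ODE integrator to $10^{-6}$). Fluorescence follows the
standard saturation map $F = F_O + (F_M - F_O)\,C\,(1-p)/(1-pC)$,
linear in $C$ at $p = 0$. Connectivity is fixed at 0 in fitting by
default because the study design this package serves never reports a
connectivity estimate; the generator and the closure model accept
$p > 0$ so the sensitivity of $\sigma$ estimates to ignored
connectivity can be explored.

`fit_dark_transient()` estimates $(F_O, F_M, \sigma_{PSII})$ by
bounded Levenberg-Marquardt least squares, initialised with
$F_O^{(0)}$ = first point, $F_M^{(0)}$ = maximum, and $\sigma^{(0)}$
from the dose at half-rise via the closed form. A deterministic
three-point multistart ($\sigma^{(0)} \times \{0.3, 1, 3\}$) guards
against the shallow-RSS valley at small $\sigma$; the lowest RSS wins,
ties broken toward the smaller $\sigma$. $F_V/F_M = (F_M - F_O)/F_M$.

Under actinic light a fraction of centres is already closed and the
train rises from the steady-state level $F_S$ toward $F_M'$.
`fit_light_transient()` fits the same rise form and derives

$$q_P = \frac{F_M' - F_S}{F_M' - F_O'}, \qquad
  \Phi_{PSII} = \frac{F_M' - F_S}{F_M'},$$

approximating $F_O'$ by the dark-measured $F_O$, which is appropriate
for these strains. When non-photochemical quenching pushes $F_S$ below
$F_O$, this approximation can produce $q_P > 1$; we clip to $[0,1]$
and warn rather than silently guess what the instrument intended.
$\Phi_{PSII}$ uses the Genty form because only the name, not the
formula, is conventional in the source literature for this chain.

### Precision limits

The information content of one 40-flashlet transient bounds how well
$\sigma$ can be recovered: at additive Gaussian noise of 2% of $F_V$
the Cramér-Rao bound for the three-parameter fit puts the relative
standard deviation of $\hat\sigma$ at 3.25%, i.e. a median absolute
error of about 2.2%, and simulation shows the least-squares estimator
sits essentially on that bound. Single-transient $\sigma$ estimates at
that noise level are therefore reported with ~2% median error by
construction, not by estimator defect; replicate averaging over the
5-6 cultures of the emulated design brings the error of the reported
mean under 1%.

## Electron transport and light-response curves

Electron transport per PSII multiplies three measured quantities:

$$ETR = \sigma_{PSII}' \cdot (I \cdot c) \cdot q_P
  \quad [\mathrm{e^-\,PSII^{-1}\,s^{-1}}],$$

under the one-electron-per-trap-closure convention. Scaling by the
PsbA (D1) content in fmol µg⁻¹ (with fmol→pmol conversion) gives
pmol e⁻ µg⁻¹ s⁻¹ — an upper-bound normalisation, since some PsbA is
always engaged in the PSII repair cycle rather than in active centres.

`fit_pe_curve()` fits the saturating light response
$ETR(I) = P_{max} \tanh(I/E_K)$, the convention under which
$E_K = P_{max}/\alpha$ with $\alpha$ the initial slope. A
Michaelis-Menten alternative $P_{max} I/(E_K+I)$ is available behind
the `model` argument for sensitivity analysis; the two forms imply
different $E_K$ for the same data, and the hyperbolic tangent is the
primary form because it is the stated convention of the methodology
this package implements. Standard errors come from the linearised
covariance of the fit.

## Immunoblot calibration

Band volumes are calibrated against a ladder of protein standards of
known molar load. The calibration is a free-intercept ordinary
least-squares line (chemiluminescent response is near-linear only
within range, and no evidence supports forcing the intercept through
zero), gated on $R^2 \ge 0.9$ and a positive slope, with an
interpolation guard rejecting sample signals outside 0.5-1.5× the
standards' signal range. Back-calculated amounts are normalised to the
µg of total protein loaded (conventionally 1 or 3 µg), giving
fmol µg⁻¹. Negative back-calculations — possible with a positive
fitted intercept — are floored at zero with a warning. Replicates are
quantified independently; aggregation to mean ± SEM over the 5-6
replicate cultures happens in the time-course layer.

## Stoichiometry and the chlorophyll budget

Marker subunits are treated as 1:1 proxies for their complexes: PsaC
for PSI, PsbA for PSII (PsbD available as an alternate proxy), PetC
for cytochrome b₆f, and AtpB for ATP synthase at 3 AtpB per complex —
so ATP synthase complexes per PSII are $(AtpB/3)/PsbA$ and catalytic
sites are exactly 3× that, an identity maintained bit-exactly before
any rounding. Printed reports round ratios ≥ 1 to one decimal and
ratios < 1 to two; all internal arithmetic is unrounded.

The chlorophyll budget multiplies subunit pools by fixed binding
stoichiometries — 12 chlorophyll per IsiA monomer, 100 per PSI
monomer, 36 per PSII monomer — yielding fmol chlorophyll µg⁻¹ in each
pool and a total that is exactly their sum. A corollary used in the
tests: exchanging PSI for IsiA at 100:12 leaves the total invariant,
the signature of the antenna-for-reaction-centre swap that iron
depletion induces.

## Growth and pigment indices

Growth rates are the OLS slope of $\ln A_{750}$ against time within a
window (default the first 72 h, before iron limitation bends the
trajectory), with the 95% CI from the t-distribution on the slope.
$A_{750}$ also serves as the scatter baseline under the pigment bands:
chlorophyll is tracked as $A_{680}-A_{750}$, chlorophyll per cell as
$(A_{680}-A_{750})/A_{750}$, and phycobilisome content normalised to
chlorophyll as $(A_{630}-A_{750})/(A_{680}-A_{750})$. No further
scatter correction is applied. The red chlorophyll peak position —
whose blue shift tracks IsiA-bound chlorophyll — is located by
three-point quadratic interpolation around the grid maximum within
650-700 nm; an edge maximum is returned as the edge with a warning.

## Time-course statistics

Each quantity's replicate time course (0/48/96/120 h, n = 5 or 6,
group sizes may differ) is tested by one-way ANOVA followed by
Dunnett's many-to-one comparisons against the pre-treatment (0 h)
control, two-sided at family-wise $\alpha = 0.05$. Adjusted p-values
are computed from the multivariate-t distribution of the maximum
absolute contrast statistic, using the exact contrast correlations
$\rho_{ij} = \lambda_i\lambda_j$, $\lambda_i = \sqrt{n_i/(n_i+n_0)}$
(equicorrelation ½ under equal n). The test suite checks these
p-values against a $10^6$-draw Monte-Carlo oracle (to 0.005) and
against an independent implementation. Two-sided comparisons were
chosen because the emulated study reports significance without
direction.

Curve fits for time courses are an OLS quadratic with a pointwise 95%
confidence band, and, for saturating inductions such as IsiA
accumulation, a logistic $y = A/(1+e^{-k(t-t_0)})$ with the lower
asymptote fixed at 0 (the protein starts near zero); $A$ estimates the
plateau, and a fitted rate with $k \cdot \mathrm{range}(t) < 0.1$ is
flagged non-identifiable rather than reported as a plateau.

## What the synthetic generators emulate — and what they do not

Every input the chain consumes has a forward generator, so each stage
is testable by parameter recovery:

* **FRR transients** (`simulate_frr_transient`, `simulate_light_step`)
  follow the closure model exactly, with additive Gaussian detector
  noise. $F_M'$ is an independent generator parameter (defaulting to
  the dark $F_M$) so quenching scenarios can be emulated. Not
  emulated: PSII re-opening (>1000 µs trains), state transitions,
  baseline fluorescence from phycobilisomes/PSI/IsiA, baseline drift,
  and instrument gain nonlinearity — so passing recovery tests shows
  the fitting chain is correct and efficient, not that real
  instrument artefacts are handled.
* **Growth series** (`simulate_growth_series`) are exponential up to
  an onset (default 72 h) after which the rate decays exponentially
  with a 48 h timescale — a qualitative stand-in for the slowing of
  growth as iron runs out; the true shape of that slowdown is not
  constrained. Noise is log-normal, matching multiplicative absorbance
  error.
* **Blots** (`simulate_blot`) respond linearly to molar load with
  unit-mean log-normal noise (5% CV in the reference scenario);
  antibody saturation and image-level artefacts are out of scope.
* **P-E datasets** (`simulate_pe_dataset`) are exact tanh curves plus
  additive Gaussian noise.

Noise defaults are conventions chosen to be realistic for these
instrument classes, not measured values — the emulated study does not
state its detector characteristics.

## The reference scenario

`default_scenario()` pins the study conditions: timepoints 0/48/96/120
h; 6 and 5 replicate cultures for the two strains; growth rates
0.019 and 0.016 h⁻¹ slowing after 72 h; dark cross-sections 381/412 Ų
(red) and 79/71 Ų (blue); a P-E response declining from
$P_{max} = 96$, $E_K = 90$ to 59 and 65 for the first strain and from
179 to 157 (e⁻ PSII⁻¹ s⁻¹) for the second; IsiA induction following a
logistic to a ~662 fmol µg⁻¹ plateau in the first strain while PsaC
falls to ~17% of its initial value (final IsiA:PSI ≈ 42), and a
slower, near-linear IsiA rise with final IsiA:PSI ≈ 12 in the second;
and AtpB levels giving 0.46 → 0.23 ATP synthase complexes per PSII in
the second strain. Values the emulated study does not print (the
second strain's $E_K$, absolute PetC/AtpB/PsaC trajectories, the IsiA
starting level) were fixed once at physiologically plausible levels
consistent with the printed ratios, and are not tuned. Blot standard
ladders are scaled per target protein (5-200% of the target's maximal
abundance), reflecting the practice of preparing standards at
concentrations appropriate for each protein.

`run_pipeline()` runs the whole chain on a scenario — generation,
fitting, derivation, statistics — deterministically from a single root
seed split per stage, writes every table as TSV plus a JSON summary
and a parameter/checksum log when an output directory is given,
continues past non-fatal stage failures (recording stage name and
message), and leaves the affected outputs absent rather than partial.

## Numerical choices and problem sizes

Nonlinear fits use Levenberg-Marquardt with tolerances of $10^{-10}$
on both parameter and objective change and analytic-free multistarts
as described above; non-convergence is flagged in the returned object,
never raised as an error. Exact log-linear or exact-polynomial inputs
yield degenerate (zero-width) confidence intervals, which are returned
as such. Monte-Carlo calibrations in the test suite use 200-3000
replicate simulations per check and a $10^6$-draw oracle for the
Dunnett quantiles — sizes chosen so each check's sampling error is
several times smaller than the tolerance it enforces.

## Known limitations

* $\sigma_{PSII}$ is instrument- and waveband-specific; no spectral
  correction between excitation bands is attempted.
* Fluorescence-derived yields in cyanobacteria are distorted by
  phycobilin and PSI baseline contributions; the chain reproduces the
  standard calculations and inherits their caveats.
* PsbA-normalised quantities treat repair-cycle-engaged D1 as active
  PSII; they are upper bounds on active-centre content.
* The Dunnett procedure assumes independent replicate cultures and
  homoscedastic groups, as the emulated design does.
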