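# cyanophys

Photophysiology analysis chain for cyanobacteria under iron limitation:
from single-turnover fluorescence transients and immunoblot band
volumes to electron-transport light-response parameters, photosystem
stoichiometries and a chlorophyll-allocation budget. Written for
phytoplankton physiologists who run fast repetition rate (FRR)
fluorometry and quantitative westerns and want the full numeric chain —
fitting, derivation, statistics — reproducible and testable.

## What it computes

**FRR induction fitting.** A flashlet train (default 40 × 2 µs flashes
with 2 µs gaps; 625 or 455 nm) progressively closes PSII within a
single turnover. The closed fraction follows the cumulative one-hit
law C(D) = 1 − exp(−σ_PSII·D), generalised to excitonic connectivity
via dC/dD = σ(1−C)/(1−pC), and fluorescence rises as
F = F_O + (F_M−F_O)·C. Nonlinear least squares on the rise yields F_O,
F_M, σ_PSII (Å² quanta⁻¹) and F_V/F_M from dark-acclimated cells, and
F_S, F_M′, σ_PSII′, q_P = (F_M′−F_S)/(F_M′−F_O′) and Φ_PSII from
illuminated cells.

**Electron transport.** ETR = σ_PSII′ × (I·c) × q_P in e⁻ PSII⁻¹ s⁻¹,
with c = 6.02214076×10⁻³ converting µmol photons m⁻² s⁻¹ to
photons Å⁻² s⁻¹; per-protein rates scale by PsbA content
(fmol µg⁻¹ → pmol e⁻ µg⁻¹ s⁻¹). Light-response curves are fit as
ETR(I) = P_max·tanh(I/E_K).

**Immunoquantitation.** Band volumes are calibrated against
standard-ladder loads (free-intercept OLS, R² ≥ 0.9 gate,
interpolation guard) and expressed as fmol subunit per µg total
cellular protein.

**Stoichiometry & chlorophyll budget.** PSI:PSII (PsaC/PsbA),
IsiA:PSI, cyt b₆f:PSII (PetC/PsbA) and ATP synthase:PSII
((AtpB/3)/PsbA, ×3 for catalytic sites); chlorophyll pools at 12 chl
per IsiA, 100 per PSI and 36 per PSII monomer.

**Growth, pigments, statistics.** ln A₇₅₀ regression for specific
growth rates with 95% CI; chlorophyll and phycobilisome indices and
the red-peak wavelength; one-way ANOVA with Dunnett comparisons
against the 0 h control (exact multivariate-t adjustment), quadratic
fits with confidence bands, and logistic plateau fits.

**Synthetic data.** Forward generators for every input — transients,
light steps, growth series, blots, P–E datasets — so each stage is
testable by parameter recovery, plus `run_pipeline()` to run the whole
chain on a scenario (`default_scenario()` emulates a two-strain
0/48/96/120 h iron-depletion experiment with 5–6 replicate cultures).

## Worked example

```r
library(cyanophys)

pr    <- flashlet_protocol()                  # 40 x 2 us flashlets, 625 nm
truth <- induction_params(Fo = 1, Fm = 3, sigma = 381)
tr    <- simulate_frr_transient(truth, pr, noise_sd = 0.02, seed = 42)
fit_dark_transient(tr)
#> Induction fit: Fo = 1.007  Fm = 2.989  sigma_PSII = 388.4 A2 quanta-1  Fv/Fm = 0.6630

light <- simulate_light_step(induction_params(1, 3, 381, C0 = 0.4),
                             pr, Fm_prime = 2.6, noise_sd = 0.02,
                             seed = 43, actinic = 66)
lfit <- fit_light_transient(light, Fo_dark = 1.007)
#> Light-step fit: Fs = 1.626  Fm' = 2.606  sigma' = 378.3 A2 quanta-1  qP = 0.613  Phi_PSII = 0.376

etr_per_psii(lfit$sigma_prime, 66, lfit$qP)
#> [1] 92.2   # e- PSII-1 s-1 at 66 umol photons m-2 s-1

d <- simulate_pe_dataset(96, 90, noise_sd = 3, seed = 44)
fit_pe_curve(d$irradiance, d$etr)
#> P-E fit (tanh): Pmax = 96.46 (SE 1.7)  EK = 97.96 (SE 4.3) umol photons m-2 s-1

complex_ratios(c(PsbA = 40, PsaC = 92, AtpB = 55.2, IsiA = 662))
#> Complex stoichiometries (mol/mol, PSII-normalised):
#>   PSI : PSII            2.3
#>   IsiA : PSI            7.2
#>   Cyt b6f : PSII        NA
#>   ATP synthase : PSII   0.46 (1.4 catalytic sites)

chlorophyll_budget(c(IsiA = 662, PsaC = 16, PsbA = 38))
#> Chlorophyll budget (fmol chl / ug total protein):
#>   IsiA pool     7944.0
#>   PSI pool      1600.0
#>   PSII pool     1368.0  (proxy: PsbA)
#>   total        10912.0
```

The dark fit recovers the generating cross-section (388 vs 381 Ų at
2% noise — single-transient precision is bound-limited to ~2%; the
pipeline averages 5–6 replicates). The stoichiometry report shows a
pre-starvation PSI:PSII of 2.3 and 0.46 ATP synthase complexes (1.4
catalytic sites) per PSII; the budget shows chlorophyll dominated by
the IsiA pool once IsiA reaches its ~662 fmol µg⁻¹ plateau.

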