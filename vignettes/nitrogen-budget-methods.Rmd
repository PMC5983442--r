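---
title: "Quantifying associative N fixation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying associative N fixation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anfbudget)
```

# The problem

Perennial grasses such as switchgrass often keep yielding with little or no
N fertilizer while harvest removes tens of kilograms of N per hectare every
year. When atmospheric deposition cannot close that gap and soil organic N
is not being depleted, the remaining candidate input is associative N
fixation (ANF): dinitrogen fixation by diazotrophs living casually in the
rhizosphere and on or in roots, without nodules. `anfbudget` implements the
complete calculus needed to test that hypothesis at desk scale: tracer-based
fixation rates, soil N transformation rates, a plot-level N mass-balance
ledger, areal/annual scaling, dose-response model selection, and a synthetic
field study so every stage can be exercised and verified without field data.

# Tracer fixation rates

A sample (5 g sieved rhizosphere soil or 1 g washed roots) is sealed in a
12-mL vial; 4 mL of headspace is withdrawn and 4.2 mL of 99 atom% ^15^N~2~
injected; after incubation (7 d) the sample's ^15^N content is compared to
an unenriched control. The fixation rate per vial is

$$\mathrm{ANF} = \frac{AE_i \, TN_i}{AE_{atm}\, t},$$

where $AE_i$ is the sample's atom-fraction excess over its control,
$TN_i$ the total N in the sample (µg), $t$ the incubation time, and
$AE_{atm}$ the atom-fraction excess of headspace N~2~. Dividing by dry mass
gives µg N g^-1^ d^-1^. Instruments report atom *percent*; all excesses are
converted to atom fractions before the quotient so numerator and denominator
share units.

`headspace_atom_excess()` models $AE_{atm}$ by equal-pressure volume
bookkeeping: the injected tracer volume over total headspace N~2~ (ambient
headspace contributing N~2~ at its atmospheric fraction, default 0.78),
minus the natural ^15^N abundance of air N~2~ (0.3663 atom%, configurable).
With the default wet-packed soil density (1.9 g cm^-3^; roots 1.0) the 5-g
assay yields headspace N~2~ at roughly half ^15^N~2~:

```{r}
occ <- occupied_volume_default(5, "soil")
as.numeric(headspace_atom_excess(12, occ, 4, 4.2, 0.99))
```

Two conservative conventions are deliberate. $AE_{atm}$ is not corrected
for denitrification-driven N~2~ release during incubation, which can only
bias rates low. And raw rates below a detection floor — the rate implied by
a sample excess of twice the instrument atom% standard deviation (default
0.0002 atom%) — are floored to zero and flagged, while the unfloored value
is always retained (`raw_rate_per_gram`), so users can choose between
flooring and excluding below-detection replicates; both conventions appear
in practice and the package takes no side beyond its default.

`contamination_bound()` gives the worst-case apparent rate if every
microgram of reactive ^15^N (NH~3~, NO~x~) delivered with the tracer were
assimilated; measured rates below that bound are not attributable to
fixation. The bound's formula is this package's own construction — a
deliberately pessimistic 100%-assimilation envelope — since published
contamination checks report outcomes, not a reusable formula.

# Mineralization, nitrification and WFPS

Net mineralization and nitrification come from paired KCl extractions
bracketing a 28-d aerobic incubation at 60% water-filled pore space:

$$N_{min} = \frac{(NO_3^{28} + NH_4^{28}) - (NO_3^{0} + NH_4^{0})}{28\ \mathrm{d}},
\qquad
N_{nit} = \frac{NO_3^{28} - NO_3^{0}}{28\ \mathrm{d}}.$$

Negative mineralization (net immobilization) is reported as-is, never
floored. *Relative nitrification* — the percent of mineralized N
accumulating as nitrate — is ambiguous in the field literature between a
Δ-ratio ($100\,N_{nit}/N_{min}$) and an end-pool fraction. The Δ-ratio is
the default here because values above 100% (nitrification outrunning
mineralization when the ammonium pool shrinks) are routinely reported and
only the Δ reading produces them; the end-pool reading is available via
`method = "end_pool"`. Extraction replicates are averaged before the rate
formulas, one rate per soil core. `water_to_target_wfps()` supplies the
bench arithmetic for bringing a sample to a target WFPS.

# The mass-balance ledger

`balance_ledger()` builds annual balances as fertilizer + deposition −
harvest N, with optional leaching/denitrification terms defaulting to zero
(their omission makes any computed deficit conservative). Fertilizer and
deposition are treated as exact, so each annual SE equals the harvest-N SE;
the cumulative SE combines annual SEs in quadrature and the mean's SE is
the cumulative SE over the number of years. All arithmetic runs at full
precision with a separate reporting layer (`ledger_report()`) rounding to
0.1 kg. The packaged seven-year table (`table1_mi()`) reproduces its source
exactly in the unfertilized column; fertilized columns agree within 0.3 kg,
the rounding slack expected when a published table was computed from
replicate-level values before rounding.

```{r}
led <- balance_ledger(table1_mi(treatment = 0), window = 2013:2015)
led
```

# Areal and annual scaling

Per-gram rates become annual per-hectare inputs via a 120-d growing season
partitioned 20 d (pre-fertilization), 40 d (post-fertilization) and 60 d
(peak biomass). Post-senescence rates are *excluded* from annual scaling by
default — the partition covers roughly May through late August — though an
extended season can be supplied explicitly in `season_days`. Soil rates are
first divided by the glucose factor (default 4.8), the measured stimulation
of soil fixation by the glucose solution used to wet samples; root assays
showed no glucose response, so root rates are never corrected. Soil
conversion is rate × days × bulk density × core depth (1 µg g^-1^ over a
1-cm slab of density 1 is 0.1 kg ha^-1^); root conversion multiplies by
areal root biomass. Period SEs propagate in quadrature on the assumption
that periods are independently sampled.

# Dose-response models and the agronomic optimum

Rates and yields are regressed on N addition within each period using five
families, parameterized exactly as they are conventionally printed
(`y = a + bx`; `a log(x+1) + c`; `a(x+1)^b`; `a e^{b(x+1)}`; quadratic
plateau). The `x + 1` offsets keep the unfertilized dose well-defined.
Fitting is weighted least squares throughout. Rather than iterative
nonlinear optimization with random restarts, the exponential and power
families profile their rate parameter over a deterministic sign-symmetric
log-spaced grid (exploiting that the amplitude is conditionally linear),
refined by golden-section search; the plateau profiles its join point the
same way, with the vertex constraint making the remaining parameters
linear. Every fit is therefore exactly reproducible and immune to starting
values. Model comparison uses the least-squares AIC
$n \ln(\mathrm{SSE}/n) + 2(k+1)$; significance of each family's shape
parameter is an asymptotic t-test from the numerical Jacobian at the
optimum. `select_model()` returns the lowest-AIC significant fit, or
nothing when no family is significant (no detectable N response); exact
AIC ties break by a fixed canonical family order. A quadratic plateau with
convex unconstrained curvature has no interior maximum and falls back to
linear with optimum 0.

`optimal_n()` estimates the minimum N rate achieving maximum biomass as the
plateau join point, clamped to the observed dose range, returning 0 when
the fit is not significant. The default replicate weighting ("inverse rank
order") is interpreted here as: within each dose level, replicates are
ranked by absolute deviation from the level median and weighted 1/rank.
The source protocol for that phrase lives in an agronomy reference we could
not consult directly, so the interpretation is exposed as a pluggable
policy (`"uniform"` is the alternative) rather than asserted as canonical.
Least-squares AIC (not REML/ML likelihood AIC) is used and stated.

# The synthetic study

`simulate_study()` generates a complete raw data set under a known truth:
2 sites × 4 blocks × 3 fertilizer levels (0/56/196 kg N ha^-1^ yr^-1^) ×
4 seasonal periods, for soil and root vials, extraction assays, and an
8-level yield gradient. The default truth encodes the published seasonal
structure: root fixation declining with N (mostly exponentially, amplitude
4.75 and decay −0.03 at senescence on the MI-like site), a post-senescence
root spike exceeding all growing-season rates, soil fixation in a narrow
0.5–1 µg N g^-1^ d^-1^ band, and mineralization increasing with N. Initial
inorganic-N pools are drawn around the published treatment × period means
with their SEs (×2, for n = 4) as between-block SDs.

Vial atom% values are produced by *inverting* the tracer equation around
the true rate and adding Gaussian instrument noise (default SD 0.0002
atom%) to treatment and control vials alike; assay end-pools add the true
mineralization (split into nitrate/ammonium by a relative-nitrification
parameter, default 0.9) to the initial pools with multiplicative
concentration noise (CV 0.1); yields take 7% CV about the plateau truth.
Block effects are multiplicative lognormal (CV 0.15, mean 1) — rates are
positive and right-skewed — drawn once per site × block × variable so the
randomized-complete-block correlation structure is present. At zero noise
the pipeline recovers every true rate to numerical precision, which is the
package's core correctness check.

Three default-curve choices were genuinely open. Two published line
segments cross zero inside the dose range (a peak-biomass root decline and
a senescence mineralization line); since truth curves must be non-negative
over the design, the defaults keep the printed intercept/slope scale but
flatten them minimally to stay admissible. Periods with no published
significant trend use flat curves at the reported rate magnitudes. The
default yield truth is a single shallow plateau year (10.9 rising to
12.9 Mg ha^-1^, join at 109 kg N): with 4 blocks × 8 levels at 7% CV this
response is near the edge of detectability, so the gated optimum is
legitimately 0 in a minority of realizations — a faithful property of
shallow yield responses, not a defect.

What the generator does *not* emulate: spatial autocorrelation, weather,
multi-year soil N feedbacks, depth profiles of diazotroph activity, or
mass-spectrometer data reduction. Passing tests therefore demonstrate that
the calculus and inference machinery are correct under the stated
statistical structure, not that field data will be this well-behaved.

# Problem sizes and numerical conventions

The test suite and acceptance script use the study's own design sizes
(n = 12 per period regression; 32 yield plots) with Monte-Carlo ensembles
of 100–500 replicates for stochastic properties — large enough for stable
frequencies at the asserted margins. Degenerate inputs are handled
explicitly: zero headspace is a geometry error; over-dilute tracer clamps
to zero excess with a warning; zero net mineralization makes relative
nitrification a flagged missing value; duplicate ledger years error;
missing deposition borrows the multi-year mean and is flagged.

# Limitations

The contamination bound is an upper envelope, not a measured contaminant
budget. The ledger omits leaching and denitrification unless supplied. The
glucose factor is a single site-level constant, while the true stimulation
surely varies with treatment and season. Scaling assumes rates measured in
the top 15 cm (soil) or on washed roots apply uniformly over the scaled
volume. And with three dose levels per period, families of similar shape
(power vs log) are only weakly distinguishable — model selection at that
design size identifies the response *class* reliably, the exact family less
so.
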