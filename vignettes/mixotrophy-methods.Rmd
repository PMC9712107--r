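---
title: "Models and methods: quantifying mixotrophic support of Prochlorococcus growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

*Prochlorococcus* grows from the surface down to the base of the photic zone,
where photon fluxes are far too low to explain the division rates observed by
cell-cycle analysis. This package quantifies how much of that growth must be
supported by assimilation of dissolved organic carbon (DOC), with four
connected components: a photo-autotrophic growth-profile model, single-cell
isotope uptake rates, an individual-based water-column simulator with
explicit DOC-uptake gating, and a light-threshold analysis of ecotype time
series. This vignette documents the models, their assumptions, the numerical
choices, and what the synthetic-data generators do and do not emulate.

## The photo-autotrophic growth-profile model

The carbon-specific, daily-averaged photosynthesis rate at a depth is the
diel average of a Platt photosynthesis-irradiance curve scaled by the
chlorophyll-to-carbon ratio:

$$\mathbb{P} \;=\; \frac{1}{\Delta t}\int_0^{\Delta t}
\frac{q_{\mathrm{Chl}}}{q_{\mathrm{C}}}\,
P^{\mathrm{Chl}}_S\left(1 - e^{-\alpha_{\mathrm{Chl}} I/P^{\mathrm{Chl}}_S}\right)
e^{-\beta_{\mathrm{Chl}} I/P^{\mathrm{Chl}}_S}\,\mathrm{d}t,$$

where $I(t)$ is hourly PAR obtained by scaling the observed noon value with
astronomical diel factors (`diel_irradiance_factors()`: cosine of the solar
zenith angle, Cooper declination, normalised to 1 at local noon, sampled at
interval midpoints over 24 h). $\Delta t$ spans the full 24 h day at hourly
resolution by default; averaging over the whole day rather than daylight
hours is what makes $\mathbb{P}$ a daily carbon budget term. With
photo-inhibition ($\beta_{\mathrm{Chl}}>0$) the curve has a single interior
maximum at $I^* = (P^{\mathrm{Chl}}_S/\alpha_{\mathrm{Chl}})
\ln\!\big((\alpha_{\mathrm{Chl}}+\beta_{\mathrm{Chl}})/\beta_{\mathrm{Chl}}\big)$.

The chlorophyll-to-carbon ratio is not measured in the field, so it is
modelled as a function of growth rate and irradiance. The full
macromolecular-allocation model is represented here by a contracted
functional form that preserves its documented monotonicities,

$$\frac{q_{\mathrm{Chl}}}{q_{\mathrm{C}}} = \frac{a_0 + a_1\,\mu}{1 + a_2 I},
\qquad
\mu_{\max}(I) = \hat\mu\,\frac{I}{I + K_I},$$

with the coefficients held in `allocation_params()` and swappable for the
full published forms. The light-limited autotrophic rate is the fixed point
of

$$\mathbb{V}_C^{\mathrm{auto}} = \min\left(\mathbb{P} - K_R,\; \mu_{\max}(I)\right),$$

solved by damped iteration (`solve_autotrophic_rate()`): under-relaxation
factor 0.5, absolute tolerance $10^{-6}\,\mathrm{day^{-1}}$, at most 200
iterations, with an error on non-convergence. The ratio is evaluated at the
noon irradiance with a floor of $10^{-3}\,\mu$mol photons m$^{-2}$ s$^{-1}$
because the contracted ratio is undefined at zero light. The raw fixed point
can be negative in the dark (respiration exceeding fixation, equal to
$-K_R$); it is retained for diagnosis and clamped at zero in limitation
profiles. On a grid of irradiances the fixed point is independent of the
initial guess to well under the tolerance, which the test suite checks.

**Calibration of the shipped presets.** Laboratory photo-physiology
coefficients are cited from culture studies but not printed in a form this
package can transcribe, so `default_config()` ships two editable presets:
a high-light-adapted parameterisation (`HL`: $P^{\mathrm{Chl}}_S=0.05$ mol C
(mol Chl)$^{-1}$ s$^{-1}$, $\alpha_{\mathrm{Chl}}=10^{-3}$,
$\beta_{\mathrm{Chl}}=2\times10^{-5}$) and a low-light-adapted one (`LL`:
$0.03$, $2\times10^{-3}$, $1.5\times10^{-4}$), with allocation coefficients
$a_0=4\times10^{-4}$, $a_1=1.5\times10^{-3}$, $a_2=1.2\times10^{-3}$,
$\hat\mu=0.6$ day$^{-1}$, $K_I=25$, $K_R=0.05$ day$^{-1}$. These were
calibrated once so that the HL preset gives surface growth of 0.4-0.6
day$^{-1}$ under 600 µmol photons m$^{-2}$ s$^{-1}$ noon PAR, the LL preset
is photo-inhibited at the surface but grows deeper than HL, and
light-limited growth vanishes near 1% of surface PAR. Users with laboratory
values should substitute them via the YAML config.

## Nutrient-specific uptake and the minimum law

Nitrogen and phosphorus limitation use quota-normalised Michaelis-Menten
uptake, $\mathbb{V}_X = (V^{\max}_X/Q_X)\, X/(X+K_X)$; dissolved iron uses a
linear surface-area scaling, $\mathbb{V}_{\mathrm{Fe}} =
k^{SA}_{\mathrm{Fe}}\,SA\,\mathrm{Fe}/Q_{\mathrm{Fe}}$. Defaults assume a
0.6 µm cell and are set so that 10 nmol l$^{-1}$ DIN yields N-limited rates
near 0.4 day$^{-1}$ and iron at the 0.03 nmol l$^{-1}$ detection limit
yields ~0.5 day$^{-1}$; they are config entries, not measurements.
Below-detection iron tokens (`"<0.03"`) in input tables are substituted with
the detection limit by `read_profile_table()`.

At every depth the modelled photo-autotrophic rate is the minimum of the
light-, N-, P- and (when iron data exist) Fe-specific rates, with the
limiting resource recorded. Where an observed growth-rate profile is
available (linearly interpolated across gaps, never extrapolated), the
shortfall `max(0, mu_observed - mu_auto)` is interpreted as heterotrophically
supported growth. Vertical trapezoidal integration of `rate x cell density x
carbon quota` (default quota 50 fg C cell$^{-1}$, a config scalar) yields
areal production and the heterotrophic fraction, overall and below the
mixotrophy onset depth. Two onset definitions are reported because both are
in use: the shallowest depth where the heterotrophic rate first exceeds
zero, and the (deeper) depth where it first exceeds the autotrophic rate.
Four canonical scenarios (HL/LL, each with and without photo-inhibition)
bracket the photo-physiological uncertainty; `scenario_envelope()` returns
their per-depth extreme range.

## Single-cell isotope uptake rates

For a cell incubated with $^{13}$C-bicarbonate and $^{15}$N-ammonium,
element-specific uptake is the linear-dilution form

$$\mu_X = \frac{(A_{\mathrm{meas}} - A_{\mathrm{nat}})/(A_{\mathrm{src}} - A_{\mathrm{nat}})}{\Delta t},$$

in day$^{-1}$; negative values (measurement noise) are clamped to zero with
a flag, and cells outside $[A_{\mathrm{nat}}, A_{\mathrm{src}}]$ are flagged
rather than silently dropped. Population summaries use medians, which are
robust to the long right tails of single-cell rate distributions. The
headline doubling time is the reciprocal $1/\mu_N$ (the convention
consistent with equating 0.16 day$^{-1}$ with a ~6 day doubling);
$\ln 2/\mu_N$ is also reported. The heterotrophic fraction implied by the
population is $1 - \mu_C/\mu_N$ computed from the medians, reflecting that a
cell growing at the N-specific rate must source the carbon shortfall
non-photosynthetically.

## The individual-based water column

`run_scenario()` simulates super-agents (each representing many identical
cells) in a 1-D column, 0-200 m at 2 m resolution, with Eulerian DIN, PO4
and DOC tracers. An agent carries a depth, carbon/nitrogen/phosphorus
reserve quotas $q_C, q_N, q_P$, a relative structural size and a
multiplicity. DOC uptake follows quota-regulated saturating kinetics,

$$V_{\mathrm{DOC}} = V^{\max}_{\mathrm{DOC}}\cdot
\max\!\Big(0,\min\!\big(1,\tfrac{q_C^{\max}-q_C}{q_C^{\max}-q_C^{\min}}\big)\Big)\cdot
\frac{\mathrm{DOC}}{\mathrm{DOC}+K^{\mathrm{sat}}_{\mathrm{DOC}}},$$

gated by the photosynthetic fraction $f_{PS} = P_S/(P_S+V_{\mathrm{DOC}})$
(defined as 1 when both rates vanish): uptake stops entirely when $f_{PS}$
falls below $f^{\min}_{PS}$ (1% by default), encoding the observation that
the organism cannot live heterotrophically in prolonged darkness. The gate
is re-evaluated from instantaneous rates every timestep with no hysteresis;
$1-f_{PS}$, flux-weighted, is the recorded DOC contribution.

Each timestep, in a fixed documented order per agent: light from the diel
surface PAR and exponential attenuation; photosynthesis into the carbon
reserve (a fixed chlorophyll-to-carbon ratio in the IBM, deliberately
decoupled from the iterative acclimation model of the profile analysis);
gated DOC uptake and quota-regulated DIN/PO4 uptake, each scaled per grid
cell so tracer mass cannot go negative; maintenance respiration from the
carbon reserve; biosynthesis converting reserves to structure at fixed
stoichiometry (N:C 1/6.6, P:C 1/106); probabilistic division (logistic in
relative size, midpoint at twice the minimum size), halving size and
reserves and either adding an agent or doubling multiplicity at the agent
cap; quadratic grazing (per-capita probability proportional to local cell
concentration) with remineralisation; and a vertical random walk consistent
with the two-layer eddy-diffusivity profile (Visser-corrected drift term,
reflective boundaries). Tracers then diffuse implicitly (backward Euler in
conservative flux form with zero-flux boundaries, solved by the Thomas
algorithm, unconditionally stable at the 10-minute step) and are restored
toward boundary values.

Three structural details matter and are deliberate:

* **Reserve bounds.** $q^{\min}$ is a kinetic subsistence threshold (uptake
  headroom and biosynthesis saturation reference it) rather than a hard
  state bound, because mass-conserving division halves reserves and can
  legitimately leave a daughter below $q^{\min}$. Hard bounds are
  $[0, q^{\max}]$ and are asserted every step.
* **Starvation.** Maintenance unfunded by the carbon reserve catabolises
  structure (its N and P remineralised), and cells below half the minimum
  size die. Without this, dark relic cells persist indefinitely under
  quadratic grazing and blur the depth at which division ceases.
* **Export and the DOC field.** A fraction of grazed N and P (default 25%)
  is exported as sinking detritus rather than remineralised locally; with
  100% local recycling a steady-state deep population has zero net nutrient
  consumption and cannot displace the nutricline. Grazed carbon is routed
  partly to DOC (default 30%). The DOC-like tracer restores (10-day default
  timescale reduced to 8 in the shipped configuration) toward a background
  of $3\times10^{-4}$ mol C m$^{-3}$ plus a Gaussian enrichment centred at
  119 m (width 15 m, amplitude $5.5\times10^{-3}$), emulating the
  remineralisation maximum of sinking detritus just below the photic zone.
  The nutritional value and supply of the labile DOC pool are the least
  constrained parameters of the whole model; the depth structure of the
  deep mixotroph layer is directly controlled by them. In the
  closed-boundary configuration used by the conservation tests, restoring is
  off and recycling is complete, so column totals of N and P are conserved
  to numerical round-off ($<10^{-9}$ relative per step).

**Problem sizes.** The desk-scale default is a 10-minute timestep, 240
simulated days, 2,000 super-agents and 5-member ensembles, with profiles
averaged over the final quarter of the run; a paired autotroph/mixotroph
comparison completes in about two minutes on one CPU. 240 days (rather than
a shorter spin-up) is needed because the nutricline displacement between the
scenarios develops on a multi-month timescale; the division-rate and DOC
contribution profiles are stable from about day 90. Ensemble members differ
only by seed; reproducibility is exact for a given seed because every
stochastic event consumes random numbers in a fixed order (division uniform,
grazing uniform, displacement normal, always drawn).

**Calibration and a known limitation.** The default parameters were
calibrated once against the qualitative and quantitative structure the
simulator is meant to exhibit: a nutrient-limited mixed layer dividing at
~0.25-0.3 day$^{-1}$ in both scenarios, autotroph division ceasing near
90-100 m from light limitation, mixotroph division of ~0.15-0.2 day$^{-1}$
persisting at 125 m, a DOC share of ~40% of production below the
nutrient-to-carbon transition, and a nutricline ~10-20 m deeper in the
mixotroph scenario. One quantity is structurally stubborn in this 1-D
configuration: the column-integrated DOC share of production settles near
20%. It cannot be pushed much lower without breaking the deep division
rates, because at any depth where autotrophs cannot persist
($\mathbb{P}<K_R$) the DOC share of a cell growing at rate $\mu$ is
energetically bounded below by $1 - \mathbb{P}/(\mu + K_R + \mathrm{costs})$,
and the deep band's production weight is pinned by the
quadratic-grazing equilibrium (density tracks division rate). A 2-D or 3-D
flow field with episodic light exposure would relax this bound; the 1-D
column cannot.

## Ecotype lightscapes

The photic depth for a strain class with light threshold $I_{\mathrm{th}}$
is $\ln(I_0/I_{\mathrm{th}})/K_d$ (zero when the surface value is already
below threshold); defaults are 10 µmol photons m$^{-2}$ s$^{-1}$ for
high-light and 2.8 for low-light strains, interpreted as thresholds on
noon-scaled attenuated PAR (the conversion from integrated-illumination
laboratory conditions is not uniquely defined; applying them to daily-mean
PAR instead is a one-line change in user code since `photic_depth()` is
pure). A date is stratified when the mixed layer is shallower than the
photic depth; only stratified dates enter the reported means (equal date
weighting by default), because deep mixing can carry cells from below the
photic depth into the light. Cell fractions below the photic depth are
trapezoidal column integrals with a linear split of the straddling layer.

## Synthetic data: what it does and does not emulate

`synthetic_spec()` fixes the study conditions for all generators:
exponentially attenuated PAR (600 µmol photons m$^{-2}$ s$^{-1}$ noon
surface, $K_d = 0.045$ m$^{-1}$), sigmoidal DIN/PO4/Fe nutriclines with
small surface floors (so the surface is nutrient-limited rather than
dark-limited), an observed-growth template declining from 0.45 day$^{-1}$ at
the surface to a 0.17 day$^{-1}$ deep plateau that persists to 150 m,
sampled sparsely with seed-reproducible gaps, a sinusoidal seasonal
mixed-layer cycle (30-220 m) crossing the photic depth twice a year,
Gaussian ecotype depth niches with low-light niches centred below high-light
ones, and single-cell isotope truth ($\mu_C = 0.024$, $\mu_N = 0.16$
day$^{-1}$) with median-preserving log-normal noise. Every generator is a
pure function of its spec and seed, and ground truth is stored on the
output (analytic error-function integrals for the below-photic fractions),
so downstream tests compare against independently derived values.

What passing tests on these fixtures shows is that the *computations* are
correct: the minimum law, the interpolation, the integrals, the estimator
recovery. What they cannot show is fidelity to real stations: the synthetic
profiles are smooth, uncorrelated and unseasonal in their vertical
structure, nutrient fields are time-invariant, and the observed-growth
template is a single sigmoid rather than a cell-cycle measurement with its
~19% replication error. Real profile tables in the documented CSV layout
drop into the same pipeline unchanged.

## Numerical conventions

Depths are positive downward in metres; percentages are reported on the
0-100 scale; concentrations are mol m$^{-3}$ except iron (nmol l$^{-1}$).
Integration is trapezoidal on the native grid. Interpolations (observed
growth, onset depths, nutricline crossings) are linear in depth, except
onset PAR which is log-linear (exact for exponential light). All randomness
flows from explicit seeds; writers emit a JSON run manifest recording the
command, a config hash, seeds and output files.
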