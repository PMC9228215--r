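---
title: "Characterizing anion binding: models, fitting, and ensemble analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing anion binding: models, fitting, and ensemble analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anionbind)
```

## The problem

Synthetic anion receptors — here the motivating system is a cyclic
pentapeptide whose five backbone amide N–H groups converge on a bound
anion — are characterized in solution by titrating the receptor **L** with
an anion salt **A⁻** while recording a multivariate response: fluorescence
emission spectra, UV absorbance, circular dichroism, per-proton ¹H NMR
chemical shifts, or calorimetric heats. Every one of those observables is
tied to the same underlying equilibrium model, so `anionbind` is organized
around a single speciation core with observable-specific fitting layers on
top, plus thermodynamic-cycle bookkeeping across solvents and structural
analysis of simulation ensembles of the complexes.

## Equilibrium model and speciation

A model is a set of complex species $\mathrm{L}_l\mathrm{A}_a$ with
cumulative formation constants on the molar scale,

$$\beta_{la} = \frac{[\mathrm{L}_l\mathrm{A}_a]}{[\mathrm{L}]^l[\mathrm{A}]^a},$$

supplied as $\log_{10}\beta$. Almost all complexes of interest are 1:1, but
dihydrogen phosphate in acetonitrile self-associates, so a competing dimer
$(0,2)$ and a receptor–dimer complex $(1,2)$ are first-class species. The
dimerization constant is a literature quantity that must be supplied by the
user (it is a *config input*, typically held `fixed` during fitting; the
placeholder default in examples, $\log\beta_{02} = 2$, is illustrative
only and is flagged as such in reports). The stepwise parameterization
$\mathrm{L} + \mathrm{A}_2$ is equivalent to the cumulative one through
$\log\beta_{12} = \log K_{\mathrm{L+A_2}} + \log\beta_{02}$.

Given total (analytical) concentrations, `solve_speciation()` finds the
free concentrations satisfying both mass balances. It iterates damped
Newton steps in $\ln$-free-concentration space — positivity is automatic
and the analytic Jacobian $J_{ij} = \sum_s \nu_{si}\nu_{sj} c_s$ follows
from the stoichiometry matrix — to a maximum relative mass-balance
residual of $10^{-12}$ (200 iterations cap; the problems are tiny), with a
nested-bisection fallback for pathological starts. Components with zero
total are handled exactly (their species are dropped), so the first point
of a titration costs nothing special.

```{r}
m <- equilibrium_model(data.frame(l = 1, a = 1, log_beta = 4))
solve_speciation(1e-4, 1e-4, m)
```

Titration schedules convert cumulative titrant volumes into compositions.
Two conventions cover the instruments involved: `dilution` (cuvette work;
the titrand is diluted by each aliquot, total volume grows) and
`constant-ligand` (NMR practice: the titrant contains the receptor at the
titrand concentration, so total L stays fixed).

## Global multivariate fitting by variable projection

A spectral titration is bilinear: the observed matrix
$Y~(\text{channels} \times \text{points})$ is
$Y \approx S\,C^{\mathsf T}$ where $C$ holds the species concentrations at
each point (a function of the constants through the mass balance) and $S$
the per-species molar spectra. Only the constants are nonlinear: for any
trial $\log\beta$ the optimal $S$ is an ordinary linear least-squares
solve. `fit_spectral()` exploits this (variable projection): the
Levenberg–Marquardt search runs over the free $\log\beta$ only, with $S$
eliminated exactly at each step via a QR solve. Rank-deficient designs
(e.g. a response with no variance across points, or degenerate speciation)
are reported as ill-conditioning errors rather than returning garbage.

Choices a user can vary, with defaults and reasons:

* **Weighting** — uniform across channels and points. No instrument noise
  model is assumed.
* **Responsive species** — all receptor-containing species (free A and
  A₂ are dark); molar responses are unconstrained in sign (difference and
  CD spectra are legitimately negative), with optional non-negativity for
  fluorescence.
* **Channel window** — the full recorded range unless a window is set.
* **Multistart** — besides the supplied starting constants, each free
  constant perturbed by ±1 log unit, as insurance against local minima.
* **Offset channel** — an optional constant background spectrum, off by
  default.

For NMR titrations in the fast-exchange regime the observed shift of
proton $j$ is the population-weighted average
$\delta_{\mathrm{obs},j} = \sum_s l_s [s]\, \delta_{s,j} / c_\mathrm{L}$;
`fit_nmr_shifts()` reuses the same variable-projection machinery with the
design columns $l_s[s]/c_\mathrm{L}$ and the limiting shifts as the linear
parameters. Slow-exchange lineshape analysis (new signals emerging during
a titration) is out of scope.

Uncertainties are asymptotic standard errors from a finite-difference
Jacobian at the optimum; `estimate_uncertainties()` additionally reports
the between-replicate spread when a titration was run in replicate. A
Monte-Carlo check in the test suite confirms the asymptotic errors agree
with the empirical scatter within a factor of two at realistic noise.

### Designing informative titrations

Parameter recovery depends on the saturation regime: a titration of a weak
complex at trace concentrations never populates the complex and carries no
information about $K$. `recovery_schedule()` encodes the standard design
rule — choose $c_\mathrm{L}$ so that $K c_\mathrm{L} \approx 10$, clipped
to the practical range $10^{-6}$–$10^{-2}$ mol dm⁻³ — which keeps the
bound fraction sweeping the informative window along a 0–3 equivalent
ladder. The package's recovery studies (and the acceptance script) probe
$\log K \in \{2,3,4,5\}$ at a signal-to-noise ratio of 100 with 15 points
under this rule; median recovery error is ≈ 0.02–0.03 log units for both
spectral and NMR data.

## ITC

`simulate_thermogram()`/`fit_thermogram()` implement the single-site model
with the displaced-volume perfusion-cell convention: each injection $v_i$
displaces an equal volume of mixed cell contents, so pre-injection species
are scaled by $(1 - v_i/V_0)$ and

$$Q_i = V_0\,\Delta_\mathrm{r}H\left([\mathrm{LA}]_i -
[\mathrm{LA}]_{i-1}\Bigl(1 - \frac{v_i}{V_0}\Bigr)\right) + q_\mathrm{blank}.$$

The blank is either a constant per-injection offset fitted alongside
$\log K$ and $\Delta_\mathrm{r}H$ (default) or a measured dilution
thermogram subtracted with `subtract_blank()`. Entropy follows from the
identity $\Delta_\mathrm{r}S = (\Delta_\mathrm{r}H + RT\ln 10\,\log K)/T$,
and every emitted `thermo_record` satisfies
$\Delta G = \Delta H - T\Delta S$ to $10^{-9}$. The Wiseman parameter
$c = K c_\mathrm{L}$ is reported and flagged outside the classically
fittable 1–1000 window; thermograms whose fitted binding signal is
indistinguishable from the residual noise are flagged non-binding.
Defaults mirror a VP-ITC setup: $V_0 = 1.4$ mL, 25 × 10 µL injections,
298.15 K — documented assumptions chosen as a typical protocol for this
instrument class. Units are J
internally, kJ mol⁻¹ / J mol⁻¹ K⁻¹ in reports (1 cal = 4.184 J in files).

```{r}
g <- gen_thermogram(log_K = 6.02, dH = -15, noise_frac = 0.01, seed = 1)
fit_thermogram(subtract_blank(g$thermogram, g$blank))
```

## Solvent-transfer cycles

Complexation in two solvents is linked by the transfer of each
participant:

$$\Delta_\mathrm{t}G^\circ(\mathrm{LA}^-) =
\Delta_\mathrm{t}G^\circ(\mathrm{A}^-) +
\Delta_\mathrm{t}G^\circ(\mathrm{L}) +
\Delta_\mathrm{r}G^\circ(\text{target}) -
\Delta_\mathrm{r}G^\circ(\text{source}).$$

`complex_transfer()` closes this cycle (exactly, by construction) for any
single unknown leg. The receptor leg comes from saturation solubilities,
$\Delta_\mathrm{t}G = -RT\ln(s_\mathrm{target}/s_\mathrm{source})$, valid
for a neutral solute equilibrated with the same solid phase; a receptor
with near-equal solubilities in the two solvents (e.g. 2.72 vs 2.81 mM)
has a negligible leg (≈ −0.08 kJ mol⁻¹). Anion legs are single-ion literature
values that depend on an extra-thermodynamic assumption, so they are
config inputs with their quoted direction recorded explicitly and
normalized on input — all cycle output is reported for source → target
(MeCN → MeOH by default). Anions are solvated far more strongly by
methanol than by acetonitrile, so their MeCN → MeOH legs are large and
negative; that, not any change in the complex itself, is why stability
constants collapse in the protic solvent.

## Ensemble analysis

Simulation output (multi-model PDB via bio3d, or XYZ trajectories) is
wrapped in a light `ensemble` container with a minimal selection language
(`"resid 2 and name N"`). The analysis chain:

* `build_coordination_matrix()` — per frame, for every (amide N–H,
  acceptor heavy atom) pair: $d(\mathrm{N\cdots X})$,
  $d(\mathrm{H\cdots X})$, and the N–H⋯X angle (vertex at H). For the free
  receptor the carbonyl oxygens stand in for the anion.
* `hbond_census()` — intramolecular hydrogen bonds per frame under a
  geometric criterion, $d(\mathrm{N\cdots O}) \le 3.5$ Å and angle
  ≥ 150°, both configurable since no universal criterion exists; pairs
  within a residue are excluded.
* `coordination_occupancy()` — per amide, the fraction of frames with
  $d(\mathrm{H\cdots X})$ within a cutoff (default 2.8 Å, a typical
  H⋯acceptor distance; per-anion overrides supported), with an optional
  angle gate. `nearest_acceptor_fractions()` attributes each frame to the
  closest acceptor atom, which is how a claim like "thiocyanate binds
  through nitrogen" is *verified* rather than assumed.
* `representative_frame()` — columns standardized (distances in Å and
  angles in degrees are not commensurate otherwise), PCA, k-means in the
  leading 2–3 PCs with $k \in 2..8$ chosen by average silhouette width and
  a single-cluster fallback below 0.5 (the conventional weak-structure
  boundary; a forced split of one homogeneous cluster scores below it).
  The result is the frame nearest the centroid of the most populous
  cluster — a reproducible stand-in for the unspecified clustering of the
  original workflow, deterministic under a fixed seed.
* `ring_centroid_distances()` — per frame, mass-weighted ring centers of
  mass against the unweighted Cα centroid, the proximity measure for
  sidechain rings versus the binding site.
* `subsample_and_average()` — strided frame subsampling (every 50th by
  default) and arithmetic averaging of externally computed per-frame
  spectra; computing those spectra (e.g. CD from structures) is explicitly
  outside this package.

All geometric operations are invariant under rigid-body transforms of the
frames, enforced by property tests with random rotations.

## What the synthetic generators emulate — and what they do not

Every pipeline input can be generated with known truth: bilinear spectral
titrations (Gaussian band templates near 283 nm, enhancement or quenching),
fast-exchange shift titrations (downfield amide shifts by default),
Wiseman thermograms with dilution blanks, and a five-fold pseudo-peptide
scaffold whose anion sits at an *endo* site above the ring (all five amide
H at 2.61 Å, inside the coordination cutoff by construction) or an *exo*
site below it, mixed at set weights with Gaussian coordinate jitter
(default 0.05 Å). Demo constants span the qualitative range of the
motivating study (strong ≈ 6 in acetonitrile down to ≈ 1.5 in methanol);
they are illustrative, not reproductions of experimental values.

The generators are deliberately idealized: homoscedastic Gaussian noise
(real photon noise is signal-dependent), no baseline drift or wavelength
calibration error, rigid scaffold geometry rather than force-field
sampling, and no photophysics of quenching. Passing recovery tests
therefore demonstrates the *estimators* are correct and well-conditioned
under the stated designs; they do not certify performance on instrument
artifacts the noise model excludes.

## Numerical choices and edge cases

* Speciation: tolerance $10^{-12}$ relative, log-space Newton, bisection
  fallback; zero totals short-circuit exactly.
* Fitting: LM with `ftol` $10^{-14}$; ±1 log-unit multistarts; species
  reported in lexicographic $(l,a)$ order (the tie-break for equivalent
  relabelings); degenerate designs error out.
* Cycles: closure is exact by construction; over-determined cycles are
  validated to $10^{-9}$ kJ mol⁻¹ and rejected otherwise.
* Ensembles: zero-variance coordination matrices (identical frames) are a
  defined tie case (first frame, distance 0); k-means uses 10 restarts per
  k under the caller's seed.
* Problem sizes throughout the tests and the acceptance study — 15-point
  titrations, 25-injection thermograms, 50-titration recovery grids,
  200-frame ensembles, 1000-draw solver checks — were chosen as the
  smallest sizes at which the statistics stabilize.

## Known limitations

Activity corrections, ionic-strength dependence, and protonation
equilibria are out of scope (constants are conditional, on the molar
scale). The ITC model is strictly 1:1 single-site. The 1:2 dihydrogen
phosphate species is supported in the model and fits, but no reference
value is shipped for it — real titrations rarely reach the data quality for
quantifying such minor species from typical titration data. CLI-style batch
use is served by `run_pipeline()` and the file readers/writers; there is
no shell executable.
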