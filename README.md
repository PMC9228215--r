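# anionbind

Determining how strongly — and how — a synthetic receptor binds anions in
solution takes a chain of inference, not a single fit: an equilibrium
speciation model shared by every observable, global multivariate regression
of spectroscopic and NMR titrations, single-site calorimetry, thermodynamic
cycles that separate solvent effects from intrinsic affinity, and
structural analysis of simulation ensembles of the complexes. `anionbind`
implements that whole chain for receptor–anion (host–guest) systems such as
cyclopeptides, whose converging amide N–H donors coordinate halides,
thiocyanate and oxoanions. It is aimed at supramolecular and analytical
chemists who have titration matrices, thermograms, or trajectory frames and
want stability constants, reaction thermodynamics, and coordination
statistics out the other end — with synthetic-data generators so every
stage can be validated against known ground truth.

## The models in brief

**Speciation.** Complex species L<sub>l</sub>A<sub>a</sub> carry cumulative
constants β<sub>la</sub> = [L<sub>l</sub>A<sub>a</sub>]/([L]ˡ[A]ᵃ) on the
molar scale. Given totals, free concentrations are solved by damped Newton
iteration in log-concentration space (analytic Jacobian from the
stoichiometry matrix, mass balance closed to 10⁻¹²), including competing
anion dimerization (A₂) and receptor–dimer complexes (LA₂).

**Global fitting.** A spectral titration is bilinear, Y ≈ S Cᵀ: the
species-concentration matrix C depends on log β through the mass balance,
the molar spectra S are linear. Fitting uses variable projection — S solved
exactly by least squares at every Levenberg–Marquardt step over log β —
for fluorescence/UV matrices, and the fast-exchange population average
δ_obs = Σ l·[s]·δ_s / c_L for per-proton NMR shifts.

**ITC.** Single-site displaced-volume model,
Q_i = V₀ΔH([LA]_i − [LA]_{i−1}(1 − v_i/V₀)) + blank, fitted for log K and
Δ<sub>r</sub>H with dilution heats subtracted or co-fitted;
Δ<sub>r</sub>S = (Δ<sub>r</sub>H + RT ln10·log K)/T.

**Transfer cycles.** Δ<sub>t</sub>G°(LA⁻) = Δ<sub>t</sub>G°(A⁻) +
Δ<sub>t</sub>G°(L) + Δ<sub>r</sub>G°(target) − Δ<sub>r</sub>G°(source),
closed exactly; receptor legs from solubility ratios
(−RT ln(s_t/s_s)), anion legs from literature single-ion values with
explicit direction bookkeeping.

**Ensembles.** Coordination matrices (N⋯X, H⋯X distances, N–H⋯X angles per
amide/acceptor pair and frame), hydrogen-bond census under a configurable
geometric criterion, per-amide occupancies, PCA + silhouette-selected
k-means representative structures, ring-centroid distributions, and strided
spectrum averaging.

## Worked example

Simulate a fluorimetric titration of a receptor with a 1:1 binder
(log K = 4, signal-to-noise 100), then fit the constant starting from a
deliberately wrong guess:

```r
library(anionbind)

sim <- gen_spectral_titration(log_K = 4, snr = 100, seed = 7)
fit <- fit_spectral(sim$series, sim$schedule,
                    set_free_constants(sim$model, 3.4))
fit
#> Global spectral fit: SS = 699.7, converged (6 iterations)
#>   log beta(1,1) = 3.9804 +/- 0.0302
```

The constant is recovered within its standard error. A calorimetric run of
a strong chloride-type complex, blank-corrected and fitted:

```r
g <- gen_thermogram(log_K = 6.02, dH = -15, noise_frac = 0.01, seed = 1)
fit_thermogram(subtract_blank(g$thermogram, g$blank))
#> log K = 6.036   DrG = -34.46 kJ/mol   DrH = -14.92 kJ/mol
#>   DrS = 65.5 J/(mol K)   T = 298.15 K
```

i.e. the generator's (log K, ΔH) are returned with ΔG = ΔH − TΔS enforced.
Finally, the solvent-transfer cycle explains why the same complex is ~4.5
log units weaker in methanol: the anion leg dominates.

```r
cycle_from_constants(log_K_source = 6.02, log_K_target = 1.5,
                     dtG_anion = -29, anion_direction = "source->target",
                     solubility_pair = c(2.72e-3, 2.81e-3))
#> Transfer cycle (kJ/mol, source -> target):
#>   dtG_anion     -29.000  [literature (source->target)]
#>   dtG_ligand     -0.081  [solubility]
#>   drG_source    -34.362  [titration]
#>   drG_target     -8.562  [titration]
#>   dtG_complex    -3.280  [cycle closure]
#>   closure             0
```

The receptor's own transfer is negligible (−0.08 kJ/mol from its
solubility pair) and the complex transfer is slightly favorable; the
stability loss in methanol is carried almost entirely by the free anion's
stronger solvation there.

See `vignette("anion-binding-workflow")` for the full methods account.

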