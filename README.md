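# bindpoly

Quantitative equilibrium binding analysis for a monomeric protein ligand
binding a DNA molecule that carries **three tandem recognition repeats** —
the situation of a replication initiator's origin-binding domain engaging
the direct repeats of a plasmid double-strand origin. The package estimates
how tightly the protein binds each repeat, whether successive binding
events help one another (cooperativity), how fast the complex falls apart,
and which bases the protein shields, all from the standard desk instruments
of the field: EMSA gel quantifications, SPR steady-state responses,
competition-chase gels and footprint densitometry scans.

## The model

Binding of a ligand at free concentration *L* (μM) to a three-site DNA is
summarised by the binding polynomial

    Z = 1 + K1·L + K2·L² + K3·L³

whose coefficients *K1* (μM⁻¹), *K2* (μM⁻²), *K3* (μM⁻³) are the
macroscopic association constants for carrying one, two or three ligands.
The fraction of DNA molecules with exactly *i* ligands bound is
θᵢ = Kᵢ·Lⁱ / Z (K₀ = 1) — in gel terms: free DNA and the C1, C2, C3
complexes. Macroscopic constants are sums of microscopic ones (intrinsic
site constants *k1, k2, k3* and pairwise coupling factors *k12, k13, k23*);
only the macroscopic constants are identifiable from a single mobility-shift
titration, so cooperativity is inferred by comparing them:

* second binding event cooperative if K2 > K1²/3  (statistic r2 = 3K2/K1²)
* third binding event cooperative if K3 > K2·K1/3 (statistic r3 = 3K3/(K1·K2))

When the repeats are identical and independent, K1 = 3·Ka, K2 = 3·Ka²,
K3 = 3·Ka³, and each order of the polynomial returns an estimate of the
per-repeat association constant *Ka*; the package averages the three and
reports *Kd* = 1/Ka. Single-repeat EMSA curves and SPR steady-state series
use the one-site hyperbola y = Bmax·x/(Kd + x); dissociation chases use
first-order decay above a measured background, with a censored upper-bound
half-life when the complex is gone by the first sample.

## Worked example

```r
library(bindpoly)

# three replicate gels of a titration: 20 nM three-repeat DNA,
# 12 protein concentrations from 0.1 to 1.3 uM, per-site Ka = 1.2 uM^-1
sim  <- simulate_titration(Ka = 1.2, reps = 3, noise = 300, seed = 42)
fits <- lapply(split(sim, sim$replicate), fit_macroscopic)
fits[["r1"]]
#> Three-site binding-polynomial fit
#>   K1 = 3.387 uM^-1 (SE 0.163)
#>   K2 = 4.401 uM^-2 (SE 0.245)
#>   K3 = 4.815 uM^-3 (SE 0.275)
#>   RSS = 0.01074 on 12 titration points (total free-ligand rule)

boot   <- bootstrap_uncertainty(sim, n_boot = 1000, seed = 42)
assess_cooperativity(fits, boot)
#> Cooperativity report (three identical DNA repeats)
#>   r2 = 1.06 +/- 0.083 (bootstrap SD 0.049): not-inferred
#>   r3 = 0.954 +/- 0.033 (bootstrap SD 0.043): not-inferred
#>   verdict rule: bootstrap lower 2.5% bound of rj > 1 (999 resamples)
#>   per-site Ka = 1.19 +/- 0.014 uM^-1;  Kd = 1/Ka = 0.843 uM
#>   replicates: 3
```

The fitted constants sit on the independent-identical line (both ratio
statistics ≈ 1, neither bootstrap lower bound above 1), so no cooperativity
is inferred and the reduction to a per-repeat constant is allowed: the
generating Ka = 1.2 μM⁻¹ comes back as 1.19 ± 0.014 μM⁻¹, i.e. a
per-repeat Kd of about 0.84 μM. Had the data been generated with pairwise
coupling, the verdict would read `cooperative` and the reduction would be
refused.

SPR steady-state data use the same hyperbolic core as single-repeat EMSAs:

```r
spr <- simulate_spr(Kd = 0.22, Rmax = 100, sigma = 1, seed = 7)
fit_spr_steady_state(spr$conc_uM, spr$Req_RU)
#> One-site saturation fit: y = Bmax * x / (Kd + x)
#>   Kd   = 0.2036 uM (SE 0.0144)
#>   Rmax = 97.18 RU (SE 2.07)

# a chase whose first 10 s sample is already at the 5% background control
fit_dissociation(c(10, 30, 60), c(0.04, 0.03, 0.04), background = 0.05)
#> Dissociation chase: complex at background by the first sample
#>   half-life < 10 s (censored upper bound; background 0.05)
```

Footprint densitometry (`normalize_profiles()`, `percent_change()`,
`average_replicates()`) turns paired free/complexed lane scans into per-base
protection and hyperexposure percentages; `run_pipeline()` drives any stage
from TSV input to a JSON report, and `inst/exec/bindpoly` wraps it for shell
use.

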