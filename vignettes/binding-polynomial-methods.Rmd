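---
title: "Methods: the three-site binding polynomial and its companions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the three-site binding polynomial and its companions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindpoly)
```

This vignette is the package's own account of the statistical machinery:
the models, the defaults and why they were chosen, the numerical choices,
and what the synthetic-data tests do and do not demonstrate about real gels.

## The three-site model

A DNA molecule carrying three tandem recognition repeats and a monomeric
protein ligand at free concentration $L$ (all concentrations in this
package are in $\mu$M, never auto-converted) populate four ligation states.
With only pairwise cooperative interactions considered, the statistical
weight of each microstate is: unliganded $1$; singly liganded at site $i$,
$k_i L$; doubly liganded at $\{i,j\}$, $k_i k_j k_{ij} L^2$; and triply
liganded, $k_1 k_2 k_3 (k_{12}+k_{13}+k_{23}) L^3$. Grouping by occupancy
gives the macroscopic constants

$$K_1 = k_1+k_2+k_3,\quad
  K_2 = k_1k_2k_{12}+k_1k_3k_{13}+k_2k_3k_{23},\quad
  K_3 = k_1k_2k_3\,(k_{12}+k_{13}+k_{23}),$$

the binding polynomial $Z = 1 + K_1L + K_2L^2 + K_3L^3$, and the occupancy
fractions $\theta_i = K_iL^i/Z$ that an EMSA resolves as free DNA and the
C1/C2/C3 complexes. `species_fractions()` implements the closed form;
`microstate_oracle()` re-derives it by brute enumeration of the eight
configurations, and the test suite holds the two routes together to
$10^{-12}$ across random parameter draws.

**The cubic-coefficient convention.** Note the *sum*
$(k_{12}+k_{13}+k_{23})$ in $K_3$. Under it, the identical-independent
limit ($k_i = K_a$, all couplings 1) gives $K = (3K_a, 3K_a^2, 3K_a^3)$,
whereas the binomial expansion of fully independent sites would give the
cubic coefficient $K_a^3$. The sum form is the pairwise-additive
convention this analysis tradition uses, and it is what the downstream
identities (the ratio statistics and the per-order $K_a$ estimates) are
built on, so it is the package default; whether it should instead be read
as the product $k_{12}k_{13}k_{23}$ (which reduces to the binomial form)
is genuinely open, so `macro_from_micro()` and `microstate_oracle()`
expose `triple_term = "product"` for comparison. Nothing downstream of the
macroscopic constants depends on the choice: fitting, ratios and the
reduction all operate on $(K_1,K_2,K_3)$ directly.

**Cooperativity statistics.** The second and third binding events are
cooperative when $K_2 > K_1^2/3$ and $K_3 > K_2K_1/3$; the package reports
the ratio statistics $r_2 = 3K_2/K_1^2$ and $r_3 = 3K_3/(K_1K_2)$, which
are exactly 1 for identical independent sites — for *any* $K_a$, a tested
identity. When neither event is judged cooperative, each order of the
polynomial estimates the per-repeat association constant
($K_1/3$, $\sqrt{K_2/3}$, $\sqrt[3]{K_3/3}$); their arithmetic mean is the
reported $K_a$ and $K_d = 1/K_a$. The arithmetic mean (rather than, say,
geometric) was chosen because the three estimates are equally valid
moment-style estimators on the same scale and the field reports
mean $\pm$ SD; the algebraic round trip
`ka_from_macro(macro_from_ka(Ka))` is exact to $10^{-12}$ either way.

## Fitting the titration

`fit_macroscopic()` minimises the weighted squared error between observed
$(f_1,f_2,f_3)$ and model $(\theta_1,\theta_2,\theta_3)$ over the
concentration grid; $f_0$ is excluded because the simplex constraint makes
it redundant. Numerical choices:

* **Positivity** by fitting $\log_{10}K_i$.
* **Multistart**: Levenberg–Marquardt from the 8 corners of the
  $\log_{10}K_i \in \{-2, 2\}$ grid; lowest RSS wins, ties (RSS within
  $10^{-9}$) broken by the smallest $\lVert\log_{10}K\rVert$. Recovery is
  exact (relative error $<10^{-6}$, tested) for constants spanning
  $10^{-2}$–$10^{2}$ in each component.
* **Free ligand**: the default equates free with total protein. The DNA
  sits at tens of nM against protein at $\ge 0.1\,\mu$M, so depletion is at
  most $3 \times 20$ nM $= 60$ nM, about 6% at the lowest grid point.
  `ligand_conservation = "exact"` instead solves the scalar mass balance
  $L + D_\mathrm{tot}(\theta_1 + 2\theta_2 + 3\theta_3) = P_\mathrm{tot}$
  by bracketed root finding at every point; the tests verify it undoes the
  depletion bias on data generated with conservation enforced.
* **Weights**: unit by default; per-point inverse-variance weights can be
  supplied when replicate SDs exist.
* **Input slack**: gel-quantified fraction rows may miss the simplex by up
  to 2%; they are renormalised to sum exactly to 1, and larger deviations
  are rejected with the row number.
* **Degenerate inputs**: a titration that never leaves the free-DNA state
  raises an identifiability error rather than returning a boundary fit.

Standard errors are delta-method values from a finite-difference Jacobian
on the log scale; they describe curvature, not replicate scatter, which is
why the bootstrap exists.

## Uncertainty and the verdict rule

`bootstrap_uncertainty()` case-resamples concentration points within each
replicate, refits every resample (started from the full-data estimate, with
a multistart fallback), and returns the empirical distributions of
$(K_1,K_2,K_3,r_2,r_3,K_a)$; failures are dropped and counted, and the
whole procedure is deterministic given its mandatory seed.

The cooperativity verdict is deliberately conservative: event $j$ is called
*cooperative* only when the bootstrap lower 2.5% bound of $r_j$ exceeds 1;
otherwise the report says *not-inferred* (the data may simply lack power).
Comparing a ratio mean to 1 informally would call cooperativity on noise;
the lower-bound rule holds the false-cooperativity rate under a true
independent generator below 10% per event (tested over 50 seeded
datasets — empirically it sits near the nominal 2.5%). Across-replicate SD
and bootstrap SD answer different questions (gel-to-gel scatter vs
within-gel sampling), so the report carries both rather than conflating
them. If either verdict is cooperative, the identical-independent reduction
no longer applies and the report refuses to produce $K_a$/$K_d$.

Coverage was checked under a three-replicate design (the field's "at least
three independent gels" convention): the central 95% percentile interval of
each $K_i$ contains the generating value in $\ge 90\%$ of 20 seeded trials.
With a single 12-point gel the percentile interval is noticeably
anti-conservative — a known small-sample property of case resampling — which
is a documented reason to run replicate gels rather than a software knob to
hide.

## Single-site affinity, kinetics, footprints

The one-site hyperbola $y = B_\mathrm{max}x/(K_d + x)$ serves both EMSA
fraction-bound curves and SPR steady-state responses through one shared
core (`fit_hyperbola()` / `fit_spr_steady_state()`), again
Levenberg–Marquardt on log-scale parameters — this also survives nearly
flat curves whose plain-`nls` gradient matrix is numerically singular, in
which case the result is flagged *poorly constrained* whenever $K_d$ falls
outside $(\min(x)/100,\ 100\max(x))$. $B_\mathrm{max}$ is free by default
(its fitted value is itself informative about the active fraction and
plateau) and can be fixed via `fix_bmax`. Fits are scale-equivariant in
concentration to $10^{-9}$, a tested invariant. Replicate $K_d$ values are
compared with a one-way fixed-effects ANOVA or a Student's equal-variance
two-sample $t$ test (Welch by flag); raw p-values are reported and no
multiple-testing correction is applied, which the report style makes
explicit.

Dissociation chases subtract a *measured* background (the competition
control in which label and excess competitor are pre-mixed) rather than
fitting it — the control lane is better information than an extra free
parameter. The censoring rule dominates: if the first sample is already at
or below background, the half-life is reported only as an upper bound equal
to that sampling time, and no exponential is fit. Otherwise
$f(t) = (f_0-\mathrm{bg})e^{-k_\mathrm{off}t} + \mathrm{bg}$ is fit and
$t_{1/2} = \ln 2 / k_\mathrm{off}$. A "gross rise" guard rejects series in
which a later sample more than doubles an earlier one *and* jumps by more
than 0.05 absolute — the absolute clause keeps near-background noise from
tripping a pure ratio test.

Footprint quantification works on already-integrated per-base lane
intensities. The complexed lane is rescaled so its total intensity over the
reference bases matches the free lane (all bases by default; a set of
known-unaffected bands can be supplied instead — which of the two a given
published gel used is generally unstated, so both are supported and the
scale factor is always reported). Per base,
$\Delta\% = 100\,(I_\mathrm{complex}-I_\mathrm{free})/I_\mathrm{free}$,
classified protected/hyperexposed at a configurable threshold
(default 20%, chosen so that gel-to-gel densitometry noise of a few percent
never classifies); zero-intensity free bases are flagged unquantifiable
rather than dropped. Replicate averaging requires at least two gels and
reclassifies on the mean. Strands are independent profiles and are never
merged. Reports are invariant to overall lane rescaling, a tested property.

## What the generators emulate — and what they don't

Each generator reproduces one experimental input at its published design
point: titrations at 20 nM three-repeat DNA over twelve concentrations
spanning 0.1–1.3 μM; single-repeat curves over 0.5–50 μM; the
five-concentration SPR injection series (0.1–1 μM); chases first sampled
at 10 s over a ~5% background; and paired lane profiles with specified
per-base protection factors. Fraction noise is Dirichlet (concentration
parameter 300 by default, i.e. per-fraction SD ≈ 0.03, typical of careful
gel densitometry) because fractions live on the simplex — independent
Gaussians would not; Gaussian noise is used only for unconstrained signals
(responses, intensities, single curves with clipping). Noiseless mode
reproduces the forward model exactly and the same seed gives bit-identical
output; generators restore the caller's RNG state.

What passing these tests shows: the estimators invert their own forward
models correctly, at the published design points, under a plausible noise
family. What it does not show: robustness to the failure modes of real
gels — band overlap and smearing, lane-to-lane transfer bias, protein
inactivation during the titration, baseline drift in SPR sensograms, or
compression artefacts in sequencing gels. Those enter upstream of this
package's inputs.

## Problem sizes

The shipped tests run at desk scale on one CPU: 12–15-point titrations,
bootstraps of 100–500 resamples, 20-trial coverage and recovery studies,
50-dataset verdict calibration, 1000-simulation type-I checks for the
ANOVA. These sizes were chosen to make the statistical assertions sharp
(binomial error small relative to the asserted bounds) while keeping the
whole suite comfortably fast; production analyses can raise `n_boot` (the
default is 1000) without touching anything else.

## Known limitations

* Three sites, one homotropic ligand; no heterotropic competition, no
  Hill-style phenomenology, no more-than-pairwise coupling.
* Macroscopic constants only from a single titration — individual-site
  (footprint-resolved) isotherms are out of scope.
* SPR is steady-state only; association/dissociation kinetics from full
  sensograms are not modelled.
* The bootstrap is percentile-based; with a single short titration its
  intervals under-cover and replicate gels are the remedy.
* The cubic-coefficient convention is selectable but its empirical
  resolution would need data beyond a single mobility-shift experiment.
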