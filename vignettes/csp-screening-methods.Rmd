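---
title: "Models and methods behind cspscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cspscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspscreen)
```

# The observable and the binding model

A protein-observed fragment screen watches one ¹⁵N-HSQC peak per
backbone amide. The per-residue observable is the weighted chemical
shift perturbation between an apo reference and a fragment-containing
sample,

$$\Delta\delta \;=\; \sqrt{(\Delta^{1}\mathrm{H})^2 +
  (\alpha\,\Delta^{15}\mathrm{N})^2},$$

where $\alpha$ rescales the nitrogen shift range onto the proton range.
We default to $\alpha = 0.14$, the standard amide weighting; it is an
argument of `compute_csp()` because other conventions exist (including a
variant with a $1/2$ normalisation under the root, which differs only by
a constant factor and therefore changes neither $\sigma$-based shifter
selection nor fitted $K_d$ values — only the absolute ppm scale of
thresholds).

Fragments bind weakly, so experiments run at ligand concentrations
comparable to the protein concentration (100 µM protein, fragment up to
400 µM — the 4:1 screening ratio). Bound ligand is then a substantial
fraction of total ligand and the hyperbolic law is wrong; the correct
two-state 1:1 closed form under ligand depletion is the quadratic root

$$f_B \;=\; \frac{(P + L + K_d) - \sqrt{(P + L + K_d)^2 - 4 P L}}{2P},$$

implemented in `bound_fraction()` with totals $P$ and $L$ over the whole
sample. No compartmental partition correction is applied; the fitted
constant is therefore an *apparent* $K_d$. In the fast-exchange regime a
peak sits at the population-weighted mean of its free and bound
positions, so $\mathrm{CSP}(L) = d_{max}\, f_B(P, L, K_d)$ with a
per-residue saturation amplitude $d_{max}$ (`predict_csp()`).
Discriminant rounding is clamped (the discriminant is analytically
positive) and the returned fraction is clipped to $[0, 1]$.

# Screening rules

All decision rules are exposed as defaults rather than constants:

* **Triage** (`triage_mixture()`): count residues of interest (membrane
  interface ∪ observable functional set) with CSP strictly above
  0.01 ppm; ≥ 5 is high priority, 3–4 medium, 1–2 low, 0 none. Bench
  triage of mixture spectra is typically done by eye; the counted
  surrogate makes it reproducible, with the tier boundaries chosen so
  that "1–2 resonances of interest" defines low priority. The boundaries
  and threshold are arguments.
* **Deconvolution hit** (`call_hit_deconvolution()`): a fragment
  retested alone is a hit when at least 7 of the observable functional
  resonances (cationic patch ∪ catalytic site minus unassigned — 15 for
  the synthetic target) exceed 0.01 ppm. "Greater than" is strict: a CSP
  of exactly 0.01 ppm never counts. The denominator comes from the
  annotation, not a hard-coded 15, so other targets can reuse the rule.
* **Top shifters** (`select_top_shifters()`): residues with CSP at least
  $k\sigma$ above the profile mean, $k = 1$ by default. $\sigma$ is the
  population standard deviation over the profile and the comparison is
  inclusive (≥). When all CSPs are equal, $\sigma = 0$ and the inclusive
  rule keeps every residue; this degenerate case warns.
* **Fit retention** (`retain_fit()`): individual fits with
  $R^2 < 0.85$ are removed before the global fit; exactly 0.85 is
  retained. $R^2$ uses the total sum of squares about the mean of the
  observed CSPs of that residue.
* **Classification** (`classify_fragment()`): *hit* requires apparent
  $K_d$ strictly below 1000 µM **and** at least half of the top shifters
  inside the interface/functional region; *weak* is localized but at or
  above the cutoff; anything non-localized is *nonspecific*. The
  locality fraction quantifies "structurally localized" and is
  config-exposed (default 0.5).

# Fitting

$d_{max}$ enters the model linearly at fixed $K_d$, so both the
per-residue and the global fit profile the amplitudes out analytically
($\hat d_r = \sum y f / \sum f^2$, clamped at 0) and minimise the
residual sum of squares over $\log K_d$ alone. The 1-D objective is
scanned on an 80-point log-spaced grid over $(10^{-4}, 1] \times 10\,
L_{max}$ — which plays the role of a multi-start and makes local minima
a non-issue — and refined with `optimize()` at tolerance $10^{-8}$ in
$\log K_d$. A brute-force 2-D grid oracle in the test suite confirms the
profiled optimum, and the joint fit agrees with
`minpack.lm::nls.lm` to five decimals on noisy data.

Two numerical points deserve emphasis:

* **The reference point is not an observation.** The titration's zero
  point is the spectrum the CSPs are measured against, so its CSP is 0
  by construction, with no measurement noise, and its Jacobian row is
  identically zero ($f(0) = 0$, $\partial f/\partial K_d|_{L=0} = 0$).
  Including it would not move the optimum but would silently inflate the
  residual degrees of freedom and shrink the estimated noise variance.
  Fits therefore use only the $L > 0$ points; a residue must still be
  observable at ≥ 3 concentrations including the reference.
* **The $K_d$ standard error is heteroscedasticity-robust.** Peak
  position noise is isotropic per peak ($\sigma_H$ in ¹H, $\sigma_N$ in
  ¹⁵N), but the CSP magnitude projects it onto the residue's
  displacement direction, so the effective CSP noise varies between
  $\alpha\sigma_N$ and $\sigma_H$ from residue to residue. A classical
  homoscedastic Gauss-Newton covariance is then mildly anti-conservative
  for the shared $K_d$. `fit_global()` reports the square root of the
  $K_d$ diagonal of an HC3 sandwich covariance built on the Gauss-Newton
  Jacobian at the optimum — the standard small-sample robust choice —
  which in simulation brings the ±2·SE interval to slightly conservative
  coverage of the true $K_d$. At zero noise the residuals vanish and the
  standard error is 0.

The global fit refits all amplitudes jointly with the shared $K_d$
(rather than freezing per-residue fit values), which is the statistically
standard choice for shared-parameter nonlinear regression.

# The synthetic-data generator

`simulation_config()` fixes the generative conditions:
100 µM protein; ligand ladder 0/50/100/250/400 µM; a 170-residue
protein with a 15-residue observable functional set (the screening
denominator) and a membrane-interface set around it; true apparent
$K_d$ = 105 µM for specific binders; per-residue $d_{max}$ drawn from
[0.02, 0.10] ppm; Gaussian peak-position noise of 0.002 ppm (¹H) and
0.01 ppm (¹⁵N) per peak per titration point. These mirror the screening
design the pipeline targets (4:1 top ratio, µM-range best binders,
typical fragment-induced shift sizes); the residue sets are synthetic
stand-ins with the canonical sizes, not a real protein's annotation.

`simulate_titration()` draws reference amide positions once from
plausible ranges (¹H 7.0–9.8 ppm, ¹⁵N 103–132 ppm), gives each residue
a fixed random displacement direction in weighted shift space, moves
responsive residues by $d_{max} f_B$ along it (so the noiseless weighted
CSP equals the model value exactly), and adds independent noise to every
peak of every titration point. Scenarios: `binder`, `weak_binder`
(same model, caller-chosen $K_d$), `nonbinder` (no displacement), and
`nonspecific_drift` (all residues drift linearly in $L$ —
non-saturating and non-localized, the signature the classifier calls
nonspecific). All randomness flows from the config seed; identical
configs are byte-identical on disk.

`simulate_screen()` partitions the library into consecutive mixtures by
ceiling division — 1911 fragments in mixtures of 10 give 192 mixtures
with the last of size 1; published mixture counts for such libraries are
sometimes quoted as ~190 because the remainder handling is not stated,
and we document rather than resolve that ambiguity. A mixture's spectrum
is generated from the strongest planted binder it contains; co-binder
additivity and inter-fragment competition are deliberately not modeled,
because the workflow retests mixture members individually anyway.
Fragment data are regenerable from recorded per-fragment seeds
(`simulate_fragment()`), which is what makes the deconvolution and
titration stages reproducible from the truth table alone.

What the generator does **not** emulate: line broadening and
intermediate/slow exchange, peak overlap and assignment ambiguity at
high ligand concentration, fragment partitioning into the membrane
mimetic, solvent/DMSO artifacts, and intensity changes. Passing
synthetic tests therefore demonstrates correctness of the analysis
chain under its stated statistical assumptions, not robustness to every
failure mode of real spectra.

# Pipeline, sizes and limitations

`run_pipeline()` chains simulate → triage → deconvolute → titrate from
a YAML or list config, writes stage CSVs, a summary JSON and a run log
(seed, thresholds, stage counts), and is deterministic per seed. Which
priority tiers advance to deconvolution is a config choice
(`advance_tiers`); advancing only high+medium mirrors
throughput-limited practice, and the default advances every flagged
tier.

Test and validation sizes were chosen to exercise the statistics at
realistic scale while staying quick: parameter recovery uses 100
titrations of 5 reporter residues; the end-to-end screen uses a
200-fragment library with 3 planted binders; the noise-dispersion sweep
uses 3 noise levels × 50 seeds on a reduced 20-residue protein.

Known limitations: 1:1 binding only (no cooperativity or multi-site
models); magnitude CSPs are slightly biased upward at low signal-to-noise
(Rice-type folding), which biases apparent $K_d$ a few percent low at
the default noise level; peak correspondence is by assignment label, so
curated transferred assignments are assumed; and the PDB writer only
rewrites the B-factor column of fixed-width ATOM/HETATM records
(CSP × 1000, capped at 999.99) — it is not a structure-manipulation
tool.
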