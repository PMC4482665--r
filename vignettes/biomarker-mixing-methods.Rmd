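---
title: "Methods: Bayesian biomarker mixing for consumer diets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian biomarker mixing for consumer diets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famix)
```

## The model

A consumer's biomarker value for tracer $j$ is modelled as a draw from a
Gaussian whose moments are determined by the diet proportions $p$ over $n$
source groups:

$$u_j = \sum_{i=1}^{n} p_i\,(m_{j,i} + f_{j,i}), \qquad
\sigma_j^2 = \sum_{i=1}^{n} p_i^2\,(s_{j,i}^2 + g_{j,i}^2),$$

with $m, s$ the per-group tracer means and SDs of the consumer-resource
library and $f, g$ the mean and SD of trophic fractionation (broadcast from
per-tracer vectors when not group-specific). Tracers are treated as
independent in the likelihood; no cross-tracer covariance is estimated. The
normality of the mixture rests on the Central Limit Theorem for linear
combinations of source signatures. Fatty-acid proportions are modelled on
the raw percentage scale rather than log-ratio transformed: individual FA
proportions need not be normal, but the weighted combination of many of them
is approximately so, and the approximation improves with the number of
tracers. The `zscore_diagnostic()` function exists precisely to check this
premise on a library: it standardizes every FA averaging above 5% of total
FA within its diet group and reports the pooled SD and median.

Because FA libraries are built from consumers experimentally fed pure diets,
trophic modification of dietary lipids is already embedded in the library's
means and SDs, and the FA fractionation terms default to zero. For stable
isotopes the packaged phytoplankton library uses a fractionation mean of
zero with SDs of 1.3 (δ13C) and 1.0 (δ15N) ‰. The zero mean is deliberate:
the pure-diet simulation scenarios are defined to leave the source means
unshifted, so fractionation enters as pure uncertainty. The global
literature means (≈0.4‰ for C, ≈3.4‰ for N) can be supplied through
`fractionation_spec()` when a field application calls for them.

## Priors

The default prior on $p$ is Dirichlet with $\alpha = 1$: uniform over
compositions, though not uniform for any single proportion (the marginal of
a $K$-component flat Dirichlet is Beta$(1, K-1)$; for $K = 3$ its median is
$1 - \sqrt{1/2} \approx 0.293$, which the prior-recovery tests pin). An
alternative form places independent Uniform$(0, 100)$ hyperpriors on each
concentration parameter and samples $\alpha$ jointly with $p$. Whether the
hyperparameter should be shared across components or per-component is
genuinely open; we chose per-component, which nests the shared case and
matches the "uniform hyperparameters" plural reading.

## Posterior sampling

The sampler is an adaptive random-walk Metropolis on additive log-ratio
coordinates $\theta_i = \log(p_i/p_K)$, with the log-ratio Jacobian
$\sum_i \log p_i$ included so draws target the stated density on the
simplex. A self-contained sampler was preferred over an external Gibbs
engine because the correctness contract here is oracle-equivalence, not
engine identity; the grid oracle below makes that contract testable.

Details that matter for reproducibility:

- **Initialisation**: a coarse simplex search (step 0.02) locates a
  high-density starting composition; each chain jitters it independently.
  This matters for the minimized-uncertainty scenarios, where posterior
  mass concentrates in a region a random start may take long to find.
- **Adaptation**: the scalar step size follows a Robbins–Monro schedule
  toward a 0.3 acceptance rate, and the proposal covariance is refreshed
  every 500 burn-in iterations from the accumulated burn-in history, then
  frozen, preserving detailed balance for the retained draws.
- **Protocol**: the default configuration is 100,000 iterations per chain,
  50,000 burn-in, thinning 50, two chains. A "fast" profile
  (10,000/5,000/5) is provided for pipelines and passes the same
  oracle-equivalence bar on the test problems.
- **Diagnostics**: split-chain potential scale reduction (flagged, not
  fatal, above 1.05) and a Geyer-style effective sample size per component.
- **Seeds**: `fit_many()` derives one seed per consumer (base seed +
  consumer index), so multi-consumer runs are reproducible and could be
  parallelised without changing results.
- **Summaries**: empirical quantiles use linear interpolation between order
  statistics (R type 7), pinned so summaries are bit-stable.

## The grid-integration oracle

For problems with at most 4 source groups, `oracle_posterior()` evaluates
likelihood × prior on a barycentric lattice (default spacing 0.002) and
normalizes. It shares no code path with the sampler beyond the algebra of
the moments, and the test suite requires all marginal quantiles
{2.5, 25, 50, 75, 97.5}% of the two routes to agree within 0.02 on a fixture
set of 2- and 3-source problems. One subtlety the oracle exposed during
development: because $\sigma_j$ depends on $p$, even a far-field consumer
with enormous source SDs does not return the prior — the normalization term
$-\tfrac12 \log \sigma_j^2$ favours compositions with smaller mixture
variance. The prior-recovery test therefore disables the likelihood (or
uses a dominating variance floor) rather than relying on "flat" data.

## Simulation machinery and conventions

`simulate_pure_si()` and `simulate_mixed_si()` draw each source group's
tracer vector from Normal$(m, s)$, combine with the diet weights, and add
**one** fractionation draw per consumer per tracer. This consumer-level
convention (variance $\sum_i w_i^2 s_i^2 + g^2$) reproduces the expected
pure-diatom δ13C SD of $\sqrt{2.3^2 + 1.3^2} = 2.64$‰; the model-side
variance keeps the per-source form $\sum_i p_i^2 (s_i^2 + g_i^2)$ exactly as
written above. Both conventions coincide at a diet vertex and differ only
mildly in the interior.

`simulate_mixed_fa()` instead resamples whole profiles: one individual
feeding-trial profile per group, combined as the weighted sum. Convexity
guarantees simulated FA consumers stay inside the hull of the library
profiles and remain closed to 100%.

The **uncertainty matrix** (`run_uncertainty_matrix()`) crosses resource
uncertainty (library SDs ×1 or ÷100 — the model does not admit exactly zero
source variance) with consumer uncertainty (noisy simulation versus a single
exact mixture). A deliberate design choice: in the low-resource-uncertainty
cells the *model-side fractionation SDs are scaled down together with the
source SDs* (`scale_fractionation_sd = TRUE`). Exact grid integration shows
this is the only convention consistent with the published behaviour of this
design: with source SDs ÷100 and an exact 0.8/0.1/0.1 consumer, retaining
$g = (1.3, 1.0)$ at full scale yields a diatom posterior near 0.70 with a
46–92% interval, whereas the minimized cell is reported as a sharp
80% (78–82%); conversely, with *both* source SDs and $g$ at full scale, the
exact consumer yields ~52% (6–89%), matching the reported
resource-only-uncertainty value of 56% (6–90%). Scaling $g$ with the
resources reproduces both regimes; the flag restores the literal
keep-$g$-fixed convention for comparison.

The **fractionation grid** (`run_fractionation_grid()`) minimizes resource
and consumer uncertainty, sets the model-side fractionation *variance* to
zero (a fixed-shift design — required for the posterior SDs of ±0.01 that
make the grid interpretable), and generates the consumer with its
fractionation shifted by ±1.96 SD per tracer while the model assumes the
mean. The reference (mean, mean) cell recovers 0.80/0.10/0.10 to two
decimals. The off-diagonal cells place the consumer outside or near the
edge of the mixing polygon; their outputs depend on boundary behaviour and
are exploratory rather than pinned. With `shift_model = TRUE` the shift is
applied to the model's assumed fractionation instead, mirroring the cells.

## Study conditions and problem sizes

The canonical simulation study uses 1,000 pseudo-consumers in batches of
100. The packaged tests and `scripts/acceptance.R` run the same scenarios
at desk scale — 100–200 consumers for the mixed-diet scenario, 60–100 per
group for the pure-diet scenarios, chains of 6,000–40,000 iterations — sizes
chosen so the whole suite completes in minutes on one CPU while keeping
Monte-Carlo error well inside the tolerances being checked (pooled medians
stabilise within ±2 percentage points by ~100 consumers). Batch-level
summaries are retained by `run_scenario()` so dispersion across batches can
be inspected.

## The synthetic fatty-acid library

FA-mode tests need a consumer-resource library with the statistical
character of real *Daphnia* feeding trials without shipping any measured
data. `default_fa_templates()` defines 26-tracer signatures for consumers
fed diatoms, greens and cryptophytes; the tracer list assembles every FA
named in the group diagnostics plus standard algal FAs, and the template
numbers are synthetic, not measurements. Marker contrasts follow the known
group diagnostics (16:1ω7 and C16 PUFAs for diatom feeders; 18:1ω9, 18:2ω6,
18:3ω3 and C16 ω3/ω6 PUFAs for green-algae feeders; 18:3ω3, 18:4ω3 and
20:5ω3 for cryptophyte feeders). Pairwise correlations between templates
stay below 0.6. A cyanobacteria template exists behind a flag but is
excluded from defaults: cyanobacteria feeding trials are known to be
contaminated by maternal lipid carryover, and the template deliberately
carries green-algae-like C18 levels to emulate that problem rather than hide
it.

Profiles are drawn by a multiplicative logistic-normal model: log
abundances perturbed by independent normal noise, then re-closed to 100%,
keeping every FA positive and the composition closed. The noise is
heterogeneous across tracers by design — diagnostic PUFAs (≥2 double bonds)
plus 16:1ω7 get log-SD 0.12 while the abundant, non-diagnostic saturates and
monounsaturates get 0.60. This structure was chosen once after an explicit
calibration experiment: with a *uniform* per-tracer CV no noise level can
simultaneously hold the profile-versus-group-mean correlation near the
feeding-trial value ($r^2 \approx 0.88$) and classify every monoculture
consumer with a true-group posterior median above 0.95 — the two demands
pull the same knob in opposite directions. Letting the non-diagnostic bulk
FAs carry the scatter (which is also what real trials look like: 16:0
varies with growth conditions, marker PUFAs track the diet) satisfies both:
across eight library seeds the mean $r^2$ spans 0.87–0.91 and in-sample
classification minima span 0.96–0.98. The classification check mirrors the
original study design, which ran the library's own monoculture cases back
through the model; held-out consumers typically classify just as well
(median true-group posterior ~0.99), but single unlucky draws can land
between groups and fall well below, so the held-out property is tested on
the median consumer rather than the minimum.

What the generator does *not* emulate: correlated within-group deviations
from shared experimental batches, species-level structure within a group,
growth/temperature/starvation effects on consumer FA, and maternal lipid
carryover dynamics. Passing tests on synthetic libraries therefore
demonstrate the *algorithm's* behaviour under controlled conditions, not the
field performance of any particular real library.

## Numerical choices and degenerate inputs

- **Variance floor** $10^{-12}$ on every $\sigma_j^2$: the SD÷100 scenarios
  make variances tiny, and an exact-mixture consumer would otherwise produce
  infinite densities.
- **Closure tolerance**: FA library means must sum to 100 ± 5 by default
  (configurable); profiles are *not* silently renormalized — closure
  violations are reported by `validate_library()`.
- **SD estimator**: sample SD ($n-1$), the lab-report convention; groups
  with a single profile record SD 0 with a warning.
- **Tracer matching**: exact name match after a curated synonym map
  (ω→w, δ→d, "n-3"→"w3"), because library and field data must use the same
  suite of tracers; a missing tracer is an error, never imputed.
- **Ties and boundaries**: the log-ratio parameterisation keeps $p$ strictly
  interior; boundary-concentrated posteriors (fractionation-grid corner
  cells) are represented by mass arbitrarily close to the vertex.

## Known limitations

- With two tracers and three or more poorly separated sources the problem
  is underdetermined; posteriors are then prior-dominated, and a
  generalist-looking output can be a symptom of model failure rather than a
  finding. The package reproduces this behaviour faithfully rather than
  masking it.
- The likelihood ignores cross-tracer covariance; for FA data with strong
  compositional coupling this is an approximation, mitigated but not
  removed by the number of tracers.
- The uniform-hyperprior form is implemented per-component and validated
  only for internal consistency (support, simplex closure, broad agreement
  with the fixed prior); no published reference values exist at a precision
  that would pin it tighter.
- `oracle_posterior()` is exact only up to its lattice spacing and refuses
  more than four sources; it is a validation tool, not an inference engine.
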