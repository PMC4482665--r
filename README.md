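# famix

Bayesian biomarker mixing models for inferring the diets of aquatic
consumers, for trophic ecologists working with fatty acid (FA) signatures,
bulk stable isotopes (SI), or both.

## The problem and the model

A consumer's biomarker profile is modelled as a convex combination of the
signatures of its food sources. For diet proportions **p** (non-negative,
summing to 1) over *n* source groups, tracer *j* of the mixture has mean and
variance

    u_j      = sum_i p_i (m_ji + f_ji)
    sigma_j² = sum_i p_i² (s_ji² + g_ji²)

where `m, s` are the per-group tracer means and SDs of the consumer-resource
library and `f, g` the mean and SD of trophic fractionation. Consumer data
are modelled as independent Gaussians around `u_j` with SD `sigma_j`, and the
prior on **p** is Dirichlet(α = 1), flat over compositions (a
Uniform(0, 100) hyperprior on each α is available as an alternative). The
posterior is sampled with an adaptive random-walk Metropolis sampler on
additive log-ratio coordinates, and validated against a dense
grid-integration oracle. When several consumers are analysed, each is fitted
independently and the posteriors are pooled by concatenating draws, so
dispersion does not collapse as consumers are added.

Two tracer families are supported:

- **Stable isotopes** (δ13C, δ15N in ‰): a packaged library of published
  lake phytoplankton values (diatoms, chlorophytes, cyanobacteria) ships
  with the package, together with fractionation SDs of ±1.3‰ (C) and
  ±1.0‰ (N).
- **Fatty acids** (% of total FA, ~26 tracers): libraries are built from
  feeding trials in which consumers ate pure diets, so trophic modification
  of dietary lipids is embedded in the library and fractionation is zero. A
  seedable synthetic-library generator reproduces the statistical structure
  of such trials for testing.

The package also implements the full simulation machinery around the model:
Monte-Carlo pseudo-consumers with known diets, a 2×2 resource/consumer
uncertainty design, and a ±1.96 SD fractionation sensitivity grid.

## Worked example

Simulate 25 pseudo-consumers that ate 80% diatoms, 10% chlorophytes and 10%
cyanobacteria, with full resource and fractionation uncertainty, and infer
their diet from δ13C and δ15N alone:

```r
library(famix)
si <- phytoplankton_si_library()
consumers <- simulate_mixed_si(c(0.8, 0.1, 0.1), si$library, si$fractionation,
                               n = 25, seed = 1)
cfg <- mcmc_config(profile = "fast", seed = 1)
fit <- fit_many(consumers, si$library, si$fractionation, cfg)
fit$pooled
#> <pooled_posterior: 25 consumers, 50000 draws>
#>           group median    q2.5 q97.5  mean    sd
#> 1       Diatoms  0.475 0.03234 0.898 0.468 0.246
#> 2  Chlorophytes  0.246 0.01070 0.762 0.285 0.206
#> 3 Cyanobacteria  0.199 0.00907 0.722 0.247 0.194
```

The pooled diatom median of ~48% sits roughly midway between the prior
expectation (33%) and the truth (80%), with a 95% credible interval spanning
most of [0, 1]: with only two tracers and realistic source uncertainty the
problem is underdetermined and the posterior is pulled strongly toward the
generalist prior. Running the same scenario with a 26-tracer fatty-acid
library (`generate_fa_library(default_fa_templates())`,
`simulate_mixed_fa(...)`) recovers ~80/10/10 with narrow intervals — the
motivation for FA-based diet inference.

A command-line entry point wraps the same workflows:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "famix.R", package = "famix"))') \
  fit --library lib.csv --consumers consumers.csv --kind si_delta --fast --out results/
```

Subcommands: `fit`, `simulate`, `sensitivity`, `validate-library`,
`make-synthetic-library`. Every run writes a JSON manifest (seeds, config,
input checksums) sufficient to reproduce its outputs.

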