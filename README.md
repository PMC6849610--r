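# occuedge

**Where in their geographic ranges do species go locally extinct?**

`occuedge` is an R package for estimating the position of recent local
extinctions within species' ranges from opportunistic point-locality
records (museum specimens, atlases, trip reports). It is aimed at
spatial ecologists and conservation scientists who have presence-only
occurrence compilations spanning decades and want to know whether ranges
are eroding from the edge or collapsing at the core — while accounting
for the fact that an absent record is usually an absent observer, not an
absent bird.

## The approach

1. **Equal-area gridding.** Records are aggregated onto a Behrmann
   (cylindrical equal-area, standard parallel 30°) grid of 48.24-km
   cells.
2. **Distance to range edge.** For every occupied cell *j* of a species,
   `D0(j)` is the geometric mean of the great-circle distances to the
   centroids of all other cells of that species' range; dividing by the
   species' largest `D0` gives the standardized score `D' ∈ (0, 1]`,
   with 1 = range edge. No centroids or drawn borders are involved, so
   the measure behaves sensibly for irregular ranges.
3. **Multispecies dynamic occupancy-detection model.** For each in-range
   species × cell pair, occupancy `z1 ~ Bern(ψᵢ)` before 1980 and

   ```
   E[z2] = z1 φᵢⱼ + (1 − z1) γᵢ
   logit φᵢⱼ = αᵢⱼ + βᵢⱼ (D'ᵢⱼ − 0.5)
   αᵢⱼ = α₀(1−R) + α₁R + α₂(1−R)C + α₃RC + uᵢ
   βᵢⱼ = β₀(1−R) + β₁R + β₂(1−R)C + β₃RC + vᵢ
   ```

   after it, where `R` is the biogeographic realm (0 = Palearctic,
   1 = Indo-Malaya), `C` the land-conversion class (1 when more than one
   third of the cell was converted), `1 − φ` the local extinction rate,
   and `uᵢ, vᵢ` species random effects (`vᵢ` is the species'
   *edge proneness*: negative = extinctions concentrated at the edge).
   Detection per survey (a cell:year species list) is
   `logit pᵢₖ = δ_t[t=2] + δ₁ᵢ + δ₂ᵢ·shortₖ + δ₃ᵢ·longₖ`, with list
   length (single / 2–3 / >3 species) proxying effort. Detection given
   absence is impossible.
4. **Fitting.** The latent states are marginalized analytically (C++
   kernel) and sampled by adaptive Metropolis-within-Gibbs with
   interweaving moves for the random-effect funnels; a slower
   data-augmentation sampler is kept as a cross-check. Summaries report
   posterior mean, SD, 95% interval, Gelman–Rubin Rhat and *f* — the
   confidence that a parameter is positive or negative (`0.5 ≤ f ≤ 1`).
5. **Products.** Extinction-rate-vs-D' curves per realm × conversion
   stratum, per-cell richness change with confidence, and species-level
   extinction-rate / edge-proneness / range-size tables.

A synthetic-data module generates opportunistic record sets with known
truth (two-realm landscape, contiguous ranges, list-length detection),
so the entire pipeline and a parameter-recovery study run without any
external data.

## A worked example

```r
library(occuedge)

# a small synthetic world with known truth
cfg <- simulation_config(n_species = 10, grid_nrow = 12, grid_ncol = 12,
                         range_size_min = 6, range_size_max = 50)
sim <- simulate_dataset(cfg, seed = 99)

surveys <- build_surveys(sim$records)          # cell:year species lists
dataset <- build_model_dataset(surveys, sim$ranges, sim$landscape,
                               cfg$grid)
dataset
#> occupancy model dataset: 10 species, 85 cells, 250 in-range pairs
#> 769 surveys, 2454 binary observations

draws <- run_mcmc(dataset,
                  settings = mcmc_settings(chains = 2, iter = 1600,
                                           burn_in = 1200, thin = 2,
                                           seed = 5))
posterior_summary(draws, pars = c("alpha0", "alpha1", "beta0", "beta3"))
#>    param  mean   sd    q2.5 q97.5 Rhat     f
#> 1 alpha0  3.86 1.44   1.619  7.00 1.00 1.000
#> 2 alpha1  2.77 1.48   0.398  6.16 1.00 0.991
#> 3  beta0 -3.21 4.71 -12.762  6.25 1.02 0.750
#> 4  beta3  2.80 7.98 -10.751 20.06 1.02 0.627
```

(Reproducible exactly — everything is seeded. The generating truth for
this world was `alpha0 = 3, alpha1 = 1.5, beta0 = -3, beta3 = 2`.)

`alpha0`/`alpha1` are the log-odds of persistence for the average
species at mid-range in unconverted cells of each realm — here
`alpha0 ≈ 3.9` means a mid-range realm-0 population persists with
probability `plogis(3.9) ≈ 0.98`, i.e. a ~2% local extinction rate per
era, and the 95% interval comfortably covers the truth. Negative
`beta0` means extinction concentrates toward the range edge in
unconverted realm-0 cells; its sign is recovered but, in a world this
small, with modest confidence (`f = 0.75`) — slope uncertainty shrinks
with more species and surveys. `f` close to 1 signals high confidence
in a parameter's sign.

Downstream products:

```r
curves <- extinction_curves_all(draws)      # Fig. 2-style curves
rich   <- richness_change(draws, dataset)   # per-cell change + confidence
eff    <- species_effects_table(draws, sim$ranges)
```

The full pipeline (simulate or load data → D' → surveys → fit →
products, with a JSON manifest of every artifact and filter count) is

```r
run_pipeline(default_config(seed = 1, out_dir = "out"))
```

or, from a shell, `Rscript inst/scripts/occuedge-cli.R all --seed 1
--out out`.

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance targets from
scratch against the installed package: the definitional worked example
of the sign statistic *f*, the lower bound of *f* over randomized
posterior samples, and the maximum Gelman–Rubin Rhat after fitting the
default 30-species synthetic benchmark with 3 chains at the desk-scale
settings. Run it from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It writes one JSON object with a numeric `value` (and the problem size
`n`) per target.

## Package layout

- `R/grid.R` – Behrmann grid, cell indexing, D0/D', realm and
  conversion covariates
- `R/surveys.R` – cell:year surveys, list-length categories, period
  split, cell/species filters, model dataset assembly
- `R/likelihood.R`, `src/loglik.cpp` – marginalized likelihood
- `R/mcmc.R` – samplers, Rhat, f, posterior summaries
- `R/products.R` – extinction curves, richness change, species effects
- `R/simulate.R` – synthetic worlds with known truth
- `R/pipeline.R` – config validation and end-to-end orchestration
- `vignettes/occuedge-methods.Rmd` – the model, its assumptions and the
  design decisions in full
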