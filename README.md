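# ssdevol

Comparative phylogenetic analysis of sexual size dimorphism (SSD)
evolution, for researchers asking whether sexual selection (via social
system) and/or natural selection (via diet) shaped body-size differences
between the sexes across a clade — the kind of question typically asked
of carnivoran mammals on a time-calibrated phylogeny with sex-specific
body masses.

The package implements the full pipeline:

- **Dimorphism and regimes.** The size dimorphism index
  `SDI = ±(S_L/S_S − 1) × 100` (positive when males are larger), and the
  aggregation of 4 social × 5 diet categories into six selective
  regimes ({solitary, group} × {carnivory, omnivory, other}).
- **Rensch's rule.** Phylogenetic reduced major axis regression of
  ln male on ln female mass, `b = sign(s_xy)·√(s_yy/s_xx)`, with Pagel's
  λ estimated simultaneously from the bivariate Brownian likelihood,
  and a log-scale test of `b = 1` with Clarke's effective degrees of
  freedom `df = 2 + (n−2)/(1 + r²/2)`.
- **Regime histories.** Mk (continuous-time Markov) model fitting and
  stochastic character mapping — node states sampled from their joint
  conditional distribution, branch histories by uniformization — with
  ancestral-state and transition-count summaries across map replicates.
- **OU model selection.** BM1, OU1 and multi-optimum OU (shared α and
  σ², regime-specific optima Θ in SDI percent) fitted across stochastic
  maps; per-map AICc weights averaged over maps; phylogenetic half-life
  `ln 2 / α`; parametric-bootstrap CIs for all parameters.
- **Shift detection.** Reversible-jump MCMC over multi-peak OU models
  (Poisson(15) prior on the number of shifts, at most one shift per
  branch), reporting per-branch posterior shift probabilities with
  Gelman–Rubin and ESS diagnostics.
- **Synthetic data.** A generator for trees, regime histories, SDI
  values and full species tables, so the entire pipeline is testable
  without any external data.

## Worked example

Generate a study-shaped synthetic data set (166 species, 60 Myr tree,
six regimes, half-life 3.16 Myr, optima 50/33/6/15/9/17%), then run the
two analyses:

```r
library(ssdevol)

rec  <- paper_like_recipe()
tree <- simulate_tree(rec, seed = 42)
sim  <- simulate_regimes(tree, rec$Q, rec$root_state, seed = 43)
tab  <- simulate_species_table(sim$map, rec, seed = 44)
sdi  <- setNames(tab$sdi_percent, tab$species)

# Rensch's rule
lnf <- setNames(log(tab$female_mass_g), tab$species)
lnm <- setNames(log(tab$male_mass_g),   tab$species)
test_slope(fit_phylo_rma(tree, lnf, lnm))
#> Phylogenetic RMA (all): slope = 1.0097 +- 0.0188, lambda = 0.996, r2 = 0.943, n = 166
#>   H0 slope = 1: T = 0.5179, df = 113.45, P = 0.6055 (none)
```

The slope is indistinguishable from 1: the generator puts no size
allometry into SSD, and the test correctly finds no Rensch trend, with
strong phylogenetic signal (λ ≈ 1) in the residuals.

```r
chars <- list(
  social   = setNames(collapse_social(tab$social_system), tab$species),
  diet     = setNames(collapse_diet(tab$diet),            tab$species),
  combined = setNames(tab$combined_regime,                tab$species))
map_sets <- lapply(seq_along(chars), function(i) {
  mk <- fit_mk(tree, chars[[i]], "ER")
  sample_simmaps(tree, mk, chars[[i]], n_maps = 20, seed = 50 + i)
})
names(map_sets) <- names(chars)

(cmp <- compare_models(map_sets, sdi, tree = tree))
#> Model comparison over 20 stochastic maps
#>         model mean_aicc delta_aicc mean_weight weight_of_mean_aicc n_best
#>           BM1  1471.056    99.7436      0.0000              0.0000      0
#>           OU1  1439.552    68.2400      0.0000              0.0000      0
#>    OUM_social  1440.520    69.2080      0.0000              0.0000      0
#>      OUM_diet  1377.881     6.5690      0.3113              0.0361      6
#>  OUM_combined  1371.312     0.0000      0.6887              0.9639     14
#> Best model (highest mean AICc weight): OUM_combined

best <- cmp$fits[[cmp$best_model]]
half_life(best$alpha)
#> [1] 3.705367

parametric_bootstrap(best, map_sets$combined[[1]], n_reps = 100, seed = 60)
#> Parametric bootstrap: 100 successful replicates, 95% CIs
#>                 parameter    point     lower     upper
#>                     alpha  0.18708   0.13983   0.32642
#>                    sigma2 97.90300 71.27800 152.22000
#>     theta_group_carnivory 34.73100  12.23600  55.96600
#>      theta_group_omnivory -0.83897 -15.75700  14.67900
#>         theta_group_other 14.80700  -7.13750  31.64800
#>  theta_solitary_carnivory 47.53800  42.90200  53.24100
#>   theta_solitary_omnivory 32.93800  26.02900  40.36100
#>      theta_solitary_other  8.27160   2.63020  12.70300
```

The combined social × diet model wins (mean AICc weight 0.69 over 20
maps here; the weight grows with the number of maps), the recovered
half-life (3.7 Myr) is close to the generating 3.16 Myr, and the
solitary-carnivory optimum is estimated at 47.5% [42.9, 53.2] against a
generating value of 50% — the largest optimum, exactly the
solitary-meat-eater signal the pipeline is designed to detect.

`run_pipeline()` wires all stages (SDI → per-clade RMA → mapping → model
comparison → bootstrap → RJ-MCMC shifts → summaries) behind one validated
config with a master seed; `inst/scripts/ssd-pipeline.R` is a thin
command-line wrapper.

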