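# chromdecay

Polymer-physics distance-decay models and penalties for chromatin
interaction proxies.

## The problem

The contact probability between two loci on a chromatin fiber decays with
their genomic separation *s* as a power law, *P*(*s*) ∝ *s*^−α, where the
exponent α = 3ν (ν the Flory exponent) reflects the folding regime of the
fiber: α → 0 for a collapsed globule, α ≈ 1 for a fractal globule, α = 1.5
for a free random walk. Real genomes mix regimes — tightly packed loop-scale
globules at short range, well-mixed TAD-scale globules at longer range — so
the log-log decay curve of Hi-C contacts is often piecewise linear rather
than a single line.

Proxy measures of chromatin interaction do not obey this physics.
Single-cell ATAC co-accessibility scores and sequence-based interaction
predictions are largely distance-independent, which grossly overestimates
long-range contacts relative to Hi-C. `chromdecay` corrects this by

1. fitting a multi-component power-law model to the distance decay of a
   Hi-C loop/contact list: the binned log-log contact histogram is
   decomposed with a 2-D Gaussian mixture model (model order chosen by a
   BIC plateau rule plus a distinct-exponent merge step), and a power law
   is regressed per regime;
2. assembling the resulting distance penalty

   *P*(*s*) = Σᵢ πᵢ βᵢ *s*^−αᵢ,

   normalized to a maximum of 1 on the fit range so it only down-weights;
3. multiplying each proxy score by *P*(*s*) at the pair's distance; and
4. quantifying proxy-vs-reference concordance on max-1 normalized decay
   profiles: Spearman ρ, 1-D Wasserstein (earth mover's) distance, and
   area-based error rates — FPR = (proxy area above the reference) / (proxy
   area), FNR = (reference area not covered) / (reference area), and the F1
   derived from the overlap area.

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

Simulate a maize-like single-regime loop set (generating exponent 2.34),
fit the decay model, penalize a flat noisy co-accessibility table, and
score both against the ground-truth curve:

```r
library(chromdecay)

cfg   <- sim_preset("maize-like", n_records = 50000, seed = 7)
loops <- simulate_contacts(cfg)                  # a BEDPE-shaped contact_set
fit   <- fit_decay_model(loops, fit_range_bp = c(35e3, 5e5),
                         n_range = 1:5, seed = 42)
fit
#> # penalty_params: P(s) = sum_i pi_i beta_i s^-alpha_i
#>   fit range:     35,000 - 5e+05 bp
#>   normalization: max_one_on_fit_range
#> # A tibble: 1 × 6
#>      pi         beta alpha x_min x_max r_squared
#>   <dbl>        <dbl> <dbl> <dbl> <dbl>     <dbl>
#> 1     1 92223665260.  2.35  4.56  5.68     0.999
```

One regime is selected and the generating exponent is recovered (α = 2.35,
R² = 0.999). Now the correction:

```r
scores <- simulate_flat_scores(sim_preset("flat-scores", n_records = 20000, seed = 8))
pen    <- apply_penalty(scores, fit)             # adds penalized_score
ref    <- make_reference_profile(cfg)            # exact generating curve

compare_profiles(scores, ref)                    # raw proxy
#>   spearman_rho wasserstein_bp      fpr          fnr        f1
#> 1      -0.0056        115151.5 0.938353 0.0001651427 0.1161335
compare_profiles(pen, ref, proxy_value_col = "penalized_score")
#>   spearman_rho wasserstein_bp          fpr        fnr        f1
#> 1            1        120.2962 0.0005886338 0.01693346 0.9911716
```

The raw flat proxy has 93.8% false-positive area against the reference
decay; after penalization the FPR collapses to 0.06%, the Spearman
concordance rises to 1, the Wasserstein distance falls by nearly three
orders of magnitude, and the F1 climbs from 0.12 to 0.99.

File-based workflows use the same functions via `read_bedpe()`,
`read_score_table()`, `write_penalty_params()` and friends, or the bundled
command-line stub:

```sh
Rscript inst/cli/chromdecay.R fit --bedpe loops.bedpe --out params.json
Rscript inst/cli/chromdecay.R apply --scores scores.tsv --params params.json --out penalized.tsv
Rscript inst/cli/chromdecay.R evaluate --proxy penalized.tsv --reference loops.bedpe --out report.json
```

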