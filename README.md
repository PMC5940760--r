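# saxsmm

Concentration-independent molecular mass (MM) of proteins from solution
small-angle X-ray scattering (SAXS), with a Bayesian consensus estimate.

## The problem

The MM of a protein in solution is the first quantity a SAXS analysis must
settle: it separates monomers from oligomers and flags aggregation or
degradation. Classical MM determination needs the sample concentration and
an absolute intensity scale — often unavailable, notably for in-line
SEC-SAXS. Concentration-independent methods need only the background-
subtracted curve *I(s)*, *s = 4π sin θ / λ*, but no single such method is
reliable across particle sizes, shapes and data quality.

`saxsmm` implements four of them and a Bayesian combination:

* **MM_Qp** — the Porod invariant *Q_p = ∫ s²I(s) ds* fixes the excluded
  volume *V_p = 2π² I(0)/Q_p* (Guinier extrapolation below the first point,
  data to *sR_g = 8*, analytic Porod tail beyond); MM \[Da\] = *V_p* \[Å³\] / 1.37.
* **MoW** — the apparent volume *V′ = 2π²/Q′* from the normalized curve up
  to a fixed *s_max*, corrected by a trained log-log law, times the protein
  mass density 0.83 × 10⁻³ kDa Å⁻³.
* **V_c** — the volume of correlation *V_c = I(0)/∫ s I(s) ds*; the ratio
  *V_c²/R_g* follows a trained power law in MM.
* **Size&Shape** — inverse-distance-weighted 5-nearest-neighbour look-up in
  the standardized space (*V′₃, V′₄, V′₅, log R_g*) of training particles.

Per-method likelihood tables *P(E|H)* over an adaptively binned mass axis
(quantile bins in the central 90%, linear bins in the 5% tails, clamped to
0.7–1300 kDa, Laplace pseudo-count of one) are combined by the product rule
with a uniform prior; methods that fail on a profile simply drop out. The
result is a MAP mass, a probability score, and a 90% credibility interval.
A posterior can be forwarded as the prior of the next frame in a series
(SEC-SAXS). Everything is trained on the bundled synthetic corpus
generator: seven particle shape classes from analytic form factors,
counting-noise levels SNR 32/11/4/2/1, and constant-offset buffer-mismatch
corruption.

## Worked example

Train a pipeline on a small synthetic corpus and score a noisy 94-kDa
globular particle:

```r
library(saxsmm)

corpus   <- build_corpus(n_per_class = 50, seed = 7)
feats    <- corpus_features(corpus$train)
pipeline <- train_mm_pipeline(feats)
pipeline
#> <mm_pipeline: 100 bins, methods [mm_qp, mm_mow, mm_vc, mm_ss], trained on 1400 profiles>

profile <- add_noise(ideal_profile(particle_spec("compact", 94)),
                     target_snr = 11, seed = 42)
profile
#> <saxs_profile 'compact_94kDa_snr11': 1001 points, s in [0.0006, 0.6] 1/A, sigma present>

post <- predict(pipeline, profile)
post
#> <mm_posterior: MAP = 88.17 kDa (p = 0.571), 90% CI [85.95, 105.4] kDa, 4 method(s)>

attr(post, "evidence")[, c("rg", "mm_qp", "mm_mow", "mm_vc", "mm_ss")]
#> # A tibble: 1 × 5
#>      rg mm_qp mm_mow mm_vc mm_ss
#>   <dbl> <dbl>  <dbl> <dbl> <dbl>
#> 1  23.7  82.4   88.7  83.9  97.6
```

The four individual estimates scatter from 82 to 98 kDa around the true
94 kDa; the consensus places the MAP at 88 kDa with a 90% interval
(86–105 kDa) that contains the truth. `glance(post)` returns the same
summary as a one-row tibble, `tidy(post)` the full per-bin posterior, and
`autoplot(post)` draws it with the MAP and interval marked. Evaluation
helpers (`binned_relative_error()`, `roc_curve()`, `best_method_heatmap()`,
`coverage()`) score whole corpora; a command-line wrapper with `guinier`,
`invariants`, `simulate`, `train`, `mm` and `bayes` subcommands is
installed under `inst/scripts/saxsmm`.

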