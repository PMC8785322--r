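# swbgrowth

Measure subjective well-being (SWB) from social-media post streams and
model its development over the phases of a public-health emergency.

Questionnaires are hard to field repeatedly during a crisis and cannot
recover pre-crisis baselines. This package instead classifies individual
posts as expressing high or low life satisfaction (LS), positive affect
(PA) and negative affect (NA), scores each user in each calendar phase by
the count score

```
SWB = #high-LS posts + #high-PA posts − #high-NA posts
```

and models the per-user score across post-outbreak waves with linear
latent growth models. The unconditional latent growth curve model (LGCM)

    y_i = Λ η_i + ε_i,   η_i ~ N(α, Ψ),   ε_i ~ N(0, Θ)

(Λ fixed: unit intercept column, slope column = time codes 0, 1, 2) is
fitted by maximum likelihood with SEM fit statistics (χ², CFI, TLI,
RMSEA, SRMR, AIC/BIC/aBIC). The latent growth mixture model (LGMM)
replaces α with class-specific means α_k under mixing proportions π_k
(Ψ, Θ shared) and is fitted by EM with multistart and quasi-Newton
refinement; class enumeration reports information criteria, relative
entropy, a Lo–Mendell–Rubin-style approximate test and the parametric
bootstrap likelihood ratio test (BLRT), flagging solutions with classes
under 3% of the sample.

The full pipeline is covered: text cleaning (originality, hashtags,
mentions, share placeholders, URLs, emoji, digits/Latin), active-user and
phase-completeness filters, seed-word lexicon expansion through
word-embedding neighbourhoods with screening and zero-feature pruning,
TF-IDF features with grid-searched radial-kernel SVMs (one per
dimension), aggregation with descriptives and repeated-measures ANOVA,
and both growth models. A synthetic-data module generates corpora,
embeddings and trajectory matrices with known ground truth so every
stage is testable offline; see the methods vignette
(`vignettes/swb-trajectories.Rmd`) for the model details and design
choices.

## Worked example

Simulate 1,322 users from a two-class linear growth population — a small
high-growth class (6.3%, intercept 14.49, slope 2.88) and a large
normal-growth class (93.7%, intercept 2.60, slope 0.57) — and refit the
two-class mixture:

```r
library(swbgrowth)

spec <- growth_spec(
  class_labels = c("high_growth", "normal_growth"),
  mixing = c(0.063, 0.937),
  intercept_mean = c(14.49, 2.60), slope_mean = c(2.88, 0.57),
  intercept_sd = 1.5, slope_sd = 0.3, intercept_slope_corr = 0.3,
  residual_sd = c(1, 1, 1))
sim <- simulate_trajectories(spec, 1322, seed = 1)
fit <- fit_lgmm(sim$y, K = 2, n_starts = 50, seed = 2)
fit
#> LGMM: K = 2, n = 1322, q = 11, logL = -7511.016
#>   class mixing intercept  slope modal_share
#>  class1 0.0681   14.2312 2.9842      0.0681
#>  class2 0.9319    2.5535 0.5798      0.9319
#> entropy = 1; AIC = 15044.03, BIC = 15101.09, aBIC = 15066.15
```

Classes are sorted by slope mean, descending: `class1` is the recovered
high-growth group (share 6.8% vs the planted 6.3%, slope 2.98 vs 2.88)
and `class2` the normal-growth group (slope 0.58 vs 0.57). With this
separation the posterior classification is essentially crisp — relative
entropy 1, and the average posterior probability matrix is the identity
to three decimals:

```r
round(avg_posterior_matrix(fit$posterior, fit$assignment), 3)
#>        class1 class2
#> class1      1      0
#> class2      0      1
```

An end-to-end run on synthetic posts — cleaning, lexicon building,
classification, scoring, LGCM and class enumeration, with a manifest of
seeds, filter counts and artifact hashes — is one call:

```r
cfg <- default_pipeline_config()
cfg$out_dir <- "swb_run"
run_pipeline(cfg)
writeLines(make_report("swb_run"))
```

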