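---
title: "Measuring and modelling subjective well-being trajectories from social-media posts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling subjective well-being trajectories from social-media posts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swbgrowth)
```

## The problem

During an acute public-health emergency, repeated questionnaire waves are
hard to field, and pre-crisis baselines cannot be measured retroactively.
Social-media post streams offer an alternative: if individual posts can be
classified as expressing high or low life satisfaction (LS), positive
affect (PA) and negative affect (NA), then a per-user, per-period count
score

\[
\mathrm{SWB} = \#\{\text{high-LS posts}\} + \#\{\text{high-PA posts}\}
             - \#\{\text{high-NA posts}\}
\]

tracks subjective well-being (SWB) over calendar phases of the crisis, and
latent growth models describe how it develops and whether distinct
trajectory groups exist.

`swbgrowth` implements that pipeline end to end — text cleaning and
filtering, lexicon construction, TF-IDF + SVM classification, score
aggregation, latent growth curve models (LGCM) and latent growth mixture
models (LGMM) — together with a synthetic-data module that generates
corpora and trajectories with known ground truth, so that every stage can
be validated offline without access to any platform's crawl.

## Preprocessing and filters

Raw posts pass through an ordered cleaning chain: non-original posts
(reposts) are dropped; topic hashtags (`#...#`), `@`-mentions, share
placeholders, URLs, emoticons/emoji (Unicode blocks plus bracketed
platform codes such as `[笑]`) are stripped; finally Arabic digits and
Latin characters are removed. A post that is non-original or empty after
cleaning maps to a drop marker. Cleaning is total and idempotent.

Two user filters are deliberately different in strictness:

* **active users** — more than 30 posts (*strictly* greater) and a
  personal (non-institutional) account;
* **phase completeness** — at least one original post in *every* phase and
  *at least* 30 posts in total across the phases (non-strict).

Phases are half-open calendar windows `[start, end)`; a timestamp exactly
on a shared boundary belongs to the later phase. The shipped default
scheme covers the early COVID-19 period in China in four phases
(pre-outbreak, outbreak, gradual containment, initial victory), anchored
at 2019-12-01, 2019-12-27 and late April 2020; the two interior boundaries
(2020-01-23, the Wuhan lockdown, and 2020-03-18) are documented
assumptions, and every function accepts a custom `phase_scheme()`. The
tests never assert these dates.

Tokenization is pluggable: production Chinese text needs a word-segmentation
engine (any function mapping a string to a token vector can be supplied);
the whitespace tokenizer used for synthetic corpora is exact there because
the generator emits space-separated tokens.

## Lexicon construction

The three-dimension lexicon starts from seed words, is expanded through
word-embedding neighbourhoods (for each seed, its `top_k` nearest words by
cosine with similarity at least `min_cos`), passes an accept/reject
screening step that stands in for manual curation, and is finally pruned
of every word with zero document frequency in the working corpus, so that
every remaining word can produce a nonzero TF-IDF feature.

Defaults: `top_k = 10`, `min_cos = 0.5`. Neither value is prescribed by
the study this design follows; 0.5 is a common neutral threshold for
cosine relatedness and 10 keeps expansion conservative. Cosine ties break
lexicographically; a word nominated by several dimensions goes to the
dimension with the highest best-seed cosine. Both rules are arbitrary but
deterministic, which we value more than any particular choice.

## Classification and scoring

Documents are featurized by TF-IDF over the lexicon vocabulary with the
smoothed inverse document frequency
\(\mathrm{idf}(t) = \ln\big((1+N)/(1+df_t)\big) + 1\) and L2-normalized
rows (empty documents stay zero vectors and are labelled "low" by
convention). One binary radial-kernel SVM per dimension is tuned by
exhaustive grid search (defaults \(C \in \{0.1, 1, 10, 100\}\),
\(\gamma \in \{0.01, 0.1, 1\}\)) maximizing mean F1 over stratified
5-fold cross-validation; ties prefer the smaller \(C\), then the smaller
\(\gamma\). Counts of predicted high posts per user per phase give the
SWB score; descriptives use the sample SD, and the phase comparison is a
one-way repeated-measures ANOVA with Bonferroni-corrected paired
comparisons (phases are within-user measurements; a between-groups variant
is available by flag since the published analysis does not state which was
used).

## Growth models

Waves are the post-outbreak phases (phases 2–4) with time codes 0, 1, 2,
so the intercept is the outbreak-phase level. The **LGCM** is the linear
latent growth model \(y_i = \Lambda\eta_i + \epsilon_i\),
\(\eta_i \sim N(\alpha, \Psi)\), \(\epsilon_i \sim N(0, \Theta)\) with
diagonal \(\Theta\), fitted by maximizing the normal log-likelihood with a
quasi-Newton optimizer on a Cholesky/log parameterization (so \(\Psi\) and
\(\Theta\) stay positive semi-definite; boundary estimates are Heywood
cases, clamped near zero with a warning). Residual variances are free per
wave by default (`residuals = "equal"` restricts them), giving q = 8 free
parameters unconditionally; published tables in this literature sometimes
count q = 9 for the same-looking model, so parameter counts are always
reported alongside the criteria. The model chi-square is
\((n-1)F_{ML}\); CFI/TLI use the independence baseline (free means and
variances), RMSEA is \(\sqrt{\max(\chi^2-df,0)/(df\,(n-1))}\), SRMR is the
root mean square of standardized residual moments (covariances and means),
and AIC/BIC/aBIC follow `information_criteria()` with the aBIC penalty
\(\ln((n+2)/24)\). TLI is truncated at 1 for reporting. Standard errors
come from the numerical information matrix (Hessian of the negative
log-likelihood at the optimum); no robust correction is applied. A
time-invariant covariate (gender, coded 0/1) enters by regressing both
growth factors on it.

The **LGMM** is a finite mixture of these models with class-specific
growth-factor means and \(\Psi, \Theta\) shared across classes (q = 11 for
two classes: 4 means + 1 mixing + 3 + 3). Estimation is EM: the E-step
computes class posteriors and the conditional moments of the growth
factors; the M-step is closed form throughout, so the observed
log-likelihood is nondecreasing — asserted at every iteration. Because EM
converges linearly and can crawl on the factor/residual variance split,
fitting uses the standard two-stage scheme: every random start (k-means
initialization plus random perturbations; 50 starts by default) gets a
short EM run, the best is pursued to convergence
(\(|\Delta \log L| < 10^{-6}\) or 500 iterations), and a quasi-Newton pass
on the marginal likelihood closes the final fraction of a log-likelihood
unit. Classes are reported sorted by slope mean descending, which resolves
label switching deterministically. Empty classes (posterior mass below one
user) abandon the start; collapsed variances are floored at `1e-8` with a
warning.

Class enumeration reports, per K: log-likelihood, AIC/BIC/aBIC, relative
entropy \(1 - \sum_{ik}(-p_{ik}\ln p_{ik})/(n\ln K)\), the
Lo–Mendell–Rubin-style approximate test, and the parametric bootstrap
likelihood ratio test (BLRT) with p-value \((1 + \#\{LR_b \ge
LR_{obs}\})/(B+1)\). Solutions whose smallest class holds under 3% of the
sample are flagged. The selection rule takes the largest K with a
significant bootstrap (or, failing that, LMR) test, no small-class flag,
and a BIC no worse than the previous solution; the full table is always
returned because enumeration decisions belong to the analyst. The exact
LMR variant used by commercial SEM software is not public; our
implementation scales the LR statistic by \(1 + 1/(d \ln n)\) and refers
it to \(\chi^2_d\), is labelled approximate, and the BLRT is the
authoritative test.

## The synthetic-data module

The generator is the package's ground truth. Trajectories follow exactly
the mixture model above. Corpora are generated phase by phase: each user's
probability of emitting a high-LS/PA/NA post is a logistic function of
their standardized latent level (increasing for LS and PA, decreasing for
NA). No distributional statement for post emission exists in the study
this package mirrors; the logistic link is our construction — the minimal
monotone map from a continuous latent level to a Bernoulli probability —
and is flagged as such. High posts embed 1 + Poisson planted words from
the matching lexicon dimension; low posts contain stray planted words at a
small rate (0.05), all posts carry background words, and optional junk
(URLs, mentions, digits) plus non-original posts exercise the cleaning
rules. Vocabulary is synthesized as short CJK strings so that tokens
survive the Latin/digit stripping rules. Embeddings place each dimension's
words around orthogonal centroids with isotropic background words, giving
the separation structure that seed-word expansion assumes.

What the generator does **not** emulate: real Chinese morphology and
segmentation ambiguity, topic drift, user-level vocabulary idiosyncrasy,
bursty posting, and label noise from imperfect questionnaire criteria.
A classifier F1 near 1 on the planted corpus therefore demonstrates the
pipeline's correctness, not the accuracy achievable on real labelled
posts, which published work places near 0.68–0.69.

## Validation scale and reproducibility

The test suite validates parameter recovery at the study's scale
(n = 1322 users, 3 waves, 10 seeded replicates) for both the LGCM
(intercept mean, slope mean, intercept–slope correlation) and the
two-class LGMM (majority-class share within ±2 percentage points, class
slope means within ±0.2/±0.1). Estimator properties are checked by
simulation at smaller sizes chosen for statistical validity per unit of
computation: the bootstrap LRT's type-I error with 20 replicates of
B = 99 at n = 60 (observed-data and bootstrap fits deliberately use the
same estimation effort, since an asymmetric effort biases the observed LR
upward), and the repeated-measures ANOVA's size with 200 null datasets of
20 users. Every random draw flows from an explicit seed; `run_pipeline()`
derives per-stage substreams from its single configured seed and records
MD5 hashes of all artifacts in a manifest, so a rerun with the same
configuration is verifiably identical.

## A small worked run

```{r pipeline, eval = FALSE}
cfg <- default_pipeline_config()
cfg$out_dir <- tempfile("swb_run")
cfg$simulate$n_users <- 100
run_pipeline(cfg)
writeLines(make_report(cfg$out_dir))
```

## Known limitations

* Complete cases only: the phase filters enforce completeness, so no
  FIML-style missing-data support is provided.
* Linear growth only; no quadratic or piecewise shapes, and no covariates
  on class membership.
* The LMR approximation is heuristic; rely on the BLRT for inference.
* Counts are modelled as continuous outcomes in the growth models, as in
  the analysis this package mirrors; an optional log1p transform of the
  score is available at aggregation time via the outcome column.
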