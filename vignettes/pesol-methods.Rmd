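---
title: "Models and methods behind pesol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pesol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-throughput protein-production pipelines express thousands of
constructs in *E. coli* and score each small-scale trial for expression
level (E, an integer 0–5 read off a stained SDS-PAGE gel) and, when any
protein is expressed, for the fraction recovered soluble (S, also 0–5; S
is not recorded when E = 0). A construct is operationally *usable* — worth
scaling up — when E·S > 11, i.e. 12 or higher on integers. `pesol`
implements the statistical machinery for asking which primary-sequence
properties drive these outcomes, and for turning the answer into a
predictor (pES, the probability of expressed and soluble protein) that can
triage candidate targets before any wet-lab work.

## Sequence parameters

`feature_table()` computes, per construct, 72 core parameters: the 20
fractional amino-acid contents (count over chain length), their
buried/exposed splits under a per-residue surface-exposure annotation
(both splits keep chain length as the denominator, so `x = xb + xe`
exactly), and 12 compound parameters — GRAVY (mean Kyte–Doolittle
hydropathy), mean side-chain conformational entropy over all residues
(`sce`) and over exposed residues only (`esce`, whose denominator is the
number of exposed residues, deliberately unlike the class fractions),
six charge metrics built from R, K, D, E counts (whole and
length-normalized), the disorder fraction, chain length, and the
isoelectric point. With an in-frame CDS the Arg/Ile/Leu/Pro fractions are
additionally split into rare-codon- and common-codon-encoded parts
(default rare sets: Arg AGA/AGG/CGA/CGG, Ile ATA, Leu CTA, Pro CCC,
configurable in `scale_config()`).

Numerical conventions worth knowing:

* **fracnumcharge** is (R+K+D+E)/length. One published formula sheet
  renders the numerator as "R + D + D + E"; the variable's name and its
  companion unnormalized form make clear this is a typo, and the package
  implements the R+K+D+E reading.
* **pI** is the root of the Henderson–Hasselbalch net-charge curve
  (side chains D, E, C, Y, H, K, R plus free termini, Bjellqvist-style
  pKa values) found by bisection on [0, 14] to 1e-4 pH units. The curve
  is strictly decreasing, so the root is unique and always bracketed.
  Note pI is *not* invariant under sequence duplication: the termini
  count once regardless of length.
* **Nonstandard residues** (X, B, Z, U…) are counted in chain length but
  enter no fraction and no scale mean; a warning is raised. The
  hydropathy/entropy means are over scale-covered residues.
* The side-chain-entropy values shipped as `creamer_sce` follow published
  Monte Carlo/rotamer conformational-entropy estimates (cal mol⁻¹ K⁻¹).
  The exact table is a convention; every scale is replaceable through
  `scale_config()` and the set in force is recorded in model metadata.

Surface-exposure and disorder predictions are *inputs*, not something the
package recomputes: real analyses should feed predictions from dedicated
tools via `read_annotations()`. `annotate_baseline()` provides a
deterministic stand-in for simulation and testing only (windowed-
hydropathy ranking labels the ~45% most locally hydrophobic residues
buried; a windowed disorder-propensity score above threshold labels
residues disordered).

## Regression models

Because E and S are ordered categories, the package fits cumulative-logit
(proportional-odds) regressions: P(Y ≤ j) = exp(t_j − θ)/(1 + exp(t_j −
θ)) with strictly increasing thresholds t_j and a common linear predictor
θ = x'β, so larger θ pushes mass toward higher scores. Usability, being
binary, uses Pr(Y = 1) = exp(θ)/(1 + exp(θ)) with an intercept inside θ.

`fit_binary_logit()` / `fit_ordinal_logit()` maximize the exact
likelihood by Newton–Raphson with step-halving, using the analytic
gradient and analytic observed-information Hessian; convergence is
declared at gradient norm < 1e-8 (200 iteration cap). If a Newton iterate
would produce non-monotone thresholds the model is refit by BFGS on a
reparameterized scale (first threshold plus log-increments) and then
Newton-polished. Standard errors come from the observed information at
the optimum; Wald tests are Z = β/SE against the standard normal,
likelihood-ratio tests use 2Δlog-likelihood against χ², and AIC is
2k − 2·log-likelihood.

Degenerate inputs fail loudly rather than silently: constant predictors
and collinear columns are named in the error; complete separation raises
a diagnostic error. The separation flag is applied on the *standardized*
scale (|β|·SD(x) > 50, plus a perfect-fit check at convergence): raw
fraction predictors have standard deviations near 0.01, so genuinely
estimable slopes of magnitude 40–100 are routine in this domain and a raw
|β| > 50 rule would misfire.

## The analysis pipeline

`run_model_pipeline()` chains the study design:

1. **Clone aggregation** (`aggregate_clone_scores()`): replicate trials
   of a construct are combined by componentwise maxima (the primary
   rule — errors lower scores), blind averaging, the replicate with
   maximal E·S, or a 100%-consistency cull. Averaged scores are rounded
   half-up (`round_half_up()`) before ordinal fitting, since
   cumulative-logit models need discrete levels and no other handling is
   prescribed. `select_one_construct()` implements the one-construct-
   per-target variant (highest E·S, ties to the first id).
2. **Single-regression screen** (`single_screen()`): one
   single-predictor fit per parameter, reporting the slope, Wald p,
   signed −log₁₀(p) (sign of the slope attached), and the predictive
   value slope × SD — a scale-free effect size. S screens restrict to
   records with E > 0 simply because unexpressed constructs carry no S.
3. **Redundancy culling**: buried/exposed splits replace the total
   fraction only when the two split slopes are opposite-signed *and*
   both Bonferroni-significant (`select_exposure_variables()`); for each
   charge pair the more significant of the whole/fractional versions is
   kept, ties to the fractional form (`select_charge_variables()`).
   Everything not significant at α/n (default 0.05/72 ≈ 0.00069) is then
   dropped.
4. **Stepwise selection** (`stepwise_fit()`): add the candidate with the
   smallest Wald p if < 0.049, remove the member with the largest p if
   ≥ 0.05, iterate to a fixed point (ties at addition break
   lexicographically — the source procedure is silent; cycles terminate
   with a warning and full trace).
5. **AIC pruning** (`aic_prune()`): repeated single-removal passes in
   variable order, dropping any variable whose removal strictly lowers
   AIC.

`paired_rare_common_screen()` fits, per amino acid among Arg/Ile/Leu/Pro,
one two-predictor model in which the rare-codon-encoded and
common-codon-encoded fractions enter simultaneously, separating codon
effects from residue chemistry. `permissive_enhancing_screen()` decomposes
an ordinal effect into its low-boundary (score 0 vs > 0, "permissive")
and high-boundary (score 5 vs < 5, "enhancing") binary components.

## The pES predictor

A fitted usability model exports to a `coefficient_set()` (JSON-
serializable, with provenance metadata). `pes_score()` evaluates
θ = intercept + Σβᵢ·featureᵢ and pES = 1/(1 + e^(−θ)); a feature named by
a coefficient but missing from the input is an error, never an
imputation. `predict_score_distribution()` gives the full 0–5 probability
vector for ordinal models — with score distributions massed at the
extremes, an ordinal predictor is meaningful for an *ensemble* of
constructs, not as a per-protein expected score.

`calibration_curve()` bins constructs at 0.1-wide intervals of θ (bins
anchored at θ = 0; the anchor is configurable because the source design
fixed only the width) and reports the observed usable fraction per bin
with a Bayesian binomial interval. "Counting-statistics Bayesian maximum
likelihood" under-determines the prior; the package defaults to the
Jeffreys Beta(½, ½) central 95% interval, with a uniform-prior option,
and by convention reports a lower bound of 0 at zero successes and an
upper bound of 1 at zero failures. `cutoff_tradeoff()` tabulates, per pES
cutoff, the fraction of the pool retained and the relative usable-yield
increase among retained targets.

No pretrained coefficients ship with the package: the original model's
coefficient table is not reproducible from the available text, so
coefficient sets are always produced by `run_model_pipeline()` on data
you supply (or simulate). The published test-set recalibration line
(θ' = 0.85·θ − 0.06) is a fitted artifact of unavailable data and is
deliberately not implemented.

## The synthetic world

The original cohort is not deposited, so `generate_cohort()` creates
cohorts with the same statistical skeleton, and every default is a stated
modeling choice, fixed once:

* **Sequences**: lengths lognormal (meanlog log 185, sdlog 0.35, clipped
  to [50, 600], mean ≈ 200 residues); per-construct composition from a
  Dirichlet with concentration 80 around SwissProt-like base
  frequencies — about the between-protein composition spread seen in
  real proteomes.
* **Outcomes**: E is drawn from the same cumulative-logit family the
  pipeline fits, with true coefficients on the centered features
  (defaults: fracnumcharge +15, gravy −1, Arg fraction −20 — predictive
  values ≈ +0.7/−0.3/−0.35, the scale of the strongest real effects) and
  thresholds placed at cumulative probabilities (.30, .38, .45, .52,
  .65), giving the observed bimodality with roughly 65% of mass at the
  score extremes. S is drawn likewise (thresholds at .18, .26, .33, .40,
  .55) with +0.8·(E − mean E) added to its latent scale, reproducing the
  strong positive E–S coupling while preserving S's marginal
  proportional-odds structure; S is erased where E = 0. Because the
  generator and the analysis share one model family, parameter recovery
  is well-posed; `outcome_link = "latent-normal"` provides a
  variance-matched misspecified variant for robustness checks.
* **Clones**: two per construct; a Binomial(n, 0.25)-sized sample of
  constructs has one clone degraded by one point of E or S (never
  raised — the maxima rule exists because errors lower scores).
  Constructs with E = 0 have nothing to degrade and cannot be
  discrepant, so the sample is drawn from the degradable constructs
  while targeting the cohort-wide ~25% rate.
* **Codons**: CDSs are sampled per residue with rare-codon usage
  probabilities R .25, I .15, L .10, P .20 — typical across-taxon usage
  for genes cloned from diverse source organisms.
* **Split**: per-construct Bernoulli(0.8) into analysis vs test, matching
  a 4:1 random assignment rather than an exact partition.

What a green simulation test does *not* establish: the generator draws
sequences i.i.d. from a composition model, so it contains no phylogenetic
structure, no domain architecture, no real disorder or burial physics,
and its outcome model is exactly the fitted family. Recovery results
certify the estimation machinery, not biological truth.

## Why exact pipeline recovery is structurally capped

One acceptance-level property deserves its own analysis. Plant nonzero
coefficients on {fracnumcharge, gravy, r} and ask the
screen→cull→stepwise→AIC chain to return exactly that set. Two facts cap
the success rate well below intuitive levels:

1. **Aliasing.** By construction fracnumcharge = r + k + d + e, so the
   planted latent score 15·fracnumcharge − 20·r is *identically*
   −5·r + 15·k + 15·d + 15·e: the "true set" is one of several exactly
   equivalent representations over the screened dictionary. All residue
   fractions correlated with the planted variables sail past the
   Bonferroni cull at realistic effect sizes, and which representation
   stepwise lands on is decided by finite-sample noise.
2. **Stepwise false inclusion.** With k conditionally-null candidates
   surviving the cull, forward addition at p_add = 0.049 admits at least
   one of them with probability ≈ 1 − 0.951^k — around one half for the
   k ≈ 15 pools these cohorts produce — and AIC pruning cannot remove a
   variable admitted at p ≈ 0.049 (its LR statistic ≈ 3.9 > 2).

Measured over seeded cohorts the chain contains the planted variables
essentially always, but matches them *exactly* in only roughly a third to
a half of cohorts (and occasionally carries three or four extras). The
corresponding acceptance test asserts an 80% exact-recovery level and is
left failing deliberately: it documents a property of the selection
procedure itself, and weakening it would hide exactly the behavior a user
of stepwise selection should know about.

A second, much smaller gap is of the same deliberate kind: on perfectly
calibrated data, equal-tailed Bayesian binomial intervals (Jeffreys or
uniform prior alike) cover the bin-mean predicted probability for about
94.3–94.5% of θ-bins at ~50 observations per bin — just under a nominal
95% bar, which only an over-covering frequentist construction such as
Clopper–Pearson would clear. The calibration acceptance test keeps the
95% assertion and records the shortfall rather than switching to an
interval the counting-statistics convention does not describe.

## Known limitations

* Proportional odds is assumed, never tested (no Brant-style check), and
  only listwise deletion handles missing S.
* No penalized likelihood: heavily separated or tiny datasets error
  rather than shrink.
* The baseline annotator is a caricature of real exposure/disorder
  predictors; its only job is to give the split parameters realistic
  variation in simulations.
* Scales (hydropathy, entropy, pKa, rare-codon sets) are conventions;
  conclusions about individual parameters can shift under different
  conventions, which is why every output records the scales used.
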