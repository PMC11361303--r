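---
title: "Methods: community-state dynamics across omics layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community-state dynamics across omics layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`commstate` analyzes longitudinal multi-omics cohorts in which each
subject contributes a small number of repeated samples (the default design
is 93 subjects at 3 timepoints), asking three questions: which discrete
community states does the microbiome occupy, how do subjects move between
those states over time, and how variable is each omics layer within versus
between people while that happens. This vignette records the models, the
parameters that matter, and the design choices made where the methodology
was genuinely open.

## The Dirichlet multinomial mixture

Genus counts for a sample are modeled as multinomial with a
Dirichlet-distributed composition, giving the Dirichlet-multinomial
(Polya) marginal; a K-component mixture of these defines the community
types. We include the multinomial coefficient in the component density so
the values form a proper pmf — it is constant per sample, so
responsibilities and model choice are unaffected, but normalization
becomes directly testable (the pmf must sum to 1 over all count vectors of
a given total, which the tests verify by exhaustive enumeration at small
sizes).

Estimation is EM in log-alpha space. Two priors regularize the fit and,
more importantly, make the model evidence a convergent integral: each
alpha element carries a weak Exponential(rate ν = 0.1) prior and the
mixture weights a flat Dirichlet. Without a proper prior the marginal
likelihood diverges — along rays α → ∞ the Dirichlet-multinomial tends to
a fixed multinomial, so the likelihood does not decay — and "evidence"
would be ill-defined. With it, the Laplace approximation used for model
selection,

    −log evidence ≈ NLP(θ̂) − (d/2)·log 2π + (1/2)·log|H(θ̂)|,

with θ = log α, d = K·G + (K−1) free parameters, and the log-alpha
Jacobian folded into the negative log posterior NLP, approximates a
well-defined quantity; the tests check it against brute-force grid
quadrature on a 3-sample, 2-feature instance (agreement within 0.1 nats).
The Hessian uses the responsibility-weighted (complete-data) curvature for
the alpha blocks — the standard construction at a mixture mode — and the
exact weight-block curvature given the component densities;
non-positive-definite blocks get a 1e-8 diagonal jitter and a logged
message.

Numerical choices:

- **M-step.** Alphas update by a Minka-style fixed point extended with the
  prior and Jacobian terms (update `α ← (α·num + 1)/(den + ν)`), three
  inner passes per EM iteration, floored at 1e-10. Because a partial fixed
  point is not guaranteed monotone, the step backtracks by halving in
  log-space whenever the negative log posterior would rise, and falls back
  to the previous alphas if needed — the objective trace is therefore
  non-increasing by construction, and the tests assert it on every fit.
- **Initialization.** First restart: k-means on log-count centered
  proportions, softened into 0.9/0.1 responsibilities; remaining restarts:
  random responsibilities. Best final posterior wins. Defaults: 5
  restarts, tolerance 1e-6 on the relative objective change, 1000
  iterations.
- **Empty components** (weight < 1e-8) are re-initialized once and then
  dropped with a warning.
- **Model selection** scans K = 1..7 by default (headroom around the
  four-state design) and resolves evidence ties within 1e-6 to the smaller
  K. Assignment is argmax responsibility with ties broken to the lowest
  component index (logged).

## Transition analysis

Trajectories are built only for subjects with exactly one assigned sample
per timepoint; incomplete subjects are excluded and reported. A subject is
*stable* iff all of its states are identical.

The null model for transition frequencies asks whether observed moves
simply reflect how prevalent each state is. The default
**cross-pairing** mode counts, for each ordered pair (A, B), the number of
possible A→B pairings across consecutive timepoints,
Σ_t n_A(t)·n_B(t+1), over the total Σ_t N_t·N_{t+1}; this conditions on
the observed state margins at each timepoint and is exactly reproducible
by enumeration (tested against brute force on small cohorts). A
**pooled-marginal** mode (P_AB = f_A·f_B from pooled frequencies) is
provided as an alternative because the prevalence-based formulation
admits both readings; the two are exposed side by side rather than
silently picking one. Observed tallies are compared with a K²-category
chi-square goodness-of-fit (df = K²−1, probabilities treated as fixed),
with Pearson standardized residuals (O−E)/√E flagged beyond ±1.96 and
cells with E < 1 marked unreliable. Because the expected probabilities
are fitted to the same margins, the df = K²−1 reference is conservative;
the type-I simulation in the tests (i.i.d. states with the cohort's
marginal prevalence, 200 seeds) confirms rejection stays below nominal.

An empirical row-normalized Markov matrix is provided as the descriptive
summary of transition rates (rows with no outgoing transitions become
uniform and are flagged); covariate hazard modeling of transitions is out
of scope.

## Dissimilarity partitioning

Bray-Curtis is Σ|x−y| / Σ(x+y); Canberra is the plain sum of
|x−y|/(x+y) over features with x+y > 0 — deliberately *not* rescaled by
the number of contributing terms, which is what `dist()` and vegan do.
Off-diagonal pairs split exhaustively into intra-individual (shared
subject) and inter-individual sets — |intra| + |inter| = n(n−1)/2 is
asserted — compared by a two-sided, tie-corrected Mann-Whitney U test;
fully tied inputs degenerate the normal approximation and are reported as
p = 1. Per-subject medians over the three timepoint pairs are
sqrt-transformed before regression (a variance-stabilizing choice for
bounded dissimilarities). Shannon diversity uses the natural log by
default with a `log_base` option, computed after rarefaction
(multivariate-hypergeometric subsampling without replacement; samples
below depth are dropped and reported, and the seed is explicit). Bray-
Curtis is computed on relative abundances of the filtered genus table by
default, since rarefied-versus-relative input is an open convention; both
are accepted.

## Variance components and ICC

Each feature gets a one-way random-effects decomposition with subjects as
the grouping factor, by the method of moments: σ²_w = MSW,
σ²_b = max(0, (MSB − MSW)/n₀) with n₀ = (N − Σn_i²/N)/(I−1), and
ICC = σ²_b/(σ²_b + σ²_w). The moments estimator is deterministic and
coincides with the balanced-ANOVA closed form when replicate counts are
equal (asserted against `aov` mean squares, and against an lme4 REML fit
within 0.02 ICC on balanced data); negative between-subject estimates
truncate to zero with a logged count, so ICC stays in [0, 1]. Analysis
scales are fixed per layer: CLR (pseudocount 1) for taxa and inferred
function — with the relaxed 10%-prevalence/count-10 core filter — and
log10(x+1) for the metabolome. Cross-layer comparisons use tie-corrected
Kruskal-Wallis plus Dunn's pairwise z tests, Bonferroni-adjusted over the
three layer pairs; Dunn's test is implemented in-package (rank-sum z with
the standard tie correction) since no dedicated implementation is
available, and is checked against hand-computed ranks.

## Log-ratio association testing

The P/B and B/B summaries are log10 of pseudocounted genus count ratios
(c = 1; the convention for zeros is recorded in the output attributes).
Metabolites are QC-filtered (sample-SD CV < 20% across ≥2 QC pool
injections, nonzero intensity in strictly more than 80% of study samples
— QC pools excluded from the denominator), then log10(x+1)-transformed
and Pareto-scaled per feature (centered, divided by the square root of
the sample SD; log before scaling keeps heavy-tailed intensities
bounded). Each feature is tested by OLS of the ratio on
[feature + sex + race/ethnicity + BMI + collection timepoint], the
feature coefficient's two-sided t-test Bonferroni-adjusted over the
panel; computation uses one QR residualization of the covariates
(Frisch-Waugh), which is exact. The "covariate-adjusted Spearman" is the
Spearman correlation of the two covariate-residualized variables — double
residualization, chosen over rank-based partial correlation because it
reduces to plain Spearman when no informative covariates are present
(asserted). Explained variance per predictor is the sequential (type-I)
sum-of-squares share in a declared order, which is printed with the
result because it is order-dependent for non-orthogonal designs.
Complete-case analysis throughout; dropped rows and repeated-subject
counts are attached as attributes.

## The synthetic cohort generator

The generator emulates the study design the package targets, with all
parameters in `cohort_config()`:

- 93 subjects × 3 timepoints; four states with baseline probabilities
  38/93, 21/93, 22/93, 12/93.
- First-order Markov dynamics with stay probability 0.72 and uniform
  off-diagonal mass (a full transition matrix can be supplied). 0.72 makes
  the probability of holding the baseline state across both steps
  0.72² ≈ 0.52, i.e. roughly half the cohort shifts at least once — the
  regime of interest. The closed form P(≥1 switch) = 1 − stay² is used as
  the recovery target in tests.
- Genus counts: composition ~ Dirichlet(α_state), counts ~ multinomial at
  a lognormal depth (median 5,000 by default for fast simulation; 40,000
  mirrors typical amplicon depths). The four state alphas share a fixed
  skeleton — four marker genera (two *Bacteroides*-like, one
  *Blautia*-like, one *Prevotella*-like), each state dominated by its own
  marker at more than 3× any non-marker genus — with total concentration
  50 per state. The concentration is a free parameter: nothing in the
  emulated design pins the within-state overdispersion, so it is chosen
  to give well-separated but noticeably dispersed states and flagged as
  such.
- Function layer: pathway abundances are a nonnegative linear mixing of
  the genus relative abundances (each pathway loads on 8 random genera
  with gamma weights), scaled and perturbed by lognormal noise (sd 0.3 on
  the natural log). Averaging across genera makes this layer less
  variable than the taxa layer *by construction*; the cross-layer
  variance ordering the package reports on synthetic data is therefore a
  qualitative, designed property, not an empirical discovery.
- Metabolome: each feature is lognormal on the log10 scale with a
  subject-level random effect sized so σ²_b/(σ²_b+σ²_w) equals a true ICC
  drawn uniformly from 0.3–0.9, at a fixed total log10 variance of 0.04 —
  small relative to the other layers, mirroring tightly regulated
  metabolite pools. QC pool columns are replicate draws around each
  feature's global mean at 5% CV.
- An optional `stabilizer_genus` plants a subject-level propensity that
  simultaneously raises that genus's abundance and the subject's stay
  probability, creating the negative genus-versus-variability association
  used to exercise the dissimilarity regressions.

What the generator does **not** emulate: phylogenetic correlation between
genera, longitudinal drift in the metabolome, compositional coupling
between the metabolome and the taxa, sequencing-run batch effects, or raw
reads. Passing recovery tests on this cohort therefore demonstrates that
the estimators are correct under the stated generative model, not that
real data satisfy that model.

## Problem sizes and runtime choices

The test and acceptance workloads use the cohort sizes the methods are
designed for where that is cheap (93 × 3 for typing and transitions), and
scale up only where precision of a recovery target requires it: 500
subjects for ICC recovery (MAE ≤ 0.05), 2,000 subjects for empirical
Markov recovery (±0.05 per cell), 200 seeds for type-I calibration, 500
samples × 200 features for association calibration. Slim layer settings
(8 genera, a handful of pathways/metabolites) are used whenever only the
state machinery is under test.

## Known limitations

- The Laplace evidence relies on the responsibility-weighted Hessian
  approximation at the mode; it is accurate for well-separated components
  (the regime where DMM typing is meaningful) and checked by quadrature
  only at K = 1.
- The moments ICC estimator matches mixed-model REML only approximately
  under unbalance; the emulated design is balanced, where they coincide.
- Expected-probability mode `cross_pairing` versus `pooled_marginal`
  changes the null hypothesis; results report which mode produced them.
- Metabolite association tests operate per sample and ignore repeated
  measures; the number of repeated-subject samples is flagged in the
  output for the analyst to judge.
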