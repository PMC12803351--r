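---
title: "Methods: from transporter repertoires to diet-microbiome association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from transporter repertoires to diet-microbiome association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sugartrait)
```

`sugartrait` implements a genotype-to-ecology inference chain for gut
bacteria: it asks whether the repertoire of sugar transport systems encoded
in a genome — in particular sugar ABC (ATP-binding cassette) importers —
predicts how the corresponding taxa respond when dietary sugar increases.
This vignette documents the models and procedures, the conventions adopted
where more than one defensible choice existed, and what the synthetic-data
tests do and do not establish about real data.

## 1. The keyword census

Annotation screens trade recall for transparency: rather than HMM or
alignment-based annotation, the census counts feature products that satisfy
a *gate-then-subtype* rule. A product must contain every gate term
("sugar" and "transporter", case-insensitive substrings) before subtype
tokens are consulted:

* **ABC**: `ABC`, `ATP-binding cassette`
* **PTS**: `PTS`, `phosphotransferase`
* **MFS**: `MFS`, `major facilitator`

Conventions, each of which materially affects counts:

* **Token dialect.** All-uppercase abbreviation tokens are matched
  case-sensitively on word boundaries, so `abc` buried inside another word
  (or a lowercase gene symbol such as `abcA` appearing in a product string)
  never matches; multi-word expansions are case-insensitive substrings.
* **One increment per feature per subtype.** The counts approximate gene
  counts, so a product mentioning `ABC` twice still counts once. A product
  matching two subtypes increments both (hybrid annotations are rare but
  real). A per-occurrence mode (`per_occurrence = TRUE`) is available for
  sensitivity analysis.
* **Deduplication.** Annotation files frequently repeat proteins; features
  are collapsed by `protein_id` when present, else by
  `(genome_id, feature_id)`.
* **Specificity.** Transporter categories are *not* resolved by sugar
  specificity; "sugar" in the product is the only substrate evidence used.

Glycolytic enzymes are screened by configurable search-term lists. The
default panel covers nine enzymes across the Embden-Meyerhof-Parnas
(hexokinase equivalents, 6-phosphofructokinase, pyruvate kinase), pentose
phosphate (glucose-6-phosphate dehydrogenase, 6-phosphogluconate
dehydrogenase, ribose-5-phosphate isomerase) and Entner-Doudoroff
(glucose-6-phosphate dehydrogenase, phosphogluconate dehydratase, KDPG
aldolase) pathways, plus phosphoglucomutase for the mixed-model predictors.
Hexokinase carries the bacterial alternates "sugar kinase", "glucokinase"
and "ROK family kinase", since few bacterial annotations use the literal
name. This panel is a default, not a claim of completeness — users with a
curated enzyme table should supply their own `enzyme_terms`. A pathway is
called complete only when all three of its representative enzymes are
present.

Species selection and genus aggregation are deterministic under a seed: per
phylum the `top_k` species by genome count are kept (ties broken by count,
then lexicographic name), per species at most 20 genomes are sampled, and
genus means are taken over seeded subsamples of at most 100 genomes. With
the cap at or above the number of genomes the genus mean equals the exact
mean — a property the tests exercise directly.

## 2. Trait structure

Presence matrices threshold transporter counts at zero and take pathway
calls as-is. Pairwise mutual information uses the plug-in
(maximum-likelihood) estimator over the empirical 2×2 joint table, reported
in **bits**; the diagonal is each trait's plug-in entropy. No bias
correction is applied — at the genome counts involved (hundreds to
thousands) the plug-in bias is far below interpretive resolution, and the
estimator is the simplest one that the brute-force oracle in the tests can
verify exactly. Constant traits have MI 0 with everything by convention.
Repertoire groups assign each genome to its exact presence pattern, so
group sizes partition the genome set (UpSet-plot semantics).

## 3. qPCR fold changes

Density changes are quantified from normalized Ct values:

    delta_Ct = (Ct_reference − Ct_sample) + log2(w_sample / w_reference)
    fold change = 2^delta_Ct

where `w` is culture volume (in vitro) or fecal weight (in vivo). The
weight term is implemented exactly as written: a heavier sample at equal Ct
yields a larger fold change. Conventions:

* **ND (not detected)** Ct values propagate as an explicit
  `not_detected` flag rather than being imputed at the cycle ceiling;
  censoring imputation would manufacture fold-change magnitudes that the
  data do not support.
* **Technical duplicates** are averaged on the Ct scale before the delta,
  the standard practice when efficiencies are not modelled.
* **Growth within a community** is called at fold change strictly greater
  than 1 over the horizon (default 0–72 h).
* The **ratio t-test** against fold change 1 operates on log2 fold changes
  versus mean 0 — equivalent to the ratio test and symmetric in inversion
  (swapping reference and sample flips the statistic's sign, not the
  two-sided p). Zero-variance inputs return the documented degenerate
  conventions (all-1 data: t = 0, p = 1; constant non-1 data: p = 0 with a
  flag).

## 4. Growth statistics and the mixed model

Growth-curve AUC is the trapezoid over the recorded grid, without baseline
subtraction unless requested. Spearman correlations use midranks; p-values
are exact (full permutation enumeration) for n ≤ 9 and use the
t approximation otherwise.

The colony-count model is a random-intercept LMM,
`y = X beta + u_group + e`, fitted by **maximum likelihood** with the
likelihood profiled over the single variance ratio
`theta = sigma_u^2 / sigma_e^2`. For fixed theta the marginal covariance is
block-diagonal `I + theta J` per group, with closed-form inverse and
determinant, so the profile is a smooth 1-D function maximised numerically
(tolerance 1e-10 on log theta) and compared against the theta = 0 boundary
— guaranteeing the fitted likelihood never falls below OLS. ML rather than
REML keeps the profiled objective elementary; at the design sizes involved
(tens of observations per stratum) the difference is negligible, and the
test suite pins the fit against both closed-form balanced ANOVA ML
estimators and an independent ML fit. Gene predictors enter as binary
indicators; the CFU outcome defaults to `log10(CFU + 1)` (raw mode
available) since colony counts span orders of magnitude.

## 5. Diet exposure

Meal records (8-digit food codes, dry grams) resolve against a nutrient
table in sugar grams per 100 g; per patient-day totals are
`sum(grams × density / 100)`. Each microbiome sample on day *d* receives
the **mean of the day sums of days d−2 and d−1**. When only one prior day
has records the mean is over that day (`n_days_available` reports how
many); zero-filling unrecorded days was rejected because it would conflate
non-recording with fasting, but a strict two-day mode is available.
Exposure is undefined (and the sample excluded downstream) when neither
prior day has records.

## 6. Compositional stage

Genus aggregation discards features without genus labels, sums counts and
renormalizes rows. The genus filter retains a genus detected at relative
abundance ≥ 1e-4 in ≥ 10% of samples (raw fraction, no rounding), or
reaching ≥ 10% abundance in any sample. The CLR transform replaces zeros by
adding **half the smallest nonzero relative abundance in the matrix** to
all entries and renormalizing (multiplicative-replacement practice), then
maps each row to centered natural logs. The log base is immaterial because
the outcome is standardized before modelling. CLR rows sum to zero by
construction, and the transform is invariant to row rescaling — both pinned
as properties in the tests.

A structural consequence worth stating: the CLR centers each sample across
genera, so only effects *relative to the across-genus mean* are
identifiable. A sugar effect shared identically by all genera is removed by
the transform. The synthetic generator therefore plants genus effects
centered to mean zero, and recovery is assessed on signs, ranks and
contrasts rather than absolute coefficients.

## 7. The Bayesian stage

Per genus, with standardized CLR abundance `y` and standardized exposure
`x`:

    y_i ~ Normal(alpha + beta x_i, sigma)
    alpha ~ Normal(0, 1); beta ~ Normal(0, 1); sigma ~ Exponential(1)

**Sampler.** The posterior is 3-dimensional, so the package uses adaptive
random-walk Metropolis on `(alpha, beta, log sigma)` with the Jacobian
correction — dependency-free and exactly reproducible under a seed. During
warmup (1000 iterations per chain) the proposal covariance is re-estimated
every 100 iterations from the second half of the warmup draws and the step
scale follows a Robbins-Monro recursion toward 30% acceptance; both are
frozen at the end of warmup, so the retained draws (1000 per chain × 4
chains = 4000 by default) come from a fixed Markov kernel. The Gaussian
likelihood is evaluated from sufficient statistics, making each iteration
O(1) in sample size; a cohort-scale run (91 genera × 1009 samples) takes
well under a minute. Initialization is `(0, 0, sigma = 1)` with up to 10
jittered retries if the posterior is non-finite.

**Diagnostics.** Split R-hat per parameter (warning above 1.01) and
Geyer-truncated effective sample sizes, used by the test suite to express
Monte-Carlo error as 3 MC-SEs when comparing against conjugate closed
forms.

**Summaries.** Posterior mean of beta, 66% and 95% equal-tail intervals,
and the 95% HPD interval computed as the shortest contiguous window over
the sorted draws. Zero-exclusion calls use the **HPD** interval. No
multiple-testing adjustment is applied across genera — the per-genus models
are independent summaries, not a family of hypothesis tests — and the
reported tables carry the count of exclusion calls so readers can judge the
multiplicity themselves. The exposure is standardized once over the
analysis sample set (not per genus), and per-genus seeds derive
deterministically from the master seed so results do not depend on which
genera are fitted together.

**Second stage.** The per-genus beta means (already z-scaled) regress on
the genus mean transporter count normalized by its maximum, with the same
priors and sampler; the fitted mean curve is simulated over the covariate
range with a 95% band, and a Spearman rank correlation accompanies the
regression. Pairing both views guards against the regression being driven
by the count scale: the rank statistic ignores it.

## 8. What the synthetic generators emulate

Generators produce every pipeline input with ground truth sufficient to
score recovery:

* **Annotations** plant exact subtype counts via products that satisfy the
  rules, surrounded by decoys engineered to fail each clause (gate term
  missing, token missing, lowercase-abbreviation traps); the census
  round-trips exactly.
* **Ct tables** invert the delta-Ct equation so planted fold changes are
  recovered exactly without noise, and with Gaussian Ct noise yield
  uniformly distributed null p-values (checked by a Kolmogorov-Smirnov
  test at the 1% level over 500 replicates).
* **Diet-abundance studies** build meal logs item by item (1–4 meals per
  patient-day, uniform item weights and sugar densities), so exposures
  arise from the same meal → day-sum → 2-day-lag chain the pipeline
  computes, rather than being drawn directly; day totals are then sums of
  several positive item contributions — right-skewed and strictly
  positive, a realistic shape for intake data. Genus responses follow the
  Bayesian model on the CLR scale with planted, centered betas;
  compositions come from inverse-CLR (softmax with max-subtraction
  overflow guard), split across ASVs, multinomially sampled at depth 1e5,
  with optional zero-inflation (default 5%).
* **Direct model draws** (`gen_genus_model_data`) generate from the priors
  for calibration: with parameters drawn from the prior, the 95% interval
  must cover the true beta at the nominal rate by construction, which the
  acceptance suite verifies (200 replicates at n = 150, coverage required
  in 90–98%, null HPD zero-exclusion ≤ 10%).

What they deliberately do **not** emulate: phylogenetic correlation among
genomes, longitudinal autocorrelation of the microbiome (the association
models are cross-sectional per sample), amplification-efficiency artefacts
in qPCR, or taxonomic misassignment. Passing tests therefore establish the
correctness and calibration of the *procedures*, not the biological effect
sizes recoverable from any particular real cohort.

## 9. Problem sizes and numerical choices

The test suite runs the coverage calibration at 200 replicates of n = 150
with 2 chains × (500 warmup + 1000 kept) draws per fit — interval endpoints
at 2000 draws are stable to well inside the acceptance bands — and the
end-to-end study at 30 genera × 200 samples; the acceptance script runs the
full chain at 91 genera × 1009 samples × 158 patients with the default
4 × 1000 draws. Other numerical conventions: profile-likelihood tolerance
1e-10; proposal covariance regularized by 1e-8 on the diagonal with a
Cholesky fall-back that keeps the previous factor on failure; HPD windows
use `ceiling(mass × n)` draws; Spearman permutation enumeration switches to
the t approximation above n = 9 (9! = 362,880 orderings is the practical
ceiling).

## 10. Known limitations

* Keyword censuses inherit the vocabulary of the annotation pipeline;
  genomes annotated with unusual product phrasing will undercount. The
  ruleset is injectable precisely so users can adapt it.
* Pairwise MI is computed pooled across all genomes by default; users
  wanting per-phylum structure should subset the presence matrix by phylum
  and compare (phylogenetically corrected association tests are out of
  scope).
* The per-genus models share no information (no hierarchical pooling) and
  adjust for no covariates; coefficients are descriptive associations.
* CLR identifiability: only contrasts against the community mean are
  estimable, as discussed in section 6.
* The delta-Ct weight term follows the stated equation verbatim; users
  whose normalizer semantics differ should pre-invert their normalizer
  values.
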