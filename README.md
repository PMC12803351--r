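# sugartrait

Do gut bacteria that carry **sugar ABC (ATP-binding cassette) transporters**
expand when their host eats more sugar? `sugartrait` is an R package for
testing that question end to end: from raw genome annotation files to a
two-stage Bayesian analysis linking genus-level transporter repertoires to
microbiome responses to dietary sugar. It is aimed at microbiome researchers
who have (i) genome annotations for the taxa in their community, (ii)
longitudinal diet records, and (iii) 16S-style relative-abundance tables —
or who want to study the statistical behaviour of this inference chain on
synthetic data with known ground truth.

## What the package computes

**Trait census.** Genome annotations (GenBank flat file, GFF3 or TSV) are
screened with a gate-then-subtype keyword rule: a feature counts toward a
transporter subtype only if its product contains both gate terms ("sugar",
"transporter") and a subtype token (ABC / ATP-binding cassette, PTS /
phosphotransferase, MFS / major facilitator). Glycolytic enzymes (EMP, PPP
and ED pathways) are screened by configurable search terms, and a pathway is
called complete when three representative enzymes are all present.
Genus-level mean counts are computed over seeded subsamples of up to 100
genomes per genus.

**Trait structure.** Binary presence matrices, pairwise mutual information
in bits (plug-in estimator), and exact-pattern repertoire groups (UpSet-style
intersections).

**Experimental readouts.** qPCR delta-Ct fold changes
(`ΔCt = (Ct_ref − Ct_sample) + log2(w_sample/w_ref)`, fold change `2^ΔCt`),
community growth calls (fold change > 1), a one-sample ratio t-test on the
log2 scale, growth-curve AUC, Spearman associations, and a random-intercept
linear mixed model `y ~ gene presence + (1 | repeat)` fitted by profiled
maximum likelihood.

**Diet and composition.** Meal logs with 8-digit food codes are resolved
against a nutrient table, summed per patient-day, and each microbiome sample
is assigned the mean sugar intake of the two prior days. Genus abundance
tables are filtered (detected at 0.01% abundance in ≥ 10% of samples, or
≥ 10% abundance anywhere) and centered-log-ratio transformed.

**Bayesian association.** Per genus *g* with standardized CLR abundance
`y_i` and standardized sugar exposure `x_i`:

    y_i ~ Normal(alpha + beta * x_i, sigma)
    alpha, beta ~ Normal(0, 1);  sigma ~ Exponential(1)

sampled with the package's own adaptive Metropolis MCMC (4 chains × 1000
retained draws by default), summarized by posterior means, 66%/95% credible
intervals and the 95% HPD interval. A second-stage regression of the same
form relates the per-genus `beta` means to the genus mean transporter count
(normalized by its maximum), alongside a Spearman rank correlation — the
headline question: do ABC-transporter-rich genera respond more positively to
sugar?

**Synthetic data.** Generators emit every input above with planted ground
truth (transporter counts, fold changes, exposures, per-genus effects), so
the whole chain is testable without downloads.

## Worked example

```r
library(sugartrait)

ann <- genome_annotation("B_theta_VPI", data.frame(product = c(
  "sugar ABC transporter permease",
  "sugar ABC transporter ATP-binding protein",
  "MFS sugar transporter",
  "PTS sugar transporter subunit IIA",
  "glucose ABC transporter",     # no gate term "sugar": not counted
  "hypothetical protein")))
census_transporters(ann)
#>     genome_id abc pts mfs total
#> 1 B_theta_VPI   2   1   1     4
```

Two ABC products, one PTS, one MFS; the decoy without the "sugar" gate term
is ignored, and `total` is the sum of the three subtypes.

The full chain on a synthetic study (30 genera, 200 samples) in which the
per-genus sugar effect is planted proportional to the genus ABC count:

```r
p <- run_sugar_pipeline(seed = 11, n_genera = 30, n_samples = 200)
p
#> Synthetic study: 30 genera fitted on 200 samples
#> HPD-excludes-zero genera: 27 of 30
#>   ABC   spearman rho  0.968   regression beta  1.711
#>   PTS   spearman rho  0.190   regression beta  0.375
#>   MFS   spearman rho -0.092   regression beta -0.211
#>   total spearman rho  0.818   regression beta  1.798
```

The ABC transporter count ranks the fitted genus sugar coefficients almost
perfectly (rho 0.97) and its second-stage regression slope is confidently
positive, while PTS and MFS counts — which were not linked to the planted
effects — show weak associations. The same steps are available from a shell
via the bundled CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "sugartrait.R", package = "sugartrait"))')" \
  pipeline --seed 11 --n-genera 30 --n-samples 200 --out results/study
```

which writes `census.tsv`, `genus_census.tsv`, `genus_fits.tsv` and
`trait_associations.tsv`. Subcommands `census`, `pmi`, `foldchange`, `clr`,
`fit`, `associate` and `simulate` expose the individual stages.

## Documentation

The methods vignette (`vignettes/sugar-transporter-inference.Rmd`) describes
the models, the keyword-rule conventions, the MCMC implementation and its
diagnostics, what the synthetic-data generators do and do not emulate, and
known limitations.
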