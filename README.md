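# stochbeta

Ecological dissection of microbiome cohorts from plain count tables:
how different are the communities of a cohort, is that difference
species **turnover** or **nestedness**, and how much of it reflects
**deterministic selection** rather than stochastic assembly — at the
taxonomic level and, through a trait (gene copy number) projection, at
the functional level. The package is aimed at amplicon/microbiome
analysts who have a denoised sample-by-feature table (ASVs/species or
pathways) and a sample-to-cohort map, and want the ecology beyond
ordination plots.

## What it computes

* **Multiple-site Sørensen partition.** For a cohort of sites with
  richness `S_i`, pooled richness `S_T`, and `b_ij` the features of site
  `i` absent from `j`:

  ```
  β_SIM = Σ min(b_ij, b_ji) / [ (Σ S_i − S_T) + Σ min(b_ij, b_ji) ]
  β_SOR = (Σ min + Σ max)   / [ 2(Σ S_i − S_T) + Σ min + Σ max ]
  β_NES = β_SOR − β_SIM
  ```

  one triple per cohort (not an average of pairs), additive to 1e-12,
  plus the pairwise forms and a nestedness/turnover ratio.

* **Null-model stochasticity ratio.** Observed Bray–Curtis similarity
  `C` of every within-cohort pair versus its expectation `E` under
  randomized communities that conserve sample totals, keep richness
  proportional (or fixed), and include features proportionally to their
  regional occurrence frequency. Selection strength
  `SS = (C − E)/C` when `C ≥ E`, `(E − C)/(1 − C)` otherwise; the
  stochasticity ratio `ST = 1 − SS` is summarized per cohort in percent.

* **Core microbiome sets** at a prevalence threshold (default ≥ 75%),
  with all exclusive Venn regions across cohorts and core fractions
  relative to cohort gamma richness.

* **Signature screen** (LEfSe-style): rarefy → relative abundance →
  per-million scaling → Kruskal–Wallis (α = 0.05) → bootstrapped
  ridge-LDA effect sizes, keeping features with log10 score > 3.

* **Trait projection**: `pathway[s, p] = Σ_t count[s, t] · copies[t, p]`
  to contrast taxonomic and functional beta diversity / stochasticity.

* **Synthetic cohort generator** with tunable assembly (neutral vs
  filtered), turnover/nestedness incidence structure, planted core taxa,
  planted fold-enrichment, and tunable functional redundancy — every
  analysis above is testable against data with known ground truth.

## Worked example

```r
library(stochbeta)

spec <- synthetic_spec(n_pool = 300, cohorts = c(normal = 12, OSCC = 12),
                       depth_range = c(8000, 12000),
                       planted = list(cohort = "each", n = 4, fold = 8),
                       seed = 17)
ds   <- make_dataset(spec)
rare <- rarefy(ds$table, 8000, seed = 1)

cohort_partitions(rare, ds$design)
#> $normal
#> <beta_partition> 12 sites: beta_sor=0.3566 (turnover 0.3224 + nestedness 0.0342)
#> $OSCC
#> <beta_partition> 12 sites: beta_sor=0.3484 (turnover 0.3071 + nestedness 0.0413)

core_sets(rare, ds$design)
#> <core_set> prevalence >= 75%
#>   normal: 219 core features (75.78% of cohort richness)
#>   OSCC: 222 core features (75.51% of cohort richness)

st <- stochasticity_ratio(rare, ds$design,
                          null_model_config(n_randomizations = 200, seed = 2))
st$normal
#> <stochasticity_result> cohort 'normal': ST = 96.71 +/- 1.04% over 66 pairs

sig <- signature_features(ds$table, ds$design, rarefy_depth = 8000, seed = 3)
head(as.data.frame(sig)[, c("feature_id", "enriched_cohort", "lda_score", "passes")], 4)
#>   feature_id enriched_cohort lda_score passes
#> 1     sp0088            OSCC  3.360833   TRUE
#> 2     sp0228            OSCC  3.331949   TRUE
#> 3     sp0272          normal  3.305940   TRUE
#> 4     sp0133            OSCC  3.298180   TRUE
```

Reading the output: the cohorts differ almost entirely by species
*turnover* (β_SIM ≈ 0.32 of β_SOR ≈ 0.36; nestedness ≈ 0.03), their
assembly is stochasticity-dominated (ST ≈ 97%, as expected for neutral
multinomial sampling from one pool), and the screen's top signatures are
exactly the planted 8-fold-enriched taxa, attributed to the correct
cohort (compare `attr(ds$table, "planted_ids")`). Projecting the same
table through the trait matrix (`project_traits(rare, ds$traits)`)
collapses β_SOR to ≈ 0.03–0.04 — the functional-redundancy effect:
pathway profiles are far more stable than the taxa carrying them.

A command-line front end over the same functions is installed at
`system.file("scripts", "stochbeta-cli.R", package = "stochbeta")`, with
subcommands `simulate`, `core`, `beta-partition`, `stochasticity`,
`signatures`, `project` and `all` (the full pipeline with a run
manifest; see `?run_pipeline`).

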