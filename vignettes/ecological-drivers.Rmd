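---
title: "Dissecting ecological drivers of microbiome cohorts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting ecological drivers of microbiome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochbeta)
```

`stochbeta` asks, for a cohort of microbiome samples treated as a
metacommunity: how different are the communities (and their functional
profiles), is that difference species *replacement* or ordered species
*loss*, and how much of it is attributable to deterministic selection
rather than stochastic assembly? The package works on plain
sample-by-feature count tables (ASVs/species or pathways) plus a
sample-to-cohort map, and ships a synthetic cohort generator so every
claim the analyses make can be exercised against data with known
structure.

## The beta-diversity partition

For two sites with `a` shared features and `b`, `c` features unique to
either side, Sørensen dissimilarity `(b + c) / (2a + b + c)` decomposes
into a Simpson-based turnover term `min(b, c) / (a + min(b, c))` — the
dissimilarity that remains if we ignore richness differences — and a
nestedness residual. The multiple-site forms aggregate the pairwise
unique-feature counts before forming the ratios, so `multisite_partition()`
is a single property of the whole cohort, not an average of pairs:

$$\beta_{SIM} = \frac{\sum_{i<j}\min(b_{ij},b_{ji})}
  {\left(\sum_i S_i - S_T\right) + \sum_{i<j}\min(b_{ij},b_{ji})},\qquad
\beta_{NES} = \beta_{SOR} - \beta_{SIM}$$

with $S_i$ the site richness, $S_T$ the pooled richness, and
$b_{ij}$ the features of site $i$ absent from $j$. Additivity
($\beta_{SOR} = \beta_{SIM} + \beta_{NES}$ to $10^{-12}$), permutation
invariance, and the two-site reduction to the pairwise form are enforced
by tests against a brute-force set-operation oracle. Incidence is
`count > 0` after rarefaction; we deliberately apply no minimum-abundance
floor. Cohorts of unequal size are analyzed as-is with `n_sites`
reported; an optional resampling mode (`resample_n` sites,
`resample_reps` repetitions, mean reported, spread in attributes) is
available when equal site numbers matter, but it is off by default since
the multi-site statistics are defined for any number of sites.

```{r beta-example}
multisite_partition(rbind(c(1, 1, 1, 1), c(1, 1, 1, 0), c(1, 1, 0, 0)))
```

## The null model and the stochasticity ratio

For every within-cohort sample pair we compare the observed Bray–Curtis
similarity $C$ with the mean similarity $E$ of the pair under
randomizations of the cohort (default 1000; analyses in this document and
in the test-suite experiments use 100–200, which puts the Monte-Carlo
error of $E$ well below the pair-to-pair spread). Each randomization
rebuilds every sample from the cohort's regional pool (all features
observed in the cohort) under three constraints:

1. **totals** — each null sample keeps its observed read total;
2. **richness** — either `fixed` (exactly the observed richness) or
   `proportional` (the default): the cohort's total occurrence count
   $O = \sum_i S_i$ is re-allocated to samples multinomially with weights
   $S_i$, so richness is preserved in expectation but free to fluctuate;
3. **occurrence frequency** — features enter a null sample with
   probability proportional to their regional occurrence frequency
   (`proportional`, default) or uniformly (`equiprobable`).

In proportional-richness mode the features of a null sample are chosen by
*capped-proportional Bernoulli inclusion* ("water-filling"): inclusion
probabilities are $p_t = \min(1, c\,f_t)$ with $c$ solved so that
$\sum_t p_t$ equals the allocated richness. We chose this over weighted
sampling without replacement deliberately: successive weighted draws
without replacement do *not* give inclusion probabilities proportional to
the weights (high-frequency features are under-included once the cap
binds), and proportional inclusion is precisely the constraint the method
advertises. Fixed-richness mode keeps classical weighted sampling without
replacement, because there exact richness is the advertised constraint.
Abundances are then assigned by giving each selected feature one read and
distributing the remainder multinomially with weights equal to the
regional mean relative abundances renormalized over the selected
features. Every draw is reproducible from `(seed, draw_index)`.

The selection strength for a pair is two-branched:

$$SS = \begin{cases}(C - E)/C, & C \ge E \text{ (homogenizing selection)}\\
(E - C)/(1 - C), & C < E \text{ (diverging selection)}\end{cases}$$

so both "more similar than the null" and "less similar than the null"
register as determinism and $SS \in [0, 1]$. The stochasticity ratio is
$ST = 1 - SS$, summarized per cohort as mean ± population SD in percent.
The divergence branch is a design choice: the method description we
follow states only the $C \ge E$ branch in words, and clamping negative
values to zero instead would hide diverging selection entirely; the
symmetric treatment keeps the ratio interpretable in both regimes.

## Core sets, the effect-size screen, and trait projection

A feature is *core* in a cohort when its prevalence meets the threshold
(default 0.75, inclusive `>=`; a strict `>` flag exists because both
conventions circulate — for cohorts of 21–27 samples a prevalence of
exactly 0.75 cannot occur, so the default is cosmetic there but must be
explicit). `core_sets()` also reports all $2^k - 1$ exclusive Venn
regions and each cohort's core fraction, whose denominator is the
cohort's gamma richness (features observed at least once in the cohort).

The signature screen mirrors the LEfSe recipe without its subclass
stage (the designs we target have none): rarefy, convert to relative
abundance, scale samples to $10^6$, Kruskal–Wallis per feature at
$\alpha = 0.05$ (via `stats::kruskal.test`, tie-corrected), then
bootstrapped (30 rounds, 2/3 per-class subsampling) ridge-regularized LDA
effect sizes for the passers. For each cohort that is the
highest-mean class of some candidates, a one-vs-rest discriminant is fit
over those candidates; a feature's effect is the average of its raw
between-class mean difference and the discriminant-axis separation
attributed to it in proportion to $|w_f \Delta m_f|$. Scores are
$\log_{10}$ of the effect (floored at 0 below 1) with the conventional
cutoff 3. The ridge constant is $10^{-6}$ times the trace-scaled
identity, because candidate blocks are routinely rank-deficient. We make
no claim of numeric parity with the published LEfSe implementation — the
tests assert calibration (null rejection at the nominal rate) and
recovery (planted enrichment found, nulls not), which is what the screen
is for. For three or more cohorts the one-vs-rest contrast with
enriched class = highest mean is used; a feature significant against
*every* other class is a stricter notion we did not adopt, since the
screen's published description does not specify it.

`project_traits()` is the community-wide abundance step of functional
prediction in isolation: pathway abundance is the copy-number-weighted
sum of taxon abundances. Placement, hidden-state prediction, and pathway
inference are upstream concerns of dedicated tools and are out of scope;
the linear projection is all that is needed to study taxonomy-versus-
function contrasts such as functional redundancy.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` defaults describe the cohort study the analyses are
sized for: three cohorts of 27, 21 and 27 samples, one regional pool of
600 species with log-normal(0, 2) relative abundances, and 40,000–60,000
reads per sample (rarefaction at or below 40,000 then retains every
sample). The moving parts:

* **assembly** — `neutral` samples are multinomial draws from the pool
  (pure sampling stochasticity); `filtered` multiplies the pool by
  $\exp(w\,e_{tc})$ with fixed standard-normal taxon-by-cohort effects,
  drawn once per dataset seed so the filter strength $w$ is the only
  moving part in monotonicity experiments. $w = 0$ reproduces the
  neutral draw exactly, seed path included.
* **structure** — `turnover` confines each sample to a rotated block of
  one third of the pool (stride pool-size/n-samples), producing species
  replacement; `nestedness` confines sample $j$ to a random-length
  prefix of the ranked pool, with *equal* within-prefix weights. The
  equal weights are deliberate: with log-normal weights the rare tail of
  a long prefix is observed erratically at realistic depths, which
  injects spurious turnover into what should be an ordered-loss pattern.
* **planted cores** — `core_target` designates disjoint per-cohort taxon
  sets whose presence per sample is Bernoulli at the target prevalence
  (forced to at least one read when present, zeroed when absent).
* **planted signatures** — `planted` multiplies the weights of the taxa
  whose regional share is closest to $5\times10^{-4}$ by `fold` in the
  target cohort: rare enough that the displaced mass is a percent or two
  of the total, abundant enough (20+ expected reads at study depths) to
  be observed in essentially every sample. With `cohort = "each"`, every
  cohort receives its own disjoint planted set; we use this design for
  recovery experiments because it displaces the *same* mass in every
  cohort, keeping the non-planted features exchangeable across cohorts —
  planting in a single cohort makes every other feature differentially
  abundant through compositional closure, and a correct screen will
  eventually flag the most dominant of them. That is a property of
  compositions, not a screen error, but it makes "false positive"
  ill-defined; the symmetric design restores a genuine null.
* **traits** — each of `n_pathways` (default 300) pathways is carried by
  `redundancy` distinct taxa (default 3; ~30 models a functionally
  redundant community) with copy numbers in 1–3, dealt from shuffled
  cycles of the pool so every taxon carries a pathway whenever the slot
  count allows.

The generator emulates the statistical skeleton of denoised cohort data:
log-normal abundance spectra, sampling-depth variation, prevalence
structure, assembly contrasts, and taxa-to-function redundancy. It does
*not* emulate chimeras or denoising artifacts, phylogenetic correlation
among taxa (all taxa are exchangeable up to their abundances; the
deterministic synthetic lineages exist to exercise rank-collapsing, not
to model evolution), overdispersion beyond multinomial sampling,
zero-inflation from technical dropout, or batch effects. Passing tests
therefore demonstrate that the *methods* behave as specified on data
with known structure — not that real saliva communities satisfy the
generator's assumptions. Two visible consequences: neutral synthetic
cohorts are far more even in prevalence than real cohorts (core sets are
large, and multi-site Sørensen dissimilarity is lower than real saliva
species profiles typically show), and stochasticity ratios sit near the
top of the scale unless filtering is switched on.

## Numerical and scale choices

* Rarefaction subsamples reads without replacement per sample; the
  spec'd depth for real studies (e.g. 43,313) is a parameter, and the
  worked examples rarefy to 40,000 so that all synthetic samples are
  retained. Samples below depth drop with a warning by default
  (`on_shallow = "error"` to refuse instead).
* Degenerate inputs have defined behavior: an all-tied Kruskal–Wallis
  feature returns $H = 0$, $p = 1$; `beta_nes / beta_sim` is `NA` with
  `ratio_defined = FALSE` when turnover is zero; empty samples, empty
  cohorts, all-zero feature pairs, and negative values are errors that
  name the offending sample/feature.
* All randomized stages (rarefaction, null draws, bootstraps, the
  generator) derive their RNG streams from explicit integer seeds and
  restore the caller's RNG state; identical inputs give byte-identical
  outputs, which the I/O layer preserves by writing numbers at 12
  significant digits.
* Test and experiment sizes are chosen so the whole suite exercises the
  study-scale defaults (75 × 600 at 40–60k reads) where the claim is
  about the defaults (neutral stochasticity, core recovery, signature
  recovery) and compact configurations (pools of 100–200, depths of
  2–5k, 100–200 randomizations) where the claim is structural
  (monotonicity in $w$, nestedness/turnover contrasts, calibration),
  with 20-seed replication for all generator-property claims.

## Known limitations

* The null-model micro-algorithm (token allocation, water-filling,
  mean-abundance read assignment) is one concrete member of the family
  of "proportional occurrence and richness" randomizations; other
  published implementations differ in unstated details, so stochasticity
  ratios are comparable within this package, not across tools.
* The effect-size screen applies no multiple-testing correction across
  features (by design, matching the recipe it mirrors: raw
  $\alpha = 0.05$ then the LDA cutoff); interpret single-feature calls
  accordingly.
* Counts are stored as doubles (pathway projections are fractional in
  general); rarefaction demands integer counts and says so.
* Abundance-based partition components (balanced variation vs abundance
  gradients) and phylogenetic diversity/null models are out of scope.
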