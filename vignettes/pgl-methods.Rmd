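---
title: "Locating gene-set co-expression in a multi-donor brain atlas, and the downstream cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating gene-set co-expression in a multi-donor brain atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pglr)
```

## The scientific question

A microRNA that is dysregulated in a psychiatric condition represses a
specific set of target mRNAs. If those targets are strongly co-expressed in
particular brain regions, those regions are candidates for structural or
functional follow-up. `pglr` operationalises this in two halves:

* **Localisation.** Given a curated target-gene set (e.g. TargetScan
  conserved targets of miR-124-3p at Aggregate P~CT~ > 0.99) and a
  multi-donor region-by-gene expression reference in the shape of the Allen
  Human Brain Atlas, find the regions of interest (ROIs) where the set is
  expressed above the background of all other genes, consistently across
  donor brains.
* **Clinical follow-up.** Given a matched case–control cohort with
  volumetric, personality (BFI) and suicidal-ideation (C-SSRS) measures,
  test whether the top ROI differs between groups and how its
  (ICV-normalised) volume relates to the clinical variables.

## The ROI statistic

For donor $d$, let $x_{gr}$ be the expression of gene $g$ in region $r$.
Within each donor every gene is standardised across its sampled regions,

$$z_{gr} = \frac{x_{gr} - \bar{x}_{g\cdot}}{s_{g\cdot}},$$

with the **population** (divide-by-$n$) standard deviation. The choice of
population vs sample SD only rescales each gene by a common factor and is
made explicit because the procedure is otherwise rank-based; genes with
zero variance are set to zero and flagged rather than dropped, and missing
gene/region cells are excluded from (never imputed into) all statistics.
Standardising per gene is what turns "expression" into "co-expression
relative to each gene's own regional profile": without it, regionally
high-expressing housekeeping genes would dominate every region.

The **region universe** is the set of regions sampled in at least
`min_donors` donors (default 5 of the 6), the same rule the atlas's sparse
sampling forces on any cross-donor analysis; its size $m$ is the Bonferroni
family size for *every* donor. Using a shared $m$ (rather than each donor's
own region count) keeps donor frequencies comparable.

For each region and donor, a **two-sided Wilcoxon rank-sum test** compares
the target genes' $z$ values against all other genes in that region. The
engine is exact (via the Mann–Whitney null distribution) when both groups
have at most 20 observations and no ties, and otherwise uses the normal
approximation with mid-ranks, tie-corrected variance and continuity
correction; a fully tied region returns $p = 1$ with direction 0. A region
*counts* for a donor when the Bonferroni-adjusted $p$ is below `alpha`
(default 0.05) **and** the direction is positive (mean target $z$ above
mean background $z$). The two-sided test mirrors the "significantly
different" phrasing of the underlying protocol, while the positive-direction
gate encodes that an ROI means *high* co-expression; a one-sided test at
$\alpha/2$ would be equivalent here, but the two-sided form keeps the
per-donor p-values interpretable on their own.

The **frequency** of a region is its number of counting donors; regions
with frequency ≥ `min_freq` (default 5) are reported. **Ranking** is by
frequency (descending), then the mean of $-\log_{10}(\text{adjusted } p)$
over counting donors (descending), then region name — the underlying
protocol never defines its ranking rule, so this package pins one that
orders first by cross-donor reproducibility and then by strength of
evidence, with a deterministic tie-break. `effect_summary` reports the mean
(over counting donors) of mean target $z$ minus mean background $z$, a
directly interpretable effect size in within-donor SD units.

Probe-level inputs are collapsed to genes first (mean by default — max is
available; mean is variance-stable), then normalised; whether the original
protocol collapsed before or after normalising is not recoverable, and the
collapse-then-normalise order is this package's choice.

## Robustness procedures

`split_half_validation()` randomly partitions the gene list into halves of
size $\lceil n/2 \rceil$ and $\lfloor n/2 \rfloor$ (47/46 for a 93-gene
list) and runs the full ROI analysis on each independently; a top region
that reappears in both halves is not an artefact of a few genes.
`false_positive_simulation()` draws `n_lists` (default 100) random gene
lists of each requested size (defaults 30/100/300) from the atlas gene
universe — the pool is the whole universe, since the protocol says only
"randomly selected genes" — and counts how many lists return *any* ROI
under the full criterion (Bonferroni + positive direction + frequency
≥ 5/6). One master seed spawns per-list child seeds so any single list can
be replayed in isolation.

## Cohort matching and the downstream statistics

`euclidean_match()` implements greedy global matching without replacement:
all (case, pool) pairs are sorted by Euclidean distance (ties broken by
case id then control id) and accepted whenever both members are still
unmatched. Greedy matching is deterministic and auditable; optimal
assignment would minimise the distance total but can trade a perfect pair
away, and the original matching reference's exact algorithm is not
reprinted, so the simpler rule is used and named in the run manifest.
Features are encoded per the scheme: age z-scored over the combined
case+pool sample, sex/race one-hot, and each diagnosis as two binary
coordinates (past, current) — so one diagnosis status difference
contributes exactly 1 to the squared distance. Balance is checked with a
one-way ANOVA on age and uncorrected Pearson chi-square tests on the
categorical variables, flagging $p < 0.05$ without multiplicity correction
(deliberately conservative for a balance check: flags too often rather
than too rarely).

Volumes are divided by intracranial volume before any test. The group
comparison of the top ROI is labelled *confirmatory*; everything else runs
under an *exploratory* label. The suicidal-ideation recovery score is
defined as admission − discharge intensity, so positive = improvement;
the sign convention matters for the reported negative correlations and is
recorded in the manifest. Outlier flagging for sensitivity re-runs uses
the upper Q3 + 3·IQR rule (the analyses concern a single extreme high
value; a symmetric rule is trivial to supply as a custom predicate), and
`sensitivity_rerun()` reports the before/after pair plus the number
excluded rather than silently replacing the primary result.

`chi_square_2x2()` reproduces published prevalence contrasts from printed
percentages via `count_from_percent()` (half-up rounding of
percent/100 × n): at n = 111 per group, prevalences of 22% vs 7% give
counts 24 vs 8 and an uncorrected chi-square p of 0.0022; only the
*uncorrected* statistic reproduces the published values, which is why the
Yates correction is off by default.

## What the synthetic data emulate — and what they do not

`make_atlas()` draws every gene × region value i.i.d. standard normal (or
log-normal), plants a `planted_shift` (default 1 SD) for the target set
(default 93 genes of 20,000) in the planted regions, in every donor, and
optionally drops regions per donor at `1 − region_sampling_rate` (planted
regions are always kept so the planted signal is interpretable at any
sampling rate). The defaults — 6 donors, 250 regions, 20,000 genes,
93-gene target set — reproduce the scale of the real analysis. Because the
pipeline standardises and then ranks, it is insensitive to the marginal
value distribution, which the suite verifies by re-running recovery under
the log-normal background.

What the generator deliberately does **not** model: spatial autocorrelation
between neighbouring regions, correlated gene modules, donor batch
effects, and hemispheric asymmetries of sampling. Passing tests therefore
demonstrate that the statistic, the multiplicity control and the
aggregation logic behave as designed under clean planted-signal
conditions — not that the pipeline's error rates transfer unchanged to
real atlas data, where correlated backgrounds make the effective number of
independent tests smaller.

`make_cohort()` generates two groups of `n_per_group` (default 111): the
normalised focal volume is normal with a standardised case deficit of
`volume_effect` (default 0.8 SD, chosen to mirror a clearly detectable
deficit at this sample size); ICV is Normal(1.5 × 10⁶, 10⁵) mm³; in cases
only, agreeableness, age and the recovery score follow planted linear
relations to the standardised normalised volume (defaults −0.13 per SD on
the 1–5 BFI scale, −3.7 years per SD, −1.2 intensity points per SD, with
natural-scale residual SDs 0.6, 9 and 6 — slopes sized so the implied R²
values sit in the few-percent-to-~15% range typical of such clinical
correlations); controls get the same marginals with no planted relation,
mirroring effects reported in cases but not controls. Comorbidity
prevalences default to the published demographic table. Ages are floored
at 1 year (a < 0.3% truncation that does not measurably bias the slope
recovery). `make_match_pool()` generates a deliberately covariate-shifted
control pool (younger, more female, lower comorbidity rates) three times
the case-group size, for exercising the matcher.

## Numerical and engineering choices

* The per-region rank-sum sweep is a compiled one-pass counting kernel:
  for each region it sorts only the target values and counts, for every
  gene, how many targets it falls below — $O(N \log n_1)$ per region
  instead of a full sort — while an open-addressing hash over value bit
  patterns collects exact tie counts for the tie-corrected variance.
  Several gene sets (a list and its two halves, say) share one sweep.
* For many-list workloads (`false_positive_simulation()`),
  `precompute_ranks()` materialises full per-donor rank matrices once;
  each list evaluation then reduces to column sums. Both paths are tested
  to agree to 1e−12, including under heavy ties.
* Matched-null evaluation uses common random numbers:
  `make_null_counterpart()` reconstructs the bit-exact shift-0 draw from
  the pristine planted block kept in the truth sidecar, and
  `get_rois_matched_null()` evaluates it by substituting only the
  re-standardised target-gene rows into the sweep, since background gene
  rows are bit-identical between the signal and null atlases. The fast
  path is tested equal to materialising and re-normalising the null atlas.
* Simulation sizes: the packaged property suite runs 100 full-scale
  signal replicates (each also evaluated as its matched null and as two
  split halves), a 100-list false-positive calibration at sizes 30 and
  100, 200 cohort replicates at n = 111 for slope recovery and power, and
  50 matching replicates; `scripts/acceptance.R` re-runs the same design
  with 40 atlas and 30 matching replicates. These sizes make a 95%
  empirical rate distinguishable from failure while keeping a full run in
  the minutes range on one CPU.
* `bonferroni_adjust()` takes the family size explicitly because a donor
  may not sample every universe region, in which case the family is larger
  than the vector of p-values at hand.
* All stochastic functions take explicit seeds; one master seed spawns
  per-replicate child seeds (`sample.int` under the master seed), so every
  replicate is individually replayable and whole runs are bit-reproducible.

## Known limitations

* The ranking rule and the two-sided-plus-direction convention are
  reasonable reconstructions of an underdocumented protocol, not copies of
  it; both are recorded in every run manifest.
* Greedy matching is order-dependent at distance ties (resolved
  deterministically) and does not minimise the total distance.
* The independence of genes in the synthetic atlas makes Bonferroni
  behave close to nominal; on real co-expression data it is conservative.
* The 93-gene count of the motivating target list is dataset-dependent
  (TargetScan release, family label) and is treated as an input property,
  never asserted by the package.
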