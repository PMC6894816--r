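---
title: "Window-based SNV similarity strain tracking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based SNV similarity strain tracking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsstrack)
```

## The problem

Shotgun metagenomics resolves gut microbes below the species level: two
people can both carry *Bacteroides vulgatus*, yet carry genomically
distinguishable variants of it — strains. Whether two samples carry the
*same* strain of a species is the question behind strain tracking: did a
donor strain engraft after a faecal transplant, did a mother seed her
infant, do twins who shared a household for decades still share their gut
strains years after separating?

`wsstrack` answers this with a window-based SNV similarity (WSS) score
computed from base-resolution variant calls, plus the cohort-level
statistics needed to turn per-pair scores into population statements, and a
synthetic cohort generator that makes the whole pipeline testable without
any sequencing data.

## The score

The input per species is a multi-sample VCF produced upstream by aligning
reads to the species' reference genome and calling haploid genotypes at
*every* reference position (gVCF-style, non-variant sites included). Each
sample column becomes a `sample_profile`: an allele call (or a missing
mark) and a read depth at every base.

Two layers of quality control precede scoring:

* **Sample filter.** A sample enters pairwise comparison only if its
  coverage breadth (fraction of positions with depth ≥ 1) strictly exceeds
  0.30 *and* its mean depth (averaged over the whole reference, zeros
  included) strictly exceeds 3.5. Averaging over the whole reference rather
  than covered positions only is the stricter reading and keeps the two
  criteria non-redundant.
* **Window filter.** The reference is tiled into non-overlapping windows
  (default 1,000 bases; the final window may be shorter). For a given
  sample pair, a window is dropped when more than 50% of its bases have
  depth below 5 in either sample. Exactly half low-depth bases is still
  usable.

A usable window is *identical* for a pair when no position at which both
samples carry a call shows differing allele strings; positions missing in
either sample are non-informative, so a usable window with no both-called
positions counts as identical (no difference was observed). The score is

$$\mathrm{WSS} = 100 \times \frac{n_\text{identical windows}}{n_\text{usable windows}}\,,$$

a percentage in $[0, 100]$, exactly symmetric in the two samples, equal to
100 for a sample against itself, and *undefined* when no window is usable —
undefined scores are propagated as indeterminate, never coerced to 0
or 100.

## From score to call

Each species carries a relatedness cut-off: a pair is called **related**
when its score strictly exceeds the cut-off and **unrelated** when the
score is at or below it. The strict inequality is deliberate — relatedness
is defined as score *above* cut-off, and the boundary case is resolved
conservatively to unrelated. Pairs whose samples failed QC, or whose score
is undefined, are **indeterminate**; the raw score is still displayed for
such cells in the summary matrix when one exists.

Cut-off provenance is explicit. Users reproducing a published analysis can
load an external per-species table (`read_cutoff_table()`); otherwise
`estimate_cutoffs()` derives cut-offs from the score distribution of
truth-unrelated pairs (all-vs-all across different individuals). The
default rule is the *maximum* unrelated score — the most conservative
placement against false relatedness; an upper quantile and mean + k·SD are
also available, and the chosen rule is recorded in the table's provenance
string.

`misclassification_rate()` quantifies how often that choice would still
miscall: among truth-unrelated pairs, the fraction whose score exceeds the
cut-off, reported as a percentage *truncated* (not rounded) to two
decimals, so 2 exceedances out of 1,544 pairs reports as 0.12.

## Cohort-level statistics

Twin pairs are binned by years of separation: "no separation" for
cohabiting pairs, then decade intervals 1–9 through 50–59 (a pair 19 years
apart belongs to 10–19). Each pair contributes one observation: its
shared-strain fraction, the number of related calls times the reciprocal of
the strain-panel size. The denominator is a fixed configured constant for
the analysis (e.g. 250 strains for an adult-only panel, 845 for a pooled
panel), not recomputed from detected species, so indeterminate cells do not
silently shrink it; the reciprocal is displayed truncated to four decimals
(1/845 → 0.0011) while internal arithmetic keeps full precision.

Group differences are tested with a one-way ANOVA followed by Tukey's HSD.
Both are computed from first principles — between/within sums of squares
and the studentized range distribution (`ptukey`), in the Tukey–Kramer form
because separation groups are unbalanced — and the test suite cross-checks
them against `stats::aov()` and `stats::TukeyHSD()` to 1e-8. Degenerate
inputs are defined: identical group means give F = 0; fully constant data
give an undefined F (reported `NA`); zero within-group variance with
non-zero between-group variance gives an infinite F with p = 0.

`concordance()` compares two call sets — e.g. the WSS calls against a
marker-gene method — and tallies agreement without adjudicating which
method is right when they differ.

## The synthetic cohort generator

The generator emulates the statistical structure of a twin strain-sharing
study, not its sequencing chemistry:

* **Population pool.** Per species, a random reference genome and a pool of
  strains, each mutated from the reference at half the target pairwise
  divergence so that two pool strains differ at ≈ divergence × length
  positions; alternate alleles are uniform over the three non-reference
  bases. Pool draws hand out *distinct* strains in random order: real
  human-population strain diversity is effectively unbounded, so unrelated
  individuals essentially never carry the identical strain, and a finite
  pool sampled with replacement would misrepresent that.
* **Twin dynamics.** Each pair is seeded with one shared strain per
  species. Over `s` years of separation each twin independently gains
  `Poisson(drift × length × s)` substitutions and, with probability
  `1 − (1 − r)^s`, has the strain replaced outright by a fresh pool draw.
  Replacement is all-or-nothing per twin and species — within-host strain
  mixtures are out of scope.
* **Observation.** Per-base depths are Poisson with configurable mean; a
  dropout probability zeroes positions outright; allele calls are masked
  wherever depth is zero. This is the simplest layer that exercises the
  breadth, mean-depth and window-depth filters together. There is no
  read-level simulation, no sequencing-error model beyond dropout, and no
  recombination or selection — the analysis consumes only site-wise
  concordance, which these omissions do not bias.

Identical parameter sets (including the seed) reproduce byte-identical
VCFs; the generator restores the caller's RNG state afterwards.

### Default study conditions

The defaults describe a realistic cohort at desk scale: 3 species of
100 kb each, a pool of 32 strains at pairwise divergence 1e-3
substitutions/base, within-lineage drift of 1e-6 substitutions/base/year,
strain replacement at 5%/year, ten twin pairs with separations
(0, 0, 1, 5, 7, 19, 25, 34, 47, 55) years spanning every interval bin,
depth mean 20 and 2% dropout. Drift and divergence are property-test
placeholders in a realistic range for gut commensals, not biological claims
about named species; the three-orders-of-magnitude gap between them is what
makes related and unrelated pairs identifiable, and the generator warns
when a parameterisation erodes that gap.

## Validation scenarios

Two fixed scenarios back the package's end-to-end claims; both run on one
CPU in a few minutes and their sizes are the package's own choice of desk
scale.

* **Recovery** (`evaluate_recovery()`): 50 seeded cohorts of 6 pairs × 2
  species, 100 kb genomes in one hundred 1 kb windows, depth mean 20,
  drift 1e-6/base/year over 1–10 years, divergence 1e-3, replacement
  8%/year so both truth classes occur. Cut-offs are re-estimated per
  replicate by the max rule; pooled sensitivity and specificity against
  simulator truth are both expected ≥ 0.95. Unrelated pairs differ at
  ≈ 100 of 100,000 positions, so roughly $1 - e^{-1} \approx 63\%$ of
  windows show a difference and unrelated scores cluster far below the
  ≈ 100% scores of shared lineages.
* **Separation trend** (`evaluate_separation_trend()`): 50 cohorts of 7
  pairs spanning the bins at a deliberately fast drift (2e-5/base/year)
  plus 2%/year replacement, so relatedness erodes within the observable
  window; the per-pair shared-strain fraction is regressed on the ordered
  bin index and the slope is expected negative (one-sided test).

Passing these shows the pipeline recovers truth under its own generative
model. It does not show robustness to what the generator omits: mixed
strains within a host, reference bias, alignment artefacts, compositional
dropout correlated along the genome, or indels mis-resolved by upstream
callers.

## Numerical and policy choices

* Thresholds are exclusive throughout (breadth > 0.30, depth > 3.5,
  score > cut-off, window low fraction > 0.5 to drop) — each mirrors an
  exclusion rule phrased as "below x is out".
* "Coverage" means breadth at depth ≥ 1; the depth floor is configurable
  where a different convention is needed.
* Window length is configurable and defaults to 1,000 bases; the score
  compares *all* both-called base-resolution positions, not variant sites
  only, which is the natural reading of gVCF input (both the length and the
  granularity convention travel with the configuration, not the code).
* Displayed truncation (two decimals for rates, four for multipliers) adds
  1e-9 before cutting to absorb binary floating-point representation
  error.
* Missing genotypes are distinct from reference calls: they are
  non-informative for identity but their depth still counts toward window
  usability.
* A VCF record with a call but zero depth is treated as no call — depth is
  the evidence the call rests on.

## Worked example

```{r example, eval = FALSE}
library(wsstrack)

params <- simulation_params(seed = 101)
sim <- simulate_twin_cohort(params, dir = "cohort")
res <- run_twin_pipeline(sim)

res$cutoffs
table(res$within$call)
summ <- build_summary_matrix(res$within, sim$cohort,
                             n_total_strains = params$n_species)
summ
cohort_group_stats(summ)$anova
```

The numbered scripts under `analysis/` run this same workflow stepwise
through the on-disk interfaces (VCF in, TSV out) and leave every
intermediate table under `results/`.

## Known limitations

Indeterminate cells are excluded from misclassification denominators and
confusion counts, which is correct for rates but means a cohort with heavy
QC failure can look deceptively clean; the counts of indeterminate units
are always reported alongside. The ANOVA treats fractions as continuous
although they are discrete multiples of the panel reciprocal — adequate for
the panel sizes the statistic is used with, coarse for very small panels.
The empirical max-rule cut-off is an order statistic and inherits its
variance; with few unrelated comparisons an upper quantile rule is the
steadier choice.
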