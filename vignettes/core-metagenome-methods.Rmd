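---
title: "Identifying a core carbohydrate-active metagenome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying a core carbohydrate-active metagenome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corecazyome)
```

## The question and the model

Replicate shotgun metagenomes from the same soil plot share surprisingly few
sequences: local spatial heterogeneity and undersampling of an enormously
diverse community mean that most assembled contigs are detected in some
replicates but not others. The *core* metagenome flips the usual
differential question around: which sequences are reliably present in
**every** replicate? Restricted to carbohydrate-active enzymes (the CAZy
classification: glycosyltransferases GT, glycoside hydrolases GH,
carbohydrate esterases CE, carbohydrate-binding modules CB, polysaccharide
lyases PL), the core is a candidate set of carbon-cycling functions required
in that soil.

The package implements this as a deterministic decision rule plus
supporting statistics, not a probabilistic occupancy model. A contig $c$ is
*present* in sample $s$ when

$$\max_i d_{c,s}(i) \ge m \quad \text{and} \quad \#\{i : d_{c,s}(i) \ge 1\} \ge \ell,$$

where $d_{c,s}(i)$ is read depth at position $i$, $m = 5$ and
$\ell = 100$ bp by default, and the core is
$\{c : \text{present}(c, s)\ \forall s\}$ over the replicate set,
intersected with the CAZy-annotated contigs. Using the *maximum* depth is a
deliberately liberal abundance proxy — it keeps low-abundance contigs with
one well-covered region eligible for the core, which suits a rule whose
point is a lower-bound inventory of shared sequences.

Two readings of the length rule exist: ≥ 100 *distinct* covered positions
(default) or a *contiguous* covered run of ≥ 100 bp
(`contig_coverage(..., contiguous = TRUE)`). The distinct-position count is
the weaker reading and the default; both thresholds combine with AND, and
both comparisons are inclusive, so a contig at exactly 5× over exactly
100 bp is present. Presence is monotone in the data and antitone in the
thresholds — raising $m$ or $\ell$ can only shrink the core — which the test
suite checks as a property.

## Annotation: best hit with reproducible random tie-breaking

Each contig inherits function (CAZy family) and taxonomy (phylum, domain)
from its best-scoring reference alignment among hits with E ≤ 1e-5.
"Best-scoring" means maximal bitscore: bitscores, unlike E-values, are
database-size independent, and exact ties in bitscore are common because
distinct reference proteins can produce identical alignments. Ties are
resolved uniformly at random; to make that reproducible without changing
its distribution, the tied candidates are first sorted by subject
identifier and a seeded draw picks one, so the outcome is independent of
input row order. The class of a family is its label prefix (GH13 → GH,
CBM50 → CB); anything unparseable is "unknown". Analysis is restricted to
bacteria, archaea, viruses and fungi — the filter drops, e.g., plant
reference proteins whose presence reflects database composition rather than
the soil community.

recA, a near-universal single-copy gene, is the per-sample normalizer: the
number of distinct sequences with a recA alignment at strict E < 1e-5
estimates the genome count sampled in that metagenome, and abundances are
reported as $\text{max\_cov} / \#\text{recA}$, "copies per recA". The CAZy
cutoff is inclusive (E ≤ 1e-5) while recA is strict (E < 1e-5); the
asymmetry is kept because the two rules are conventionally quoted that way,
and both are arguments.

## Replicate aggregation

Profiles sum copies-per-recA within each sample over the core contigs of a
group (class, family, phylum, or family × phylum — a contig's whole
abundance goes to its single best-hit category, no fractional assignment),
then report the across-replicate mean, $\mathrm{SE} = s/\sqrt{n}$, and the
95% CI using $t_{0.975, n-1}$ — with $n = 4$ replicates the normal quantile
would be badly anticonservative ($t = 3.18$ vs $1.96$). Both SE and CI are
emitted, since figures conventionally show mean ± SE while methods sections
quote CIs. With one replicate the dispersion is `NA`, never zero.
Prevalence (distinct core contigs per group) and abundance are conserved:
groups partition the core, unknown categories form an explicit group, so
group sums reproduce the per-sample totals exactly — an invariant the
acceptance suite checks at every level.

## The database-bias resampling test

Because core membership requires a CAZy hit, the core's category
composition could in principle echo database composition rather than
biology. The test: draw `n_draw` proteins (without replacement — distinct
proteins from a finite catalogue; `replace = TRUE` is available when the
pool is small) from a reference pool `n_rep` times, reduce each draw to
category frequencies, and measure the observed core's distance from the
null mean $\bar p$ by
$\chi^2(p) = \sum_k (p_k - \bar p_k)^2 / \bar p_k$ (categories with zero
null mean contribute nothing, so padding the universe with absent
categories leaves the statistic unchanged). The empirical p-value uses the
standard $+1$ correction, $(1 + \#\{r : \chi^2_r \ge \chi^2_{obs}\})/(R+1)$,
so it is never exactly zero. A named "ANOVA" on such distributions is
under-specified; the resampling construction above is distribution-free and
matches how the null is actually generated, so it is the default, with an
`ftest` mode providing per-category empirical two-sided p-values
(Bonferroni-corrected) for the category-by-category reading.

Calibration is checked by simulation in the acceptance suite: with the
observed set drawn from the same pool as the null (10 uniform categories,
pool 20,000, `n_draw` 5,000, `n_rep` 200, 400 outer replicates), the
type-I error at $\alpha = 0.05$ falls in $[0.03, 0.08]$ and the p-value
distribution is near-uniform (KS < 0.1). One subtlety: the reference mean
is computed from the null draws only, which inflates the observed statistic
by $O(1/R)$ relative to perfect exchangeability; at $R = 200$ the
simulations show the effect is within the calibration band, so the
standard nulls-only reference is kept. Power: doubling one category's
frequency (0.1 → 0.2 at `n_draw` 5,000) is detected at p < 0.05 in
essentially every run.

## k-mer core versus sequencing depth

Contig-level cores depend on assembly; the k-mer analysis asks the same
sharing question assembly-free. Per bootstrap, `subset_size` reads are
subsampled per sample without replacement, k-mers are canonicalized
(lexicographic minimum of a k-mer and its reverse complement — short-read
data are strandless), and the core fraction is
$|\cap_s K_s| / |\cup_s K_s|$. The union is the default denominator for
"total unique k-mers"; the mean per-sample count is available as an
alternative. $k = 20$ by default, matching the k-mer size used in the
upstream digital-normalization convention, and `n_boot = 4`. Reads are
sorted before subsampling so the estimate is invariant to read order, and
the returned object carries the subsampled read indices, so any bootstrap
can be recomputed independently — the tests use that to verify estimates
against a naive set computation. Reads shorter than $k$ are skipped with a
logged count.

## The synthetic community generator

The generator emulates the statistical structure of a replicated field
experiment — four replicate whole-soil metagenomes by default — with a
*planted, unambiguous* core:

* Per-contig, per-sample mean depth is lognormal (default
  `meanlog = 0.8, sdlog = 0.9`, a right-skewed distribution with most
  contigs at low coverage, the standard shape for metagenome contig
  abundance); per-base depth is the rounded mean with ±1 uniform jitter.
  Max depth and covered length are the only coverage features downstream
  analysis uses, so read-level simulation would add cost without adding
  test power.
* Core contigs draw their mean depth as `presence_min_cov` + lognormal, so
  they pass the depth rule in every sample (a guard bumps one position in
  the measure-zero case where jitter would hide the max), and the minimum
  contig length is required to be ≥ `presence_min_len`, so they pass the
  length rule.
* Every non-core contig fails the presence rule in at least one sample *by
  construction*: each sample fails independently with `dropout_rate`
  (default 0.3, with at least one forced failure per contig), and a failing
  sample either drops the contig entirely or caps its depth at
  `presence_min_cov − 1`. Truth is therefore exact and core recovery is
  tested by set equality, not approximately.
* Annotations draw classes, families-within-class and phyla from
  configurable frequency vectors (defaults give a Proteobacteria- and
  Actinobacteria-dominated community with ~5% plant-derived annotations to
  exercise the taxonomy filter, and class frequencies led by GT and GH);
  domains follow a built-in phylum → domain map.
* Synthetic alignment-hit files plant exact bitscore ties for
  `tie_fraction` of contigs (default 0.15); tied subjects share the winning
  annotation, so tie-breaking exercises the random-choice machinery without
  making truth seed-dependent. recA hit files contain exactly the configured
  count of qualifying queries plus one at exactly E = 1e-5, which the strict
  cutoff must exclude.
* Default per-sample recA counts are 100, 110, 120, 130 — unequal on
  purpose, so normalization errors would surface as profile distortions.

Everything is a deterministic function of (configuration, seed): fixtures
are byte-identical across runs, with per-purpose seeds derived from the
configured seed by a fixed scheme. What the generator does **not** emulate:
sequencing error, chimeric assembly, strain-level variation, GC or length
biases in coverage, or correlated community structure across replicates.
Passing tests therefore demonstrate correctness of the decision rules and
statistics, not robustness to assembly artifacts in real data.

## Numerical and design choices

* `core_fraction()` rounds half-up (0.45% → 0.5%), matching how percentages
  are conventionally quoted, rather than R's round-half-to-even.
* Duplicated (contig, position) depth rows keep the maximum depth and never
  double-count covered length; positions are 1-based.
* Sharing by coverage uses "present in ≥ 1 target replicate" by default
  (`min_samples` configurable); sharing by alignment counts a contig on
  *any* qualifying hit (E ≤ 1e-5, alignment length ≥ 70 columns — not query
  fraction — and identity ≥ 70%), with a best-hit-only mode as a flag.
  Group summaries label SE and SD explicitly rather than an ambiguous "±".
* Pipeline stages communicate only through written TSV/JSON files, so every
  stage can be re-run or audited independently; a global seed is split into
  per-stage seeds by a fixed derivation; the run manifest (parameters,
  input checksums, record counts, outputs) suffices to reproduce a run.
* Problem sizes in the shipped checks — 2,000-contig communities, 10,000
  contigs for frequency recovery, 400 outer replicates for test
  calibration, 150–250-read samples at k = 8 for k-mer oracles — were
  chosen as the smallest sizes at which the properties under test are
  sharp (set equality, 3-SE frequency bands, calibration within
  [0.03, 0.08]).

## Limitations

* The core rule is binary presence/absence at fixed thresholds; no
  uncertainty is attached to membership of contigs near the boundary.
* Taxonomy is only as good as the best-hit subject metadata; a single
  best hit can misassign mosaic or horizontally transferred genes.
* The k-mer core fraction depends strongly on read subset size and error
  content; it is a depth-sensitivity probe, not an estimator of a
  population quantity.
* Published headline counts from the original field study (e.g. 911 → 843
  core contigs of 226,887) depend on the real metagenomes and the live CAZy
  database; this package reproduces the *arithmetic and rules*, validated
  on synthetic communities, not those data-dependent numbers.
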