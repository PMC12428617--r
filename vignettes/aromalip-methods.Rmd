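---
title: "Screening, ROAV scoring and cross-omics correlation: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening, ROAV scoring and cross-omics correlation: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aromalip)
```

## The problem

Dry-cured meats owe their flavor to two interacting pools: volatile
compounds (aldehydes, alcohols, esters and others generated largely by
lipid hydrolysis and oxidation during long fermentation) and non-volatile
taste compounds (chiefly free amino acids from proteolysis). Instrument
output for the volatile side is a compounds × replicates table of GC-MS
peak areas; the lipid side arrives as shorthand species names with
relative abundances; the amino-acid side as relative contents. This
package implements the desk half of that workflow: quality screening,
odor-activity scoring, nomenclature parsing, taste annotation and
cross-block correlation.

## Screening semantics

Two per-compound filters precede everything else:

* **Detection rate** `> min_rate` (default 0.5): the fraction of replicate
  samples in which the compound's peak is present at all. Non-detection is
  encoded as `NA`, never 0 — a zero area means "not seen", and conflating
  it with a tiny area would bias both filters and the means below.
* **CV** `< max_cv` (default 0.30): sample standard deviation over mean of
  the *detected* areas. The n−1 (unbiased) standard deviation is used
  because replicate counts are small — four hams is typical — and that is
  the defensible default at small n. A compound with a single detected
  replicate has no defined CV and is removed, with a message.

Both comparisons are strict because the usual phrasing of these rules is
"greater than 50%" and "less than 30%"; an `inclusive` flag relaxes them
to `>=`/`<=` for users who read the boundaries the other way. Because both
filters depend only on per-compound statistics, they commute — a property
the test suite asserts on random tables.

**Relative content.** After screening, `C%` is each compound's mean
detected area as a percentage of the summed mean areas of *all retained
compounds*. The subsequent odor-threshold join drops compounds without a
threshold annotation but deliberately does **not** renormalize `C%`: the
denominator remains the full screened set. This matters in practice — in
the packaged ham reference table the 28 annotated compounds' `C%` values
sum to about 14.9%, because the screened set contained many more
(mostly flavor-irrelevant) compounds than the annotated subset. Any
pipeline that renormalized after the join could not reproduce such a
table.

**Name matching.** Peak tables and threshold databases rarely agree on
spelling. Joins run on canonicalized names (case-fold, trim, collapse
whitespace) through a packaged synonym map covering common alias pairs
("ethyl butyrate" / "Butanoic acid, ethyl ester", "valeraldehyde" /
"pentanal", ...). Users can extend or replace the map.

## ROAV

The relative odor activity value ranks compounds by flavor contribution.
The contribution kernel is `C%/T` — content over odor threshold — and the
compound maximizing it is the *standard*, whose ROAV is fixed at 100:

$$\mathrm{ROAV}_A = 100 \cdot \frac{C\%_A}{C\%_{stan}} \cdot \frac{T_{stan}}{T_A} \le 100.$$

"Greatest contribution" is operationalized as maximal `C%/T` because that
ratio *is* the ROAV kernel: with any other choice of standard, some
compound would exceed 100. On the packaged ham table this rule uniquely
selects 1-octen-3-ol (mushroom odor, `T` = 1 µg/kg, `C%` = 4.2624). Ties
are broken by canonical name order and logged. The standard's score is
assigned exactly 100 rather than recomputed, so floating-point noise never
produces 99.9999....

Categories use the standard bands: `ROAV ≥ 1` characteristic,
`0.1 ≤ ROAV < 1` modifier. A third band, *negligible* (< 0.1), is added
for completeness so the classification is total.

On the packaged reference table the `ROAV ≥ 1` rule retains 15 of the 28
tabulated compounds. The source study's narrative describes all 28
tabulated compounds as characteristic; applied to the tabulated scores
themselves, the stated rule yields 15 (13 compounds have ROAV far below
0.1). The package implements the rule as stated and reports the count the
rule produces; the discrepancy is asserted in the test suite as a
documented inconsistency rather than silently matched in either
direction.

**Reproduction tolerance.** The packaged table's `C%` column is printed
at four decimals. Recomputing ROAV from those rounded inputs can differ
from the published scores by up to the propagated input rounding,
roughly `0.5e-4 / C%_A + 0.5e-4 / C%_stan` in relative terms — negligible
(≪ 0.5%) for every compound with `C% ≥ 0.05`, but a few percent for trace
compounds printed as, say, 0.0003. The acceptance tests therefore hold
well-determined rows to 0.5% relative and trace rows to the propagated
rounding bound; nothing tighter is attainable from the printed inputs.

**Class composition.** Integer percentage shares of chemical classes are
computed by the largest-remainder method, which is the only way to make
rounded integer shares sum to exactly 100. Leftover points go to the
largest fractional remainders; remainder ties are broken by descending
count, then name. On the published volatile-class counts
(15/19/9/10/13/14, total 80) this reproduces the published shares
19/24/11/12/16/18 exactly — including the tie between the ester (12.5)
and other (17.5) remainders, which resolves toward the larger class.

## Lipid shorthand grammar

`parse_lipid()` accepts `ClassCode '(' ChainSpec (Sep ChainSpec)* ')'`
with `Sep` either `_` (sn-positions unknown) or `/` (known), and
`ChainSpec = [O-|P-] carbons ':' double_bonds (';' token)*`. Oxygenation
tokens (`O`, `2O`, `O2`, `3O`, ...) are normalized to an extra-oxygen
count — shorthand dialects disagree on digit placement, so `O2` and `2O`
are the same modification. A single chain spec with no separator is a
sum-composition (species-level) name. Spaces after `:` and `;`, which
typesetting tends to introduce, are stripped before parsing.

Two deliberate choices favour losslessness over speculation:

* Unrecognized suffix tokens (e.g. the `T` in `ST(24:1;O3;T/20:1)`) are
  preserved verbatim in `extra_tokens` instead of failing the parse or
  being guessed at.
* `format_lipid()` emits a canonical compact form, and the round trip
  `parse(format(x))` is structurally identical to `x` — asserted for the
  14 reference names and for 1000 grammar-fuzzed names per test run.

The default class registry maps codes to the six top-level categories
(GL, GP, SP, FA, ST, PR). Two assignments are genuinely convention-bound
and therefore configurable rather than hard-coded: `PE-Cer` sits under SP
(it is a ceramide backbone, not a glycerophospholipid), and `NAGly`
(N-acyl glycine) under FA, both following the LIPID MAPS convention.
Key-lipid selection defaults to the top 14 species by mean relative
abundance — a simple, deterministic criterion with name tie-breaks;
14 mirrors the reference study's key-lipid count.

## Amino acids

Taste annotation is a lookup against a packaged map covering the 20
proteinogenic amino acids plus L-ornithine, L-citrulline, 4-aminobutyric
acid and beta-alanine. The fixed points are L-alanine = sweet, L-lysine =
sweet-bitter, L-valine = neutral; the remainder follow standard
flavor-chemistry classes and every entry is user-overridable. Key amino
acids are those with relative content `>= 40` (inclusive) on the input's
own unit scale, applied to the mean across samples when several sample
columns are present. Units are carried as opaque labels and never
rescaled silently. Selection is monotone in the cutoff, which the suite
checks property-style.

## Correlation

`block_correlate()` computes all pairwise Pearson correlations between
two feature × sample blocks over their shared samples,
pairwise-complete on missing values, with p from the exact t transform
`t = r·sqrt((n−2)/(1−r²))` on n−2 degrees of freedom. Benjamini–Hochberg
adjustment across the whole grid is on by default — a 14 × 28 grid of
unadjusted p-values invites over-reading — and can be disabled to mirror
analyses that report raw p-values. Zero-variance features are excluded
with a message (their correlation is undefined), pairs with fewer than 3
complete observations are suppressed, and runs with ≤ 5 shared samples
are flagged low-power: with n = 4 replicates, |r| must exceed 0.95 for
p < 0.05, so at that scale the sign pattern is the informative output.

## Synthetic data: what it emulates and what it does not

The generators provide ground truth for every stage:

* `generate_peak_table()`: log-normal replicate areas with arithmetic
  mean proportional to the true relative content and arithmetic CV equal
  to `replicate_cv` (`sdlog² = log(1+cv²)`), plus Bernoulli detection
  dropout encoded as `NA`. With `cv = 0, dropout = 0` screening recovers
  the true contents exactly, which anchors the pass-through tests.
  Defaults mirror the reference study's conditions: 4 replicates;
  CV and dropout default to mild values (0.1, 0) and are explicit
  arguments, since the study reports only the post-hoc filter bounds
  (CV < 0.30), not the underlying noise level.
* `generate_lipid_table()`: names drawn from the class grammar with
  user-specified class weights (e.g. the reference study's
  TG 25.29% / DG 13.43% / DGCC 8.47% shares); every generated name
  parses, and at n = 10,000 the empirical class frequencies sit within
  ±3% of the weights.
* `generate_correlated_blocks()`: bivariate-normal latent pairs whose
  population correlation equals `target_r` exactly; `|r| = 1` is
  constructed affinely and recovered exactly. Blocks are shifted to mean
  10, sd 1 — Pearson r is affine-invariant, so the planted value is
  untouched; values are not truncated at zero because truncation would
  bias the planted correlation.

Every generator takes an explicit seed, runs in a private RNG stream
(the caller's `.Random.seed` is restored), and is bit-reproducible.

What the generators do *not* emulate: chromatographic artifacts
(retention drift, co-elution, baseline), inter-compound abundance
correlation within a block, heavy-tailed contamination, or any
relationship between a lipid's structure and its abundance. Passing tests
therefore demonstrate correctness of the *computations* under controlled
noise, not robustness to every pathology of real instrument data.

## Numerical conventions and problem sizes

* Screening/ROAV arithmetic is double precision throughout; exports
  default to full precision (`C%` sums to 100 within 1e-12 in tests).
* The standard's ROAV is exactly 100 by assignment; all other scores are
  computed.
* Test problem sizes: 100 random tables of ≤ 20 compounds × 4 replicates
  for the brute-force screening equivalence; 1000-name parser fuzzing;
  100 seeds × 200 samples for planted-correlation recovery; 10,000 draws
  for class-frequency checks. These sizes give stable Monte-Carlo
  estimates (recovery of r = 0.8 within ±0.05 of the mean) while keeping
  the full suite under a minute.

## Known limitations

* ROAV is a *relative* measure; absolute odor-activity values would need
  absolute concentrations and are out of scope.
* The threshold database is only as good as its provenance; thresholds
  vary by matrix and the packaged values apply to a ham-like matrix.
* The lipid parser handles shorthand nomenclature, not systematic names,
  and does not attempt isomer resolution or mass computation.
* With four replicates, correlation p-values are reported for
  completeness but are underpowered; treat sign structure, not
  significance stars, as the result at that scale.
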