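---
title: "Scanning vitamin D response elements and scoring regulatory variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning vitamin D response elements and scoring regulatory variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdrescan)
```

## The problem

Antithrombin deficiency is usually explained by coding mutations in
*SERPINC1*; when it is not, the gene's regulatory regions become the
suspects. DR3-type vitamin D response elements (VDREs) — two hexamer
half-sites for the RXRα/VDR heterodimer separated by a 3 bp spacer, 15 bp
in all — are one concrete regulatory signal a variant can destroy or
duplicate. This package chains together the four quantitative steps such a
study needs: finding candidate elements with a position weight matrix,
rescoring mutant alleles, testing carrier status against plasma anti-FXa
activity in a cohort, and quantifying a vitamin D dose response by qPCR.

## Motif model

A JASPAR-style count matrix $c_{b,i}$ (bases $b \in \{A,C,G,T\}$,
positions $i = 1..L$) becomes a log-odds weight matrix against a
background $q_b$ with pseudocount $p$:

$$ w_{b,i} = \log_2 \frac{c_{b,i} + p\,q_b}{(N_i + p)\,q_b}, \qquad
   N_i = \sum_b c_{b,i}. $$

A window scores the sum of its per-position weights (bits); the
**relative score** rescales it to percent of the achievable range,
$100\,(s - s_{\min})/(s_{\max} - s_{\min})$, which is the scale scan
thresholds live on. Defaults: uniform background, pseudocount 0.8 (the
common choice in the JASPAR ecosystem), threshold 70% with 80% as the
stricter preset. All three are arguments, not constants: the exact
smoothing used by any given web tool is rarely recoverable, so small
offsets against scores printed elsewhere are expected.

Scanning covers both strands; a reverse-strand hit reports the
reverse-complemented site in motif orientation and the window's forward
start. Windows containing non-ACGT bases are skipped and counted in a
message rather than scored — inventing a score for an ambiguous base would
only look like information. Internally all coordinates are 0-based
half-open; the TSV writer emits 1-based inclusive coordinates.

The packaged matrix (`dr3_matrix()`) is a *synthetic* DR3-style matrix:
two AGGTCA-like half-sites around an uninformative spacer, 20 counts per
column. It has the canonical structure and information content of an
RXR/VDR matrix but is not a database entry, and the file and its header
say so. Scores quoted from real-matrix analyses (e.g. bit scores of
specific genomic elements) are therefore not reproduced here; runs against
the real matrix and reference sequence use `read_jaspar()`,
`read_fasta()` and `read_gene_model()` on user-supplied files and take the
identical code path.

## Variant coordinates and allele rescoring

The clinical shorthand in this domain anchors positions two ways:
`c.1-N` means N bp upstream of the translation start (synonymous with
standard HGVS `c.-N`; both parse), and `c.42-N` means N bp upstream of
the first base of exon 2 — valid because exon 1 carries coding positions
1–41. The parser handles SNVs, duplications, deletions and insertions,
with ranges like `c.42-1060_-1057dupTTGA`. Duplications insert the new
copy immediately 3′ of the duplicated interval, the HGVS convention.
Stated reference bases are verified against the sequence at application
time; a mismatch is an error quoting expected vs found. Reverse-strand
gene models are implemented but flagged experimental — every fixture here
is a forward-strand gene.

`assess_variant()` scans a padded window around the variant locus in both
alleles without a threshold, then asks two questions:

1. Does any above-threshold hit overlap the locus in either allele? If
   not, there is no element to disturb: the change is 0 and the category
   `none`. (This also covers the corner case of a no-op substitution
   sitting inside a hit: nothing changed, so nothing is reported as
   disrupted.)
2. Otherwise the best-scoring overlapping hit of each allele is compared:
   `pct_change = 100 (s_wt − s_mut)/s_wt`, positive when the variant
   weakens the site. For insertions and duplications the mutant locus is
   widened by the inserted length so shifted copies still count as
   overlapping, and when the mutant allele carries strictly more
   above-threshold hits over the locus than the wild type the category is
   `creates/duplicates`.

`pct_change` uses the raw log-odds score by default; reports of percent
score reductions in the literature do not always state whether they are
on the raw or the min-max scale, so `score_scale = "relative"` is
provided and both were checked to behave identically on the fixtures'
categorical calls. When the wild-type best score is non-positive the
ratio has no meaningful sign and the change is reported as undefined.
Ties in best-hit selection break by smaller start, then forward strand.

## Cohort statistics

Allele frequency is the unrounded $({\rm het} + 2\,{\rm hom})/(2n)$;
published values rounded to 3 decimals (0.008 for 5/614, 0.013 for
8/614) follow by rounding. The Hardy–Weinberg exact test conditions on
the allele count and sums the probabilities of all heterozygote counts no
more probable than the observed one.

The dominant-model comparison contrasts carriers (1 or 2 minor alleles)
with non-carriers on anti-FXa activity. Both the pooled-variance and the
Welch t-test are returned, from raw data (`dominant_ttest()`) or from
published group summaries (`ttest_from_summary()`); with 8 carriers at
90.7 ± 6.5 against 299 non-carriers at 96.4 ± 7.5 the Welch p rounds to
0.04 while the pooled p is 0.03 — reporting both avoids guessing which
row of a statistics package's output a paper quoted. "Adjusted t-test" is
implemented as ordinary least squares on a carrier indicator plus
covariates (age, sex, and the background intron-1 polymorphism rs2227589
coded dominantly, mirroring the tested variant); with no covariates this
reproduces the pooled t-test exactly, which is tested. Missing genotypes
are dropped listwise per analysis.

The reference-pool interval uses the normal quantile,
$\bar{x} \pm 1.959964\,s/\sqrt{n}$, which reproduces the published
[95.8–98.4] for $n=100$, 97.1 ± 6.6; a t-quantile option exists and is
slightly wider.

## qPCR quantification

Relative expression is $2^{-(CT_{\rm target} - CT_{\rm reference})}$
against the internal control gene (β-actin in the motivating experiment).
Replicates aggregate by geometric mean — the arithmetic mean of ΔCT —
because the quantity is exponential in the measurement; the arithmetic
option is kept for comparison. Fold change versus the untreated dose is
the ratio of aggregated relative expressions (exactly $2^{-\Delta\Delta
CT}$ for single replicates) with a first-order propagated standard
deviation. Dose dependence is tested by regressing per-replicate log2
relative expression on the numeric dose (0/40/80/106 ng/ml paricalcitol —
the ng/ml reading of the dose ladder is used throughout); the log scale
matches fold-change semantics. Three distinct doses are the minimum for a
trend.

## Synthetic data: what it emulates, what it does not

Every generator is a pure function of its arguments and a seed, and each
returns a machine-readable truth record that downstream tests read their
expectations from.

- `simulate_background()` draws i.i.d. bases at a target GC (default
  0.40, a realistic genomic figure for these loci).
- `plant_motif()` starts from the consensus and greedily applies the
  single-base substitution landing closest to the target relative score
  without undershooting the tolerance band, so planted elements have
  controlled strengths (the defaults span 75–92%, bracketing the 70/80%
  working thresholds).
- `simulate_gene_fixture()` assembles the study-shaped toy gene — 1.5 kb
  promoter, 41 bp exon 1 (anchoring `c.42-N`), 2 kb intron 1, 150 bp
  exon 2, 1 kb intron 2 — plants five elements (two promoter, two
  intron 1, one intron 2) and derives three variants whose expected
  categories (`none`, `disrupts`, `creates/duplicates`) mirror the
  motivating study's promoter SNV and the two intron-1 duplications. The
  background is locally resampled until no window outside the planted
  sites clears the working threshold; this guarantee — the plant list
  *is* the above-threshold inventory — is what makes the truth record an
  oracle, and it is a design property of the generator, not a
  post-processing step of any test.
- `simulate_cohort()` draws genotypes under Hardy–Weinberg at the target
  MAF and builds the trait as baseline + carrier effect + covariate terms
  + Gaussian noise. Defaults mirror the motivating cohort: n = 307,
  baseline 96.4%, carrier effect −5.7 percentage points, residual sd 7.4
  (the published non-carrier spread), age ≈ 43 ± 12, 45% male, background
  polymorphism at MAF 0.10; covariate effects are small and documented in
  the function signature.
- `simulate_qpcr()` gives the reference gene a fixed CT and each target a
  CT of base − log2(fold(dose)) + noise (sd 0.15 cycles, 6 replicates by
  default). The default fold maps are log-linear in dose and reach
  1.5-fold (*SERPINC1*-like) and 2-fold (*VDR*-like) at 106 ng/ml.

What passing tests on these fixtures shows is that the *computations* are
correct: the scanner equals a brute-force rescoring oracle, impact calls
match an independent two-allele rescan, the association model recovers
planted effects at the right error rates, and the CT pipeline inverts the
generator. What they cannot show is anything about real sequence:
background DNA is not i.i.d., real binding sites do not tile a clean
threshold gap, cohort traits are not exactly Gaussian, and amplification
efficiency in real qPCR is not exactly 2 per cycle (no standard-curve
calibration is attempted). Conclusions about a real gene require the real
inputs through the same readers.

## Numerical choices and degenerate inputs

- Relative scores are clamped to [0, 100]: vectorized window sums can
  land a rounding error outside the achievable range at its exact
  endpoints.
- Consensus ties break alphabetically (A < C < G < T); best-hit ties by
  start, then forward strand — all deterministic.
- A zero-total matrix column with zero pseudocount, a degenerate
  min = max score range, reversed variant ranges, offset-0 coordinates
  (`c.1-0`), reference-base mismatches, groups of size < 2, collinear
  design matrices, non-positive CTs, and fold maps ≤ 0 are all explicit
  errors rather than silent NA paths.
- Report JSON is written with sorted keys and fixed precision so repeated
  runs are byte-identical.

## Problem sizes

The test and acceptance workloads are sized for a laptop-class single
core: brute-force scanner comparisons on 200 random matrix/sequence pairs
up to 2 kb, type-I error over 10,000 null cohorts of n = 300, qPCR
recovery over 1,000 simulated plates, and the full fixture pipeline in
seconds. These sizes give Monte-Carlo standard errors comfortably inside
the asserted bands (e.g. ±0.0022 on a 0.05 rejection rate estimated from
10,000 draws, against a ±0.01 acceptance band).

## Known limitations

Single-matrix engine (no multi-matrix databases, no higher-order
backgrounds); no full HGVS grammar (four variant kinds, no p./g./r.
notation); no haplotype or compound-variant modelling; no
binding-affinity thermodynamics; no amplification-efficiency calibration;
reverse-strand gene models are untested against real data and flagged
accordingly.
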