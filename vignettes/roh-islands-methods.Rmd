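---
title: "Methods: ROH detection, island calling and validation in rohscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH detection, island calling and validation in rohscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
```

`rohscan` implements the SNP-array workflow for detecting runs of
homozygosity (ROH) and ROH islands in a livestock population. This vignette
is the package's account of the underlying methods: the models and
procedures, the parameters that matter and why their defaults are what they
are, the numerical and design choices that were genuinely open, and what the
synthetic validation does and does not demonstrate.

## The genotype model

Every stage consumes a `genotype_dataset`: ordered samples, an ordered
marker map (chromosome, id, cM, physical bp), and a samples × markers matrix
of codes 0 (hom A), 1 (het), 2 (hom B), NA (missing). The A/B orientation of
a marker is arbitrary — it is fixed at load time by first-seen allele order
in the PED file — and every downstream computation depends only on the
hom/het/missing trichotomy, a property the test suite asserts by flipping
orientations and comparing detector output.

One subtlety follows from the first-seen recoding rule: a marker whose first
non-missing call is the code-2 homozygote cannot survive a write/read round
trip unchanged, because the reader must assign code 0 to the first allele it
encounters. We therefore define a *canonical orientation* (first non-missing
call is code 0 or heterozygous); `read_ped_map()` always produces it,
`canonicalize_alleles()` converts to it, the simulator emits it, and
round-trip identity is guaranteed — and tested — on canonical datasets.
Coordinates are 1-based physical bp throughout, matching the MAP convention;
BED gene tracks are converted from 0-based half-open on import.

## Quality control

Three filters run in a fixed order: per-sample call rate (default ≥ 0.90),
per-SNP call rate (≥ 0.90), then an exact Hardy–Weinberg test (reject at
p < 10⁻⁶). The order matters — removing a low-call-rate sample can rescue a
marker's call rate — and is covered by a dedicated test. The filters run as
a single ordered pass, not iteratively: a second pass removes nothing on
typical data (idempotence is tested), and iterative re-filtering has no
accepted semantics in standard array QC.

The HWE test is implemented in the package rather than delegated: it is the
two-sided exact test conditional on allele counts, summing the conditional
probabilities of all heterozygote counts whose probability does not exceed
the observed table's (ties included, with a 10⁻⁹ relative guard against
floating-point inequality of mathematically equal terms). Probabilities are
computed through log-factorials, max-shifted and normalized, so the test is
exact to floating precision at any realistic sample size. The suite checks
it against an independent direct-enumeration oracle on every genotype table
with up to 40 alleles, against a value frozen from exact rational
arithmetic, and against the 1-df chi-square asymptote. A practical caveat
discovered in that comparison: at n = 1,000 genotypes the discreteness of
the exact test still leaves gaps near p ≈ 0.75 of ~0.05 relative to the
chi-square value; agreement within 0.02 only sets in around n ≳ 5,000. The
asymptote test is therefore asserted on large tables, together with the
monotone convergence of the gap.

No minor-allele-frequency filter is applied: the workflow this package
implements uses none, and a MAF filter would bias ROH detection by removing
exactly the low-diversity markers that runs are made of.

## Minimum-SNP calibration

Short chance runs of homozygosity arise constantly; the guard is the
smallest SNP count `l` such that the expected number of chance runs across
`n_s` SNPs × `n_i` individuals stays below `alpha`:

$$ l = \left\lceil \frac{\ln(\alpha / (n_s\,n_i))}{\ln(1 - \bar h)} \right\rceil $$

with `mean_het` (h̄) the mean per-SNP heterozygosity. The ceiling is taken
because `l` is a minimum count (a fractional run length is not observable),
with a 10⁻⁹ guard so that exactly-integer quotients are not rounded up; the
result is floored at 1. `mean_heterozygosity()` computes h̄ as the mean over
markers of the heterozygous fraction among non-missing calls, the reading
consistent with "average heterozygosity over all SNPs"; h̄ can also be
supplied explicitly. Note that published applications of this formula do not
always report h̄, and reported `l` values cannot generally be reproduced
without it; `rohscan` therefore always reports the `l` it used (as an
attribute of the detection result and in the pipeline log).

## ROH detection

Detection is the consecutive-SNP (sequential) method, not the sliding-window
score: per individual and chromosome, a candidate run grows across markers
in map order while cumulative heterozygous calls stay ≤ `max_het_in_run`
(default 1), cumulative missing calls ≤ `max_missing_in_run` (default 1),
and each inter-SNP gap ≤ `max_gap_bp` (default 1 Mb). Runs are trimmed to
homozygous endpoints — a run flanked by a heterozygote should not claim that
SNP's position — and emitted if they span at least `min_snps` markers and at
least `min_length_bp` (default 500 kb, set above the reach of background
linkage disequilibrium so that short LD-driven homozygous stretches do not
qualify). Length is `end_bp − start_bp`, the distance between the first and
last SNP of the run; this convention is fixed by the published island tables
the descriptive statistics reproduce.

The implementation computes, for each homozygous start, the furthest
extension compatible with the allowances in O(1) from cumulative counts (the
extension point is monotone in the start, and gap-bounded blocks are split
off first), then keeps the earliest start per trimmed end. The emitted set
is exactly the set of *maximal qualifying windows*: no emitted run is
contained in another qualifying run, but two partially overlapping maximal
runs of one individual can both appear (e.g. when the heterozygote allowance
can be spent on either flank). An O(m²) brute-force enumeration oracle
verifies this equivalence on hundreds of randomized chromosomes and
configurations in the acceptance suite. The allowances (1 het, 1 missing)
exist to keep single genotyping errors from fragmenting long runs; the
simulator's error-rate sweep shows detection power degrading monotonically
once the error load per run exceeds the allowance.

## Islands

Island support at a marker is the fraction of *all* retained individuals —
not just those carrying any ROH — whose ROH covers the marker's position
(closed interval on trimmed run boundaries, marker-level rather than
bp-level, matching the per-SNP support plots and SNP-count columns of the
field's island tables). Islands are maximal runs of consecutive qualifying
markers at a support threshold: 0.5 by default (majority of the breed), 0.7
as the stricter variant. Deliberately, *no* minimum length or SNP count is
applied to islands, and adjacent qualifying markers merge regardless of gap
size — the only size filtering in the workflow happens at run detection.
Lowering the threshold never shrinks an island (tested monotonicity), and
island calling is idempotent.

## Descriptive statistics

`summarize_length_classes()` bins lengths into half-open Mb classes and
reports count, percent, mean, SD, min, max per class plus a totals row. SD
uses the n − 1 sample denominator — verified against the published class
summary it reproduces (sample SD of the eight 0.5–1 Mb island lengths is
0.16707 → printed 0.167; the population SD would give 0.156). For
single-member classes the SD is reported as NA: published tables sometimes
echo the single value in the SD column, which we consider indefensible. The
percent denominator defaults to the input count but can be overridden
(`total_n`) when summarizing a tabulated subset of a larger collection —
exactly the situation with published island tables that list only the
islands above 0.5 Mb.

`chromosome_coverage()` reports per-chromosome run counts and the percentage
of the chromosome covered, computed per individual (union of that
individual's runs, so overlapping maximal windows are not double-counted)
and averaged over all retained individuals. The chromosome extent
denominator is the last mapped SNP position — assembly lengths are not part
of the input — and can be overridden. Mean-per-individual coverage was
chosen over pooled coverage (total ROH bp / (n × extent)); the two coincide
whenever every individual is retained, which is why the test fixtures
exercise both readings.

## Gene annotation

Islands are intersected with a BED3+ gene track via GenomicRanges. The
default mode is `overlap` (any shared bp, closed intervals), because island
gene lists in this literature include genes "within or in close proximity";
`contained` requires the gene fully inside the island, and `flank_bp` pads
islands symmetrically for an explicit proximity radius (default 0, since no
radius is canonical). Containment-mode gene sets are provably subsets of
overlap-mode sets, and both are verified against an all-pairs brute-force
intersection on random fixtures.

## Association

The regressor at each marker is the 0/1 ROH-coverage indicator — the scan
asks where *being autozygous* moves the trait, which is the stated aim of
ROH–phenotype analysis; a genotype-dosage matrix can be passed instead for
the alternative reading, since the OLS core accepts any numeric regressor.
The fit is closed-form simple regression with a two-sided t-test at
n − 2 df; for a binary regressor the slope equals the difference of
phenotype group means (asserted as an exact identity), and `lm()` serves as
the independent oracle in tests. No covariates are fitted by default — the
design cohort is same-sex, same-age, single-herd contemporaries — and no
kinship correction is attempted (out of scope). Markers with fewer than 5
phenotyped samples in either state (configurable) are skipped with a logged
reason; zero-residual-variance fits are flagged `degenerate` with p = NA
rather than reported as infinitely significant. The default significance
threshold is the literature constant 1.5 × 10⁻⁶, kept verbatim as a default
(it is not 0.05 divided by any panel size used here) and overridable with
`0.05 / n_tests`.

## The synthetic cohort: what it shows and what it cannot

`simulate_population()` draws marker positions uniformly per chromosome,
minor-allele frequencies uniform on [0.05, 0.5], and background genotypes
from per-marker Hardy–Weinberg proportions, *independently across markers —
there is no linkage disequilibrium*. Planted autozygous segments overwrite a
random ⌈carrier_fraction · n⌉-subset of individuals with per-marker
major-allele homozygotes (autozygosity is about homozygosity, not haplotype
identity, so carriers need not share alleles across markers); a
heterozygous-error process (default 0.002) and missingness (default 0.005)
are then applied everywhere, and an optional phenotype adds per-segment
carrier effects to Gaussian noise. One integer seed drives all draws;
identical seeds give byte-identical PED/MAP output.

The defaults emulate the study design this workflow targets: 189
individuals, three 50 Mb chromosomes × 2,000 markers (≈ 25 kb spacing, the
density of a ~150K array on a ~2.7 Gb genome — panels are scaled down, not
sparsified, so per-run SNP counts stay realistic). The validation suite
plants a 1.5 Mb segment at 60% carrier fraction in 100 individuals and
requires the pipeline to call exactly one island at 50% support overlapping
it — and none at 70% — in at least 19 of 20 seeds; association calibration
requires the null false-positive rate at p < 0.05 to be 0.05 ± 0.02 and a
1.5σ planted effect at n = 189 to be the scan's top hit in at least 18 of 20
seeds.

Passing these tests shows the machinery is correct *under the model's
assumptions*. Real SNP-array data differ in ways the simulator deliberately
omits: LD makes neighbouring markers correlated (hence more, shorter chance
runs than the independence model predicts — the 500 kb floor exists for
exactly this reason), real autozygous segments have an exponential length
distribution from pedigree depth rather than fixed planted lengths, allele
frequencies are not uniform, and genotyping artefacts cluster by batch and
probe rather than falling independently. Counts observed on real data
(numbers of islands, of post-QC SNPs, of annotated genes) therefore cannot
be reproduced from synthetic cohorts and are not asserted anywhere; what is
asserted is the arithmetic of every published worked example that depends
only on printed numbers, plus the behavioural properties above.

## Numerical choices and degenerate inputs

* Exact-integer quotients in the minimum-SNP formula are protected from
  float round-up by a 10⁻⁹ slack under the ceiling.
* HWE tie detection uses a 10⁻⁹ *relative* tolerance; the conditional
  distribution is renormalized after a max-shift, and the enumeration's
  probabilities are checked to sum to 1 within 10⁻¹² in the oracle.
* Zero-residual association fits: flagged, never 1/0.
* Empty inputs: empty segment lists yield zero-support profiles, empty
  island sets, zero totals; an empty length list yields an all-NA totals
  row with n = 0; a 0-sample dataset writes a valid empty PED.
* Ties in island support exactly at the threshold qualify (≥, not >).
* Duplicate marker positions on a chromosome are rejected at load; marker
  sorting is natural-numeric for integer chromosome labels.

## Problem sizes

The shipped validation runs at sizes chosen to exercise every code path
while keeping the full suite around a minute and a half on one core: 200
randomized oracle-equivalence chromosomes of up to 200 SNPs, exhaustive HWE
enumeration to 40 alleles, 20-seed island-recovery replicates at 100 × 2,000
markers, and 20-seed association calibration at 200 × 1,000 plus power at
189 × 2,000. The acceptance script's synthetic cohort is 189 × 6,000
markers. All sizes are configuration, not constants; nothing in the
implementation assumes them.

## Known limitations

Sliding-window (score-based) ROH detection, genetic-map-distance run
lengths, ROH-based inbreeding coefficients, kinship-corrected association,
coalescent simulation of realistic ROH length spectra, and gene-ontology
enrichment of island genes are all out of scope. The island support
denominator counts all retained individuals; populations with substructure
would need stratified support, which is not provided.
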