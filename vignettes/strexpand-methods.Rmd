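---
title: "Detecting rare STR expansions with strexpand: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting rare STR expansions with strexpand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strexpand)
```

## The method in one page

Short tandem repeat (STR) expansions that exceed the read length defeat
ordinary variant callers: the expanded allele produces reads that are
nearly pure repeat, which aligners mis-place or discard. `strexpand`
detects such expansions genome-wide in four stages.

**Decoy chromosomes.** All repeat units of 1–6 bp are grouped by circular
permutation and reverse complement; each class keeps its
lexicographically smallest member, and classes that are tandem multiples
of a shorter unit are removed. This yields 501 canonical units
(`enumerate_canonical_units(6)`), each written as a pure 2000 bp tandem
repeat named `STR-<unit>` and appended to the reference
(`augment_reference()`). A read composed mostly of one repeat finds its
longest exact match on the corresponding decoy, so decoy-mapped reads
mark repeat-derived fragments. The 2000 bp default comfortably exceeds
typical fragment lengths and is configurable.

**Allocation.** A decoy-mapped read says *which motif* it came from but
not *where*. Its mate, sequenced from the unique flank of the same
fragment, says where: the read is assigned to the closest annotated locus
with the same canonical unit whose edge-to-edge distance to the mate's
interval is at most `max_dist` (default 500 bp, matching the fragment
lengths of standard libraries). Reads whose mate is unmapped, itself on a
decoy, or not near any same-unit locus stay unassigned (per unit), and
the per-unit total of assigned + unassigned always equals the decoy
count — an invariant asserted throughout the tests. Close same-unit locus
pairs are the one route to misallocation; `proximity_fraction()`
quantifies how rare they are in a given annotation.

**Outlier statistics.** Raw counts are normalized to a nominal 100×
coverage, $y = \log_2(100\,(n+1)/\text{median coverage})$, so samples of
different depth are comparable and zero counts stay finite. Control
samples define a per-locus null via Huber's Proposal-2 joint M-estimates
of location $M$ and scale $\sigma_M$, and each tested locus receives

$$z = \frac{y - M}{\sigma_M},$$

a one-sided upper-tail normal $p$ (only *more* repeat reads than
controls is of interest), and Benjamini–Hochberg adjustment across the
loci tested in that sample (those with at least one assigned read). A
locus is significant when the adjusted $p$ falls below `alpha` (default
0.05).

**Sizing.** The number of reads allocated to a locus grows with the
length of the expanded tract. On simulated expansions the relationship is
linear on the log-log scale, so an ordinary least-squares fit
$y = \beta_0 + \beta x + \varepsilon$ (with $y$ the normalized log2
coverage and $x = \log_2$ inserted bp) can be inverted:
$\widehat{\text{bp}} = 2^{(y - \hat\beta_0)/\hat\beta}$, reported both as
inserted bases and as total repeat units.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `decoy_length` | 2000 bp | length of each decoy chromosome; must exceed the insert size |
| `flank` | 800 bp | widening of annotated loci when extracting candidate read pairs |
| `max_dist` | 500 bp | maximum mate-to-locus gap during allocation |
| `tuning_k` | 1.5 | Huber winsorization constant |
| `scale_floor` | 0.01 | minimum $\sigma_M$ on the log2 scale |
| `alpha` | 0.05 | adjusted-p significance threshold |
| `str_fraction` | 0.9 | simulator: repeat fraction at which a read routes to the decoy |

Distances are edge-to-edge gaps between intervals (0 when overlapping),
the most permissive reading consistent with mate positions reflecting
fragment length; equidistant candidate loci are broken toward the smaller
start coordinate so allocation is deterministic. All coordinates are
0-based half-open (BED convention) everywhere, including reports, which
state the convention in a header comment.

## Numerical and design choices

**Huber variant.** The joint location/scale fixed point ("Proposal 2")
iterates winsorizing at $M \pm k\sigma$, re-averaging, and rescaling the
winsorized variance by the normal consistency factor
$\beta = 2[(\Phi(k)-\tfrac12) + k^2(1-\Phi(k)) - k\phi(k)]$.
Initialization is median / normalized MAD, falling back to the standard
deviation when the MAD is zero. Convergence is declared when both
location and scale move by less than `tol` relative to the scale
(default `1e-6`, at most 50 iterations); on non-convergence the estimator
falls back to the median and MAD with a warning. Two degeneracies are
handled explicitly: if all values coincide the scale is reported at the
floor directly, and if the scale iteration collapses toward zero (more
than half the values identical — beyond the estimator's breakdown point)
the location settles on the median and the floor applies. The floor
matters: a locus whose controls all have identical counts would otherwise
yield an infinite z-score for a single extra read.

**Robustness rationale.** The controls may themselves contain expansions
(patient cohorts used as "internal controls"); winsorization at
$k = 1.5$ keeps one or two expanded samples from inflating $\sigma_M$ and
masking true outliers, valid as long as fewer than half the samples share
an expansion at the same locus. Internal-control mode deliberately
includes the tested sample in parameter estimation (no leave-one-out):
the robust estimator already discounts it, and including it makes the
parameters identical across samples of a batch.

**Zero-filling and fallbacks.** When building control parameters, a
sample without reads at a locus contributes a raw count of zero rather
than a missing value — absence of decoy reads is informative. A locus
absent from the control table entirely (e.g. annotated after the control
parameters were estimated) is still tested, with location set to the
normalized zero count at 100× and scale set to the median control scale;
this keeps late annotation additions testable.

**BH family.** Adjustment is across exactly the loci with at least one
assigned read in the tested sample — every such locus receives a $p$
value, and loci with no evidence are not part of the family.
For $z \le 0$ the literal upper-tail value ($p \ge 0.5$) is reported
rather than `NA`.

**Canonicalization totality.** Periodic motifs are reduced to their
primitive root before minimization, so `canonical_unit()` is total on all
ACGT strings up to 6 bp rather than only on primitive ones; annotation
rows whose motif cannot be canonicalized (ambiguity codes such as `N`, or
length > 6) are skipped with a warning rather than failing the parse.

## What the simulator emulates — and what it does not

`simulate_locus_reads()` reproduces the study design used for
calibration: a diploid locus, one allele at the reference copy number and
one expanded, 150 bp paired-end reads with fragment lengths drawn from
Normal(500 bp, 50 bp), and 30× total coverage shared between haplotypes
in proportion to their length. Fragments are placed uniformly; a read
with at least 90% of its bases inside the repeat tract is emitted as
aligned to the decoy of the locus's unit with its mate at its true flank
position, and all other reads are emitted at their (reference-clamped)
genomic positions. Cohorts add a Poisson background of assignable decoy
reads per locus (default mean 1), emulating the low-level repeat-read
noise of real data. Everything is seeded and byte-reproducible.

The simulator deliberately does *not* model base-calling errors, the
aligner's actual decision boundary (a hard 90% repeat-content threshold
stands in for "mostly repeat sequence"), mapping-quality variation,
reference loci embedded in genuine genomic context, or multi-locus
cross-talk between same-unit loci. Passing tests therefore demonstrate
the correctness of the counting, statistics and calibration machinery
under the stated generative model — not aligner behavior on real reads,
which additionally depends on BWA-MEM's scoring and the repeat content of
the real genome.

The default calibration shipped in `inst/extdata/default_calibration.json`
is fitted on `simulate_calibration_dataset(n = 100, seed = 20180821)`:
100 synthetic individuals, one allele fixed at 16 repeat units and the
other uniform on 0–500 units at a CAG-type locus, mirroring the design
above. Individuals with zero decoy reads or non-positive inserted length
are dropped (their logarithms are undefined); drops concentrate at small
alleles, which are below the method's detection scale anyway. Users
analyzing libraries with different read or insert lengths should refit
with `fit_calibration()` (or the `calibrate` CLI verb) and pass the model
via `run_config(calibration = ...)`.

## Problem sizes used in the tests

The shipped tests run the statistical acceptance checks at deliberately
modest scale, chosen as the smallest sizes at which the checked
properties are statistically meaningful: null calibration on 20-sample ×
200-locus Poisson cohorts over 20 seeds; spike-in recovery on 10-sample
cohorts with a 300-repeat-unit expansion over 20 seeds; calibration
recovery on 100-point cohorts over 20 seeds. The end-to-end pipeline test
runs a full 5-sample SAM→BAM cohort. Larger cohorts only sharpen these
checks; they do not change the code paths exercised.

## Known limitations

* **Size saturation.** Alleles longer than the insert size are
  underestimated: both reads of a fragment wholly inside the repeat map
  to the decoy and cannot be allocated. Such loci remain *detected* (the
  count excess is still extreme) but their size estimate is a lower
  bound. No correction is attempted.
* **Short expansions are invisible.** An expanded allele must produce
  reads that are ≥ 90% repeat; expansions that keep the allele well under
  the read length are better served by spanning-read genotypers.
* **One-sided test only.** Contractions are out of scope, as are diploid
  two-allele genotypes — the short allele should be genotyped with a
  spanning-read tool.
* **Annotation-bound.** Only loci present in the STR annotation can
  receive reads; an unannotated locus is silently unassigned (the
  per-unit unassigned counts are the place to look for such evidence).
* **hg19 proximity statistics.** The genome-wide fractions of same-unit
  neighbors depend on the exact annotation release and distance
  convention; the implementation fixes the edge-gap convention and leaves
  genome-scale verification to an optional integration test that runs
  when a local copy of the UCSC simpleRepeat table is present.
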