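---
title: "Maternal CNV-aware aneuploidy screening: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maternal CNV-aware aneuploidy screening: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(niptcnv)
```

## The problem

Read-count NIPT calls a fetal trisomy when a chromosome's coverage
proportion, standardised against a euploid reference panel, exceeds a
Z-score of 3. A constitutional copy-number variant in the *mother* shifts
that chromosome's read counts in every fragment of the dominant maternal
compartment: a duplication pushes the Z-score up (false positives), a
deletion pushes it down (false negatives). This package implements a
screening workflow that (i) detects maternal CNVs from binned read depth,
(ii) removes their effect on chromosome coverage through an analytic
coefficient before Z-scoring, and (iii) flags residual false positives by
the disagreement between two independent fetal-fraction estimates.

## The coverage coefficient

Plasma cell-free DNA is a two-compartment mixture: a fraction $f$ of
fetal (placental) origin and $1-f$ maternal. For a maternal CNV of size
$n$ Mb and copy number $cn$ on a chromosome of valid length $m$ Mb
(chromosome length minus the gaps that unique reads cannot cover), the
multiplicative effect on chromosome coverage is

* inherited by the fetus (both compartments carry $cn$):
  $\alpha = 1 + \dfrac{n\,(cn-2)}{2m}$
* not inherited (only the maternal compartment carries it):
  $\alpha = 1 + \dfrac{(1-f)\,n\,(cn-2)}{2m}$

Both equal 1 exactly when $cn = 2$ or $n = 0$, exceed 1 for a
duplication, fall below 1 for a deletion, and the not-inherited form
reduces to the inherited one at $f = 0$. Dividing the observed coverage
by $\alpha$ restores the CNV-free value. **A caveat on provenance:** the
closed forms above are a reconstruction from the surrounding descriptive
constraints of the source method (the stated limits, the direction of the
inherited/not-inherited difference, and printed coefficient values of
roughly 1.01 for sub-Mb duplications on a ~35 Mb valid-length
chromosome); the original formulas are not typeset in the text we worked
from, so the forms here should be read as this package's model, stated
explicitly so it can be checked.

Because inheritance of the CNV is unobserved, the selection rule is
asymmetric on purpose: duplications use the not-inherited (attenuated)
form and deletions the inherited (unattenuated) one. A wrong guess then
always errs *against* suppressing a true positive: duplications are
over-corrected (never under-), deletions over-corrected upward. The
price, visible in the simulations below, is a small positive residual
Z-score for large deletions at high fetal fraction. Multiple CNVs on one
chromosome combine additively in the excess term; `select_alpha()`
implements the rule, with an explicit `inherited` override.

## Workflow stages and their parameters

1. **Binning.** Unique reads (primary, non-duplicate, mapping quality >=
   30 — the source method gives no policy, so we fix one) are counted
   into 100-kb bins by leftmost base, 0-based half-open.
2. **GC correction** (`correct_gc()`). LOWESS of count on GC (span 0.3,
   one robustness iteration), each bin rescaled by median/fit. The
   divisor curve is built in two backfitting passes and held constant
   beyond the central 98% of the GC distribution: a single
   locally-linear pass leaves ~10% of a steep bias's slope in the GC
   tails, and the sparse extremes cannot support a stable local fit.
3. **Mappability correction** (`correct_mappability()`): division by the
   per-bin mappability.
4. **Chromosome Z-scores.** Coverage proportions are taken over valid
   autosomes (chromosome X excluded, so male-fetus samples are
   comparable to a female-pregnancy panel — the normalisation base is a
   choice we make explicit) and standardised by the panel mean/SD.
5. **Maternal CNV detection.** Bin Z-scores are formed against the panel
   and aggregated into 100-kb windows offset by half a bin (each window
   averages the two 50-kb halves of adjacent bins, so a breakpoint
   mid-bin still yields a clean step). Windows are segmented by a native
   re-implementation of circular-binary-segmentation-style changepoint
   detection; segments with a detectable mean shift, a footprint over
   300 kb, and an estimated integer copy number different from 2 become
   CNV calls. The copy number bridge is
   $cn = 2\,(1 + \bar{Z}\cdot\mathrm{CV})$ rounded half away from 2,
   with CV the panel's per-bin coefficient of variation — this bridge is
   our construction, not part of the source method.
6. **Adjustment and call.** Per chromosome, $\alpha$ from the detected
   calls and the estimated fetal fraction; trisomy called when the
   adjusted Z exceeds 3 (one-sided: deficits are flagged as possible
   monosomy, not auto-called, since the screening scope is T13/T18/T21).
7. **Discrepancy filter.** For positive male-fetus samples, the fetal
   fraction from chromosome X under-representation, $f_X = 2(1-\bar{x})$,
   is compared with the one from the aneuploid chromosome's
   over-representation, $f_{aneu} = 2(\bar{r}-1)$:
   $Z_{fetal} = (f_X - f_{aneu})/sd$, with $sd$ the cohort SD of the
   difference among concordant positives. $|Z_{fetal}| \ge 3$ flags a
   potential false positive — the call is annotated for karyotyping,
   never deleted. Under a mosaicism model the implied trisomic-cell
   fraction is $f_{aneu}/f_X$.

### Segmentation details

`segment_signal()` is recursive maximal-t splitting with a permutation
p-value (threshold 0.01, 500 permutations with early exit). Three
refinements matter in practice and are part of this package's design:

* *Arc rescue.* A CNV in the middle of a flat chromosome is an inserted
  arc whose flanks share a mean; no single split may be significant even
  when the arc is obvious. Segments where the single-split test fails
  are probed with the best split *pair* (F-type statistic, own
  permutation null, middle segment capped at 100 windows — CNV scale).
* *Bin-level permutation.* Half-shifted windows share a bin with each
  neighbour (correlation 0.5), so permuting windows is anticonservative;
  permutations shuffle the underlying bin values and rebuild windows.
* *Breakpoint refinement.* Each accepted breakpoint is re-located at the
  least-squares split within its two flanking segments, because the
  first greedy split of a multi-changepoint segment can land a couple of
  windows off.

The "undo" merge collapses adjacent segments whose means differ by less
than `sd_coefficient` standard errors of the difference; the default
coefficient is 4 rather than the usual 3 — the conservative setting,
since a falsely called maternal CNV corrupts the aneuploidy call it
feeds, while a missed small CNV merely leaves the general behaviour.
CNV size is measured on the merged genomic footprint of contiguous
same-sign detected segments, so a CNV split by level heterogeneity is
sized whole.

## The plasma simulator

`simulate_sample()` draws every valid bin independently from a Poisson
distribution with mean `base * dosage`: `base` is proportional to
`total_reads x mappability x gc_bias`, normalised to sum to
`total_reads`; `dosage = f * cn_f/2 + (1-f) * cn_m/2` encodes maternal
CNVs, fetal trisomy (a chromosome-wide extra copy), fetal sex (one X for
a male fetus), and CNV inheritance (the fetus carries the maternal copy
number). The injected GC bias is a smooth unimodal multiplier peaking at
GC 0.42 with amplitude 20% — chosen so the LOWESS stage has real work to
do; the source describes no bias model.

Study conditions are the defaults: CNV sizes 0.5–5 Mb in 0.25 Mb steps,
fetal fractions 5/10/15%, duplications at copy number 3 and deletions at
1, 7.5 million reads per sample (midpoint of the stated 5–10 million),
and a 100-sample euploid reference panel. The default genome
(`default_genome()`) is an hg19-scale synthetic model: chr13/18/21-like
chromosomes whose valid lengths (~95.5/74.1/35.0 Mb) approximate the
build-37 uniquely mappable lengths, an X chromosome, and 2.5 Gb of
background autosomes so coverage proportions — and hence their Poisson
sampling CVs — are genome-realistic. Simulation experiments place each
CNV uniformly over the chromosome's valid runs per replicate, so local
GC/mappability structure averages out of cell means.

What the simulator does *not* emulate: inter-sample biological variance
beyond Poisson counting noise (real panels have per-chromosome CVs
several-fold larger, which is why the printed clinical false-positive
size thresholds of 1.5/2.2/3.2 Mb are reproduced here only as an
*ordering*, at a common clinical-scale CV), GC bias that varies between
samples, mappability artefacts correlated along the genome, fragment
length structure, and mosaicism. Passing tests therefore demonstrate the
statistical identities and the workflow logic, not clinical performance.

## Numerical choices and degenerate inputs

* Panel SDs floored at 1e-6 (normalised-count scale) with a warning.
* Non-positive LOWESS fits replaced by the nearest positive fitted
  value; non-positive mappability drops the bin.
* `NaN` windows are excluded before segmentation; all-equal segments
  return a single segment.
* Fetal fractions are clipped to [0, 1]; the chromosome X ratio above
  1.02 means no informative under-representation (female fetus), and the
  pipeline treats ratios above 0.99 as uninformative for sex.
* Fetal-fraction ratios are referenced to autosomes excluding both
  chromosome X and the chromosome under assessment (and the screened
  chromosomes, for $f_X$): on a genome where the screened chromosomes
  are a non-trivial share of the total, leaving the trisomic chromosome
  in the reference deflates $\bar{x}$ and inflates $f_X$ by about
  $f \cdot w/2$ ($w$ = its bin share).
* Mosaic percentages round half up to one decimal; the euploid
  complement is exactly `100 - mosaic`.

## Problem sizes used in the validation suite

The packaged tests run the full grid (3 chromosomes x dup/del x 19 sizes
x 3 fetal fractions) with 50 paired replicates per cell for the
coefficient-agreement check and 3 replicates per cell through the full
detection-and-adjustment pipeline; the false-positive-threshold ordering
uses 6 replicates per size at a common 0.5% panel CV. These sizes give
Monte-Carlo error comfortably below every asserted tolerance while
keeping the suite's runtime moderate.

## Known limitations

* CNVs below ~300 kb are out of scope by design (the 300-kb rule);
  sub-100-kb detection would need a different statistical approach.
* The discrepancy filter requires a positive call *and* a male fetus;
  for female fetuses only the maternal-CNV adjustment protects against
  false positives.
* The deletion selection rule leaves a residual $+f\,n/(2m)/\mathrm{CV}$
  in the adjusted Z of large deletions at high fetal fraction; at
  clinical panel CVs this is negligible, at the simulator's pure-Poisson
  CVs it can approach the call threshold for the largest deletions on
  the shortest chromosome.
* $\alpha$ uses detected size and copy number; mis-estimated copy number
  (e.g. a cn-4 CNV read as cn-3) propagates into the adjustment.

## A worked example

```{r example, eval = FALSE}
genome <- default_genome(seed = 1)
panel <- simulate_reference_panel(genome, 100, seed = 2) |>
  build_reference_panel(genome)

cnv <- place_cnv(genome, "chr21", size_mb = 2, cn = 3)
sample_counts <- simulate_sample(
  genome,
  sim_params(fetal_fraction = 0.10, fetus_sex = "male",
             maternal_cnvs = cnv, seed = 3)
)

report <- run_pipeline(sample_counts, panel, genome, fcd_sd = 0.01)
tidy(report)
autoplot(report)
```
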