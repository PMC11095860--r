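---
title: "Methods: paired-biopsy profiling of acquired resistance to PD-(L)1 blockade"
author: "ARpipe maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-biopsy profiling of acquired resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ARpipe)
```

# Scope

ARpipe implements the bespoke computations of a matched pre-/post-therapy
tumor-biopsy resistance analysis for non-small-cell lung cancer treated
with immune checkpoint inhibitors (ICI): shared-lineage similarity
scoring, purity-corrected absolute copy number (ACN), acquired-alteration
calling with biallelic-inactivation detection, spatial PD-1/PD-L1
engagement and neighbor-distance metrics, immunohistochemistry (IHC)
H-scores, and the exact paired statistics that tie them together. A
seeded synthetic-cohort generator with planted ground truth provides the
validation substrate: real study cohorts of this design live in clinical
data systems, so the package's guarantees are demonstrated by parameter
recovery on simulation plus arithmetic identities, not by re-analysis of
patient data.

# Tumor-pair similarity score

Whether a pre- and a post-therapy biopsy arose from the same tumor
lineage is decided from how surprising their shared somatic events are.
With $f_i$ the cohort frequency of event $i$ (SNVs, small indels,
gene-level CNAs, structural variants) and $f_i^2$ the probability of
observing event $i$ independently in two samples, the score for samples
$a, b$ over their combined event universe is

$$S(a,b) = -\ln \prod_i \begin{cases} \alpha\, f_i^2 & i \in a \cap b \\ 1 - f_i^2 & \text{otherwise.} \end{cases}$$

Sharing a rare event contributes $-\ln(\alpha f_i^2)$, which grows as
$f_i$ falls; an unshared event contributes $-\ln(1-f_i^2)$, small unless
the event is near-ubiquitous. Design choices that the formula itself
leaves open:

* **$\alpha$** is a co-occurrence scaling with no canonical value; the
  default is $\alpha = 1$ (pure independence surprisal), exposed as a
  parameter. With $\alpha \le 1$ every contribution is nonnegative.
* **Log base** is natural; base only rescales scores and never changes
  ranks, but is fixed for reproducibility.
* **Event universe** defaults to the union of the two samples' events;
  an all-catalog mode is available (`universe = "catalog"`), under which
  events absent from both samples enter as unshared terms.
* **Cohort frequencies** count one sample per patient (conventionally
  the pre-treatment biopsy) so patients contributing two biopsies do not
  inflate $f_i$; `buildCatalog(countSamples=)` makes the selection
  explicit.
* **Unseen events** (scored sample not in the catalog cohort) are
  imputed $f = 1/(N+1)$ and logged.
* **Degenerate case**: an unshared event with $f_i = 1$ has contribution
  $-\ln 0 = +\infty$; the result is flagged rather than dropped, since a
  ubiquitous event missing from one member of a true pair is itself
  informative.
* A documented oddity of the printed form is that an *unshared*
  high-frequency event *increases* the score ($-\ln(1-f^2)$ grows with
  $f$). The formula is implemented as stated, not "corrected"; with
  realistic catalogs the effect is dwarfed by shared-event terms.

No calling threshold accompanies the formula, so the shared-lineage call
is made against an empirical null: `calibrateNull()` scores random
cross-patient sample pairs and a pair is called shared-lineage when its
score exceeds the null's 95th percentile (percentile configurable). On
simulated cohorts of 200 patients whose pairs share five patient-private
passenger variants ($f = 1/200$ each), every pair scores far above the
null threshold — the basis of the power check in the acceptance suite.

# Purity-corrected absolute copy number

A targeted panel reports piecewise-constant segmented $\log_2$ tumor/
normal ratios. The gene-level ratio $l$ is the overlap-length-weighted
mean of segments across the gene (1-based inclusive SEG coordinates;
internal interval arithmetic uses Bioconductor ranges with the
conversion confined to the I/O boundary). With tumor purity
$p \in (0,1]$,

$$\mathrm{ACN} = \frac{2^{\,l+1} - 2(1-p)}{p}.$$

This is the unique reading of the relation under which $l = 0$ yields
$\mathrm{ACN} = 2$ at every purity — a diploid gene must look diploid
regardless of stromal admixture. Raw values below zero (observed ratio
lower than pure stroma would allow) are preserved as a purity-diagnostic
alongside the clamped value used for categorization. At fixed $l < 0$
the estimate increases with $p$: the same depressed ratio implies a
near-total loss when the tumor fraction is small.

CNA categories are not accompanied by printed cutoffs anywhere we could
adopt them from, so the defaults mirror common targeted-panel practice
on the clamped ACN scale — homozygous deletion $< 0.5 \le$ heterozygous
deletion $< 1.5 \le$ neutral $\le 2.5 <$ gain $\le 6 <$ high-level
amplification, boundaries resolving to the lower-severity class — and
are configurable (`defaultAcnThresholds()`).

The arm-level aneuploidy score is a deliberate simplification of
coverage-weighted arm callers for targeted panels: an arm is callable
when segments cover $\ge 70\%$ of it, called gained (lost) when
$\ge 70\%$ of its covered length sits at $\log_2$ ratio $\ge +0.2$
($\le -0.2$), and the score counts non-neutral arms. Output metadata
labels the simplification; allele-specific copy number and
purity/ploidy estimation are out of scope.

# Acquired-alteration calling

Variants flagged benign or as clonal hematopoiesis (CHIP) are removed
first; absent flags are treated as false and logged. Matching is
presence/absence on canonical event keys (gene, event class, detail) —
the panel's variant allele fractions are not modeled, so presence at any
level in the pre-biopsy blocks an "acquired" call. A gene CNA is
acquired when the post category moves away from the pre category into,
or further into, a non-neutral state (neutral to loss, neutral to
amplification, heterozygous to homozygous deletion, or a direction
flip). A literal "differs and non-neutral" rule would also label a
homozygous-to-heterozygous *reversion* as acquired; we classify moves
toward neutral as reversions and report them in a separate `lost` table,
since only acquisitions are biologically at issue. Biallelic
inactivation is called when an acquired mutation and an acquired copy
loss hit the same gene in the same post-biopsy.

Cohort summaries report, with explicit denominators, the fraction of
pairs with at least one acquired mutation, CNA, or change of any kind,
and per-gene frequencies deduplicated to one count per patient per gene
per finding type (a patient with two STK11 point mutations counts once
for STK11 mutation, but a mutation and a deletion of the same gene count
in their own categories). Percentages are rounded to one decimal for
report parity. Stratified comparisons (time to resistance dichotomized
at 6 months, therapy category, best response, PD-L1 TPS bin) attach
exact Fisher tests to two-stratum splits.

# Spatial single-cell metrics

All metrics operate on centroid tables in microns (a pixel-to-micron
scale factor is applied at read time when needed); no cell-shape
modeling is attempted. The PD-1/PD-L1 engagement fraction is the
fraction of PD-L1+ cells with at least one PD-1+ cell within 20 microns,
i.e. potential interaction pairs normalized per sample by total PD-L1+
cells; the per-pair count is also emitted. Choices worth stating:

* **Boundary inclusive** ($d \le 20\,\mu m$): "within a radius" is read
  inclusively, and ties at machine precision resolve to inclusion.
* **Double-positive** PD-1+PD-L1+ cells belong to both query and target
  sets but never pair with themselves.
* **Zero PD-L1+ cells** make engagement undefined: the metric returns
  missing with a diagnostic, never 0.
* **Edge effects** are uncorrected; the fraction of query cells within
  one radius of the frame's bounding box is reported as a note field.

Neighbor search uses a uniform-grid spatial index (radius-sized buckets,
3×3 neighborhood scans; ring expansion with a brute-force fallback for
degenerate geometries in the nearest-neighbor path). No kd-tree is
involved; the index is exact, and the test suite holds it equal to a
literal all-pairs scan on hundreds of random frames. Tumor-to-T-cell
distance is the per-tumor-cell (cytokeratin+) Euclidean distance to the
nearest CD8a+PD-1+ cell, summarized by the median. Densities are counts
over the declared tissue area in cells/mm².

# H-scores and exact paired statistics

The H-score is the standard pathologist scale
$1\cdot\%_{1+} + 2\cdot\%_{2+} + 3\cdot\%_{3+} \in [0, 300]$; scores may
also be consumed directly as numbers when intensity fractions were never
recorded. Percent change from a zero baseline is reported missing, not
infinite.

The paired Wilcoxon signed-rank test is exact by full enumeration of all
$2^n$ sign assignments for $n \le 25$ (average ranks on tied absolute
differences; the enumeration runs on a half-unit lattice so tied ranks
stay exact), with a continuity-corrected normal approximation above.
Zero differences are dropped by default (classic behavior); the Pratt
variant is available behind a flag. Six untied pairs all moving one
direction give $p = 2/64 = 0.03125$ — the configuration behind a printed
$P = .03$ at $n = 6$. Fisher's exact test is two-sided by the
probability-ordering convention (all tables with hypergeometric
probability at most the observed one, to a $1+10^{-7}$ relative
tolerance, as in the standard implementations); a zero margin returns
$p = 1$ with a warning. A continuity-corrected $\chi^2$ is provided only
as the large-sample fallback. No multiplicity correction is applied
across report tables by default, matching the analysis the package
reproduces; `p.adjust` can be applied downstream.

# The synthetic cohort generator

`simulateCohort()` emulates the statistical structure the analysis
assumes, with every planted truth serialized alongside the outputs:

* **Acquired events** are sampled independently per patient per event.
  Default planting probabilities are the recurrent acquired-event rates
  reported at resistance to PD-(L)1 blockade (STK11 LOF 8.9%, B2M 6.3%,
  SMARCA4 6.3%, KEAP1 2.5%, JAK1 1.3% mutations; B2M 22.8%, STK11
  17.7%, KEAP1 16.5% heterozygous losses; CDKN2A 8.9% homozygous
  deletion; MDM2 5.1% and KRAS 3.8% high amplification). Event
  co-occurrence has no described generative model, so independence is
  the default and concurrent mutation + heterozygous loss (biallelic
  inactivation) is planted via an explicit `biallelicFreq` knob
  (default 0.3, a mid-range choice: roughly half of recurrent acquired
  LOF mutations co-occur with losses in the motivating data).
* **Baseline events** (KRAS driver at 34.1%, TP53 at a typical NSCLC
  50%) and a configurable number of patient-private passenger variants
  (default 3) appear in both biopsies — the private variants are the
  shared-lineage signal.
* **Copy number** is planted by inverting the ACN relation:
  $l = \log_2(p\cdot\mathrm{ACN} + 2(1-p)) - 1$, one segment per gene
  plus diploid background, so the forward formula round-trips exactly at
  zero noise; Gaussian segment noise (default SD 0.05 log2 units, a
  typical targeted-panel segment SD) is added on top. Purity is drawn
  uniformly from (0.3, 0.9) — a realistic biopsy range — and held equal
  pre/post, matching the reported purity balance of matched cohorts.
* **Spatial frames** place cells by homogeneous Poisson processes
  (densities per class; defaults of order 10²–10³ cells/mm² as in
  NSCLC mIF panels; a clustered alternative was considered and left out
  because no point-process model is stated for the data this emulates).
  To plant engagement, $k = \mathrm{round}(t \cdot n_{PDL1})$ PD-L1+
  cells receive a PD-1+ partner within 20 microns and every other PD-1+
  cell keeps $> 20\,\mu m$ from every non-interactor PD-L1+ cell (a
  25 µm berth between non-interactors and interactors keeps the
  construction feasible; a 20.1 µm rejection buffer absorbs the
  two-decimal coordinate rounding that keeps emitted files stable
  across platforms). The achieved fraction $k/n_{PDL1}$ is recorded in
  the ground truth; it equals the target exactly whenever
  $t \cdot n_{PDL1}$ is an integer, in particular at 0 and 1. The
  generator plants a post/pre engagement ratio of one half, mirroring
  the reported decline at resistance.
* **H-scores** shift by `hscoreShift` (default −40) plus noise;
  time-to-resistance is 3 months plus an exponential with mean 8
  months, consistent with progression kinetics after an initial
  response.

What the simulation does *not* emulate: subclonal structure and variant
allele fractions, sequencing noise in variant calls, spatially clustered
or tissue-structured cell patterns, inter-marker correlation beyond the
planted engagement, and survival processes. Passing recovery tests
therefore certify the pipeline's arithmetic and calling logic under the
stated generative assumptions, not robustness to real-world artifacts
such as purity misestimation or segmentation error.

# Numerical and testing choices

Problem sizes used by the validation suites are the package's own: 1,000
random small instances for the similarity oracle (tolerance $10^{-12}$),
an ACN round-trip grid over $p \in \{0.2, \dots, 1.0\}$ and
$\mathrm{ACN} \in \{0.5, \dots, 8\}$ at $10^{-9}$, 200 random frames of
50–1,500 cells against the all-pairs neighbor oracle, 200 simulated
clonal pairs against a 1,000-permutation null, full $2^n$ enumeration
checks for all $n \le 12$, Fisher enumeration for margins $\le 30$, and
a 500-patient cohort for frequency recovery (observed counts within the
exact binomial 95% CI of the planted truth; mutation-class events are
recovered exactly because presence/absence matching is deterministic).
All simulation entry points accept a single integer seed from which
module-level streams are derived, so reruns are byte-identical.

The bundled gene and chromosome-arm interval files are synthetic
reference tables (approximate hg19 coordinates for the recurrently
altered genes); they stand in for an assay's interval definitions in
simulations, examples and tests, and any BED file can be supplied in
their place.

# Known limitations

Clonality is scored, not reconstructed: no CCF modeling or phylogenetics.
The arm caller is an acknowledged simplification. Fisher stratification
tests are per-table and unadjusted. The spatial metrics assume marker
flags and classes are already called (image analysis is upstream of this
package). H-score inputs are pathologist-scale summaries; no slide-level
intensity modeling is attempted.
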