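---
title: "Methods: proteomic, morphometric and accessibility analysis of flow-sorted mitotic chromosomes"
author: "chromosort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteomic, morphometric and accessibility analysis of flow-sorted mitotic chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromosort)
```

# Scope

`chromosort` implements the three computational procedures used to
characterise native mitotic chromosomes purified by flow cytometry:

1. **LFQ enrichment analysis** — which proteins are significantly
   enriched or depleted on flow-sorted chromosomes relative to the total
   mitotic lysate pellet, from a label-free quantification (LFQ)
   protein-group intensity table;
2. **chromosome morphometry** — total chromosome and DAPI-high
   (pericentric) areas of isolated chromosomes in calibrated
   fluorescence images, compared between cell lines with unpaired
   two-tailed Student's *t*-tests;
3. **ATAC accessibility transforms** — Tn5 insertion-centre extraction
   with the +4/−5 bp offset, 25 kb windowed log2 enrichment tracks, and
   summit-centred accessibility trend profiles split by bookmarking
   class.

Because the raw mass-spectrometry, imaging and sequencing data sit in
external repositories, every stage is paired with a seeded synthetic
generator that emits ground truth, so correctness is established by
parameter recovery rather than by re-processing deposited data.

# The enrichment model

## Preprocessing

The analysis consumes a MaxQuant-style protein-group table. Rows flagged
as reverse decoys, potential contaminants or "only identified by site"
are removed, as are groups identified by fewer than two razor + unique
peptides. Zero LFQ intensities denote "not quantified" and are treated
as missing; no imputation is performed anywhere in the pipeline —
proteins with fewer than two valid values in either condition are
reported as `not_tested`. Technical duplicates are averaged on the raw
intensity scale (a single valid value stands for its pair), and the
averaged matrix is log2-transformed. The order — average, then log —
matters: averaging after the log transform would estimate the geometric
rather than arithmetic mean of duplicate injections.

## The moderated statistic

For protein $i$ with averaged log2 intensities $x$ (sorted) and $y$
(lysate),

$$ d_i = \frac{\bar{x}_i - \bar{y}_i}{se_i + s_0}, \qquad
   se_i = s_{p,i}\sqrt{1/n_x + 1/n_y}, $$

where $s_{p,i}$ is the pooled standard deviation. The constant
$s_0 = 0.1$ (log2 units) damps the significance of low-variance,
low-effect proteins — the SAM-style moderation used by standard
proteomics volcano analyses. At $s_0 = 0$, $d$ is the classical pooled
two-sample *t* statistic; the test suite verifies this equivalence
against an independent textbook implementation. When both groups have
zero variance and $s_0 = 0$ the statistic is reported as $\pm\infty$
with the sign of the mean difference.

## Permutation FDR

Significance is not read from the *t* distribution (which would be
badly anti-conservative at $n = 3$ per group with thousands of tests)
but from relabelings of the six averaged samples into two pseudo-groups
of three. Three numerical decisions deserve note:

* **The identity relabeling is excluded.** The identity split
  reproduces every observed statistic, so with it included the
  estimated FDR at *any* cutoff has a floor of $1/n_\text{splits}$
  (0.1 for 3 vs 3) and a 1% FDR target could never be met at this
  design size. Nine distinct non-identity splits remain for 3 vs 3
  (a split and its complement are equivalent for equal group sizes).
* **Exhaustive enumeration when feasible.** When the number of
  distinct splits does not exceed the requested randomisation count
  (always true for 3 vs 3 against the default 250), all splits are
  enumerated instead of sampled — the exact version of the same
  estimator, and deterministic. Sampling mode is retained for larger
  designs and is cross-checked against enumeration in the tests.
* **FDR estimator.** For a cutoff $c$ on $|d|$,
  $\widehat{FDR}(c) = \min\!\left(1, \frac{\overline{\#\{|d^\ast| \ge c\}}}{\#\{|d| \ge c\}}\right)$,
  with the numerator averaged over relabelings. The estimate is made
  monotone by a running minimum taken from the least significant cutoff
  upward (the step-up convention of q-values), and the significance
  threshold is the smallest cutoff whose adjusted estimate is at or
  below the target FDR. No null-proportion ($\pi_0$) factor is applied.

Rows untestable under a given relabeling (fewer than two valid values
in a pseudo-group, possible with missing data) simply contribute no
null value for that relabeling.

Calls partition every protein exhaustively: `enriched` (significant,
log2 fold change > 0), `depleted` (significant, < 0), `ns`, or
`not_tested`. The plotted significance ($-\log_{10} p$) comes from the
plain pooled *t* with $2(B-1)$ degrees of freedom; the calls come from
the permutation FDR — the two scales answer different questions and are
kept separate.

## Clustering

Follow-up clustering prefilters rows to those with at least two valid
values in one condition and a significant plain *t* test (permutation
FDR 0.05, $s_0 = 0$), z-scores each row — population (divide-by-$n$)
convention, fixed for testability — reduces rows with k-means (300
centroids, 10 iterations, 1 restart; skipped when fewer rows than
centroids), and agglomerates rows and columns with euclidean distance
and average linkage. Missing values in z-scored rows are set to 0 (the
row mean) for distance computations only; this slightly shrinks
distances for sparse rows but avoids imputing abundances. The row
dendrogram is verified against a naive $O(n^3)$ average-linkage
implementation in the tests.

# Morphometry

## Segmentation and measurement

Segmentation is deliberately simple: a global threshold on the DAPI
channel (Otsu by default — parameter-free and robust for bimodal
images of bright objects on dark background; fixed and quantile
thresholds are available), 8-connected component labeling, removal of
components below `min_object_px`, and exclusion of border-touching
components (partial objects bias areas down). Areas are pixel counts
times `pixel_size_um`². No calibration is assumed: `pixel_size_um` is a
required input because magnification-to-µm mappings vary per
acquisition.

The DAPI-high (pericentric heterochromatin) domain is defined
*per object*: pixels whose intensity strictly exceeds the object's own
0.8 intensity quantile, keeping the largest connected component. A
relative, per-object rule is robust to staining variation between
slides; the strict inequality makes a perfectly flat object report zero
DAPI-high area. The 0.8 default reflects that pericentric domains
occupy roughly the top fifth of a chromosome's intensity distribution;
it is a config parameter, not a constant, because any absolute
definition would be arbitrary. When a Cenpa channel is present, the
fraction of thresholded Cenpa-positive pixels inside the DAPI-high mask
is reported as a consistency check between the two centromere markers.

Group comparisons use the pooled-variance (classical Student, not
Welch) unpaired two-tailed *t*-test, with per-group mean and sample SD
($n-1$).

## What the generator emulates

Synthetic images hold one rotated superellipse (exponent 2.5, mildly
blunter than an ellipse) per image, with low-order radial boundary
jitter (SD 0.015, small enough that the analytic area stays within a
fraction of a percent of the rasterised truth), a DAPI-high band at one
end of the major axis (mouse chromosomes are telocentric) holding 15%
of the area at 2.5× brightness, Poisson shot noise plus Gaussian read
noise on a 16-bit scale, and an optional Gaussian Cenpa spot centred on
the band. Default areas (18.4 ± 3.0 µm²) match wild-type chromosome 19;
the mutant and X-chromosome distributions are produced by changing the
mean/SD. The generator does **not** emulate overlapping or touching
chromosomes, uneven illumination, out-of-focus blur, or debris — so
passing recovery tests demonstrates that the measurement chain is
unbiased on well-isolated objects, not that segmentation is robust to
crowded fields.

# ATAC transforms

Coordinates are 0-based half-open (BED convention) throughout. The 5′
end of a minus-strand read is `end - 1`; insertion centres are
`start + 4` (plus strand) and `(end - 1) - 5` (minus strand). Sites
offset outside the chromosome are dropped and counted, and site counts
are conserved exactly: input reads = retained + unknown-strand +
out-of-bounds.

Enrichment tracks tile each chromosome with 25 kb windows (the final
partial window keeps its true length in the expectation), and report
$\log_2(\text{count}/\text{expected})$ against the genome-wide average
density. Zero-count windows take a pseudocount of 0.5 inside the log so
the track stays finite; counts themselves are untouched.

Trend profiles extend each insertion site by ±25 bp, accumulate
interval coverage across ±1 kb windows centred on peak summits, average
within a bookmarking class, bin at 10 bp, and normalise each class
profile to mean 1. The mean-1 convention is a stated choice — "average
relative distribution" admits per-summit or global normalisations, and
the global mean-1 form keeps flat backgrounds at exactly 1, which makes
the retained-vs-lost contrast directly readable.

The read generator plants peaks with a triangular density over
summit ± half-width scaled to a per-condition fold-accessibility
(folds below 1 thin the local background instead), assigns strands
Bernoulli at `frac_minus_strand`, and emits fixed-length BED6 reads
whose 5′ ends encode the planted centres under the same +4/−5
convention the extractor inverts. It does not model fragment-size
distributions, duplicates, GC bias or mappability.

# Pipeline and reproducibility

`run_pipeline()` validates a YAML configuration up front (all
violations reported together, each naming its key path; inputs must
resolve before any stage runs), executes the selected stages in
dependency order, and writes stage outputs plus a JSON/text report
whose counts are internally consistent (the call partition sums to the
filtered row count; retained sites plus drops equal input reads). One
global seed propagates to every stochastic component; identical
configuration and seed give byte-identical output files. A thin
command-line wrapper (`inst/cli/chromosort.R`) exposes the stages as
subcommands.

# Problem sizes and test design

The test suite establishes, among others: FDR control on all-null
tables (20 seeds × 5000 proteins at the default design), exact
agreement of sampled and exhaustive permutation calls (50 random
20-protein tables), area recovery against the four study size
distributions (50 images per group), detection power for the ~27%
wild-type vs mutant area difference at 200 objects per group (100
repetitions), and ATAC null tolerances at ≥100 expected sites per
window. These sizes were chosen to make Monte-Carlo error comfortably
smaller than each tolerance while keeping the default run quick on a
laptop.

# Known limitations

* With three biological replicates per condition, only nine distinct
  relabelings exist; the permutation null is therefore coarse, and the
  1% FDR target is conservative — planted effects need to be large
  relative to within-group variation to be called, which matches the
  behaviour of the original software at this design size.
* The printed headline counts of the motivating study (5888 identified,
  615 enriched, 1548 depleted, 1354 unchanged) depend on the deposited
  raw data and are deliberately not reproduced here; the ambiguity in
  how those counts relate to the peptide filter is left unresolved.
* Perseus's exact volcano internals (asymmetric thresholds, S0-curve
  parameterisation) are not public; the estimator above is a documented
  substitute, not a claim about the original implementation.
* The morphometry stage measures projected 2D areas only, and its
  generator does not produce crowded fields; metaphase-spread-like
  images are handled per label but without any overlap resolution.
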