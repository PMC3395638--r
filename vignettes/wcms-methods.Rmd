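---
title: "Whole-cell MALDI-TOF fingerprinting with wcms: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-cell MALDI-TOF fingerprinting with wcms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wcms)
```

## The problem

Whole-cell MALDI-TOF mass spectrometry (WC-MS) types bacteria from the
protein peaks of intact or crudely extracted cells.  In the m/z 2,000 to
20,000 range (linear mode, singly protonated species), the dominant and
most reproducible peaks come from ribosomal proteins; culture medium and
cultivation time change peak intensities but barely move peak
*positions*.  A strain's set of peak positions is therefore a fingerprint:
replicate spectra of one strain share nearly all positions, different
species of the same genus share few, and closely related species are
intermediate.  `wcms` implements the full chain from profile spectra to a
dendrogram and known/novel call, the mass-level annotation of peaks to
ribosomal proteins, and a synthetic-spectrum generator used to validate
every stage without instrument data.

## Preprocessing model

A raw profile spectrum is an intensity trace on a (near-)uniform m/z
grid.  Preprocessing is deterministic given its configuration and
consists of:

1. **Savitzky-Golay smoothing**, applied for `sgCycles = 3` cycles.  Each
   cycle replaces every point by a local least-squares polynomial fit
   (window `sgWindow = 7` points, order `sgPolyorder = 2`).  The
   three-cycle convention follows the established WC-MS clustering
   workflow; the window and order of that workflow are not published, so
   the defaults here are deliberately gentle and are configuration
   options, not inferred values.  The filter preserves polynomials up to
   its order, so flat baselines and linear ramps pass through unchanged;
   on synthetic Gaussian peaks at least 3 grid steps wide the apex moves
   by less than one grid step (a tested invariant).  Small negative
   excursions are clipped to zero after the final cycle.
2. **Top-hat baseline subtraction.**  The baseline is a morphological
   opening: a rolling minimum followed by a rolling maximum over a
   window of half-width `baselineHalfwidth = 50` Da.  The estimate is
   subtracted and the result clipped at zero.  This operator was chosen
   because it is deterministic, parameter-light and testable against an
   explicit double-loop oracle: peaks narrower than the structuring
   element survive unchanged, smooth drifts wider than it are removed
   (a linear drift leaves a residual below 1% of its range).  For
   pre-centroided data `baselineMethod = "none"` bypasses the step.
3. **Relative intensity.**  Intensities are rescaled so the base peak is
   100; all later thresholds are percentages of the base peak.  All-zero
   spectra are flagged (`metadata(x)$empty`) rather than rescaled.
4. **Replicate averaging.**  Replicates of one strain are averaged
   pointwise (after linear resampling to the coarsest common grid when
   grids differ; the common step is the largest median spacing).  The
   mean of relative spectra does not generally peak at exactly 100, so
   the average is returned at stage `"baselined"` and the pipeline
   re-applies `toRelative()` before peak picking.  This is why
   `averageSpectra()` does not claim the `"relative"` stage -- the stage
   invariant (base peak = 100) is kept strict instead of being weakened
   for one operation.

## Peak matrix

**Peak picking** reports local maxima above a minimal relative intensity
(default 1%) with topographic prominence of at least 1%, apex position
at the grid point of the maximum.  The low defaults deliberately pick
peaks *below* the later 5% binarization cut, so that the strict
threshold -- not the picker -- decides presence.

**Peak matching** groups peaks across spectra with a greedy single-pass
scan of the pooled, m/z-sorted peaks: a peak joins the open consensus
position when it lies within `maxShift` of the running mean of the
members, otherwise it opens a new position; a spectrum never contributes
two peaks to one position (the nearer wins, the other becomes its own
position).  Pooling before scanning makes the result independent of the
order of the input spectra.  The conventional "maximum shift 20" is
interpreted as **20 Da** on the working grid: the classical tools count
data points, but the instrument's native point spacing is not knowable
from exported text, so a 1 Da working grid makes the two readings
coincide and keeps runs reproducible.  `--max-shift` is exposed in Da.

**Binarization** converts aligned relative intensities to bits with a
*strict* inequality -- a peak counts as present only when its relative
intensity exceeds 5% -- restricted to m/z 3,500-20,000 (positions
outside the window are dropped; both bounds inclusive).  Thresholding
happens *after* alignment, on the aligned relative intensities; whether
the classical workflow thresholded before or after its alignment step is
not documented, and this package fixes the after-alignment reading.
Spectra that lose every peak are retained as all-zero columns and
flagged, because downstream correlation is undefined for them and the
user should see which strain vanished rather than have it silently
dropped.

## Clustering, novelty, Mantel

Similarity between two binarized spectra is the **Pearson correlation of
their bit vectors** (the phi coefficient); a constant bit vector is an
error naming the offending spectrum.  The dendrogram is **UPGMA** on the
distance `d = 1 - r` (the transform is a package convention -- the
classical workflow does not state one -- and is held fixed), with merge
heights `d/2` so leaf depth equals half the cophenetic distance; ties
between equally close pairs break toward the lowest-index pair, making
trees bit-reproducible.  Newick export goes through `ape`; heights are
doubled into the `hclust` convention on conversion because
`ape::as.phylo()` halves them again.

A query spectrum is compared to a type-strain library on a jointly
binarized matrix; its **best similarity** is the maximum phi over the
references.  Below the novelty threshold the query is flagged
`candidate_novel`.  The threshold defaults to 0.5 -- the similarity
level observed between *nearly indistinguishable* sister species in
genus-scale libraries, i.e. anything scoring below it matches no known
type strain even loosely -- and is configurable because 0.5 is an
approximate, genus-calibrated value, not a universal constant.

The **Mantel test** correlates the spectral similarity matrix with an
external one (typically 16S rRNA identity) over the same strains: the
statistic is the Pearson correlation of the n(n-1)/2 upper-triangle
entries, significance comes from jointly permuting rows and columns of
the second matrix, one-sided for positive association, with
`p = (1 + #{r_perm >= r_obs}) / (n_perm + 1)` and a default of 9,999
permutations.  The permutation stream is seedable and leaves the
caller's RNG state untouched.

## Ribosomal protein masses and annotation

Theoretical masses are **average** (not monoisotopic) masses -- linear
mode resolves only the isotopic envelope -- computed as the sum of
standard average residue masses plus one water, from a versioned
constants table (`massConstants()`).  The proton mass is tabulated but
not added: observed m/z and theoretical masses are compared directly,
following the convention of the reference data, and the ~1 Da difference
is far inside the matching tolerance.

The **N-terminal methionine excision rule** removes the initiator Met
exactly when the second residue is small: G, A, S, C, T, P, V (the
canonical methionine-aminopeptidase specificity).  In the packaged AM1
reference table the rule reproduces 51 of the 54 recorded loss states;
the three exceptions (S19, S14, L28 -- all with small second residues
but recorded as retaining Met) cannot be captured by *any* rule driven
by the second residue alone, since the same residues trigger loss
elsewhere in the table.  The package keeps the canonical rule and the
discrepancy is visible in the test suite rather than patched around.

**Annotation** pairs each observed peak with the hypothesis minimizing
the absolute error, within a tolerance of ±5 Da (covering the largest
error seen for an unmodified ribosomal protein match, 4.58 Da).  The
hypothesis space is each protein's unmodified mass plus modification
hypotheses: methylation +14.0266, acetylation +42.0367,
beta-methylthiolation +46.0916 Da (average-mass deltas; the list is
user-extensible).  Two error conventions are reported: against the
chosen hypothesis mass, and against the unmodified mass
(`error_vs_unmodified`), the form in which modified subunits are usually
quoted.

One design choice matters here.  With a *generic* hypothesis space
(every modification on every protein), a peak can be captured by a
spurious modified neighbour: in the AM1 whole-cell data the S13 peak at
13,716.81 lies 0.50 Da from *acetylated* S12 but 1.53 Da from unmodified
S13, and a blind minimal-error rule picks the wrong protein.
Modification states of ribosomal proteins are in practice known from
homology (L33 methylated, S12 beta-methylthiolated, S18 N-terminally
acetylated), so `annotatePeaks()` honours an optional
`known_modifications` column restricting each modification hypothesis to
the proteins documented to carry it.  The packaged table ships with that
column; without it the generic screening rule applies.  On the packaged
table the curated space reproduces every recorded assignment and signed
error, and the per-channel detection counts (19 whole-cell, 23 purified
ribosome).

The acetylation delta deserves a note: the quoted acetylated S18 mass
(9,254.00) implies a delta of +42.01 while the average-mass delta is
+42.037.  Which constant produced the quoted value is unknowable from
the data, so consistency is asserted to ±0.05 Da rather than exactly.
Similarly, the reference count of proteins "in the analysis range" (41)
differs from the count of table rows with theoretical mass at or below
20,000 Da (42); the in-range criterion behind 41 is not recoverable, so
`detectionReport()` reports its own tally and no test asserts 41.

## 16S identity and K2P

Pairwise 16S similarity is percent identity over aligned columns,
**skipping every column where either sequence has a gap** -- and,
additionally, columns with ambiguity codes (N, R, Y, ...), since
EzTaxon-style identity ignores undetermined positions; only the gap
behaviour is fixed by the reference convention, the ambiguity behaviour
is this package's declared choice.  Alignment itself is out of scope;
the functions consume pre-aligned FASTA.  The Kimura two-parameter
distance `d = -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q)` is provided as a helper
with the same column filter; saturation (non-positive log argument) is
an error, not NaN.

## The synthetic generator

`makeSpeciesProfiles()` / `renderReplicate()` emulate the data the
pipeline is meant for: per-species latent peak sets in m/z 2,000-20,000
rendered as Gaussian peaks (sigma 3 Da) on a 1 Da grid, with Gaussian
m/z jitter (sd 2 Da), multiplicative lognormal intensity noise (CV
0.25), per-peak dropout (3%), and a linear baseline (amplitude 5%
of the latent height scale, decaying to zero across the range).  These
defaults were chosen once as a realistic emulation of
replicate-to-replicate WC-MS variability -- positions stable to a few
Da, intensities fluctuating by tens of percent, occasional missing minor
peaks -- and the jitter is kept below a quarter of the matching radius.
Latent heights are log-uniform over 5-100% so that some peaks sit right
at the binarization threshold and the strict-inequality semantics are
exercised.  Latent masses keep a 50 Da minimum separation within and
between species (except deliberately shared sibling peaks), so distinct
latent peaks never co-align by construction; sibling species share an
exact fraction of peak positions *and heights*, as conserved proteins
would.  `makeCorrelated16S()` maps latent peak-set Jaccard similarity
affinely into the 97-100% band typical of congeneric 16S identities,
plus controllable noise, giving the Mantel test a positively correlated
matrix pair by construction.

What the generator does **not** model: additive detector noise, isotope
envelopes, doubly charged ions, ion-suppression between peaks,
mass-dependent resolution, and real phylogenetic structure in which
peak sharing decays gradually with distance.  Passing recovery tests on
this generator therefore demonstrates that the pipeline's logic is
correct under its stated noise model, not that the instrument-level
robustness of the classical workflow is reproduced.

Validation problem sizes (the package's own choices): species recovery
uses 5 species x 4 replicates over 40 seeded runs, requiring a perfect
adjusted Rand index in at least 95% of runs; sibling-species similarity
(50% shared peaks, replicates averaged per strain as in the reference
workflow, alongside three unrelated species and one library-absent
query) must average into the 0.35-0.65 band over 40 runs, mirroring the
"approximately 0.5" similarity of near-identical type strains; the
library-absent query must be flagged novel in at least 90% of runs; and
Mantel null calibration uses 100 independent 10-strain matrix pairs.

## Numerical conventions

* Strict `>` at the 5% binarization threshold; values of exactly 5 are
  absent (tested on straddling values).
* Inclusive m/z window bounds at 3,500 and 20,000.
* UPGMA tie-break: lowest-index pair first; heights stored as `d/2`.
* Degenerate inputs error loudly: all-zero spectra at correlation,
  constant off-diagonals at Mantel, saturated K2P, unknown residue
  letters, non-monotonic m/z axes.
* `pmin(100 * y / max(y), 100)` guards relative scaling against
  floating-point overshoot of the base peak.
* All stochastic components (generator, Mantel permutations) take
  explicit seeds and restore the caller's RNG state.

## Limitations

* Peak matching is greedy and mean-tracking, not an optimal assignment;
  pathological peak configurations spaced just around `maxShift` can
  split or merge differently than a global method would.
* The novelty call reduces a library to pairwise best similarity; it
  does not model within-species similarity spread.
* Binary fingerprints discard intensity information by design; two
  strains differing only in peak heights are indistinguishable after
  binarization.
* The Met-excision rule is sequence-context-free; experimentally
  observed exceptions (see above) are reported, not predicted.
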