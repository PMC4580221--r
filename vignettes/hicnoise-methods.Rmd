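---
title: "Methods: quantifying random-ligation noise in Hi-C di-tag data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying random-ligation noise in Hi-C di-tag data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hi-C reads out chromatin architecture through proximity ligation: fragment
ends that were cross-linked in the same chromatin complex are re-ligated and
sequenced as paired-end *di-tags*. Any ligation that instead joins fragments
from *different* complexes — most likely from different cells — carries no
spatial information. These spurious (random) ligations inflate
trans-chromosomal and far-cis contact counts, flatten distance-decay curves,
degrade reproducibility between replicates, and blur structural features
such as TAD boundaries. Because a spurious ligation within a single sample
is indistinguishable from a real one, the classical way to measure the
random-ligation rate is a species-mixing experiment: pool cells of two
species, and count *hybrid* di-tags whose two ends map to different genomes.

`hicnoise` implements that whole chain of analysis — di-tag classification
and library QC, the hybrid-fraction expectation, bias estimation, matrix
correction, compartment calling, reproducibility statistics and
directionality-index TAD boundary detection — together with a synthetic
di-tag generator with known ground truth, so every step can be exercised
and validated end to end without sequencing data.

## The random-ligation model

If restriction digestion is complete and ligation is fully random over the
pooled fragment-end library, the chance that a di-tag is hybrid is the
chance that two independently drawn fragment ends come from different
species:

$$p_{hybrid} = \frac{2\,n_1 n_2}{(n_1 + n_2)^2}, \qquad
  n_s = \mathrm{cells}_s \times 2 \times \mathrm{fragments}_s .$$

For a 5:1 mouse:human cell mixture with HindIII fragment counts 823,379
(mouse) and 837,163 (human), $p_{hybrid} = 0.281$. `expected_hybrid_fraction()`
evaluates this closed form; `simulate_ditags()` with
`random_ligation_fraction = 1` reproduces it stochastically.

The same model predicts the trans fraction of a pure random-ligation
library: two uniform draws land on different chromosomes with probability
$1 - \sum_i (L_i/L)^2$, i.e. 95% for 20 equal chromosomes.

## The synthetic generator

`simulate_ditags()` draws each di-tag from a two-component mixture:

* **intra-complex** (probability $1 - f_{random}$): both ends from one
  cell. Cis pairs follow a truncated power-law distance decay
  $P(s) \propto s^{-\alpha}$ (default $\alpha = 1$, the canonical Hi-C
  regime, minimum distance 1 kb), with two optional structural overlays
  applied by rejection sampling: a fold boost for pairs inside one planted
  TAD, and a fold boost for pairs whose planted compartment labels agree
  (alternating A/B blocks laid out at 1 Mb bin scale). A fraction
  `trans_background_weight` (default 0.12, in the range observed for clean
  libraries) of intra-complex contacts is trans-chromosomal.
* **spurious** (probability $f_{random}$): both fragment ends drawn
  independently and uniformly over the pooled fragment-end library of all
  cells of all species. This is the simplest model consistent with random
  cross-complex ligation, and it is the only source of hybrid di-tags in a
  mixture.

Fragment maps are generated per species: fragment lengths are drawn i.i.d.
as $100 + \mathrm{Exp}(\mu - 100)$ bp so the requested mean $\mu$ is exact
and no fragment is shorter than 100 bp (the last fragment of each
chromosome is truncated); each fragment end carries a clipped-Gaussian GC
fraction standing in for the GC content of its terminal 200 bp. No sequence
is stored — the downstream analyses only consume length and GC
heterogeneity. Optional *bias injection* thins candidate di-tags with
probability proportional to the entries of true 20×20 acceptance matrices
over fragment-length and GC quantile bins, giving ground truth for the bias
estimator.

Read positions are placed near the ligated fragment end (exponential
offset, mean 150 bp), with strand encoding which end was ligated; this is
what makes segment-length filtering and re-ligation detection meaningful on
synthetic data.

Every record carries a hidden `truth` label (`intra_complex`/`spurious`).
All randomness flows from one master seed through deterministically derived
sub-streams, so any dataset is exactly reproducible.

**What the generator does not emulate:** mappability holes, copy-number
variation, chromosome territories and arm-level structure, sequence-driven
digestion patterns, PCR duplication structure, and the distance-dependence
of spurious partners within partially lysed nuclei (an open question for
any such model — uniform pooling is assumed, not inferred). Tests passing
on synthetic data therefore validate the *algorithms* under the stated
statistical model, not the full complexity of real libraries.

## Di-tag classification

`classify_ditags()` assigns each mapped record one class, in priority
order: `same_fragment` (both ends on one fragment), `re_ligation`
(adjacent fragments, inward-facing reads — the re-joined native cut site),
`duplicate` (identical coordinate/strand tuple after canonical end
ordering, so duplicates are orientation-invariant), then `valid`. Locality
(`cis`/`trans`/`hybrid`) is assigned on unique (valid, deduplicated)
records. In the summary, percent re-ligation is expressed relative to
mapped di-tags while the locality percentages are relative to unique
di-tags, so cis + trans + hybrid = 100; this matches the usual pipeline
report arithmetic. The re-ligation definition and the re-ligation
denominator are conventions, stated here because upstream report formats
leave them implicit.

## Library QC

`locality_ratios()` reports the trans fraction and the far-cis fraction
(default threshold 20 Mb, with 10 Mb exposed as the common alternative —
both conventions are in circulation, and `contamination_sweep()` uses
10 Mb). Both ratios increase together as the random-ligation fraction
rises, and their near-perfect correlation across libraries differing only
in contamination is itself a diagnostic.

`powerlaw_curve()` bins unique cis di-tags into 50 bins of equal width in
log10 distance over 10 kb–100 Mb and reports frequency density as count
divided by the *linear* (bp) bin width, so the log–log slope of the density
estimates the decay exponent directly. Distances are measured between the
5' read positions of the two ends, which is stable under fragment-length
variation.

## Fragment-end bias estimation

Coverage biases factorize over fragment ends. `estimate_bias()` fits the
model in which the probability of a trans contact between fends $i, j$ is
proportional to
$F_{len}[b_{len}(i), b_{len}(j)] \cdot F_{gc}[b_{gc}(i), b_{gc}(j)]$,
with each fend assigned to one of 20 equal-occupancy quantile bins of
fragment length and of terminal-200-bp GC. Trans data are used because,
absent bias, all trans fend pairs are a priori equally likely. Di-tags can
first be cleaned with `segment_length_filter()` (default 500 bp on the
summed read-to-fend distances).

Rather than enumerating per-fend-pair Bernoulli outcomes, the likelihood is
aggregated: observed contacts per feature-bin cell are Poisson events
against the number of possible trans fend pairs in that cell as exposure.
Coordinate ascent alternates closed-form conditional-MLE updates of the two
matrices (each update can only increase the likelihood), with
symmetrization and geometric-mean normalization each sweep, until the
log-likelihood gain falls below 1e-6. Empty feature bins stay fixed at 1;
unmappable fends are excluded outright rather than modeled as a third
matrix. Because this aggregation is over *feature* bins, the genomic bin
resolution does not enter the likelihood; a `resolutions` argument is
recorded for provenance only. This collapses what would otherwise be
independent re-runs at several genomic resolutions into the single
finest-limit estimate.

**Calibration note.** Under the null (no bias), the log entries of the
estimated matrices are approximately Gaussian with SD
$\approx 1/\sqrt{K_{cell}}$. At $10^5$ di-tags over $\sim 210$ free cells
this puts the *expected maximum* absolute log entry near 0.10–0.13, so
null-recovery checks use a 0.2 ceiling on the maximum together with a 0.05
ceiling on the mean — bounds derived from that sampling model rather than
from a single realization.

## Contact matrices: masking, balancing, distance correction

`bin_contacts()` bins unique di-tags at a fixed bin size (or over explicit
variable-size bins such as TADs); each di-tag increments exactly one
upper-triangle cell and the stored matrix is symmetrized. `mask_bins()`
excludes bins with coverage below 20% of the mean or more than 4 SD from
it; mean and SD are computed over nonzero-coverage bins (zero-coverage bins
are always excluded — whether they belong in the mean is unstated in common
usage, so the nonzero convention is chosen and flagged).

`ice_correct()` factorizes observed counts as
$O_{ij} = \mu\, b_i b_j T_{ij}$ with equal corrected coverage per included
bin, by iterative proportional scaling (divide by the outer product of
relative coverages, accumulate $b$) until the coefficient of variation of
included-bin coverage is below 1e-6. The bias vector is normalized to mean
1 and $T$ is rescaled to the raw total, the scalar $\mu$ carrying the
residual scale. The fixed point is exact for already-balanced matrices, and
balancing a constructed $O = (b \otimes b)\,T$ recovers $b$ to cosine
similarity > 0.999.

`distance_correct()` divides each cis cell by the mean corrected value at
its bin distance, pooled over chromosomes, yielding an observed/expected
matrix with per-distance mean exactly 1; diagonal (distance-0) cells are
dropped because self-bin counts are artefact-dominated, and trans cells are
scaled by the mean included trans value.

## A/B compartments

Per chromosome, `call_compartments()` eigen-decomposes the Pearson
correlation matrix of the distance-corrected interaction profiles over
included bins. Distance correction is applied first so the trivial decay
component does not dominate the leading eigenvector. Labels follow the
eigenvector sign (positive = A) after orienting the vector to a supplied
activity track (an active-chromatin proxy): the vector is negated when its
correlation with the track is negative.

Among the first two eigenvectors, the one with the larger absolute
correlation with the activity track is selected. A sign-change-counting
rule ("the checkerboard rather than the arm split") was considered and
rejected: higher-order noise eigenvectors always oscillate more, so
counting sign changes systematically prefers noise on genomes without arm
structure, whereas activity correlation directly operationalizes what the
orientation step is for. When the two leading eigenvalues are separated by
less than 5% (configurable), the chromosome is excluded as having no clear
compartment signal — the generic form of dropping a chromosome whose first
two eigenvector profiles do not separate.

`hybrid_compartment_test()` counts hybrid di-tags whose two ends both fall
in labeled bins of their respective genomes into a 2×2 (A/B × A/B) table
and applies a two-sided Fisher's exact test. Under fully random
cross-complex ligation no association is expected; the test's type-I rate
on null simulations is part of the acceptance checks.

## Reproducibility: Spearman and DES

`matrix_spearman()` rank-correlates the shared included upper-triangle
cells of two matrices. Rank correlation is insensitive to noise that
preserves ordering, so it can report high reproducibility for libraries
with very different noise content. The *deviation from expected slope*
(`des()`) complements it: cells are stratified by genomic distance (log10
bins plus one trans stratum), an OLS line $y = ax + b$ is fitted per
stratum on raw counts, the slope is corrected for library size,
$a_{corr} = a\,C_x/C_y$, and

$$\mathrm{DES} = \mathrm{atan}(a_{corr}) - \mathrm{atan}(1)$$

in radians. DES is exactly 0 for identical libraries and for a pure global
rescaling ($y = 2x$ gives $a = 2$, $C_y = 2C_x$, $a_{corr} = 1$).
Uncorrelated noise attenuates the OLS slope
($a \to \mathrm{var}(signal)/[\mathrm{var}(signal) + \mathrm{var}(noise)]$),
driving DES negative — exactly what random ligation does to far-cis and
trans strata while near-cis strata stay reproducible.

Fits are on raw counts by default (a log2 option exists, and zero-zero
cells can be dropped); strata with fewer than 3 points or zero variance are
skipped and flagged. The stratum edges are a package choice — log10 bins
spanning the observed distances — since no canonical edge set exists. Two
caveats, both visible in the test suite: a stratum in which the expected
signal is nearly constant (so within-stratum signal variance ≈ 0) is
attenuation-dominated even for clean replicates, and a stratum straddling a
systematic change in the relation mixes two linear maps, attenuating both
fit directions. Comparative statements (noisier pair vs cleaner pair at
equal depth) are therefore the robust use of DES, and that is how the
package's checks phrase them.

## TAD boundaries from the directionality index

`directionality_index()` computes, for each 25-kb window stepped at 5 kb,
the contact sums $A$ (upstream) and $B$ (downstream) within 1 Mb on the
coverage-corrected fine-binned matrix, and the signed chi-square-like
statistic

$$\mathrm{DI} = \mathrm{sign}(B - A)\left[\frac{(A - E)^2}{E} +
  \frac{(B - E)^2}{E}\right], \quad E = \frac{A + B}{2},$$

with DI = 0 when $A = B$. Elementary bins failing a 15%/4 SD coverage rule
are excluded. The profile is smoothed with a ±25 kb running average
(11 points; truncated, NA-aware at edges), and `call_boundaries()` keeps
local extrema at least 0.5 SD from the genome-wide mean. Since every domain
junction produces a qualifying minimum (end of the upstream domain)
followed by a qualifying maximum (start of the downstream one), treating
each extremum as a boundary would double-count; one boundary is therefore
placed at the DI sign transition between a qualifying minimum and the next
qualifying maximum, rounded to a 25-kb lattice. Reversing a chromosome's
coordinate axis negates the profile exactly.

`consensus_boundaries()` intersects two sets after lattice rounding; exact
lattice match is the default, with `slop = 1` accepting one-step
neighbours (used where position jitter between replicates would otherwise
dominate the comparison). `boundary_overlap()` reports the fraction of one
set reproduced within a window (default 100 kb) of the other.
`aggregate_boundary_profile()` averages z-scored raw DI around boundaries
against `n_random` uniformly drawn control positions (default 9686,
seeded), optionally with a mean observed/expected contact pileup.

## Problem sizes and numerical choices

The packaged checks run at desk scale, chosen to keep each statistic's
sampling noise well inside its assertion margin: genomes of 1–20
chromosomes of 5–100 Mb; $10^4$–$2\times10^5$ di-tags per dataset; 1 Mb
bins for compartments (60 bins per 60 Mb chromosome), 5 kb elementary bins
for DI (≤ 2000 bins per chromosome); planted TADs of 0.75–1 Mb with 2–4×
enrichment; checkerboard enrichment 3×; contamination contrasts 0.01 vs
0.3–0.6. Convergence tolerances: balancing CV 1e-6 on constructed matrices
(1e-3–1e-4 on sparse fine-binned simulated matrices, where integer
sparsity makes the terminal CV plateau); bias-model log-likelihood gain
1e-6. Degenerate inputs are handled explicitly: zero-variance paired
differences, zero Fisher margins, empty strata, all-masked matrices and
chromosomes with fewer than 10 included bins all return flagged results or
informative errors rather than silent numbers.

## Limitations

* The spurious-ligation model is uniform over the pooled library; any
  spatial preference of cross-complex partners is out of scope.
* The bias estimator assumes the two 20×20 matrices factorize and ignores
  mappability as a modeled term (it is a hard filter).
* Compartment calling on genomes without arm structure cannot exercise the
  arm-vs-checkerboard ambiguity that motivates inspecting two eigenvectors
  on real human chromosomes.
* DES on sparse strata is attenuation-dominated; use it comparatively at
  matched depth.
* Dense matrices cap practical resolution at a few thousand bins per
  genome; genome-wide kb-scale human matrices are out of scope.
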