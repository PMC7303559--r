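---
title: "Nonspecific TF binding affinity and genomic zone classification"
author: "ntbaZones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonspecific TF binding affinity and genomic zone classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntbaZones)
```

## The model

Transcription factors spend most of their nuclear lifetime bound
*nonspecifically*, sliding along DNA in search of their true target sites.
`ntbaZones` quantifies this with a per-window **nonspecific TF binding
affinity (nTBA)**: the differential affinity of an *ensemble* of TFs —
represented by a collection of position weight matrices — to a short DNA
window, averaged over the whole collection.

Each motif is first converted to a **binding energy matrix**. We use the
Berg–von Hippel mismatch form

$$E_{j,b} = \ln\frac{f_{max,j} + p_0}{f_{b,j} + p_0},$$

where $f_{b,j}$ is the frequency of base $b$ at motif position $j$. The
consensus base has energy exactly 0 at every position and all energies are
non-negative, so site energies are additive mismatch penalties in thermal
units. The pseudocount $p_0$ (default 0.01) keeps energies finite for bases
never observed in the motif; the PWM-to-energy map itself is a modelling
choice — the mismatch form is the standard one in biophysical TF models and
is invariant to rescaling count matrices.

The probability that a TF occupies a site of energy $E$ follows a
**Fermi–Dirac form**

$$P(S) = \frac{1}{1 + \exp(E \cdot S - \mu)},$$

with the chemical potential $\mu$ tracking protein concentration; at
vanishing concentration the **Maxwell–Boltzmann limit** $P(S) \approx
\exp(-E \cdot S)$ applies. Both are implemented in
`bindingProbability()`; the two agree within 1% once $E - \mu \ge 5$, a
property the test suite checks against the closed form. Note that in this
parameterization more-negative $\mu$ *suppresses* binding: profiles
computed at $\mu = -13$ and below are essentially zero, which is why the
default scan potentials are $\mu \in \{0, -10\}$ — the regime where the
signal is informative.

A window of size $L$ (default 50 bp, stepping 5 bp) is scored for one TF as

$$A_i = p \sum_{l=1}^{L-m+1} P_{i,l}(S_i),$$

summing the binding probability over every motif offset; both strands are
scored and summed, since TF binding is strand-symmetric (a single-strand
switch is exposed). The local sequence-composition bias is removed by
subtracting the mean affinity over $R$ (default 10) mononucleotide shuffles
of the same window:

$$dbA_{i,T} = A_i - A_{i,R},$$

and the expected nTBA of the window is the ensemble average
$\frac{1}{n}\sum_T dbA_{i,T}$, assigned to the window center. The number of
windows on a sequence of length $N$ is $k = \lfloor (N-L)/st \rfloor + 1$.

Two reproducibility details matter. First, the $R$ shuffled variants of a
window are drawn once per window from a seeded stream
(`shuffleIndices()`) and scored by *every* motif: the mutated DNA exists
independently of the TF scoring it. This makes profiles bit-identical
across worker counts and invariant to motif reordering. Second, windows
where undetermined bases (N) exceed $L/2$ are reported as missing rather
than scored, so assembly gaps cannot masquerade as negative affinity; an
isolated N contributes its position's mean energy.

## Integration with epigenomic tracks and Hi-C

Downstream of the scan, the pipeline mirrors a standard integrative
workflow:

* **Feature preprocessing** (`preprocessFeatures()`): elements shorter than
  100 bp are dropped, a 1000 bp window is centered on each element's
  midpoint (for TSS records, the strand-aware 5' end), and duplicate
  windows are removed. Coordinates are BED-convention 0-based half-open at
  file boundaries and 1-based inside GRanges.
* **Coverage tracks** (`binCounts()`, `normalizeTracks()`): reads or
  intervals are counted into 100 bp bins by their midpoints (which makes
  bin totals conserve read counts exactly), scaled to counts per 10
  million, replicate-averaged, log2(x+1)-transformed and standardized to
  Z-scores per marker and chromosome. The upstream publication's exact
  normalization is cited but not printed; library-size scaling is the
  simplest scheme consistent with its description, and it is configurable.
  Z-scores use the population SD throughout the package (the convention
  that reproduces the worked 3-bin contact-matrix example exactly).
* **Hi-C contacts** (`zscoreMatrix()`, `detectedInteractions()`): a
  KR/ICE-normalized intra-chromosomal matrix at 250 kb resolution is
  standardized over its finite off-diagonal entries (matrix balancing
  itself is out of scope); a **detected interaction** is a bin pair with
  contact Z strictly above 0. Z-scoring is not distance-stratified,
  matching the single-matrix description of the source method.
* **Enrichment testing** (`markerBinValues()`, `enrichmentTable()`): within
  each 250 kb bin only signal inside ±500 bp feature windows (TSS and HOT
  centers) counts. Feature values are combined per bin by mean for
  epigenomic markers and by *sum* for nTBA — the affinity of clustered
  regulatory sequence is additive. Each detected pair is compared against
  100 random bin pairs with a rank-sum test (normal approximation with tie
  correction, checked against `wilcox.test` and exhaustive rank
  computation).

One genuinely open design point deserves emphasis: with bin-averaged
values the tested sample has $n_A = 2$, which caps the rank-sum $|Z|$ near
2.43 — *below* the high-enrichment threshold $Z \ge 3$ used downstream.
The package therefore defaults to a pooled mode in which every individual
feature value of the two bins enters sample A (`mode = "features"`), which
is the only reading under which the threshold is attainable; the
bin-average mode remains available as `mode = "bins"`. The nTBA channels
use TSS-only and HOT-only feature sets (sum rule) and the eight epigenomic
markers use the union of both (mean rule), yielding the 12-feature vector
per bin.

* **Frequencies** (`binFrequencies()`): per bin, $N_{vi}$ counts detected
  interactions and $F_i = N_{vi}/N_t$; per marker, $N_{ei}$ counts detected
  interactions with enrichment $Z \ge 3$ (inclusive) and
  $F_{he} = N_{ei}/N_t$. $N_t = \lceil \text{length}/\text{resolution}
  \rceil$ is the chromosome's bin count — 325 for hg19 chr17 and 253 for
  chr20 at 250 kb.

## Zone classification

Bins are clustered on their 12-dimensional $F_{he}$ vectors:

1. seeded k-means (k = 3 for the zone analysis; `stressCurve()` offers a
   data-driven choice via $stress(k) = \sqrt{WSS/TSS}$ with a 10% elbow
   rule — the cited stress function is not printed in the source, so this
   Kruskal-stress-like ratio is used and documented as the package's
   choice; the elbow selects the last k before the curve flattens, which
   is the reading consistent with a three-cloud example selecting k = 3);
2. per bin, inverse-distance probabilities $p_{dist}(c) \propto
   1/(\varepsilon + d_c)$ with $\varepsilon = 10^{-12}$ guarding bins that
   coincide with a centroid;
3. a Gaussian mixture with k components fitted to the same rows (via
   `mclust`), components matched to k-means clusters by optimal
   centroid-to-mean assignment (exhaustive over permutations for k ≤ 7);
   when the mixture fit is singular — common when many rows are exactly
   zero — the package falls back to diagonal Gaussians estimated from the
   k-means partition with inflated variances, with a warning;
4. final probability $w \cdot p_{dist} + (1-w) \cdot p_{mix}$ with
   $w = 0.5$ by default (the weighting is unspecified in the source and
   exposed as a parameter); each bin takes the argmax, ties to the lower
   index.

`labelZones()` then ranks the three clusters by mean $F_i$ ascending: low,
medium and high interaction frequency become types I, II and III — the
Inactive, Poised and Active Genomic Zones. Exact ties in mean $F_i$ break
by mean $F_{he}$. `stateOverlap()` intersects zone bins with seven-state
chromatin segmentations (codes TSS, PF, E, WE, CTCF, T, R; ≥ 1 bp overlap
counts a segment), and `coreBins()` intersects labelings across cell lines
to define core type I/II/III bins with Venn counts.

## What the synthetic fixtures emulate — and what they do not

`fixtureSpec()` drives seeded generators for every input:

* `genSequence()` — i.i.d. background at human-like GC (0.41) with exact
  consensus instances of `genMotifs()` motifs planted in a 200 bp central
  cluster (10 instances, random strand). The scan's profile maximum should
  fall within ±100 bp of the cluster center; the suite requires this in at
  least 9 of 10 seeds.
* `genZoneDataset()` — 60 bins of 250 kb in three equal contact regimes.
  A pair's contact value is the sum of its bins' regime strengths
  (1, 2, 3) plus Gaussian noise (SD 0.5), so detected-interaction
  frequency rises with regime. Every bin carries 10 TSS and 10 HOT
  features (the real chr17/chr20 densities are roughly 6 and 13 per
  250 kb bin); markers are lognormal noise (sdlog 0.25) boosted inside
  feature windows by regime effects of 0, 2.5 and 5 noise-SDs for active
  marks and nTBA surrogates, with repressive marks held at the moderate
  boost in both regimes 2 and 3. This reproduces the qualitative zone
  signature — type II bins show low nTBA enrichment but moderate
  histone-mark enrichment, type III high everything.

The fixtures deliberately omit Hi-C distance decay, nucleosome-scale
sequence structure, replicate variability and mappability artifacts.
Passing tests therefore demonstrate that the *algorithms* recover planted
structure under realistic noise, not that the biological conclusions
transfer to any particular dataset.

Problem sizes were chosen so the whole suite runs in a few minutes on one
core: oracle comparisons use ≤ 2 kb of sequence and ≤ 5 motifs, recovery
checks use 5 kb sequences and 60-bin chromosomes, each across 10 seeds.

## Numerical choices and degenerate inputs

* Exponents in `bindingProbability()` are clamped at ±700, so extreme
  energies underflow to 0 instead of overflowing.
* Energy matrices are re-anchored after the log so the per-position
  minimum is *exactly* 0 despite floating point.
* A zero-total or constant coverage track raises an error naming the
  marker (no Z-score exists).
* A contact matrix with zero off-diagonal variance is an error; an
  already-standardized matrix passes through unchanged.
* `makeGrid()` with N < L returns an empty grid (k = 0), not an error;
  motifs wider than the window are skipped with a warning, and a scan with
  no usable motif is an error.
* Unknown chromatin-state codes and mismatched bin grids are errors listing
  the offending labels/grids.
* k-means uses 10 restarts under a fixed seed; all randomness in the
  package flows through explicit seeds (windows use a per-window derived
  seed kept below $2^{31}$), and global RNG state is saved and restored
  around every seeded operation.

## Known limitations

* The rank-sum normal approximation is coarse for very small samples; the
  pooled "features" mode exists precisely because the bin-average mode
  cannot reach $Z \ge 3$. Interpret per-pair Z values comparatively, not
  as calibrated p-values.
* Chemical-potential wording: the implementation follows the printed
  Fermi–Dirac form, under which more-negative $\mu$ means *less* binding;
  no attempt is made to reinterpret $\mu$ physically.
* Matrix balancing (KR/ICE), trans contacts, TAD/loop calling, motif
  discovery and external enrichment services are out of scope.
* Genome-scale inputs work but the scan is plain R; for whole-chromosome
  runs, split by chromosome and use the `workers` argument.
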