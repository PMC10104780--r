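---
title: "Methods: multiscale Hi-C and translocation analytics for DSB repair"
author: "dsb3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale Hi-C and translocation analytics for DSB repair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsb3d)
```

# Scope and model

`dsb3d` analyzes how sequence-specific DNA double-strand breaks (DSBs)
reorganize the 3D genome, and how that reorganization relates to chromosomal
translocations. The experimental system it targets is a cell line carrying a
4OHT-inducible AsiSI restriction endonuclease: induction creates on the
order of a hundred efficiently cut sites genome-wide, Hi-C captures the
contact-map response, and high-throughput genome-wide translocation
sequencing (HTGTS) recovers junctions between a fixed bait break and
genome-wide prey loci.

The package has two analysis arms plus a synthetic-data generator:

* **Hi-C arm** — sparse binned contact matrices (cooler-dump-compatible
  text), iterative-correction (ICE) balancing, distance-decay expected
  models and observed/expected (O/E) transforms, contact-probability
  scaling P(s) with its log-log derivative, diamond insulation, compartment
  eigenvectors phased by gene density, compartment-flip calling, saddle
  plots/strength, aggregate pileups at damaged-site pairs and oriented CTCF
  anchors, a cluster-enrichment score with a constrained resampling null,
  convergent-loop scores, and anchored differential tracks.
* **HTGTS arm** — TLX-style junction tables, bait-only and per-1,000-event
  normalization, 100-kb frequency tables, prey-distance classes,
  microhomology (MH) / blunt / insertion junction classification, insertion
  mapping, promoter/gene-body/intergenic annotation, and differential
  comparison between treatment arms with a Wilcoxon test.
* **Generator** — plants every parameter the two arms estimate, so the test
  suite is built on parameter recovery rather than golden files.

# Hi-C methodology

## Balancing and expected models

`ice_balance()` computes per-bin multiplicative weights equalizing balanced
marginals, masking the first two cis diagonals (self-ligation and adjacent
bins carry protocol artifacts, so they are excluded from the marginals by
default; `ignore_diags` is exposed). Bins with zero coverage, or log
coverage more than `mad_max = 5` median absolute deviations below the
median, are filtered to missing and propagate as missing through every
downstream stage. Convergence is a relative marginal deviation below
`tol = 1e-5` (capped at `max_iter = 1000`, with an error carrying the last
residual on failure). The test suite checks the balanced matrix elementwise
against a dense Sinkhorn oracle.

`expected_cis()` averages balanced values per chromosome per diagonal over
pairs of unfiltered bins; diagonals with no valid element are undefined
(NA), never zero. `observed_over_expected()` divides by the expected at the
same separation, which forces every diagonal's mean O/E to 1 — an identity
the tests assert to 1e-9 rather than a tunable.

## P(s) and its derivative

`contact_scaling()` pools the per-diagonal expected into geometric
separation bins (default 8 per decade) and differentiates log P against
log s by central finite differences on the binned curve, with one-sided
differences at the ends. No smoothing is applied beyond the log binning;
the derivative of a pure power law therefore recovers the exponent
analytically, and the tests demand planted exponents of -1.0 and -1.5 back
within 0.1 from Poisson-sampled maps at 5 million pairs.

## Insulation

The insulation score is a reconstruction (the upstream literature names the
phenomenon but not a formula): a sliding diamond of `window` (default
100 kb) on each side of the bin, log2-normalized to the chromosome-mean
diamond score, the convention of standard Hi-C toolkits. Bins within a
window of a chromosome end are missing. Planted block boundaries score as
local minima in the tests.

## Compartments, flips, saddles

`compartment_eigenvector()` takes, per chromosome, the leading eigenvector
(largest eigenvalue) of O/E - 1 with filtered rows removed and re-inserted
as NA, scales it by the square root of its eigenvalue, and orients it so
its correlation with gene density is non-negative. A/B labels follow the
sign; an exactly zero value is left unassigned (strict inequalities leave
zero undefined), and a chromosome with fewer than 10 valid bins gets a
missing eigenvector with a warning. When the correlation with gene density
is exactly zero the arithmetic sign is kept and a warning emitted.

`detect_flips()` classifies each bin's A/B transition between conditions.
Headline fractions use the pooled-condition labels when pooled results are
supplied (replicate 1 otherwise), while the consistency flag demands that
every pairing of a condition-1 replicate with a condition-2 replicate
agrees on the transition; fractions are reported over consistently
assigned bins and sum to 1. This split mirrors how damage-induced B-to-A
flips are reported as replicate-consistent percentages while pooled tracks
are plotted.

`saddle()` ranks bins by eigenvector value, drops the outer 0.2 percentiles
of the ranked values, and splits the rest into 30 equal-count groups
(sizes differ by at most one bin). Trimming and ranking are genome-wide by
default with a per-chromosome option — the choice is not determined by
upstream conventions; genome-wide ranking keeps quantile boundaries
comparable across chromosomes. Strength at depth k is the mean O/E of the
k-by-k A-A (or B-B) corner divided by the mean of the two matching A-B
corners; it is exactly 1 on a uniform map and scale-invariant.

## Pileups and scores

`pairwise_pileup()` snips O/E windows of +/-1 Mb at 25-kb bins around each
cis pair of damaged sites ("2 Mb flanking window" is read as a 2-Mb-wide,
+/-1 Mb window — an 81 x 81 aggregate — which is also the only reading
under which the 125 kb–1 Mb score ring fits). Snippets are dropped, and
counted, when a site is within a flank of a chromosome end or the pair
separation is at most twice the flank (the window would cross the
diagonal); cells with missing O/E are skipped per cell, and a snippet whose
center cell is missing is dropped wholesale.

`cluster_enrichment_score()` is the mean linear O/E of the central 5 x 5
block (125 kb at 25-kb bins, reconciling the "5 x 5 central bins" and
"five central bins (125 kb)" phrasings as a 2-bin Chebyshev radius)
divided by the mean over cells beyond the block and within 1 Mb of center,
ring membership by cell-center Chebyshev distance with ties at the radius
included. Ratios are computed on linear O/E means — "average interaction
frequency" is a linear quantity — with a `log_space` flag for sensitivity
analysis; log2 matrices are kept for display only.

`matched_control_null()` re-draws the damaged-site catalog 100 times under
three constraints: control loci at least 125 kb from every recognition
motif, per-chromosome counts identical to the damaged set, and undamaged-
control compartment labels identical. The last two are enforced jointly by
sampling within (chromosome, label) strata, which guarantees both
marginals; an understocked stratum is an error naming the stratum. Each
resample uses an independently derived RNG stream from the master seed,
recorded in the output.

`ctcf_pileup()` aggregates on-diagonal windows at oriented CTCF anchors,
reflecting minus-strand snippets so all motifs point rightward, and
quantifies extrusion "flame" lines as the mean O/E along the row/column
from center (two nearest-diagonal cells excluded) minus off-line
background. `convergent_loop_score()` aggregates windows at convergent
(+ upstream, - downstream) anchor pairs separated by 25–1,000 kb and
scores the central 5 x 5 block against the 25–100 kb ring; short-range
pairs may cross the diagonal and are retained.

# HTGTS methodology

A junction record carries the prey locus, the read sequence, and the
1-based read coordinates of the last bait-aligned base (`bait_end`) and
first prey-aligned base (`prey_start`). With `gap = prey_start - bait_end`:
gap 1 is blunt (classical NHEJ signature), gap <= 0 is a microhomology of
`1 - gap` shared bases (alternative end-joining signature), gap >= 2 is an
insertion of the intervening bases. Classification is coordinate-driven
even when flanking micro-matches exist, matching coordinate-based
pipelines; supplied references trigger a cross-check warning when the
implied homology is unsupported. The class summary buckets MH lengths as
"MH 1–5" versus "MH >= 6": the published labels "MH 1–5" and "MH > 6"
leave length 6 ambiguous, and partitioning requires assigning it to the
upper bucket; the boundary is the `mh_split` parameter.

Frequency tables bin junctions into 100-kb windows and normalize both per
bait-only read (the cross-library comparable scale) and per 1,000 total
events; both are always emitted since figures use both conventions.
`differential_translocation()` keeps bins with at least 10 raw events
summed over the two conditions (whether the published filter counts one or
both conditions is unstated; the combined count is used and exposed),
reports log2 fold changes with a 0.5-raw-event pseudocount applied only to
the fold-change display, and tests the genome-wide shift with a paired
Wilcoxon signed-rank test on the raw normalized differences (the +/- drug
comparison lives on the same bait and bin grid; an unpaired option
exists). Prey-distance classes use motif-center to junction-base distance:
below 500 bp proximal, above 10 kb distal, the gap in between reported as
intermediate but excluded from two-class summaries. Promoter annotation is
TSS +/- 3 kb with precedence over gene bodies. Insertion mapping does an
exact-match search of the insert and its reverse complement in the prey
flank, then the bait flank, restricted to the 20–30 nt range the reporting
pipeline can place.

# The synthetic-data generator

`simulate_contact_map()` draws Poisson pixel counts from a cis intensity

    p_ij  ~  s^-alpha * (1 + kappa c_i c_j) * loop(i,j) * cluster(i,j)

with `s` the bin separation (the diagonal uses the adjacent-bin intensity,
keeping the off-diagonal decay a clean power law), `c` a +/-1 block
("plaid") compartment vector whose configured flip set switches B-to-A in
the damage condition, and multiplicative focal boosts at cut-site pairs
(damage only) and convergent CTCF anchor pairs. Defaults encode the study
conditions the estimators are validated against: decay exponent 1,
compartment contrast kappa up to 0.3–0.4, a 15% B-to-A flip fraction drawn
from B bins, cluster boost beta = 2 at damaged-site pairs, loop boost
lambda = 2.5, two replicates per condition, and library sizes of 3–10
million pairs on toy genomes of two to four 30–50 Mb chromosomes — sizes
chosen so every planted parameter is recoverable with comfortable margin
by the corresponding estimator.

Two shape choices matter for interpretability. The cluster boost is a
flat-top of Chebyshev radius 2 bins (125 kb at 25-kb bins, the width of
the score's central block) with Gaussian shoulders (sigma 1 bin): a pure
point Gaussian would make the planted height and the 5 x 5 block average
diverge, leaving no ground truth for the score to recover. Loop dots are
hard-edged (sigma 0) by default because their score ring is tight
(25–100 kb) and Gaussian shoulders would leak planted signal into the
ring's denominator. Counts are Poisson, not negative-binomial — the
simplest noise sufficient for recovery testing; overdispersion, per-bin
bias (testable by binomial thinning), trans contacts, TADs, and
polymer-physics realism are out of the generator's scope, so passing
recovery tests demonstrates estimator correctness on the planted
structure, not performance on real Hi-C libraries.

`simulate_junction_library()` builds each read as bait prefix + (shared MH
bases | nothing | insertion) + prey suffix with coordinates set from the
construction, returning truth labels for round-trip testing. References
avoid adjacent repeated bases and junction-flank coincidences so the
planted class is the unique maximal-overlap reading of each read — the
brute-force overlap oracle in the tests must agree on 100% of 10,000
reads, which is only a meaningful bar if chance homology cannot blur the
truth. The default class mixture is 18% blunt / 69% MH / 13% insertion,
and insertions are capped at 30 bp (the reporting pipeline's limit); an
`insertion_source = "prey_antiparallel"` mode copies inserts from the
reverse complement of the prey flank so the mapper's strand call can be
validated on planted truth.

`mouse_like_cut_sites()` is a synthetic 19-chromosome stand-in for the
frequently cut AsiSI catalog: 97 sites whose per-chromosome counts were
constructed to give exactly 304 cis pairs, the two published constraints;
the real per-chromosome table is not redistributed. `make_site_catalog()`
also scans sequences for the (palindromic, checked at runtime) AsiSI
recognition motif GCGATCGC.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; BED/bedGraph are read
  as-is, 1-based sources (TLX `Junction`) are converted on ingest.
* Bin ids are 1-based in memory and 0-based in pixel files, matching
  cooler dumps.
* Balancing normalizes each marginal to 1; O/E is invariant to that scale.
* Equal-count quantile assignment uses `floor((rank-1) * q / n) + 1`, so
  group sizes differ by at most one.
* Empty pixel lists, all-zero bins, fully filtered diagonals, chromosomes
  below the eigenvector bin minimum, empty gene models and zero bait-only
  counts all degrade to NA/warnings rather than silent zeros; genuinely
  uninterpretable states (no usable snippets, no bins past the event
  filter, understocked resampling strata) are errors.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; replicate and resample streams are derived
  deterministically from the master seed.

# Known limitations

The generator's plaid-plus-power-law world omits distance-dependent
compartment mixing, TAD hierarchies, and trans contacts, and its gene
density is a noiseless function of the planted compartments, so phasing is
easier than on real annotation. Insulation is a reconstruction, not a
published formula. The Wilcoxon variant, the >= 10-event filter scope, and
the MH length-6 bucket follow documented choices among readings the source
material leaves open. Scores on real data additionally reflect mapping,
filtering and balancing artifacts that the synthetic inputs do not carry.
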