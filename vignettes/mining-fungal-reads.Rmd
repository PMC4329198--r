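---
title: "Mining a fungal community from raw host shotgun reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining a fungal community from raw host shotgun reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycomine)
```

## The problem

Whole-genome shotgun sequencing of a eukaryote co-sequences whatever
microbes travel with the sample. After the host genome is assembled, the
reads that do not map to it — often a double-digit percentage of the raw
data — are usually discarded, yet they contain a usable census of the
associated microbial community. `mycomine` implements the full procedure
for extracting a fungal community from such a raw read pool: exact-match
host subtraction, identity-threshold marker-gene matching with
best-stratum semantics, conservative taxon assignment, richness and
abundance summaries, rarefaction, community comparison, and a ratio-based
extrapolation of the total fungal read content.

Real inputs at the original scale (hundreds of millions of reads, a
hundred-thousand-sequence ITS reference set) are not tractable on a
workstation, so the package ships a first-class synthetic-data generator
that reproduces the statistical structure of the problem with known
ground truth. Everything the tests and the acceptance script claim is
measured on those synthetic conditions or on self-contained arithmetic
over published counts; neither stands in for a re-analysis of the
original dataset.

## Host subtraction

A read is classified as host iff it has at least one *perfect*
end-to-end placement (zero mismatches, either strand) on the host
genome. This mirrors exact-match host exclusion: reads carrying even one
sequencing error survive subtraction, so the unmapped pool is a mixture
of true non-host reads and error-bearing host reads. That is a property
of the method being modeled, not a defect of the implementation — the
downstream marker matching is what separates fungi from the remainder.
`subtract_host()` is idempotent and reports `total = host_matched +
unmapped`.

## The matcher: identity thresholds as mismatch budgets

The alignment step emulates an ungapped short-read aligner run in
best-stratum reporting mode:

* **End-to-end, ungapped, both strands.** A placement aligns the whole
  read against a contiguous reference window; the reverse complement is
  searched symmetrically. There are no gaps, consistent with the
  substitution-only error model.
* **Identity per read.** A minimum identity `t` on a read of length `L`
  becomes a mismatch budget `b = floor((1 − t)·L)`; identity is
  `(L − mismatches)/L`. The floor makes the threshold conservative (95%
  on 76 bp means ≤ 3 mismatches). A tiny epsilon (`1e-9`) guards the
  floor against floating-point representation (e.g. `(1−0.9)·10`
  evaluating just below 1).
* **Best stratum.** Among admissible placements, only those with the
  minimal mismatch count are reported, deduplicated by
  `(reference, offset, strand)`. An important consequence used by
  `threshold_sweep()`: the best stratum of a read is *identical* at every
  threshold that admits it, so one alignment at the loosest threshold,
  filtered by per-read minimal mismatch count, reproduces every stricter
  run exactly — and matched-read sets are provably nested as the
  threshold relaxes.
* **Seeding.** Candidate placements are found through a hash index of
  every reference k-mer (forward strand, default `k = 16`): a placement
  is discovered iff read and reference share one exact k-mer at a
  compatible offset. By pigeonhole, discovery of every admissible
  placement is guaranteed when `L ≥ k·(b + 1)`; the pipeline refuses
  configurations that violate this (e.g. 40-bp reads with `k = 16` at
  95%). Tests that use shorter reads drop to `k = 8`.
* **Ambiguity codes.** Any position where either base is not A/C/G/T
  counts as a mismatch, and k-mers containing such codes are not seeded.
  This is the conservative, reproducible choice; IUPAC-aware matching
  would admit placements that depend on how the reference encodes
  uncertainty.

The matcher core is C++ (via Rcpp), as is usual for this kind of inner
loop; the test suite checks it against an independent exhaustive-offset
oracle built on `Biostrings::neditStartingAt` over every reference
window and strand, at four thresholds.

## FC1 and FCT communities

A matched read's best-stratum hits may name one taxon or several. Two
community summaries follow:

* **FC1** — reads whose hits all agree on a single taxon *at the rank
  under consideration*. Agreement is evaluated per rank, because a read
  can be ambiguous between two genera of the same class (FC1 at class,
  MULTI at genus). Only FC1 supports exact relative abundances.
* **FCT** — every taxon named by any matched read, with supporting-read
  counts. It is a presence catalogue: multi-taxon reads make exact
  abundance undefined, so `relative_abundance()` refuses FCT profiles
  outright rather than normalizing something that is not a composition.
  FCT overestimates richness by construction; FC1 taxa are always a
  subset of FCT taxa.

Hits whose lineage is `UNKNOWN` at the rank are excluded from the
agreement vote; a read whose every hit is `UNKNOWN` there is
unassignable (MULTI). Reference lineages are seven fixed ranks (phylum
through species), padded with the `UNKNOWN` sentinel so per-rank tables
stay rectangular; a named rank below an `UNKNOWN` rank is legal but
flagged. Lineages load from a two-column TSV sidecar or from
`p__`-style header suffixes — both encodings are common for ITS
datasets, and the choice of a sidecar as the canonical on-disk form is
this package's normalization.

## Rarefaction

`rarefy()` subsamples the FC1 read labels without replacement
(`replicates` per depth, default 100; default depth grid 20 log-spaced
points) and reports mean and sd of distinct-taxon counts. At full depth
it equals the full-sample richness with sd 0. On a uniform community the
mean matches the hypergeometric closed form
`S·(1 − C(N−n, d)/C(N, d))`, which the tests verify within 3 standard
errors (and cross-check against `vegan::rarefy`). The curve answers the
saturation question: a curve still rising at full depth means deeper
sequencing would reveal more taxa.

## Community comparison

`bray_curtis()` implements `d = 1 − 2·Σ min(p_i, q_i)/(Σp + Σq)` on raw
counts. Counts, not proportions, are the default because the comparison
tool being emulated operates on the data as given; `bray_curtis_matrix()`
offers optional proportion normalization for communities of very
different depth. The dissimilarity is symmetric, relabeling-invariant,
and scale-invariant under joint rescaling — all property-tested, with
`vegan::vegdist` as an independent cross-check.

`nj_tree()` produces the Saitou–Nei neighbour-joining tree. Neighbour
joining is a standard step, so it is delegated to `ape::nj()` behind the
package's interface rather than reimplemented; the package adds input
validation (symmetry, zero diagonal), a two-leaf closed form, and the
post-processing rule for negative branch lengths (clamp to zero, move
the deficit to the sister branch so adjacent path lengths are
preserved). On additive distances the generating tree is recovered
exactly — property-tested over random 5–8-leaf trees.

## The fraction estimator

Marker hits see only the marker-covered slice of each fungal genome. For
a calibration subset of fungi with both a sequenced genome and a marker
sequence, the ratio

&nbsp;&nbsp;&nbsp;&nbsp;`r = genome hits / marker hits`

measures how many genome-wide reads stand behind one marker hit.
Applying `r` to the marker hits against the *full* marker dataset
extrapolates the total fungal read count; dividing by the pool sizes
gives its fractions of the unmapped and raw data. All counts are
deduplicated read counts at the same identity threshold (default 0.95).

The estimator is exactly scale-invariant in the calibration counts, and
unbiased when the calibration subset and the community share their
marker copy number: with copy number `c`, marker hits scale like `c·f₁`
both in the calibration denominator and the community numerator, so `c`
cancels. A copy-number *mismatch* biases the estimate predictably — a
ratio calibrated on `c`-copy genomes applied to a single-copy community
underestimates by the factor `1/c` — which the tests demonstrate by
construction, and which is the mechanism by which abundant marker copies
depress the calibration ratio in real data.

The published worked example carries a small internal inconsistency
(the printed total, 2,715,759, is the product of the printed marker
count and a ratio of ≈ 44.36, while the ratio is printed as 44.1). The
package computes from raw counts at full precision and reports both pool
fractions from the printed total; rounding conventions (ratio to 1
decimal, percentages to 2) are applied only at presentation time. A
related presentation detail: 89 matched reads over 2,362 references is
0.0376…, printed as 0.037 — i.e. truncated, not rounded, and the
acceptance report follows that convention for that value.

## The synthetic-data generator

`sim_config()` defaults describe the validation conditions: 100,000
reads of 100 bp, 83% host (so ~17% of reads survive into the non-host
pool), a four-genus community with weights 0.88/0.05/0.04/0.03
(a strongly dominant genus, as observed in real insect mycobiomes), 1%
per-base substitution error, 500-bp genus-specific markers embedded once
per 30-kb genome. Where a study condition fixes a value (weights, host
fraction, error magnitude, read length) the default *is* that value;
genome and host lengths are desk-scale choices that keep marker-hit
counts in the hundreds-to-thousands range where the statistical checks
have power without multi-minute runtimes.

What it emulates: the host/fungal mixture; genus-specific marker regions
at recorded coordinates inside fungal genomes (configurable copy
number); a nested seven-rank taxonomy; i.i.d. substitution errors with
recorded per-read counts; full reproducibility (byte-identical files
from the same seed). A "confusable markers" mode derives one genus's
marker from another at a configurable Hamming distance to exercise MULTI
assignments.

What it does not emulate — and therefore what passing tests do *not*
show about real data: real ITS length variation and copy-number
heterogeneity across taxa, indels (the error model is substitution-only,
consistent with the ungapped matcher), GC bias, chimeras, quality-score
structure, paired-end inserts, and real inter-genus sequence similarity
(markers are independent random sequences unless the confusable mode is
used, so cross-genus ambiguity is rarer than in real references).
Genomes outside marker regions are random sequence: adequate for the
genome-vs-marker ratio logic, not for biological realism.

`expected_marker_read_fraction()` gives the closed-form expectation of a
read overlapping a marker copy, `copies·(m + L − 1)/G` per genome
(composition-weighted, capped at 1). It ignores the small edge effect
(read starts range over `G − L + 1`, not `G`), which the Monte-Carlo
test accounts for explicitly.

## Numerical and design choices

* Mismatch budgets use `floor` with a `1e-9` epsilon (see above).
* Profile listings order taxa by count descending, then name ascending —
  a deterministic tie-break.
* Neighbour-joining tie-breaking among equal Q-values is delegated to
  `ape::nj`'s deterministic implementation.
* Degenerate inputs fail loudly: empty reference FASTA, duplicate record
  ids, malformed lineage lines (with the line number), non-symmetric
  distance matrices, FCT abundance requests, zero calibration marker
  hits, rarefaction depths beyond the sample.
* Reads shorter than the seed length are classified unmatched with a
  warning rather than erroring, so one fragmentary read cannot abort a
  run.
* Host subtraction is fixed at 100% identity; the marker threshold
  defaults to 0.95 with the sweep covering 1.00/0.99/0.97/0.95.
* `run_pipeline()` artifacts embed a hash of the analysis parameters
  (excluding the output directory) and the seed, so reruns are
  byte-identical wherever they are written.

## Repository shape

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` (simulate → subtract → sweep → profile → diversity →
fraction) are thin narrative drivers over the exported functions, writing
their tables under `results/` and bulky regenerable inputs under
`scratch/`. All computation lives in the package so the tests and
`scripts/acceptance.R` exercise the same code paths; `run_pipeline()`
provides the same stages as a single orchestrated call driven by a
configuration object or YAML file. No shell-level interface is provided:
the intended users work in R, and the scripts plus the vignette are the
command surface.

## Validation problem sizes

The checks are sized for statistical power at workstation scale: aligner
oracle equivalence on 1,000 reads × 50 references × 4 thresholds;
composition recovery on 100,000 reads (the dominant-genus conditions
above) with multinomial 3σ bands around the configured weights;
estimator recovery on 10 seeds × 50,000 reads with a 15% mean relative
error bound (per-seed sampling noise is ~5%, so the bound tests the
method, not one draw); rarefaction against the hypergeometric form with
200 replicates; neighbour-joining recovery over 10 random additive
trees. The full test suite runs in about five minutes on one CPU.

## Known limitations

* Ungapped matching cannot place reads across indels or chimeric
  junctions; real divergent ITS alleles will under-match relative to a
  gapped aligner at the same nominal identity.
* FC1 conservatism discards genuinely informative multi-taxon reads; the
  FCT catalogue bounds the community from above but carries no
  abundances.
* The fraction estimator inherits every copy-number caveat above: with
  unknown real copy numbers it is a lower-bound-flavoured point
  estimate, not a confidence interval.
* Host subtraction at 100% identity leaves error-bearing host reads in
  the unmapped pool; they are invisible to marker matching but inflate
  the denominator of "fraction of unmapped data" quantities, exactly as
  in the emulated procedure.
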