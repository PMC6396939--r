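---
title: "Peak calling on variation graphs: model and methods"
author: "dagpeaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak calling on variation graphs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dagpeaks)
```

## The problem

ChIP-seq detects transcription-factor binding by sequencing the ends of
immunoprecipitated DNA fragments and looking for positions where many
fragments pile up.  Classic peak callers assume reads are mapped to a
*linear* reference genome.  When reads are instead mapped to a
*variation graph* — a DAG of sequence nodes in which alternative alleles
(SNP branches, insertion nodes, deletion edges) diverge from and rejoin
a designated linear reference path — every step of the classic pipeline
needs a graph analogue, and in return the caller can trace binding
sites through variants that are not part of the linear reference at
all.

`dagpeaks` implements that generalization.  The five classic stages
and their graph analogues are:

1. **Fragment-length estimation.**  Reads are projected onto the linear
   reference path and the shift maximizing the cross-correlation
   between forward-strand and reverse-strand 5' start densities is
   taken as the fragment length $f$ (`estimate_fragment_length()`).
2. **Fragment pileup.**  Each read of length $r$ is extended from its
   3' end by $f - r$ bases along *all* possible directed paths
   (breadth-first); the pileup value at a base is the number of reads
   whose extended coverage set contains it — a read contributes at most
   once per base no matter how many extension paths reach it
   (`extend_alignment()`, `fragment_pileup()`).
3. **Background track.**  Control (or input) read starts are projected
   to linear coordinates; the local expected rate at a position is
   $\lambda = f \cdot \max(\rho_{global}, \rho_{1kb}, \rho_{10kb})$
   where $\rho_w$ is the read-start density in a centered window of
   size $w$.  The linear rate vector is then assigned back to every
   graph base through the projection, so parallel alleles share their
   background.  With a control library, rates are scaled by
   $n_{input}/n_{control}$ (`background_track()`).
4. **Scoring.**  Pileup counts are treated as Poisson observations
   with the background rates: $p = P(X \ge k),\ X \sim \text{Pois}(\lambda)$,
   upper tail including the observed count.  Because every base of the
   graph is one test, q-values are computed by Benjamini–Hochberg over
   all bases, pooled by distinct p-value with multiplicities
   (`pvalue_track()`, `qvalue_track()`).
5. **Peaks.**  Bases with $q < \alpha$ (default 0.05, strict) form
   candidate regions; gaps shorter than the read length are filled
   (all short parallel paths are filled, longer ones are not); the
   result is partitioned into connected *peak subgraphs*; within each,
   the directed path containing the largest number of input alignments
   is reported, peaks shorter than $f$ are removed, and each peak is
   trimmed to a fixed window (default 120 bp) around its summit — the
   path base with the lowest q-value (`fill_gaps()`,
   `connected_subgraphs()`, `find_max_path()`, `peak_summit()`,
   `trim_peak()`).

`call_peaks()` wires the stages together and returns a classed object;
`peaks_to_linear()` projects final peaks to approximate linear
coordinates for downstream tools expecting BED/narrowPeak.

## Coordinate projection

All linear coordinates come from one rule: a position on a reference
node maps to its cumulative offset; an off-reference position maps by
walking the *shortest backward distance* to the end of the nearest
upstream reference node and then walking that same distance forward
along the reference.  Parallel alleles of a bubble therefore collapse
to the same coordinate, which is exactly what the background track and
the final BED output need.  Ties among equally short backward routes
are broken by the smallest predecessor node id; positions inside
insertions longer than the remaining reference are clamped to the
reference length.  The rule is implemented as a single DAG dynamic
program over the topological order (`build_linear_projection()`), and
is checked in the tests against a brute-force backward breadth-first
search.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `min_mapq` | 37 | mapping-quality filter applied to input and control reads (inclusive) |
| `fragment_length` | estimated | fragment length $f$ in bases; the estimator scans shifts 0–600 and smooths the correlation profile with a 21-shift moving average before the argmax |
| `qvalue` | 0.05 | FDR threshold; a base is significant iff $q <$ this value (strict) |
| `windows` | 1 kb, 10 kb | local background window sizes; without a control the input backgrounds itself and the smallest window is replaced (5 kb, 10 kb) so the signal does not inflate its own background |
| `trim_width` | 120 bp | reporting window around the summit; `NULL` disables trimming |

## Numerical choices

* Poisson p-values are computed in log space
  (`ppois(..., log.p = TRUE)`), so deep pileups keep finite
  $-\log_{10} p$ scores; scores are capped at 1000.
* The BH adjustment runs on the $-\log_{10}$ scale, pooling bases by
  distinct p-value (the adjustment only depends on the multiplicity of
  each distinct value), with monotonicity enforced by a running
  maximum from the smallest p upward and $q \ge p$ capping.  The unit
  tests compare it against `p.adjust(method = "BH")` on raw p-values.
* Background rates are floored at machine epsilon so p-values stay
  defined; every rate is strictly positive whenever at least one
  control read exists.
* All tie-breaks are deterministic: topological order and the
  maximum-path choice prefer reference-path nodes, then smaller node
  ids; summits take the leftmost base of a score plateau.  Identical
  inputs give byte-identical outputs.

## Maximum-path support

"The path with the most reads" is interpreted as *full containment*:
an alignment supports a path iff its node path appears consecutively
on it and all its bases lie on the path.  Containment (rather than
overlap) is what lets the caller distinguish alleles — every read
overlapping a bubble flank would support both branches under overlap
counting.  Because a read can span several nodes, the dynamic program
over the subgraph's topological order carries the short suffix of runs
needed to decide containment exactly; the suite verifies it against
exhaustive path enumeration on hundreds of random DAGs.  One
consequence worth knowing: when two bubbles sit closer than a read
length, a read spanning both supports only paths taking *both* of its
alleles, so branch choices are coupled exactly as haplotypes couple
them.

## Gap filling semantics

Gaps are measured in intervening bases and filled when strictly
shorter than the read length, computed once on the original thresholded
regions: a base is added iff it lies on some directed path between two
region bases with fewer than $r$ bases between them.  On chains and on
clean bubbles (branches that only meet at their flanks) one pass is
transitively closed, and the suite asserts idempotence there.  On
graphs where parallel gap paths interconnect mid-way, re-application
could join further regions; the package deliberately performs the
single, original-region pass.  Filling happens before components are
extracted, so a fill that bridges two candidate regions merges their
subgraphs.

## The synthetic generator

Real graph ChIP-seq experiments need a reference graph built from a
variant panel, a read mapper, and sequencing data; none of that is
desk-reproducible.  The package therefore ships a generator
(`simulate_experiment()`) that emulates the relevant structure end to
end and emits the same formats the pipeline consumes (vg-style JSON,
GFA1, GAM JSON-lines, VCF, FASTA):

* a random backbone chopped into ≤ 32 bp nodes carrying SNP bubbles at
  5% per base and indels (≤ 8 bp) at 0.5% per base — about one variant
  per 18 bp before thinning, the density of a pruned plant pangenome —
  thinned so bubbles never overlap and always connect through a shared
  reference base;
* a panel of 10 haplotypes in which every variant has at least one
  carrier, written as a haploid-GT VCF;
* planted binding sites marked by an 8 bp synthetic motif
  (consensus `TGACGTCA`); at *alt-allele sites* the reference carries a
  one-base mismatch and a forced SNP restores the consensus on the
  alternative branch only — the scenario where a graph-aware caller
  can find what a linear caller cannot;
* 200 bp fragments centered on each site: 70% with Gaussian jitter
  (sd 20 bp), which keeps the strand cross-correlation peak sharp, and
  30% placed uniformly across the protected region, which is the
  fraction whose 36 bp end-reads physically cover the site sequence —
  real sonication positions fragments loosely, and without this
  component no read would ever carry the site's allele;
* at alt sites, 80% of reads are drawn from carrier haplotypes; every
  read is carved from its haplotype's path, so reads are always
  haplotype-consistent; uniform background, control and optional
  low-mapq noise reads complete the libraries.

What the generator does *not* emulate: sequencing errors, duplicate
reads, mappability artifacts, diploid coverage structure, or mapping
itself (reads are emitted pre-aligned with mapq 60).  Passing tests on
these fixtures therefore demonstrate the pipeline's correctness and
its allele-tracing behavior, not robustness to mapper noise.

## Test problem sizes

The tests run the full pipeline on 20–100 kb graphs with 2 000–4 000
reads: large enough that backgrounds, FDR pooling and subgraph
extraction operate in their intended regime, small enough to iterate
quickly.  The brute-force cross-checks (path enumeration, bounded gap
search, union-find) run on 200 random DAGs of at most 12 nodes, where
exhaustive enumeration is exact.  On a 50 kb chain graph the whole
graph pipeline is compared base-exactly against an independently coded
scalar implementation of the linear five-step pipeline — the
degenerate-graph equivalence that anchors the generalization.

## Evaluation statistics

`two_proportion_z_test()` implements the pooled-variance one-sided
z-test used to compare motif-match proportions between peak sets
(pooled variance reproduces the published comparisons to the printed
precision, which is why the pooled form was adopted).
`pwm_scan()` is an internal log-odds scanner standing in for an
external motif tool: JASPAR counts become log2-odds with a
background-weighted pseudocount of 0.8, and the default match
threshold is the smallest score whose *exact* background tail
probability (computed by discretized convolution on a $10^{-3}$ grid)
is at most $10^{-4}$.  On short motifs such a tail may be unreachable
(the consensus alone can carry more mass), in which case no window
matches — the honest behavior for an exact-tail definition.
`alignment_haplotype_compatibility()` and `peak_two_haplotype_test()`
implement the panel-compatibility analysis: an alignment is compatible
with a haplotype when the haplotype carries every variant allele the
alignment traverses (strict mode also requires agreement at covered
reference sites; a flag relaxes this), and a peak's read set is
"two-haplotype consistent" when some pair of haplotypes covers every
read's compatibility set.

## Known limitations

* Graphs must be DAGs with one reference path per object; a
  multi-chromosome pangenome is handled as a list of graphs keyed by
  path name.
* Only narrow peaks are called; there is no broad/gapped mode and no
  p-value thresholding mode.
* The fragment-length estimator is a strand cross-correlation argmax,
  not a paired-peak model; pathological libraries should pass
  `fragment_length` explicitly.
* Alternative-peak reporting (`alternative_peak()`) enumerates paths
  through the matched sub-region and is intended for peak-sized
  subgraphs, not chromosome-scale components.
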