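# dagpeaks

ChIP-seq peak calling on directed acyclic variation graphs.

Transcription-factor binding sites are usually found by mapping
ChIP-seq reads to a *linear* reference genome and running a peak
caller over the resulting coverage.  When reads are instead mapped to
a **variation graph** — a DAG of sequence nodes where alternative
alleles (SNP branches, insertion nodes, deletion edges) diverge from
and rejoin a designated linear reference path — the caller can follow
the reads through variants that are not part of the linear reference
at all, and report the allele the binding site actually sits on.

`dagpeaks` generalizes the classic five-stage pipeline to such graphs:

1. fragment-length estimation by strand cross-correlation on the
   reference path,
2. fragment pileup: each read of length *r* is extended to the
   estimated fragment length *f* along **all** possible paths from its
   3' end (breadth-first), contributing at most once per base,
3. a local-lambda Poisson background: control read densities are
   measured on the linear projection (global plus 1 kb / 10 kb
   windows, combined by max, scaled by *n*<sub>input</sub>/*n*<sub>control</sub>)
   and projected back so parallel alleles share rates,
4. per-base p-values *P*(X ≥ count) for X ~ Poisson(rate) and
   Benjamini–Hochberg q-values over *every* base of the graph,
5. peaks: q < 0.05 bases, gaps shorter than the read length filled
   (all short parallel paths), connected peak subgraphs extracted, and
   for each the directed path containing the most input reads reported
   with its summit (lowest q-value), trimmed to 120 bp around it.

The package also ships the surrounding toolbox: vg-style JSON / GFA1
graph IO, GAM JSON-lines alignment IO, graph→linear coordinate
projection, narrowPeak/BED output, evaluation statistics (pooled
one-sided two-proportion z-test, motif-match ratios, an exact-tail
log-odds PWM scanner, VCF haplotype-compatibility analysis), and a
synthetic-data generator that produces variant graphs, haplotype
panels, planted binding sites and pre-aligned reads so the whole
pipeline is testable without any external downloads.

## Worked example

Simulate a 20 kb variant graph (SNP + indel bubbles, 10 haplotypes)
with three planted binding sites — one of which carries its motif only
on a non-reference allele — and call peaks:

```r
library(dagpeaks)

cfg <- sim_config(backbone_length = 20000L, n_sites = 3L, n_alt_sites = 1L,
                  reads_per_site = 60L, background_reads = 200L,
                  control_reads = 400L, seed = 11L)
sim <- simulate_experiment(cfg)
sim$graph
#> graph_genome 'sim': 3524 nodes (21109 bp), 4538 edges, ref path 2553 nodes (20000 bp)

res <- call_peaks(sim$graph, sim$input, sim$control)
res
#> dag_peaks on 'sim': 3 peaks (q < 0.05)
#>   alignments: 380 (380 after mapq >= 37 filter), 400 control reads
#>   fragment length 204, read length 36, 3 candidate subgraphs

res$linear
#>   chrom start   end   name score support summit_qscore summit_offset
#> 1   sim   329   449 peak_1   451      37      45.07742            60
#> 2   sim  9916 10036 peak_2   461      43      46.09675            60
#> 3   sim 19536 19656 peak_3   497      47      49.73328            60
```

All three planted sites (at linear positions 400, 10000 and 19600)
come back as 120 bp peaks centered on their summits; the `score`
column is the summit q-score × 10 and `support` is the number of input
reads fully contained in the reported maximum path.  The true fragment
length was 200, estimated as 204 from the reads alone.  For the
alt-allele site the maximum path runs through the alternative branch
(`sim$sites$alt_node[1]` is on `res$peaks[[1]]$full_path$node_path`),
which is exactly the information a linear caller cannot report.

Peak-set comparisons use the pooled one-sided z-test:

```r
two_proportion_z_test(927, 14637, 750, 13073)
#>  One-sided two-proportion z-test (pooled variance)
#> data:  927/14637 vs 750/13073
#> z = 2.0779, p-value = 0.01886
```

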