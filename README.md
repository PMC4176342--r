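# nucbarrier

Nucleosome occupancy analysis around transcription-factor barriers.

Promoters of fission-yeast stress genes carry broad nucleosome-depleted
regions (NDRs) centered on the CRE motif bound by the bZIP transcription
factor Atf1. The bound factor competes with histones: it keeps nucleosomes
off the CRE, pins the +1 nucleosome just downstream of the TSS, and phases
the coding-region array against this barrier. Without the factor, the +1
slides into the NDR with a shoulder, the NDR narrows, the array loses
phasing with distance, and antisense transcription is derepressed at
factor-dependent genes. `nucbarrier` is for chromatin biologists who want
to measure these phenotypes from MNase-seq and qPCR data — or to study the
barrier model itself on fully controlled synthetic data.

## What it computes

**MNase-seq pipeline.** Single-end reads (BED6 or minimal SAM) are
converted to dyad-centered coverage: each read's start is shifted by half
the fragment length `F` (estimated by strand cross-correlation of `+` read
starts against `-` read 5' ends), then extended 20 nt per side, so each
read contributes a 40 bp interval centred on the nucleosome dyad.
Coverage is normalized to reads per million,

```
RPM(x) = coverage(x) * 1e6 / total mapped reads,
```

and smoothed by an FFT low-pass filter that keeps Fourier components with
frequency index `k <= ceiling(pc_keep * N / 2)` (retained wavelengths
`>= 2/pc_keep` bp). On the smoothed track the package calls nucleosome
dyads (local maxima with minimum-height and minimum-separation rules),
detects promoter NDRs (maximal runs below `0.5 x` the local TSS+/-2 kb
median, `>= 80` bp wide, reported at the CRE), and assigns each gene's +1
nucleosome (first call downstream of the TSS within 300 bp, strand-aware).

**Profiles and phasing.** Anchored occupancy matrices (genes x positions,
`+/-flank` around the CRE or the +1 dyad, minus-strand genes reversed) are
averaged on the log scale, `mean over genes of log2(occupancy + 0.1)`, into
composite profiles. The nucleosome repeat length is the lag (120-220 bp)
maximizing the windowed autocorrelation of the downstream composite;
phasing amplitudes `A_k` (peak-to-trough in `[(k-1/2)s, (k+1/2)s)`) and the
decay ratio `A4/A1` quantify how fast the array fades; two conditions are
compared position-by-position on their shared gene set.

**Low-throughput assays.** Nucleosome-scanning qPCR occupancy
(`mono/input`, input = 1, mean +/- SEM over replicates), strain occupancy
ratios and strand-specific RT-qPCR fold changes (reference strain = 1) with
delta-method SEMs.

**Synthetic generator.** `sim_config()` + `simulate_*()` draw per-cell
nucleosome configurations under the barrier model — Bernoulli(`p_bound`)
factor binding, NDR exclusion, pinned +1, sequential array placement with
cumulative jitter, hard-core exclusion — and emit reads, qPCR tables and
transcript tables with known ground truth.

## Worked example

Simulate the two study conditions (barrier bound in every cell vs barrier
absent), run the full pipeline, and compare:

```r
library(nucbarrier)

run <- function(cfg, seed) {
  genes <- sim_gene_models(cfg)
  conf <- simulate_configurations(genes, cfg, seed = seed)
  reads <- simulate_reads(conf, sim_genome(cfg), cfg, seed = seed + 1)
  track <- build_coverage(reads, sim_genome(cfg),
                          fragment_length = estimate_fragment_length(reads))
  sm <- smooth_track(normalize_rpm(track), pc_keep = 0.05)
  p1 <- assign_plus_one(call_peaks(sm), genes)
  m <- build_anchor_matrix(sm, genes,
                           tibble::tibble(gene_id = p1$gene_id,
                                          anchor = p1$dyad), flank = 800)
  list(genes = genes, sm = sm, matrix = m)
}

wt <- run(sim_config(), 201)
free <- run(sim_config(p_bound = 0), 301)

glance(wt$sm)
#> # A tibble: 1 × 7
#>   state    n_chrom genome_bp total_mapped clipped total_coverage max_value
#>   <chr>      <int>     <int>        <int>   <int>          <dbl>     <dbl>
#> 1 smoothed       1    102000       100000       0      40112895.     2710.

c(barrier = mean(detect_ndr(wt$sm, wt$genes)$width),
  no_barrier = mean(detect_ndr(free$sm, free$genes)$width))
#>    barrier no_barrier
#>     320.16     164.10

estimate_spacing(composite_log2(wt$matrix))
#> # A tibble: 1 × 4
#>   spacing autocorrelation threshold phased
#>     <int>           <dbl>     <dbl> <lgl>
#> 1     166           0.951        NA NA

c(barrier = phasing_decay(composite_log2(wt$matrix), 165)$decay_ratio,
  no_barrier = phasing_decay(composite_log2(free$matrix), 165)$decay_ratio)
#>    barrier no_barrier
#>  0.8534538  0.2285068
```

Read out: with the barrier bound, promoter NDRs are about twice as wide
(320 vs 164 bp), the composite repeat length is ~165 bp (147 bp core + 18
bp linker), and the phased array persists to the +4 nucleosome
(`A4/A1 = 0.85`); without the barrier the array has largely vanished by +4
(`A4/A1 = 0.23`). `autoplot(compare_conditions(wt$matrix, free$matrix))`
overlays the two composites.

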