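---
title: "Nucleosome occupancy around transcription-factor barriers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleosome occupancy around transcription-factor barriers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucbarrier)
library(dplyr)
```

## The problem

Stress-response promoters in fission yeast carry unusually broad
nucleosome-depleted regions (NDRs) centered on the CRE motif bound by the
bZIP transcription factor Atf1. The factor competes with histones for the
DNA: while it is bound, no nucleosome can occupy the site, the +1 nucleosome
is pinned just downstream of the TSS, and the coding-region array is phased
against this barrier. When the factor is absent, the +1 slides toward the
NDR and develops a shoulder, the NDR narrows, the array loses phasing with
distance, and antisense transcripts are derepressed specifically at
factor-dependent genes.

`nucbarrier` implements the complete MNase-seq analysis needed to observe
these phenotypes — dyad-centered coverage, RPM normalization, FFT smoothing,
nucleosome/NDR calling, anchored composite profiles and phasing metrics —
together with the matching low-throughput quantifications
(nucleosome-scanning qPCR, strand-specific RT-qPCR), and a synthetic
generator that produces MNase-seq reads under an explicit barrier model so
that every stage can be validated against known ground truth. All
user-facing functions take and return tibbles (coverage tracks and profile
matrices are light S3 objects with `tidy()`/`glance()` views); the R
functions themselves, this vignette, and `scripts/acceptance.R` are the
package's interface — there is no shell wrapper.

## The coverage pipeline

**Dyad centering.** Each single-end read marks one end of an
MNase-protected mononucleosomal fragment. For a `+` read the dyad estimate
is `start + floor(F/2)`; for a `-` read it is the 5' end (rightmost base)
shifted left by `floor(F/2)`, where `F` is the library's fragment length.
Treating the two strands symmetrically is essential: on zero-noise
simulations an asymmetric shift visibly splits the coverage peak. The
shifted coordinate is extended `trim/2 = 20` nt on each side, so every read
contributes a half-open interval of width exactly `trim = 40` centred on
the dyad. `floor()` on odd fragment lengths is a fixed, tested convention;
any consistent rule would do, stating one prevents silent drift.

**Fragment length.** `estimate_fragment_length()` cross-correlates the
per-base density of `+` read starts with that of `-` read 5' ends and
returns the maximizing lag plus one — i.e. the insert size, locked by a
zero-noise fixture in the tests (starts at `x`, minus ends at `x + 149`
give 150). Ties break toward the smaller lag; a flat correlation is an
error rather than a guess.

**Conservation and clipping.** Raw coverage increments every base under a
dyad interval by one, so total raw mass is exactly (non-clipped reads) x
trim. Intervals that would run off a chromosome end are excluded from
accumulation but remain in `total_mapped` (they were sequenced and mapped)
and are reported in the track's `clipped` count. This keeps the
conservation law exact and the RPM denominator faithful to the library
size.

**RPM.** Each value is divided by the total mapped reads and multiplied by
one million. This is a linear map, tested as such.

**Smoothing.** `fft_lowpass()` keeps Fourier coefficients with frequency
index `k <= ceiling(pc_keep * N / 2)` plus their conjugate mirrors and
inverts the transform, then clamps negatives to zero (occupancy is
non-negative; the linear-algebra invariants — idempotence, energy,
mean preservation — are tested pre-clamp). The retained band always reaches
down to wavelength `~2 / pc_keep` bases regardless of track length. Two
settings matter in practice:

* `pc_keep = 0.02` (the package default, mirroring the common convention of
  MNase-seq smoothers): cutoff wavelength ~100 bp. Good for occupancy
  landscapes and NDR detection, but it retains only the fundamental of a
  165 bp nucleosome repeat, so individual peak positions become sensitive
  to neighbour amplitudes.
* `pc_keep = 0.05`: cutoff wavelength 40 bp, below the repeat length. This
  is what the dyad-calling analyses in the tests and the acceptance script
  use; with it, called dyads recover zero-jitter ground truth to +/-1 bp.

Chromosomes longer than `chunk_size` are filtered in overlapping windows
whose central regions are stitched. A sharp spectral cutoff convolves the
signal with a sinc kernel whose tails decay as `1/(pi * x)`, so the
disagreement between stitched and whole-signal transforms at distance `d`
inside a window is of order `1/(pi * d)` of the local signal scale — about
1e-3 of the maximum at the default overlap. Exact agreement is not
achievable with a sharp cutoff; the tests assert the theory-derived bound.

**Peak calling.** Nucleosome dyads are strict local maxima of the smoothed
signal (plateaus report their leftmost base); candidates below `min_height`
(default 0.1 x the track's 90th percentile) are discarded and, within
`min_separation = 120` bp, the higher (then leftmost) call wins. All
tie-breaks are leftmost-deterministic so repeated runs agree bit for bit.
Calling on unsmoothed tracks is refused.

**NDR detection.** Depletion is judged relative to the median occupancy of
the gene's TSS +/- 2 kb window (`rel_threshold = 0.5`), not on an absolute
scale, because RPM levels vary with library size and digestion depth. The
promoter scan window is strand-aware (1 kb upstream to 200 bp downstream of
the TSS); qualifying runs must be at least `min_width = 80` bp wide, and
the run overlapping (else nearest to) the CRE site is reported. Genes whose
median window hangs off a chromosome end keep a clipped window; on the toy
genome this deflates the first gene's local median — a documented edge
artifact of bare chromosome margins, and the reason composite analyses of
real data conventionally exclude chromosome-end genes.

**+1 assignment and profiles.** The +1 nucleosome is the first called dyad
at or downstream of the TSS (strand-aware) within 300 bp; genes without one
are logged and dropped from profile matrices rather than zero-padded,
because padding dilutes composites toward zero. Anchored matrices have
exactly `2 * flank + 1` columns, minus-strand rows reversed so positive
positions always read downstream. Composites are log-then-average:
`mean(log2(value + pseudocount))` per column, with a 0.1 RPM pseudocount
bounding depleted positions; averaging before the log would let a single
high-coverage gene dominate. No per-gene scaling is applied before
averaging (it is not obviously desirable and is easy to apply upstream via
`tidy()` if wanted).

**Spacing and phasing decay.** The repeat length is the lag (120-220 bp)
maximizing the autocorrelation of the downstream half of the composite. The
implementation linearly detrends first and uses the Pearson correlation of
the two overlapping windows per lag: the raw product autocorrelation of a
finite three-period cosine peaks a couple of bp off the true period
(boundary term), and a monotone drift autocorrelates strongly at every lag,
so without detrending an aperiodic profile can masquerade as phased. With
this estimator a pure 165 bp cosine returns exactly 165, and a permutation
null (95th percentile of the shuffle maximum) flags monotone profiles as
unphased. Phasing amplitudes `A_k` are peak-to-trough ranges in windows
`[(k - 1/2) s, (k + 1/2) s)` downstream of the anchor; `A_4/A_1` is the
decay ratio. Measuring `A_4` needs the profile to reach `4.5 s ~ 743` bp,
so decay analyses use `flank = 800` while the standard composite window
stays at +/-500.

## The synthetic generator

Each simulated cell draws, per gene, a barrier state
`bound ~ Bernoulli(p_bound)`. When bound, the +1 dyad sits at
`tss + plus_one_offset` with jitter `sigma_plus_one`, and no dyad may fall
in the NDR interval (CRE +/- `ndr_width/2`; rejection sampling, erroring
after 1000 rounds). Downstream dyads follow sequentially at
`nuc_footprint + linker` steps with cumulative per-step jitter, so
positional variance grows linearly with array index — statistical
positioning against a fixed barrier, at a fraction of the cost of a full
hard-rod equilibrium model, and sufficient to reproduce the decay of
phasing with distance. A -1 nucleosome mirrors the +1 across the CRE with
its own larger jitter (upstream nucleosomes are less well phased than the
+1), and a short upstream chain continues away from the NDR so promoter
flanks are not artificially bare. When unbound, the exclusion is lifted,
the +1 slides `fill_shift` bp toward the NDR with jitter
`sigma_plus_one_free`, and the array is laid with the larger
`sigma_step_free`.

`sigma_step_free` deserves a note. With a single per-step jitter the
composite amplitude at array position `k` is damped by the Gaussian
smearing factor `exp(-2 pi^2 sigma_k^2 / s^2)` with
`sigma_k^2 = sigma_1^2 + (k - 1) sigma_step^2`, so the decay ratio
`A_4/A_1` depends only on `sigma_step` — a wider initial +1 distribution
alone cannot make the array "vanish faster", it only lowers every amplitude
by the same relative schedule. Losing the barrier must therefore also
loosen the spacing itself, which is exactly the disorganization the
barrier-free condition is meant to show; the generator makes that a
separate, documented knob.

Reads pick a (cell, gene, nucleosome) uniformly, draw a fragment length
`round(N(frag_mean, frag_sd))` clamped to [100, 250] (a conceptual
mononucleosome gel-purification window; the exact bounds are conventions),
centre the fragment on the dyad, choose a strand fairly, and report the
sequenced end. qPCR tables score an amplicon as protected in a cell when
some 147 bp footprint fully covers it; transcript tables multiply baseline
quantities by `antisense_fold` only on the antisense strand of
factor-dependent genes in the barrier-free condition. All noise is
multiplicative `1 + N(0, noise_cv)`.

### Default study conditions

| parameter | default | meaning |
|---|---|---|
| `n_genes`, `gene_spacing` | 50, 2000 bp | tandem gene slots on one ~100 kb chromosome |
| `n_nucs`, `n_nucs_up` | 8, 2 | downstream array and upstream chain lengths |
| `p_bound` | 1 (barrier) / 0 (barrier-free) | barrier occupancy per cell |
| `ndr_width`, `cre_offset` | 150, 120 bp | NDR span centred on the CRE, CRE-to-TSS distance |
| `plus_one_offset` | 90 bp | TSS to +1 dyad |
| `nuc_footprint`, `linker` | 147, 18 bp | 165 bp repeat |
| `sigma_plus_one`, `sigma_minus_one`, `sigma_plus_one_free` | 5, 15, 20 bp | anchor jitters |
| `sigma_step`, `sigma_step_free` | 8, 25 bp | per-step array jitters |
| `fill_shift` | 80 bp | +1 slide toward the NDR when unbound |
| `n_cells`, `total_reads` | 200, 1e5 | fibers and reads per condition |
| `frag_mean`, `frag_sd`, `read_length` | 147, 10, 50 bp | library geometry |

These are desk-scale conventions of this package (the linker and footprint
are the field's textbook values; the jitters and `fill_shift` are chosen so
the barrier-free condition shows a clear shoulder without collapsing the
NDR entirely), not measurements from any particular dataset. Fifty genes
and 1e5 reads keep a full two-condition comparison under ~10 s on one CPU
while leaving Monte-Carlo error far below every margin the tests use; the
acceptance script runs exactly these sizes.

### What the generator does and does not emulate

It reproduces dyad-centered read geometry, barrier-dependent NDRs, +1
pinning, statistical positioning with distance-growing variance, and the
downstream phenotypes of losing the barrier. It has no DNA-sequence
energetics, no MNase sequence preference, no digestion-depth variation, no
PCR duplicates, and no transcription-coupled remodeling; genes sit in
regular tandem slots rather than a real gene landscape. Passing tests
therefore demonstrate that the pipeline measures what it claims on data
whose generating process is known — not that any particular biological
dataset will show these effect sizes.

## Low-throughput quantifications

Scanning-qPCR occupancy is `mono_quantity / input_quantity` per
replicate (the undigested input defines 1), summarized as mean and SEM
(`sd/sqrt(n)`; undefined below two replicates). Strain ratios are ratios of
means with delta-method SEMs (relative variances adding in quadrature); a
mean-of-ratios estimator pairing replicates by index is available as an
option in `transcript_fold_change()`, and `strain_ratio()` can either
display a control gene's ratio alongside or divide through by it
(`normalize_to_control`) — both behaviours are offered because display
conventions differ between labs. Ct-to-quantity conversion is expected
upstream.

## Worked example

```{r example, eval = FALSE}
cfg_wt <- sim_config()                 # barrier bound in every cell
cfg_free <- sim_config(p_bound = 0)    # barrier-free condition

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

wt <- run(cfg_wt, 201)
free <- run(cfg_free, 301)
mean(detect_ndr(wt$sm, wt$genes)$width)     # barrier NDRs are ~2x wider
mean(detect_ndr(free$sm, free$genes)$width)
phasing_decay(composite_log2(wt$matrix), 165)$decay_ratio
phasing_decay(composite_log2(free$matrix), 165)$decay_ratio
autoplot(compare_conditions(wt$matrix, free$matrix))
```

## Known limitations

* Chunked smoothing is approximate near window seams (order
  `1/(pi * overlap)`); use a larger `chunk_size` when exactness matters
  more than memory.
* Half-open, even-width dyad intervals are asymmetric by one base around
  the centre, so genome mirroring shifts raw coverage by exactly 1 bp —
  harmless downstream, but visible in base-exact comparisons.
* NDR detection relies on a local median; genes whose +/-2 kb window is
  mostly unmappable or bare (chromosome ends of the toy genome) get
  unreliable thresholds.
* The spacing estimator reports a single dominant lag; bimodal spacing
  distributions are out of scope.
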