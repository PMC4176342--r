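#' Configuration for the transcription-factor barrier simulator
#'
#' Bundles every tunable of the synthetic MNase-seq generator. The model:
#' each simulated cell carries, per gene, a promoter where the transcription
#' factor is bound with probability `p_bound`. When bound, the factor
#' excludes nucleosome dyads from a nucleosome-depleted region (NDR) of
#' width `ndr_width` centered on the CRE site and pins the +1 nucleosome at
#' `plus_one_offset` bp downstream of the TSS with small jitter
#' `sigma_plus_one`. Downstream nucleosomes are laid sequentially at
#' `nuc_footprint + linker` bp steps with per-step Gaussian jitter
#' `sigma_step` (cumulative, so positional variance grows with distance —
#' statistical positioning against the barrier). When unbound, the NDR
#' exclusion is lifted, the +1 slides `fill_shift` bp toward the NDR with a
#' larger jitter `sigma_plus_one_free`, and the array is laid with the
#' larger per-step jitter `sigma_step_free`, so phasing decays much faster.
#' A -1 nucleosome mirrors the +1 across the CRE site (with its own, larger
#' jitter `sigma_minus_one` — upstream nucleosomes are less well phased than
#' the +1), and `n_nucs_up - 1` further nucleosomes continue upstream away
#' from the NDR at the same repeat length.
#'
#' Defaults are desk-scale conventions of the package (a 147 bp core
#' particle, an 18 bp linker giving 165 bp repeat, 50 genes on a single
#' ~100 kb chromosome), not measured values from any particular dataset.
#'
#' @param n_genes Number of genes on the toy chromosome.
#' @param gene_spacing bp between successive gene slots.
#' @param margin bp of empty genome left at each chromosome end.
#' @param n_nucs Number of nucleosomes in the downstream array (+1..+n).
#' @param n_nucs_up Number of upstream nucleosomes (-1, -2, ...).
#' @param p_bound Probability the barrier factor is bound in a given cell
#'   (wild-type-like high; barrier-free condition 0).
#' @param ndr_width Target NDR width (bp) when the barrier is bound.
#' @param cre_offset bp from the TSS upstream to the CRE-site midpoint.
#' @param plus_one_offset bp from the TSS to the +1 dyad (downstream).
#' @param linker,nuc_footprint Linker and core-particle lengths (bp).
#' @param sigma_plus_one,sigma_plus_one_free +1 dyad jitter SD (bp), barrier
#'   bound / absent; `sigma_plus_one_free >= sigma_plus_one` is enforced.
#' @param sigma_step,sigma_step_free Per-step array jitter SD (bp), barrier
#'   bound / absent.
#' @param sigma_minus_one Jitter SD (bp) of the -1 dyad when the barrier is
#'   bound (the unbound condition uses `sigma_plus_one_free`).
#' @param fill_shift bp the +1 dyad slides toward the NDR when unbound.
#' @param n_cells Number of simulated chromatin fibers.
#' @param total_reads Total single-end reads to emit.
#' @param frag_mean,frag_sd Mononucleosomal fragment length mean / SD (bp);
#'   lengths are clamped to the gel-purification-like window [100, 250].
#' @param read_length Sequenced read length (bp).
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 50, gene_spacing = 2000, margin = 1000,
                       n_nucs = 8, n_nucs_up = 2, p_bound = 1, ndr_width = 150,
                       cre_offset = 120, plus_one_offset = 90,
                       linker = 18, nuc_footprint = 147,
                       sigma_plus_one = 5, sigma_plus_one_free = 20,
                       sigma_minus_one = 15,
                       sigma_step = 8, sigma_step_free = 25,
                       fill_shift = 80, n_cells = 200,
                       total_reads = 1e5, frag_mean = 147, frag_sd = 10,
                       read_length = 50) {
  cfg <- list(n_genes = n_genes, gene_spacing = gene_spacing, margin = margin,
              n_nucs = n_nucs, n_nucs_up = n_nucs_up, p_bound = p_bound,
              ndr_width = ndr_width,
              cre_offset = cre_offset, plus_one_offset = plus_one_offset,
              linker = linker, nuc_footprint = nuc_footprint,
              sigma_plus_one = sigma_plus_one,
              sigma_plus_one_free = sigma_plus_one_free,
              sigma_minus_one = sigma_minus_one,
              sigma_step = sigma_step, sigma_step_free = sigma_step_free,
              fill_shift = fill_shift, n_cells = n_cells,
              total_reads = total_reads, frag_mean = frag_mean,
              frag_sd = frag_sd, read_length = read_length)
  if (n_nucs < 1 || n_nucs_up < 1) abort("n_nucs and n_nucs_up must be >= 1")
  if (p_bound < 0 || p_bound > 1) abort("p_bound must be in [0, 1]")
  if (sigma_plus_one_free < sigma_plus_one) {
    abort("sigma_plus_one_free must be >= sigma_plus_one")
  }
  if (nuc_footprint + linker <= 0) abort("nuc_footprint + linker must be > 0")
  bp_fields <- c("gene_spacing", "margin", "ndr_width", "cre_offset",
                 "plus_one_offset", "linker", "nuc_footprint",
                 "sigma_plus_one", "sigma_plus_one_free", "sigma_minus_one",
                 "sigma_step", "sigma_step_free", "fill_shift",
                 "frag_mean", "frag_sd", "read_length")
  if (any(unlist(cfg[bp_fields]) < 0)) abort("bp fields must be >= 0")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Toy genome for a simulator configuration
#'
#' @param cfg A [sim_config()].
#' @return Genome tibble with columns `chrom`, `length`.
#' @export
sim_genome <- function(cfg) {
  tibble(chrom = "chrI",
         length = as.integer(2 * cfg$margin + cfg$n_genes * cfg$gene_spacing))
}

#' Toy gene models for a simulator configuration
#'
#' Genes are laid in tandem slots of `gene_spacing` bp. A `+` gene's TSS
#' sits 400 bp into its slot (leaving room for the NDR and -1 nucleosome
#' upstream); a `-` gene mirrors this within the slot. The CRE site is
#' `cre_offset` bp upstream of the TSS.
#'
#' @param cfg A [sim_config()].
#' @param strands Strand per gene (recycled); default all `"+"`.
#' @param atf1_dependent Logical flag per gene (recycled); default `TRUE`.
#' @return Gene model tibble (see [read_gene_models()] for columns).
#' @export
sim_gene_models <- function(cfg, strands = "+", atf1_dependent = TRUE) {
  n <- cfg$n_genes
  strands <- rep_len(strands, n)
  atf1_dependent <- rep_len(atf1_dependent, n)
  slot0 <- cfg$margin + (seq_len(n) - 1L) * cfg$gene_spacing
  body <- cfg$n_nucs * (cfg$nuc_footprint + cfg$linker)
  plus <- strands == "+"
  tss <- ifelse(plus, slot0 + 400L, slot0 + cfg$gene_spacing - 400L)
  tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    chrom = "chrI",
    strand = strands,
    start = as.integer(ifelse(plus, tss, tss - body)),
    end = as.integer(ifelse(plus, tss + body, tss + 1L)),
    tss = as.integer(tss),
    cre_site = as.integer(ifelse(plus, tss - cfg$cre_offset,
                                 tss + cfg$cre_offset)),
    atf1_dependent = atf1_dependent
  )
}

#' Simulate ground-truth nucleosome configurations
#'
#' Draws, for every cell and gene, the dyad coordinates of the -1
#' nucleosome, the +1 nucleosome and the downstream array under the barrier
#' model described in [sim_config()]. Placement is strand-aware: minus-strand
#' genes mirror all offsets. Hard-core exclusion (no two dyads within one
#' cell/gene closer than `nuc_footprint`) is enforced by resampling; when
#' the barrier is bound, no dyad may fall inside the NDR interval
#' `[cre_site - ndr_width/2, cre_site + ndr_width/2]`.
#'
#' @param genes Gene model tibble.
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed (sets the RNG state).
#' @return Tibble with columns `cell`, `gene_id`, `chrom`, `strand`,
#'   `nuc_index` (-1, -2, ... for the upstream nucleosomes, 1..n for the
#'   downstream array), `dyad` (0-based bp) and `bound` (barrier state of
#'   that cell/gene).
#' @export
simulate_configurations <- function(genes, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nc <- cfg$n_cells
  step <- cfg$nuc_footprint + cfg$linker
  half_ndr <- cfg$ndr_width / 2
  per_gene <- vector("list", nrow(genes))
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    dir <- if (g$strand == "+") 1 else -1
    cre <- g$cre_site
    in_ndr <- function(d) d >= cre - half_ndr & d <= cre + half_ndr
    bound <- runif(nc) < cfg$p_bound

    nominal_b <- g$tss + dir * cfg$plus_one_offset
    nominal_f <- g$tss + dir * (cfg$plus_one_offset - cfg$fill_shift)
    draw_plus1 <- function(idx) {
      round(ifelse(bound[idx],
                   nominal_b + rnorm(length(idx), 0, cfg$sigma_plus_one),
                   nominal_f + rnorm(length(idx), 0, cfg$sigma_plus_one_free)))
    }
    d1 <- reject_loop(draw_plus1(seq_len(nc)),
                      function(d) bound & in_ndr(d), draw_plus1)

    # -1 nucleosome mirrored across the CRE site
    m_nominal_b <- 2 * cre - nominal_b
    m_nominal_f <- 2 * cre - nominal_f
    draw_minus1 <- function(idx) {
      round(ifelse(bound[idx],
                   m_nominal_b + rnorm(length(idx), 0, cfg$sigma_minus_one),
                   m_nominal_f + rnorm(length(idx), 0, cfg$sigma_plus_one_free)))
    }
    dm1 <- reject_loop(draw_minus1(seq_len(nc)), function(d) {
      (bound & in_ndr(d)) | abs(d1 - d) < cfg$nuc_footprint
    }, draw_minus1)

    sig <- ifelse(bound, cfg$sigma_step, cfg$sigma_step_free)
    up <- matrix(NA_real_, nrow = nc, ncol = cfg$n_nucs_up)
    up[, 1] <- dm1
    if (cfg$n_nucs_up > 1) {
      for (k in 2:cfg$n_nucs_up) {
        prev <- up[, k - 1]
        draw_k <- function(idx) {
          round(prev[idx] - dir * step + rnorm(length(idx), 0, sig[idx]))
        }
        up[, k] <- reject_loop(draw_k(seq_len(nc)), function(d) {
          abs(d - prev) < cfg$nuc_footprint | (bound & in_ndr(d))
        }, draw_k)
      }
    }

    arr <- matrix(NA_real_, nrow = nc, ncol = cfg$n_nucs)
    arr[, 1] <- d1
    if (cfg$n_nucs > 1) {
      for (k in 2:cfg$n_nucs) {
        prev <- arr[, k - 1]
        draw_k <- function(idx) {
          round(prev[idx] + dir * step + rnorm(length(idx), 0, sig[idx]))
        }
        dk <- reject_loop(draw_k(seq_len(nc)), function(d) {
          abs(d - prev) < cfg$nuc_footprint | (bound & in_ndr(d))
        }, draw_k)
        arr[, k] <- dk
      }
    }
    n_tot <- cfg$n_nucs + cfg$n_nucs_up
    per_gene[[gi]] <- tibble(
      cell = rep(seq_len(nc), n_tot),
      gene_id = g$gene_id,
      chrom = g$chrom,
      strand = g$strand,
      nuc_index = rep(c(-seq_len(cfg$n_nucs_up), seq_len(cfg$n_nucs)),
                      each = nc),
      dyad = c(as.vector(up), as.vector(arr)),
      bound = rep(bound, n_tot)
    )
  }
  purrr::list_rbind(per_gene) |> arrange(.data$cell, .data$gene_id, .data$nuc_index)
}

# Index-aware rejection sampler: redraw elements failing reject(), at most
# max_tries rounds.
reject_loop <- function(x, reject, draw_idx, max_tries = 1000) {
  bad <- which(reject(x))
  tries <- 0
  while (length(bad) > 0) {
    tries <- tries + 1
    if (tries > max_tries) {
      abort("nucleosome placement rejected more than 1000 times; degenerate simulator configuration")
    }
    x[bad] <- draw_idx(bad)
    bad <- which(reject(x))
  }
  x
}

#' Simulate single-end MNase-seq reads from nucleosome configurations
#'
#' Each read picks a (cell, gene, nucleosome) uniformly at random, draws a
#' fragment length `F ~ round(N(frag_mean, frag_sd))` clamped to [100, 250],
#' centers the fragment on the dyad (`[dyad - floor(F/2), dyad - floor(F/2)
#' + F)`), assigns a strand with probability 1/2, and reports the sequenced
#' end: a `+` read starts at the fragment's left end, a `-` read's leftmost
#' coordinate is `fragment end - read_length`. The read length is
#' `min(read_length, F)`. Fragments extending past a chromosome end are
#' resampled.
#'
#' @param config Configuration tibble from [simulate_configurations()].
#' @param genome Genome tibble (`chrom`, `length`).
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @return Reads tibble (`chrom`, `start`, `length`, `strand`) with
#'   attribute `total_mapped = cfg$total_reads`.
#' @export
simulate_reads <- function(config, genome, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(cfg$total_reads)
  lens <- chrom_lengths(genome)
  draw <- function(m) {
    idx <- sample.int(nrow(config), m, replace = TRUE)
    f <- pmin(pmax(round(rnorm(m, cfg$frag_mean, cfg$frag_sd)), 100), 250)
    dyad <- config$dyad[idx]
    left <- dyad - floor(f / 2)
    tibble(chrom = config$chrom[idx], left = left, right = left + f, f = f)
  }
  frags <- draw(n)
  bad <- which(frags$left < 0 | frags$right > lens[frags$chrom])
  tries <- 0
  while (length(bad) > 0) {
    tries <- tries + 1
    if (tries > 1000) abort("fragment placement failed repeatedly; genome too small")
    frags[bad, ] <- draw(length(bad))
    bad <- which(frags$left < 0 | frags$right > lens[frags$chrom])
  }
  minus <- runif(n) < 0.5
  rl <- pmin(cfg$read_length, frags$f)
  start <- ifelse(minus, frags$right - rl, frags$left)
  new_reads(frags$chrom, start, rl, ifelse(minus, "-", "+"),
            total_mapped = n)
}

#' Simulate nucleosome-scanning qPCR tables
#'
#' The true protection of an amplicon is the fraction of cells in which some
#' nucleosome footprint `[dyad - 73, dyad + 74)` fully covers the amplicon
#' interval `[center - halfwidth, center + halfwidth]`. Each replicate's
#' mononucleosomal quantity is `protection * (1 + N(0, noise_cv))`; the
#' undigested input quantity is `1 * (1 + N(0, noise_cv))`.
#'
#' @param config Configuration tibble from [simulate_configurations()].
#' @param amplicons Tibble with columns `target`, `center` (0-based bp) and
#'   `halfwidth` (bp); optionally `chrom` (default the config's chromosome).
#' @param genome Genome tibble, used to reject out-of-genome amplicons.
#' @param replicates Number of replicates per amplicon.
#' @param noise_cv Coefficient of variation of the measurement noise.
#' @param strain Condition label stamped on the table.
#' @param seed Optional integer seed.
#' @return Tibble with columns `target`, `position`, `replicate`,
#'   `mono_quantity`, `input_quantity`, `strain`.
#' @export
simulate_qpcr <- function(config, amplicons, genome, replicates = 3,
                          noise_cv = 0.1, strain = "WT", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- chrom_lengths(genome)
  if (!"chrom" %in% names(amplicons)) amplicons$chrom <- config$chrom[1]
  lo <- amplicons$center - amplicons$halfwidth
  hi <- amplicons$center + amplicons$halfwidth
  if (any(lo < 0 | hi >= lens[amplicons$chrom])) {
    abort("amplicon outside genome bounds")
  }
  n_cells <- dplyr::n_distinct(config$cell)
  half <- 73  # footprint [dyad - 73, dyad + 74) covers [lo, hi] iff
              # dyad - 73 <= lo and hi <= dyad + 73
  prot <- purrr::map_dbl(seq_len(nrow(amplicons)), function(i) {
    hit <- config$chrom == amplicons$chrom[i] &
      config$dyad >= hi[i] - half & config$dyad <= lo[i] + half
    dplyr::n_distinct(config$cell[hit]) / n_cells
  })
  tidyr::expand_grid(i = seq_len(nrow(amplicons)),
                     replicate = seq_len(replicates)) |>
    mutate(
      target = amplicons$target[.data$i],
      position = amplicons$center[.data$i],
      mono_quantity = prot[.data$i] * (1 + rnorm(dplyr::n(), 0, noise_cv)),
      input_quantity = 1 * (1 + rnorm(dplyr::n(), 0, noise_cv)),
      strain = strain
    ) |>
    select("target", "position", "replicate", "mono_quantity",
           "input_quantity", "strain")
}

#' Simulate strand-specific transcript tables
#'
#' Sense and antisense quantities per gene and replicate are drawn as
#' `base * fold * (1 + N(0, noise_cv))`. The fold factor is 1 everywhere
#' except the antisense strand of TF-dependent genes in the `no_barrier`
#' condition, where it equals `antisense_fold` — enhanced antisense
#' transcription restricted to barrier-dependent genes.
#'
#' @param genes Gene model tibble (uses `gene_id`, `atf1_dependent`).
#' @param condition `"barrier"` or `"no_barrier"`; also the strain label.
#' @param base_sense,base_antisense Baseline quantities.
#' @param antisense_fold Antisense derepression factor in `no_barrier`.
#' @param noise_cv Coefficient of variation of the noise.
#' @param replicates Number of replicates.
#' @param seed Optional integer seed.
#' @return Tibble with columns `gene_id`, `strand_sense`, `quantity`,
#'   `replicate`, `strain`.
#' @export
simulate_transcripts <- function(genes, condition = c("barrier", "no_barrier"),
                                 base_sense = 10, base_antisense = 1,
                                 antisense_fold = 4, noise_cv = 0.1,
                                 replicates = 3, seed = NULL) {
  condition <- match.arg(condition)
  if (!is.null(seed)) set.seed(seed)
  tidyr::expand_grid(gene_id = genes$gene_id,
                     strand_sense = c("sense", "antisense"),
                     replicate = seq_len(replicates)) |>
    left_join(select(genes, "gene_id", "atf1_dependent"), by = "gene_id") |>
    mutate(
      base = ifelse(.data$strand_sense == "sense", base_sense, base_antisense),
      fold = ifelse(condition == "no_barrier" & .data$atf1_dependent &
                      .data$strand_sense == "antisense", antisense_fold, 1),
      quantity = .data$base * .data$fold * (1 + rnorm(dplyr::n(), 0, noise_cv)),
      strain = condition
    ) |>
    select("gene_id", "strand_sense", "quantity", "replicate", "strain")
}
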