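test_that("zero-noise limit places dyads exactly on the nominal lattice", {
  cfg <- zero_jitter_config(n_genes = 2, n_cells = 5, linker = 18,
                            nuc_footprint = 147, plus_one_offset = 90)
  genes <- sim_gene_models(cfg)
  conf <- simulate_configurations(genes, cfg, seed = 1)
  for (gi in 1:2) {
    d <- conf[conf$gene_id == genes$gene_id[gi] & conf$cell == 3, ]
    rel <- d$dyad[order(d$nuc_index)] - genes$tss[gi]
    # upstream -2, -1 then the array 90, 90+165, ...
    expect_equal(rel[d$nuc_index[order(d$nuc_index)] >= 1],
                 90 + 165 * (0:(cfg$n_nucs - 1)))
    expect_equal(rel[1:2], c(-330 - 165, -330))
  }
  # every cell identical under zero noise
  spread <- tapply(conf$dyad, interaction(conf$gene_id, conf$nuc_index), sd)
  expect_true(all(spread == 0))
})

test_that("barrier loss shifts the mean +1 dyad toward the NDR by fill_shift", {
  n <- 1e4
  cfg1 <- sim_config(n_genes = 1, n_cells = n, p_bound = 1)
  cfg0 <- sim_config(n_genes = 1, n_cells = n, p_bound = 0)
  genes <- sim_gene_models(cfg1)
  d1 <- simulate_configurations(genes, cfg1, seed = 3)
  d0 <- simulate_configurations(genes, cfg0, seed = 3)
  p1 <- d1$dyad[d1$nuc_index == 1]
  p0 <- d0$dyad[d0$nuc_index == 1]
  shift <- mean(p1) - mean(p0)
  se <- sqrt(var(p1) / n + var(p0) / n)
  expect_lt(abs(shift - cfg1$fill_shift), 3 * se + 1e-9)
})

test_that("simulator output is bit-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 3, n_cells = 50, total_reads = 2000)
  genes <- sim_gene_models(cfg)
  genome <- sim_genome(cfg)
  c1 <- simulate_configurations(genes, cfg, seed = 42)
  c2 <- simulate_configurations(genes, cfg, seed = 42)
  expect_identical(c1, c2)
  r1 <- simulate_reads(c1, genome, cfg, seed = 7)
  r2 <- simulate_reads(c2, genome, cfg, seed = 7)
  expect_identical(r1, r2)
  amp <- tibble::tibble(target = "a", center = genes$tss[1], halfwidth = 30)
  expect_identical(simulate_qpcr(c1, amp, genome, seed = 9),
                   simulate_qpcr(c1, amp, genome, seed = 9))
  expect_identical(simulate_transcripts(genes, "no_barrier", seed = 11),
                   simulate_transcripts(genes, "no_barrier", seed = 11))
})

test_that("hard-core exclusion holds within every cell and gene", {
  cfg <- sim_config(n_genes = 4, n_cells = 200, sigma_step = 25,
                    sigma_step_free = 40, p_bound = 0.5)
  genes <- sim_gene_models(cfg)
  conf <- simulate_configurations(genes, cfg, seed = 5)
  gaps <- conf |>
    dplyr::arrange(cell, gene_id, dyad) |>
    dplyr::group_by(cell, gene_id) |>
    dplyr::summarise(min_gap = min(diff(dyad)), .groups = "drop")
  expect_true(all(gaps$min_gap >= cfg$nuc_footprint))
})

test_that("positional variance grows along the array (cumulative jitter)", {
  cfg <- sim_config(n_genes = 1, n_cells = 5000, sigma_step = 10)
  genes <- sim_gene_models(cfg)
  conf <- simulate_configurations(genes, cfg, seed = 8)
  s <- tapply(conf$dyad, conf$nuc_index, sd)
  expect_gt(s[["4"]], s[["1"]])
})

test_that("minus-strand genes mirror the dyad distribution of plus twins", {
  cfg <- sim_config(n_genes = 2, n_cells = 3000)
  genes <- sim_gene_models(cfg, strands = c("+", "-"))
  conf <- simulate_configurations(genes, cfg, seed = 7)
  plus <- conf[conf$gene_id == genes$gene_id[1], ]
  minus <- conf[conf$gene_id == genes$gene_id[2], ]
  for (k in c(-2L, -1L, 1L, 2L, 4L, 8L)) {
    mp <- mean(plus$dyad[plus$nuc_index == k]) - genes$tss[1]
    mm <- genes$tss[2] - mean(minus$dyad[minus$nuc_index == k])
    sp <- sd(plus$dyad[plus$nuc_index == k])
    sm <- sd(minus$dyad[minus$nuc_index == k])
    se <- sqrt(sp^2 + sm^2) / sqrt(3000)
    expect_lt(abs(mp - mm), 4 * se + 0.1)
    expect_lt(abs(sp - sm) / sp, 0.15)
  }
})

test_that("read fragments are dyad-centered with the stated end conventions", {
  conf <- tibble::tibble(cell = 1L, gene_id = "g", chrom = "chrI",
                         strand = "+", nuc_index = 1L, dyad = 1000,
                         bound = TRUE)
  genome <- tibble::tibble(chrom = "chrI", length = 3000L)
  cfg <- sim_config(total_reads = 500, frag_mean = 150, frag_sd = 0,
                    read_length = 50)
  r <- simulate_reads(conf, genome, cfg, seed = 2)
  expect_equal(nrow(r), 500L)                       # conservation
  expect_equal(total_mapped(r), 500L)
  plus <- r[r$strand == "+", ]
  minus <- r[r$strand == "-", ]
  expect_true(all(plus$start == 925))               # dyad - floor(150/2)
  expect_true(all(minus$start + minus$length == 1075))  # fragment end
  expect_true(all(r$length == 50))
})

test_that("mean read start recovers the mean dyad (law of large numbers)", {
  cfg <- sim_config(n_genes = 1, n_cells = 500, total_reads = 1e5,
                    n_nucs = 1, n_nucs_up = 1, sigma_minus_one = 5)
  genes <- sim_gene_models(cfg)
  genome <- sim_genome(cfg)
  conf <- simulate_configurations(genes, cfg, seed = 21)
  r <- simulate_reads(conf, genome, cfg, seed = 22)
  plus <- r[r$strand == "+", ]
  expect_lt(abs(mean(plus$start) + cfg$frag_mean / 2 - mean(conf$dyad)), 1)
})

test_that("qPCR protection reflects footprint coverage and NDR exclusion", {
  cfg <- zero_jitter_config(n_genes = 1, n_cells = 400, p_bound = 1)
  genes <- sim_gene_models(cfg)
  genome <- sim_genome(cfg)
  conf <- simulate_configurations(genes, cfg, seed = 13)
  amp <- tibble::tibble(
    target = c("plus1", "ndr"),
    center = c(genes$tss + cfg$plus_one_offset, genes$cre_site),
    halfwidth = 30
  )
  q <- simulate_qpcr(conf, amp, genome, replicates = 3, noise_cv = 0, seed = 1)
  expect_equal(q$mono_quantity[q$target == "plus1"], rep(1, 3))  # fully protected
  expect_equal(q$mono_quantity[q$target == "ndr"], rep(0, 3))    # excluded zone
  expect_equal(q$input_quantity, rep(1, 6))
  # zero noise: replicates identical
  expect_equal(dplyr::n_distinct(q$mono_quantity[q$target == "plus1"]), 1L)
  # out-of-genome amplicon refused
  bad <- tibble::tibble(target = "x", center = 10, halfwidth = 30)
  expect_error(simulate_qpcr(conf, bad, genome), "outside")
})

test_that("CRE-amplicon protection is non-increasing in barrier occupancy", {
  prot <- vapply(c(0, 0.5, 1), function(pb) {
    cfg <- sim_config(n_genes = 1, n_cells = 1e4, p_bound = pb)
    genes <- sim_gene_models(cfg)
    conf <- simulate_configurations(genes, cfg, seed = 31)
    amp <- tibble::tibble(target = "cre", center = genes$cre_site,
                          halfwidth = 30)
    q <- simulate_qpcr(conf, amp, sim_genome(cfg), replicates = 1,
                       noise_cv = 0, seed = 1)
    q$mono_quantity[1]
  }, numeric(1))
  expect_true(all(diff(prot) <= 0))
  expect_equal(prot[3], 0)  # full binding excludes nucleosomes from the CRE
})

test_that("antisense derepression is restricted to dependent genes", {
  cfg <- sim_config(n_genes = 4)
  genes <- sim_gene_models(cfg, atf1_dependent = c(TRUE, TRUE, FALSE, FALSE))
  b <- simulate_transcripts(genes, "barrier", noise_cv = 0, seed = 1,
                            antisense_fold = 4)
  f <- simulate_transcripts(genes, "no_barrier", noise_cv = 0, seed = 2,
                            antisense_fold = 4)
  ratio <- function(gid, ss) {
    mean(f$quantity[f$gene_id == gid & f$strand_sense == ss]) /
      mean(b$quantity[b$gene_id == gid & b$strand_sense == ss])
  }
  expect_equal(ratio("g001", "antisense"), 4)
  expect_equal(ratio("g003", "antisense"), 1)
  expect_equal(ratio("g001", "sense"), 1)   # sense unaffected by the fold
  expect_equal(ratio("g004", "sense"), 1)
})
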