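test_that("dyad intervals shift by half the fragment and span exactly trim", {
  p <- processing_params(trim = 40)
  plus <- tibble::tibble(chrom = "chrI", start = 1000L, length = 50L,
                         strand = "+")
  iv <- dyad_intervals(plus, 150, p)
  expect_equal(c(iv$start, iv$end), c(1055L, 1095L))  # 1000 + 75 - 20
  minus <- tibble::tibble(chrom = "chrI", start = 1000L, length = 50L,
                          strand = "-")
  iv <- dyad_intervals(minus, 150, p)
  expect_equal(c(iv$start, iv$end), c(954L, 994L))    # 1049 - 75 = 974
  # width invariant over random reads and odd fragment lengths
  set.seed(1)
  r <- tibble::tibble(chrom = "chrI", start = sample.int(1e5, 200),
                      length = 50L,
                      strand = sample(c("+", "-"), 200, replace = TRUE))
  for (f in c(147, 150)) {
    iv <- dyad_intervals(r, f, p)
    expect_true(all(iv$end - iv$start == 40L))
  }
  expect_error(dyad_intervals(plus, 40, p), "exceed")
})

test_that("fragment-length estimation locks the insert-size convention", {
  # + starts at x, - 5' ends at x + 149: insert size 150
  x <- seq(500, 50000, by = 37)
  reads <- tibble::tibble(
    chrom = "chrI",
    start = c(x, x + 149 - 49),
    length = 50L,
    strand = rep(c("+", "-"), each = length(x))
  )
  expect_equal(estimate_fragment_length(reads), 150L)
})

test_that("fragment-length estimation refuses degenerate inputs", {
  plus_only <- tibble::tibble(chrom = "chrI", start = 1:100, length = 50L,
                              strand = "+")
  expect_error(estimate_fragment_length(plus_only), "both strands")
  # + and - densities too far apart for any lag in range: flat correlation
  flat <- tibble::tibble(chrom = "chrI", start = c(0L, 5000L),
                         length = 50L, strand = c("+", "-"))
  expect_error(estimate_fragment_length(flat), "no fragment-length signal")
})

test_that("fragment length is recovered from simulated libraries", {
  cfg <- sim_config(n_genes = 20, total_reads = 5e4)
  pipe_genes <- sim_gene_models(cfg)
  conf <- simulate_configurations(pipe_genes, cfg, seed = 11)
  reads <- simulate_reads(conf, sim_genome(cfg), cfg, seed = 12)
  est <- estimate_fragment_length(reads)
  expect_lte(abs(est - cfg$frag_mean), 3)
})

test_that("raw coverage counts every non-clipped dyad interval base once", {
  genome <- tibble::tibble(chrom = "chrI", length = 2000L)
  p <- processing_params(trim = 40)
  one <- tibble::tibble(chrom = "chrI", start = 500L, length = 50L,
                        strand = "+")
  trk <- build_coverage(one, genome, fragment_length = 150, params = p)
  v <- trk$values$chrI
  expect_equal(sum(v), 40)
  expect_equal(sum(v == 1), 40L)
  expect_equal(which(v == 1)[1] - 1L, 555L)  # interval start

  # two overlapping reads double the overlap
  two <- dplyr::bind_rows(one, dplyr::mutate(one, start = 510L))
  trk2 <- build_coverage(two, genome, fragment_length = 150, params = p)
  expect_equal(sum(trk2$values$chrI == 2), 30L)
  expect_equal(sum(trk2$values$chrI), 80)

  # chromosome-edge interval is dropped but stays in total_mapped
  edge <- tibble::tibble(chrom = "chrI", start = c(500L, 1950L),
                         length = 50L, strand = "+")
  expect_message(
    trk3 <- build_coverage(edge, genome, fragment_length = 150, params = p),
    "excluded"
  )
  expect_equal(trk3$clipped, 1L)
  expect_equal(sum(trk3$values$chrI), (2 - 1) * 40)
  expect_equal(trk3$total_mapped, 2L)
})

test_that("RPM normalization is the documented linear map", {
  trk <- coverage_track(list(chrI = c(5, 3, 0)), state = "raw",
                        total_mapped = 1e6)
  n <- normalize_rpm(trk)
  expect_equal(n$values$chrI, c(5, 3, 0))
  expect_equal(n$state, "rpm")
  n2 <- normalize_rpm(trk, total_mapped = 2e6)
  expect_equal(n2$values$chrI[2], 1.5)
  expect_equal(sum(n2$values$chrI), sum(trk$values$chrI) * 1e6 / 2e6)
  trk0 <- coverage_track(list(chrI = c(1)), state = "raw", total_mapped = 0)
  expect_error(normalize_rpm(trk0), "positive")
})

test_that("mirrored reads give the mirrored track up to the half-open offset", {
  # an even-width half-open dyad interval covers [c-20, c+20), so mirroring
  # the genome shifts the interval pattern by exactly 1 bp
  L <- 5000L
  genome <- tibble::tibble(chrom = "chrI", length = L)
  set.seed(3)
  reads <- tibble::tibble(chrom = "chrI",
                          start = sample(500:4000, 300, replace = TRUE),
                          length = 50L,
                          strand = sample(c("+", "-"), 300, replace = TRUE))
  mirrored <- tibble::tibble(chrom = "chrI",
                             start = L - (reads$start + reads$length),
                             length = 50L,
                             strand = ifelse(reads$strand == "+", "-", "+"))
  t1 <- build_coverage(reads, genome, fragment_length = 147)$values$chrI
  t2 <- build_coverage(mirrored, genome, fragment_length = 147)$values$chrI
  expect_equal(rev(t2)[-1], t1[-L])
})

test_that("raw coverage maxima sit on true dyads in the zero-noise limit", {
  cfg <- zero_jitter_config(n_genes = 5, n_cells = 20, total_reads = 2e4)
  genes <- sim_gene_models(cfg)
  conf <- simulate_configurations(genes, cfg, seed = 15)
  reads <- simulate_reads(conf, sim_genome(cfg), cfg, seed = 16)
  trk <- build_coverage(reads, sim_genome(cfg), fragment_length = 147)
  v <- trk$values$chrI
  truth <- unique(conf[conf$nuc_index >= 1, c("gene_id", "nuc_index", "dyad")])
  for (d in truth$dyad) {
    win <- v[(d - 79):(d + 81)]  # 0-based d -> index d + 1
    top <- which(win == max(win)) + (d - 80)
    plateau_mid <- (min(top) + max(top)) / 2
    expect_lte(abs(plateau_mid - d), 1)
  }
})
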