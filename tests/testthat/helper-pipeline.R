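# Run the generator and coverage pipeline in one go. pc_keep = 0.05 keeps
# wavelengths down to 40 bp, below the 165 bp nucleosome repeat, which is
# required to localize individual dyads.
run_sim_pipeline <- function(cfg, seed, pc_keep = 0.05) {
  genes <- sim_gene_models(cfg)
  genome <- sim_genome(cfg)
  config <- simulate_configurations(genes, cfg, seed = seed)
  reads <- simulate_reads(config, genome, cfg, seed = seed + 1L)
  fl <- estimate_fragment_length(reads)
  track <- build_coverage(reads, genome, fragment_length = fl)
  smoothed <- smooth_track(normalize_rpm(track), pc_keep = pc_keep)
  list(cfg = cfg, genes = genes, genome = genome, config = config,
       reads = reads, fragment_length = fl, raw = track, smoothed = smoothed)
}

# Zero-jitter configuration: deterministic dyad positions, fixed-length
# fragments. Used for exact-recovery checks.
zero_jitter_config <- function(...) {
  sim_config(sigma_plus_one = 0, sigma_plus_one_free = 0, sigma_minus_one = 0,
             sigma_step = 0, sigma_step_free = 0, frag_sd = 0, ...)
}

# A smoothed-state track built directly from values (for peak-calling unit
# tests on constructed signals).
smoothed_track <- function(values) {
  coverage_track(values, state = "smoothed")
}

mean_plus_one_anchor <- function(pipeline) {
  calls <- call_peaks(pipeline$smoothed)
  assign_plus_one(calls, pipeline$genes)
}
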