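#' Read-processing parameters
#'
#' Parameters of the dyad-centering stage. Each read's start coordinate is
#' shifted by half the (estimated) fragment length to land on the nucleosome
#' dyad, then extended `extension = trim/2` nucleotides on each side, so
#' every dyad interval has width exactly `trim` (default 40 bp, i.e. extend
#' 20 nt per side).
#'
#' @param trim Width (bp) of the dyad interval; must be a positive even
#'   number (`trim = 2 * extension`).
#' @param fragment_length Fragment length (bp) to use for shifting; `NULL`
#'   means estimate it from the data with [estimate_fragment_length()].
#' @param lag_search Two-element (min, max) bp window searched by the
#'   fragment-length estimator.
#' @param pc_keep Fraction of Fourier components kept by [fft_lowpass()].
#' @param pseudocount Small positive value added before log2 in composite
#'   profiles (RPM units).
#' @param flank Half-width (bp) of anchored profile windows.
#' @return An object of class `processing_params`.
#' @export
processing_params <- function(trim = 40, fragment_length = NULL,
                              lag_search = c(100, 250), pc_keep = 0.02,
                              pseudocount = 0.1, flank = 500) {
  if (trim <= 0 || trim %% 2 != 0) abort("trim must be a positive even number")
  if (pc_keep <= 0 || pc_keep > 1) abort("pc_keep must be in (0, 1]")
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  if (length(lag_search) != 2 || lag_search[1] >= lag_search[2]) {
    abort("lag_search must be (min, max) with min < max")
  }
  structure(list(trim = as.integer(trim), extension = as.integer(trim / 2),
                 fragment_length = fragment_length,
                 lag_search = as.integer(lag_search), pc_keep = pc_keep,
                 pseudocount = pseudocount, flank = as.integer(flank)),
            class = "processing_params")
}

#' Estimate the fragment length by strand cross-correlation
#'
#' Builds per-base densities of `+` read 5' starts and `-` read 5' ends
#' (rightmost coordinate) and returns the fragment length maximizing their
#' cross-correlation. The convention is locked so that the returned value is
#' the insert size: the distance from a `+` read start to the fragment's
#' last base, plus one. Ties break toward the smaller lag.
#'
#' @param reads Reads tibble.
#' @param lag_search (min, max) bp window to search.
#' @return Estimated fragment length (bp).
#' @export
estimate_fragment_length <- function(reads, lag_search = c(100, 250)) {
  plus <- reads$strand == "+"
  if (!any(plus) || !any(!plus)) {
    abort("both strands must be represented to estimate the fragment length")
  }
  # lag d between 5' end densities corresponds to fragment length d + 1
  lags <- (lag_search[1] - 1L):(lag_search[2] - 1L)
  cc <- numeric(length(lags))
  for (cn in unique(reads$chrom)) {
    sel <- reads$chrom == cn
    p5 <- reads$start[sel & plus]
    m5 <- (reads$start + reads$length - 1L)[sel & !plus]
    if (length(p5) == 0 || length(m5) == 0) next
    L <- max(p5, m5) + 1L
    pd <- tabulate(p5 + 1L, nbins = L)
    md <- tabulate(m5 + 1L, nbins = L)
    for (j in seq_along(lags)) {
      d <- lags[j]
      if (d >= L) next
      cc[j] <- cc[j] + sum(pd[1:(L - d)] * md[(d + 1):L])
    }
  }
  if (max(cc) <= mean(cc) + 1e-12) abort("no fragment-length signal")
  lags[which.max(cc)] + 1L
}

#' Dyad intervals of reads
#'
#' For a `+` read the dyad center is `start + floor(F/2)`; for a `-` read it
#' is the 5' end (rightmost base) shifted left, `(start + length - 1) -
#' floor(F/2)`. The returned half-open interval is `[center - extension,
#' center + extension)`, width exactly `trim`.
#'
#' @param reads Reads tibble.
#' @param fragment_length Fragment length `F` (bp); must exceed `trim`.
#' @param params A [processing_params()].
#' @return Tibble with columns `chrom`, `start`, `end`.
#' @export
dyad_intervals <- function(reads, fragment_length, params = processing_params()) {
  if (fragment_length <= params$trim) abort("fragment_length must exceed trim")
  half <- floor(fragment_length / 2)
  center <- ifelse(reads$strand == "+",
                   reads$start + half,
                   reads$start + reads$length - 1L - half)
  tibble(chrom = reads$chrom,
         start = as.integer(center - params$extension),
         end = as.integer(center + params$extension))
}

#' Accumulate dyad-centered raw coverage
#'
#' Each base covered by a dyad interval increments by one, so the total raw
#' coverage mass equals (number of non-clipped reads) x `trim` exactly.
#' Intervals extending past a chromosome end are excluded from accumulation;
#' they are still counted in `total_mapped` (used later for RPM) and
#' reported in the track's `clipped` field.
#'
#' @param reads Reads tibble.
#' @param genome Genome tibble (`chrom`, `length`).
#' @param fragment_length Fragment length (bp); `NULL` uses
#'   `params$fragment_length`, or estimates it from the reads.
#' @param params A [processing_params()].
#' @return A raw-state `coverage_track`.
#' @export
build_coverage <- function(reads, genome, fragment_length = NULL,
                           params = processing_params()) {
  fragment_length <- fragment_length %||% params$fragment_length %||%
    estimate_fragment_length(reads, params$lag_search)
  iv <- dyad_intervals(reads, fragment_length, params)
  lens <- chrom_lengths(genome)
  unknown <- setdiff(unique(iv$chrom), names(lens))
  if (length(unknown) > 0) {
    abort(sprintf("reads on chromosome(s) absent from genome: %s",
                  paste(unknown, collapse = ", ")))
  }
  clipped <- iv$start < 0 | iv$end > lens[iv$chrom]
  keep <- iv[!clipped, ]
  values <- lapply(names(lens), function(cn) {
    L <- lens[[cn]]
    d <- numeric(L + 1L)
    sel <- keep$chrom == cn
    if (any(sel)) {
      s <- keep$start[sel]; e <- keep$end[sel]
      add_s <- tabulate(s + 1L, nbins = L + 1L)
      add_e <- tabulate(e + 1L, nbins = L + 1L)
      d <- add_s - add_e
    }
    cumsum(d)[seq_len(L)]
  })
  names(values) <- names(lens)
  track <- coverage_track(values, state = "raw",
                          total_mapped = total_mapped(reads),
                          clipped = sum(clipped))
  track$fragment_length <- fragment_length
  if (any(clipped)) {
    message(sprintf("%d read(s) with chromosome-edge dyad intervals excluded from coverage",
                    sum(clipped)))
  }
  track
}

#' Normalize a raw track to reads per million (RPM)
#'
#' Divides every value by the total number of mapped reads and multiplies by
#' one million.
#'
#' @param track A raw `coverage_track`.
#' @param total_mapped Override for the mapped-read count (defaults to the
#'   count stored on the track).
#' @return An RPM-state `coverage_track`.
#' @export
normalize_rpm <- function(track, total_mapped = NULL) {
  tm <- total_mapped %||% track$total_mapped
  if (is.na(tm) || tm <= 0) abort("total_mapped must be a positive count")
  out <- track
  out$values <- lapply(track$values, function(v) v * 1e6 / tm)
  out$state <- "rpm"
  out$total_mapped <- tm
  out
}
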