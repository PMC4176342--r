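#' FFT low-pass filter
#'
#' Discrete-Fourier-transforms the signal, keeps the DC component and every
#' coefficient with frequency index `k <= ceiling(pc_keep * N / 2)` (plus
#' the conjugate mirror), zeroes the rest, and inverse-transforms. The
#' retained band therefore always contains wavelengths down to about
#' `2 / pc_keep` bases, independent of `N`. Negative values produced by the
#' truncation are clamped to zero by default (occupancy is non-negative);
#' set `clamp = FALSE` to inspect the linear projection itself, which is
#' idempotent, mean-preserving and energy-non-increasing.
#'
#' @param x Numeric signal (length >= 2, all finite).
#' @param pc_keep Fraction of Fourier components kept, in (0, 1]. 1 returns
#'   the input (within numerical tolerance).
#' @param clamp Clamp negative output to zero?
#' @return Numeric vector of the same length.
#' @examples
#' i <- 0:999
#' x <- 5 + 2 * cos(2 * pi * 3 * i / 1000)
#' max(abs(fft_lowpass(x, 0.02) - x)) < 1e-9  # inside the passband
#' @export
fft_lowpass <- function(x, pc_keep = 0.02, clamp = TRUE) {
  n <- length(x)
  if (n < 2) abort("signal must have length >= 2")
  if (!all(is.finite(x))) abort("signal contains non-finite values")
  if (pc_keep <= 0 || pc_keep > 1) abort("pc_keep must be in (0, 1]")
  cutoff <- ceiling(pc_keep * n / 2)
  fy <- fft(x)
  k <- seq_len(n) - 1L               # 0-based frequency index
  keep <- k <= cutoff | k >= n - cutoff
  fy[!keep] <- 0
  y <- Re(fft(fy, inverse = TRUE)) / n
  if (clamp) y <- pmax(y, 0)
  y
}

#' Smooth a coverage track by FFT low-pass filtering
#'
#' Applies [fft_lowpass()] per chromosome. Chromosomes longer than
#' `chunk_size` are processed in overlapping windows whose central regions
#' are stitched together; the overlap (several times the cutoff wavelength
#' `2 / pc_keep`) keeps windowing artifacts away from the retained centre,
#' with residual disagreement relative to the whole-chromosome transform on
#' the order of `1 / (pi * overlap)` of the local signal scale.
#'
#' @param track A `coverage_track` (raw or rpm).
#' @param pc_keep Fraction of Fourier components kept.
#' @param chunk_size Window size (bp) above which chunked processing kicks
#'   in.
#' @return A smoothed-state `coverage_track`.
#' @export
smooth_track <- function(track, pc_keep = 0.02, chunk_size = 500000L) {
  overlap <- max(ceiling(4 / pc_keep), 256L)
  if (chunk_size <= 4L * overlap) abort("chunk_size too small for the required overlap")
  out <- track
  out$values <- lapply(track$values, function(v) {
    L <- length(v)
    if (L < 2) return(v)
    if (L <= chunk_size) return(fft_lowpass(v, pc_keep))
    res <- numeric(L)
    step <- chunk_size - 2L * overlap
    s <- 1L
    repeat {
      e <- min(s + chunk_size - 1L, L)
      sm <- fft_lowpass(v[s:e], pc_keep)
      keep_from <- if (s == 1L) 1L else s + overlap
      keep_to <- if (e == L) L else e - overlap
      res[keep_from:keep_to] <- sm[(keep_from - s + 1L):(keep_to - s + 1L)]
      if (e == L) break
      s <- s + step
    }
    res
  })
  out$state <- "smoothed"
  out
}
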