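# Independent O(N^2) direct-summation DFT truncation oracle for the FFT
# low-pass filter: computes the DFT by explicit complex-exponential sums,
# zeroes coefficients outside the retained band, and inverts by direct
# summation. Deliberately does not call fft().
dft_truncate_oracle <- function(x, pc_keep, clamp = TRUE) {
  n <- length(x)
  cutoff <- ceiling(pc_keep * n / 2)
  j <- 0:(n - 1)
  X <- vapply(0:(n - 1), function(k) sum(x * exp(-2i * pi * k * j / n)),
              complex(1))
  k <- 0:(n - 1)
  X[!(k <= cutoff | k >= n - cutoff)] <- 0
  y <- vapply(0:(n - 1), function(m) sum(X * exp(2i * pi * k * m / n)) / n,
              complex(1))
  y <- Re(y)
  if (clamp) y <- pmax(y, 0)
  y
}
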