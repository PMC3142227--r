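## DFT, one-sided periodogram PSD, adjacent-bin smoothing, ensemble
## averaging and log-log slope estimation.

.window_weights <- function(window, N) {
  n <- 0:(N - 1)
  switch(window,
    rectangular = rep(1, N),
    hamming = 0.54 - 0.46 * cos(2 * pi * n / (N - 1)),
    blackman = 0.42 - 0.5 * cos(2 * pi * n / (N - 1)) +
      0.08 * cos(4 * pi * n / (N - 1)),
    stop("unknown window '", window, "' (rectangular, hamming, blackman)"))
}

#' Discrete Fourier transform of a uniform signal
#'
#' Multiplies the signal by the chosen weighting window (rectangular =
#' identity) and computes the standard DFT C(k) = sum_n c[n]
#' exp(-2 pi i k n / N) via the FFT. The signal length must be even (the
#' one-sided PSD convention assumes it).
#'
#' @param sig a \linkS4class{UniformSignal} of even length.
#' @param window one of \code{"rectangular"}, \code{"hamming"},
#'   \code{"blackman"}.
#' @return list with \code{coeffs} (complex, length N), \code{F} (Hz),
#'   \code{N}, \code{window}.
#' @export
dftSpectrum <- function(sig, window = "rectangular") {
  N <- length(sig@values)
  if (N %% 2 != 0) stop("signal length must be even")
  w <- .window_weights(window, N)
  list(coeffs = stats::fft(sig@values * w), F = 1 / sig@dt, N = N,
       window = window)
}

#' One-sided periodogram PSD estimate
#'
#' Subtracts the sample mean (fluctuation analysis around a steady state;
#' also prevents DC leakage through finite-window sidelobes), applies the
#' window, and reports P(f_k) = 2 |C(k)|^2 / (F N W) on the positive
#' frequencies f_k = F k / N, k = 1..N/2, where W is the window's mean-square
#' power normalization (1 for rectangular). DC is excluded. The factor 2 is
#' applied to every reported bin including Nyquist (documented
#' simplification; irrelevant for smoothed log-log slopes).
#'
#' @param sig a \linkS4class{UniformSignal} of even length.
#' @param window weighting window name.
#' @param demean subtract the sample mean first (default TRUE).
#' @return A \linkS4class{PSDEstimate} in (signal units)^2 / Hz.
#' @examples
#' set.seed(1)
#' sig <- UniformSignal(rnorm(1024), dt = 1e-3)
#' psd <- periodogramPSD(sig)
#' # one-sided Parseval: sum(P) * F/N ~ var(values)
#' @export
periodogramPSD <- function(sig, window = "rectangular", demean = TRUE) {
  N <- length(sig@values)
  if (N %% 2 != 0) stop("signal length must be even")
  v <- sig@values
  if (demean) v <- v - mean(v)
  w <- .window_weights(window, N)
  W <- mean(w^2)
  C <- stats::fft(v * w)
  Fs <- 1 / sig@dt
  k <- 1:(N / 2)
  new("PSDEstimate", freqs = Fs * k / N,
      power = 2 * Mod(C[k + 1])^2 / (Fs * N * W),
      nAveraged = 1L, binWidth = 1L)
}

setMethod("show", "PSDEstimate", function(object) {
  cat(sprintf(
    "PSDEstimate: %d bins, f in [%g, %g] Hz, %d realization(s), bin width %d\n",
    length(object@freqs), min(object@freqs), max(object@freqs),
    object@nAveraged, object@binWidth))
})

#' Smooth a PSD by aggregating adjacent frequency bins
#'
#' Aggregates non-overlapping groups of \code{m} consecutive bins (a trailing
#' remainder is dropped), reporting the group mean power at the group mean
#' frequency. The mean (rather than the sum) keeps the units (units)^2/Hz;
#' the two differ only by the constant factor m and give identical log-log
#' slopes.
#'
#' @param psd a \linkS4class{PSDEstimate}.
#' @param m integer group size >= 1 (1 = identity).
#' @return A smoothed \linkS4class{PSDEstimate} with \code{binWidth}
#'   multiplied by m.
#' @export
smoothBins <- function(psd, m) {
  if (length(m) != 1 || m != round(m) || m < 1) stop("m must be an integer >= 1")
  m <- as.integer(m)
  if (m == 1L) return(psd)
  n <- length(psd@freqs) %/% m
  if (n < 1) stop("fewer than m bins")
  idx <- rep(seq_len(n), each = m)
  keep <- seq_len(n * m)
  new("PSDEstimate",
      freqs = as.numeric(tapply(psd@freqs[keep], idx, mean)),
      power = as.numeric(tapply(psd@power[keep], idx, mean)),
      nAveraged = psd@nAveraged, binWidth = psd@binWidth * m)
}

#' Ensemble-average PSD estimates over replicate realizations
#'
#' Pointwise mean over realizations sharing the same frequency grid; the
#' chi-squared scatter of a raw periodogram bin shrinks as 1/sqrt(n).
#'
#' @param psds non-empty list of \linkS4class{PSDEstimate}s on identical
#'   frequency grids.
#' @return A \linkS4class{PSDEstimate} with \code{nAveraged} summed.
#' @export
ensembleAverage <- function(psds) {
  if (!length(psds)) stop("empty list of PSDs")
  f0 <- psds[[1]]@freqs
  for (p in psds)
    if (!isTRUE(all.equal(p@freqs, f0, tolerance = 1e-12)))
      stop("mismatched frequency grids")
  pw <- Reduce(`+`, lapply(psds, function(p) p@power * p@nAveraged))
  n <- sum(vapply(psds, function(p) p@nAveraged, 1L))
  new("PSDEstimate", freqs = f0, power = pw / n, nAveraged = as.integer(n),
      binWidth = psds[[1]]@binWidth)
}

#' Log-log spectral slope
#'
#' Ordinary least squares of log10 P on log10 f over the band
#' [fLo, fHi]. Bins with non-positive power are excluded; at least 8 usable
#' bins are required. For a power-law (1/f^alpha) process the slope
#' estimates -alpha: -2 for a random walk, -1 for pure 1/f noise, 0 for
#' white noise.
#'
#' @param psd a \linkS4class{PSDEstimate}.
#' @param fLo,fHi band limits (Hz); defaults give one decade of margin at
#'   each end of the available grid.
#' @return named numeric c(slope, stderr).
#' @export
loglogSlope <- function(psd, fLo = 10 * psd@freqs[1],
                        fHi = max(psd@freqs) / 10) {
  sel <- psd@freqs >= fLo & psd@freqs <= fHi & psd@power > 0
  if (sum(sel) < 8)
    stop("fewer than 8 usable bins in [", fLo, ", ", fHi, "] Hz")
  x <- log10(psd@freqs[sel]); y <- log10(psd@power[sel])
  fit <- stats::lm.fit(cbind(1, x), y)
  r <- fit$residuals
  n <- length(x)
  s2 <- sum(r^2) / (n - 2)
  se <- sqrt(s2 / sum((x - mean(x))^2))
  c(slope = unname(fit$coefficients[2]), stderr = se)
}

#' Export a PSD as CSV
#'
#' Columns freq_hz, power, n_averaged, bin_width.
#'
#' @param psd a \linkS4class{PSDEstimate}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePSD <- function(psd, path) {
  utils::write.csv(data.frame(freq_hz = psd@freqs, power = psd@power,
                              n_averaged = psd@nAveraged,
                              bin_width = psd@binWidth),
                   path, row.names = FALSE)
  invisible(path)
}
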