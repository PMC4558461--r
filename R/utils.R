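# Small numerical utilities shared by the package and its tests.

#' Welch spectral density estimate
#'
#' One-sided power spectral density by averaging Hann-windowed, overlapping
#' segment periodograms; density units are power per Hz, so the integral
#' over 0 to Nyquist approximates the signal variance.
#'
#' @param x Time series (numeric vector).
#' @param fs Sampling rate (Hz).
#' @param seg_s Segment length in seconds (default 2).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param freq Optional frequency grid to interpolate the estimate onto.
#' @return A tibble with columns `frequency` and `density`.
#' @export
welch_psd <- function(x, fs, seg_s = 2, overlap = 0.5, freq = NULL) {
  nseg <- round(seg_s * fs)
  if (nseg > length(x)) stop("segment longer than the series", call. = FALSE)
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))
  U <- sum(win^2)
  m <- nseg %/% 2
  acc <- numeric(m)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1L)]
    seg <- (seg - mean(seg)) * win
    X <- fft(seg)
    acc <- acc + Mod(X[2:(m + 1)])^2
  }
  dens <- 2 * acc / (length(starts) * fs * U)
  fgrid <- (1:m) * fs / nseg
  if (!is.null(freq)) {
    dens <- stats::approx(fgrid, dens, xout = freq, rule = 2)$y
    fgrid <- freq
  }
  tibble::tibble(frequency = fgrid, density = dens)
}

# relative root-mean-square difference between two positive spectra
rel_rms <- function(a, b) {
  sqrt(mean(((a - b) / b)^2))
}

# resample by sharp FFT low-pass: keep bins up to the new Nyquist, invert
# on the shorter grid
fft_resample <- function(x, fs, fs_new) {
  n <- length(x)
  n2 <- round(n * fs_new / fs)
  X <- fft(x)
  keep <- floor(n2 / 2)
  Y <- complex(n2)
  Y[1:(keep + 1)] <- X[1:(keep + 1)]
  Y[(n2 - keep + 1):n2] <- X[(n - keep + 1):n]
  Re(fft(Y, inverse = TRUE)) / n
}
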