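# From EEG time series to the windowed, seizure-averaged spectral densities
# the model is fitted to: band-pass + notch filtering, window-length
# selection by a time-frequency stationarity criterion, autoregressive
# spectral estimation with a shrinkage prior, and onset-aligned averaging
# over seizures.

#' Band-pass and notch filtering of EEG
#'
#' Zero-phase 5th-order Butterworth band-pass between 0.5 and 70 Hz followed
#' by a 50 Hz notch (biquad, Q = 30). Multichannel input (one column per
#' channel) is re-referenced to the common average first.
#'
#' @param x Numeric vector, or matrix with one column per channel.
#' @param fs Sampling rate in Hz; must be at least 160 so the 70 Hz band
#'   edge is represented comfortably.
#' @param band Band-pass edges in Hz.
#' @param notch Notch frequency in Hz (`NULL` to skip).
#' @param notch_q Notch quality factor.
#' @return Filtered data, same shape as the input.
#' @export
eeg_preprocess <- function(x, fs, band = c(0.5, 70), notch = 50,
                           notch_q = 30) {
  if (fs < 160)
    stop("sampling rate must be >= 160 Hz for a 70 Hz band edge", call. = FALSE)
  mat <- is.matrix(x)
  xm <- if (mat) x else matrix(x, ncol = 1)
  if (ncol(xm) > 1) xm <- xm - rowMeans(xm)
  bp <- signal::butter(5, band / (fs / 2), type = "pass")
  out <- apply(xm, 2, function(col) {
    y <- signal::filtfilt(bp, col)
    if (!is.null(notch)) {
      nc <- notch_biquad(notch, fs, notch_q)
      y <- signal::filtfilt(signal::Arma(b = nc$b, a = nc$a), y)
    }
    y
  })
  if (mat) out else as.numeric(out)
}

# RBJ-cookbook biquad notch
notch_biquad <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  al <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + al, -2 * cos(w0), 1 - al)
  list(b = b / a[1], a = a / a[1])
}

# complex-Gaussian (Morlet-style) wavelet power via FFT convolution;
# returns a time x frequency matrix of |W(t,f)|^2 at the input rate
cgauss_wavelet_power <- function(x, fs, freqs, n_cycles = 3) {
  n <- length(x)
  nfft <- stats::nextn(2 * n, 2)
  X <- fft(c(x, rep(0, nfft - n)))
  fax <- (seq_len(nfft) - 1) / nfft * fs
  P <- matrix(0, n, length(freqs))
  for (j in seq_along(freqs)) {
    f0 <- freqs[j]
    sigma_t <- n_cycles / (2 * f0)
    sigma_f <- 1 / (2 * pi * sigma_t)
    # Gaussian frequency-domain window centred on f0 (analytic wavelet)
    Hf <- exp(-((fax - f0)^2) / (2 * sigma_f^2))
    w <- fft(X * Hf, inverse = TRUE) / nfft
    P[, j] <- Mod(w[seq_len(n)])^2
  }
  P
}

#' Select a spectral analysis window length
#'
#' Picks the longest window over which spectral activity is approximately
#' stationary: the largest candidate whose piecewise-constant (per-window)
#' approximation retains at least 90 percent of the energy of a
#' complex-Gaussian-wavelet time-frequency power estimate, averaged over the
#' recording. The wavelet power is pre-smoothed over each candidate length
#' so that estimator variance, rather than genuine nonstationarity, does not
#' dominate the criterion; edges are trimmed to the wavelet support.
#'
#' @param x Source time series (numeric vector).
#' @param fs Sampling rate (Hz).
#' @param candidates Candidate window durations in seconds, ascending;
#'   the default includes 2.0 s.
#' @param threshold Retained-energy threshold (default 0.9).
#' @return Chosen duration in seconds, with attribute `"retention"` giving
#'   the retained fraction per candidate. If no candidate reaches the
#'   threshold the smallest is returned with a warning.
#' @export
select_window_length <- function(x, fs, candidates = c(0.5, 1, 2, 4),
                                 threshold = 0.9) {
  if (is.unsorted(candidates)) stop("candidates must be ascending", call. = FALSE)
  freqs <- seq(2, 40, by = 2)
  P <- cgauss_wavelet_power(x, fs, freqs)
  # reduce to ~32 Hz frames
  dec <- max(1L, floor(fs / 32))
  nfr <- floor(nrow(P) / dec)
  Pd <- sapply(seq_len(ncol(P)), function(j)
    colMeans(matrix(P[seq_len(nfr * dec), j], nrow = dec)))
  fr_rate <- fs / dec
  retention <- vapply(candidates, function(L) {
    # smooth the power field at half the candidate length (taming estimator
    # variance while preserving sub-window structure), then measure the
    # energy fraction retained by its piecewise-constant window projection
    win <- max(1L, round(L * fr_rate))
    half <- max(1L, round(win / 2))
    sm <- stats::filter(Pd, rep(1 / half, half), sides = 2)
    trim <- ceiling((2.5 + L / 2) * fr_rate)
    sm <- sm[seq(trim, nrow(Pd) - trim), , drop = FALSE]
    sm <- sm[stats::complete.cases(sm), , drop = FALSE]
    nw <- floor(nrow(sm) / win)
    if (nw < 2) return(NA_real_)
    sm <- sm[seq_len(nw * win), , drop = FALSE]
    idx <- rep(seq_len(nw), each = win)
    num <- 0; den <- 0
    for (j in seq_len(ncol(sm))) {
      pj <- sm[, j]
      phat <- stats::ave(pj, idx)
      num <- num + sum(phat^2)
      den <- den + sum(pj^2)
    }
    num / den
  }, numeric(1))
  ok <- which(!is.na(retention) & retention >= threshold)
  if (length(ok) == 0) {
    warning("no candidate window retains ", threshold * 100,
            "% of the time-frequency power; returning the smallest")
    chosen <- candidates[1]
  } else {
    chosen <- candidates[max(ok)]
  }
  attr(chosen, "retention") <- stats::setNames(retention, candidates)
  chosen
}

#' Autoregressive spectral density of a segment
#'
#' Fits an AR(order) model by least squares with a Gaussian shrinkage
#' (ridge) prior on the coefficients (relative weight 1e-3) and evaluates
#' its one-sided spectral density on the frequency grid; the density
#' integrates to approximately the segment variance over 0 to Nyquist.
#' Unstable fits are stabilised by reflecting the offending roots with a
#' warning.
#'
#' @param x Segment (numeric vector, length at least `4 * order`).
#' @param fs Sampling rate (Hz).
#' @param order AR order (default 8).
#' @param freq Frequency grid (Hz).
#' @return Numeric vector of spectral density values on `freq`.
#' @export
ar_spectrum <- function(x, fs, order = 8, freq = frequency_grid()) {
  n <- length(x)
  if (n < 4 * order)
    stop("segment too short: need at least 4 x order samples", call. = FALSE)
  x <- x - mean(x)
  X <- stats::embed(x, order + 1)
  y <- X[, 1]
  Z <- X[, -1, drop = FALSE]
  G <- crossprod(Z)
  lam <- 1e-3 * mean(diag(G))
  b <- solve(G + lam * diag(order), crossprod(Z, y))
  # stationarity: roots of 1 - sum b_k z^k must lie outside the unit circle
  rts <- polyroot(c(1, -b))
  if (any(Mod(rts) <= 1)) {
    warning("unstable AR fit; reflecting roots outside the unit circle")
    bad <- Mod(rts) <= 1
    rts[bad] <- 1 / Conj(rts[bad])
    # rebuild 1 - sum b_k z^k from its roots
    co <- 1
    for (r in rts) co <- c(co, 0) - c(0, co) / r
    co <- Re(co / co[1])
    b <- -co[-1]
  }
  sigma2 <- mean((y - Z %*% b)^2)
  ek <- exp(-2i * pi * outer(freq / fs, seq_len(order)))
  dens <- 2 * sigma2 / fs / Mod(1 - ek %*% b)^2  # one-sided AR density
  as.numeric(dens)
}

new_spectral_data <- function(S, freq, window_s, n_seizures, n_avg = NULL,
                              onset_index = 1L) {
  S <- as.matrix(S)
  if (any(S < 0)) stop("spectral densities must be non-negative", call. = FALSE)
  structure(list(S = S, freq = freq, window_s = window_s,
                 n_seizures = n_seizures,
                 n_avg = n_avg %||% rep(n_seizures, nrow(S)),
                 onset_index = onset_index),
            class = "spectral_data")
}

#' @export
print.spectral_data <- function(x, ...) {
  cat(sprintf(
    "<spectral_data> %d windows x %d frequencies (%.3g-%.3g Hz), %.3g s windows, %d seizure(s) averaged\n",
    nrow(x$S), ncol(x$S), min(x$freq), max(x$freq), x$window_s, x$n_seizures))
  invisible(x)
}

#' @export
#' @importFrom tibble as_tibble
as_tibble.spectral_data <- function(x, ...) {
  tibble::tibble(
    window = rep(seq_len(nrow(x$S)), each = length(x$freq)),
    time_s = rep((seq_len(nrow(x$S)) - 0.5) * x$window_s, each = length(x$freq)),
    frequency = rep(x$freq, nrow(x$S)),
    density = c(t(x$S))
  )
}

#' Windowed, seizure-averaged spectral data
#'
#' The full preprocessing-to-features path: each seizure is filtered, cut
#' into non-overlapping windows from its onset, each window reduced to an
#' AR spectral density, and densities averaged across seizures per
#' onset-aligned window index. Trailing partial windows are discarded;
#' window indices beyond the shortest seizure are averaged over the subset
#' of seizures that reach them (the count is recorded).
#'
#' Low-order autoregressive fits at a high sampling rate spread spectral
#' mass far beyond the modelled band and bias the in-band density downward,
#' so each seizure is resampled (sharp FFT low-pass) to 2.5 times the
#' band's upper edge before AR estimation.
#'
#' @param seizures A list of single-channel seizure time series (numeric
#'   vectors), or a single vector.
#' @param fs Sampling rate (Hz).
#' @param onsets Optional seizure onset times in seconds (one per seizure);
#'   data before the onset is dropped. Default: the series start at onset.
#' @param window_s Window duration in seconds (default 2).
#' @param freq Frequency grid (Hz).
#' @param ar_order AR order for spectral estimation (default 12 at the
#'   decimated rate).
#' @param preprocess Apply [eeg_preprocess()] first (default TRUE).
#' @return A `spectral_data` object.
#' @export
build_spectral_data <- function(seizures, fs, onsets = NULL, window_s = 2,
                                freq = frequency_grid(), ar_order = 12,
                                preprocess = TRUE) {
  if (is.numeric(seizures)) seizures <- list(seizures)
  if (length(seizures) < 1) stop("need at least one seizure", call. = FALSE)
  if (!is.null(onsets) && length(onsets) != length(seizures))
    stop("one onset per seizure required", call. = FALSE)
  # resample (sharp FFT low-pass) to ~2.5x the band's upper edge so the
  # all-pole fit spends its poles inside the modelled band
  fs_ar <- min(fs, 2.5 * max(freq))
  nwin_samp <- round(window_s * fs_ar)
  per_seizure <- purrr::imap(seizures, function(x, i) {
    if (!is.null(onsets)) x <- x[-seq_len(min(length(x), round(onsets[i] * fs)))]
    if (preprocess) x <- eeg_preprocess(x, fs)
    if (fs_ar < fs) x <- fft_resample(x, fs, fs_ar)
    nw <- floor(length(x) / nwin_samp)
    if (nw < 1) return(NULL)
    t(vapply(seq_len(nw), function(w) {
      seg <- x[((w - 1) * nwin_samp + 1):(w * nwin_samp)]
      ar_spectrum(seg, fs_ar, order = ar_order, freq = freq)
    }, numeric(length(freq))))
  })
  per_seizure <- purrr::compact(per_seizure)
  if (length(per_seizure) == 0)
    stop("no complete windows after windowing", call. = FALSE)
  W <- max(purrr::map_int(per_seizure, nrow))
  S <- matrix(0, W, length(freq))
  n_avg <- integer(W)
  for (sz in per_seizure) {
    for (w in seq_len(nrow(sz))) {
      S[w, ] <- S[w, ] + sz[w, ]
      n_avg[w] <- n_avg[w] + 1L
    }
  }
  S <- S / n_avg
  new_spectral_data(S, freq, window_s, length(per_seizure), n_avg = n_avg)
}
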