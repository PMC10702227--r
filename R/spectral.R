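#' Downsample a signal to the 1 kHz analysis rate
#'
#' Applies an anti-alias zero-phase Butterworth low-pass (cutoff 450 Hz)
#' before resampling. Signals already at 1 kHz are returned unchanged.
#'
#' @param x Numeric vector, or a channels x samples matrix.
#' @param rate Input sample rate in Hz (must be >= 1000).
#' @return The signal at 1000 Hz (same shape class as the input).
#' @export
downsample_to_1khz <- function(x, rate) {
  if (rate < 1000) stop("input rate must be >= 1000 Hz", call. = FALSE)
  if (rate == 1000) return(x)
  if (is.matrix(x)) {
    out <- t(apply(x, 1, downsample_to_1khz, rate = rate))
    return(out)
  }
  bf <- signal::butter(6, 450 / (rate / 2), type = "low")
  xf <- signal::filtfilt(bf, x)
  if (rate %% 1000 == 0) {
    xf[seq(1, length(xf), by = rate / 1000)]
  } else {
    t_in <- (seq_along(xf) - 1) / rate
    t_out <- seq(0, t_in[length(t_in)], by = 1e-3)
    approx(t_in, xf, xout = t_out)$y
  }
}

# Welch PSD of one channel, one estimate per non-overlapping bin of bin_s
# seconds, from 50%-overlapping Hann segments of seg_s seconds.
# Returns bins x freqs matrix (one-sided density, power per Hz).
welch_one_channel <- function(x, fs, bin_s, seg_s, keep) {
  seg <- round(seg_s * fs)
  bin_len <- round(bin_s * fs)
  hop <- seg %/% 2
  if (bin_len < seg) stop("bin shorter than one Welch segment", call. = FALSE)
  n_bins <- floor(length(x) / bin_len)
  if (n_bins < 1) stop("need at least one full bin of samples", call. = FALSE)
  n_per <- (bin_len - seg) %/% hop + 1
  w <- hann(seg)
  U <- sum(w^2)
  nf <- seg %/% 2 + 1
  scale <- 1 / (fs * U)
  out <- matrix(0, n_bins, sum(keep))
  chunk <- max(1L, 2^21 %/% bin_len)
  seg_starts <- (seq_len(n_per) - 1) * hop
  for (b0 in seq(1L, n_bins, by = chunk)) {
    b1 <- min(n_bins, b0 + chunk - 1L)
    nb <- b1 - b0 + 1L
    starts <- rep((b0:b1 - 1) * bin_len, each = n_per) +
      rep(seg_starts, times = nb)
    idx <- outer(seq_len(seg), starts, `+`)
    S <- matrix(x[idx], nrow = seg) * w
    P <- Mod(stats::mvfft(S))^2 * scale
    P <- P[seq_len(nf), , drop = FALSE]
    if (nf > 2) P[2:(nf - 1), ] <- 2 * P[2:(nf - 1), ]
    Pk <- P[keep, , drop = FALSE]
    out[b0:b1, ] <- rowsum(t(Pk), group = rep(seq_len(nb), each = n_per)) / n_per
  }
  out
}

#' Per-bin Welch power spectral density
#'
#' Splits each channel into non-overlapping bins (default 8 s) and computes a
#' Welch density estimate per bin from 2-s Hann segments with 50% overlap
#' (7 segments per 8-s bin). By default only the 0-50 Hz range used by the
#' state classifier is retained (0.5 Hz grid, 101 points).
#'
#' @param lfp Numeric vector or channels x samples matrix at 1 kHz.
#' @param fs Sample rate, Hz (default 1000).
#' @param bin_s Bin length in seconds (default 8).
#' @param seg_s Welch segment length in seconds (default 2).
#' @param max_freq Highest frequency retained, Hz; `NULL` keeps everything up
#'   to Nyquist.
#' @return A `spectral_estimate`: list with `freqs` (Hz) and `psd`, a
#'   channels x bins x freqs array of one-sided densities.
#' @export
welch_psd_bins <- function(lfp, fs = 1000, bin_s = 8, seg_s = 2,
                           max_freq = 50) {
  if (!is.matrix(lfp)) lfp <- matrix(lfp, nrow = 1)
  seg <- round(seg_s * fs)
  freqs <- (0:(seg %/% 2)) * fs / seg
  keep <- if (is.null(max_freq)) rep(TRUE, length(freqs)) else freqs <= max_freq
  freqs <- freqs[keep]
  per_ch <- lapply(seq_len(nrow(lfp)), function(ch) {
    welch_one_channel(lfp[ch, ], fs, bin_s, seg_s, keep)
  })
  psd <- array(0, c(nrow(lfp), nrow(per_ch[[1]]), length(freqs)))
  for (ch in seq_along(per_ch)) psd[ch, , ] <- per_ch[[ch]]
  structure(list(freqs = freqs, psd = psd, fs = fs, bin_s = bin_s),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat("<spectral_estimate> ", dim(x$psd)[1], " channel(s) x ", dim(x$psd)[2],
      " bins x ", length(x$freqs), " freqs (", min(x$freqs), "-",
      max(x$freqs), " Hz)\n", sep = "")
  invisible(x)
}

# Core of the classifier feature construction, operating on a bins x freqs
# matrix of channel-averaged densities.
normalize_feature_matrix <- function(M, freqs) {
  mins <- apply(M, 1, min)
  M0 <- M - mins
  ints <- apply(M0, 1, function(v) trapz(freqs, v))
  if (any(ints <= 0)) {
    stop("degenerate (all-constant) PSD bin: cannot normalize", call. = FALSE)
  }
  M0 / ints
}

#' Normalized mean-PSD feature vectors
#'
#' Averages the per-bin Welch density across channels, then normalizes each
#' bin by subtracting its minimum and dividing by the trapezoidal integral
#' over frequency, so that relative rather than absolute power drives the
#' classifier. Every output bin has minimum 0 and integral 1.
#'
#' @param estimate A `spectral_estimate` from [welch_psd_bins()].
#' @return A `somn_features` object: list with `freqs` and `X`
#'   (bins x freqs matrix of normalized features).
#' @export
normalize_mean_psd <- function(estimate) {
  stopifnot(inherits(estimate, "spectral_estimate"))
  M <- apply(estimate$psd, c(2, 3), mean)
  structure(
    list(freqs = estimate$freqs,
         X = normalize_feature_matrix(M, estimate$freqs),
         bin_s = estimate$bin_s),
    class = "somn_features"
  )
}

#' @export
print.somn_features <- function(x, ...) {
  cat("<somn_features> ", nrow(x$X), " bins x ", length(x$freqs),
      " frequencies (", min(x$freqs), "-", max(x$freqs), " Hz)\n", sep = "")
  invisible(x)
}

#' @method tidy somn_features
#' @export
tidy.somn_features <- function(x, ...) {
  tibble::tibble(
    bin = rep(seq_len(nrow(x$X)), each = length(x$freqs)),
    freq = rep(x$freqs, times = nrow(x$X)),
    power = as.vector(t(x$X))
  )
}

# Shared segmentation for coherence/wPLI: cross- and auto-spectra of
# 50%-overlapping Hann segments drawn from contiguous same-state stretches.
cross_spectra_segments <- function(x, y, fs, state_mask, seg_s, max_freq) {
  stopifnot(length(x) == length(y))
  if (is.null(state_mask)) state_mask <- rep(TRUE, length(x))
  seg <- round(seg_s * fs)
  hop <- seg %/% 2
  r <- rle(state_mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values & r$lengths >= seg)
  seg_starts <- unlist(lapply(runs, function(i) {
    seq(starts[i], ends[i] - seg + 1, by = hop)
  }), use.names = FALSE)
  if (length(seg_starts) < 2) {
    stop("need at least 2 segments of contiguous in-state data (",
         seg_s, " s each)", call. = FALSE)
  }
  w <- hann(seg)
  freqs <- (0:(seg %/% 2)) * fs / seg
  keep <- freqs <= max_freq
  nf <- sum(keep)
  acc <- list(Sxy = complex(nf), absIm = numeric(nf),
              Pxx = numeric(nf), Pyy = numeric(nf))
  rows <- which(keep) # rows of the full FFT matrix to retain
  # accumulate in chunks of segments to bound memory on long recordings
  for (s0 in seq(1L, length(seg_starts), by = 256L)) {
    ss <- seg_starts[s0:min(length(seg_starts), s0 + 255L)]
    idx <- outer(seq_len(seg) - 1L, ss, `+`)
    X <- stats::mvfft(matrix(x[idx], nrow = seg) * w)[rows, , drop = FALSE]
    Y <- stats::mvfft(matrix(y[idx], nrow = seg) * w)[rows, , drop = FALSE]
    Sxy <- X * Conj(Y)
    acc$Sxy <- acc$Sxy + rowSums(Sxy)
    acc$absIm <- acc$absIm + rowSums(abs(Im(Sxy)))
    acc$Pxx <- acc$Pxx + rowSums(Mod(X)^2)
    acc$Pyy <- acc$Pyy + rowSums(Mod(Y)^2)
  }
  ns <- length(seg_starts)
  list(
    freqs = freqs[keep],
    mean_Sxy = acc$Sxy / ns,
    mean_absIm = acc$absIm / ns,
    mean_Pxx = acc$Pxx / ns,
    mean_Pyy = acc$Pyy / ns,
    n_segments = ns
  )
}

#' Magnitude-squared coherence between two channels
#'
#' Welch-averaged coherence `|Pxy|^2 / (Pxx * Pyy)` on a 0.1 Hz grid (10-s
#' Hann segments, 50% overlap), restricted to contiguous stretches where
#' `state_mask` is TRUE.
#'
#' @param x,y Numeric vectors at `fs` Hz.
#' @param fs Sample rate in Hz.
#' @param state_mask Logical vector (same length); `NULL` uses everything.
#' @param seg_s Segment length in seconds (10 gives the 0.1 Hz grid).
#' @param max_freq Highest frequency retained, Hz.
#' @return A tibble with `freq`, `coherence` and `n_segments`.
#' @export
magnitude_squared_coherence <- function(x, y, fs = 1000, state_mask = NULL,
                                        seg_s = 10, max_freq = 120) {
  cs <- cross_spectra_segments(x, y, fs, state_mask, seg_s, max_freq)
  cxy <- Mod(cs$mean_Sxy)^2 / (cs$mean_Pxx * cs$mean_Pyy)
  tibble::tibble(freq = cs$freqs, coherence = pmin(cxy, 1),
                 n_segments = cs$n_segments)
}

#' Weighted phase lag index between two channels
#'
#' wPLI = |mean(Im Sxy)| / mean(|Im Sxy|) over Welch segments; it discounts
#' zero-lag (volume-conducted) coupling, which has a purely real
#' cross-spectrum. Frequencies where all imaginary parts vanish get 0.
#'
#' @inheritParams magnitude_squared_coherence
#' @return A tibble with `freq`, `wpli` and `n_segments`.
#' @export
weighted_phase_lag_index <- function(x, y, fs = 1000, state_mask = NULL,
                                     seg_s = 10, max_freq = 120) {
  cs <- cross_spectra_segments(x, y, fs, state_mask, seg_s, max_freq)
  num <- abs(Im(cs$mean_Sxy))
  den <- cs$mean_absIm
  # an imaginary part at rounding-noise level (zero-lag mixtures) counts as 0
  floor_im <- 1e-10 * sqrt(pmax(cs$mean_Pxx * cs$mean_Pyy, 0))
  wpli <- ifelse(den > floor_im, num / den, 0)
  tibble::tibble(freq = cs$freqs, wpli = wpli, n_segments = cs$n_segments)
}
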