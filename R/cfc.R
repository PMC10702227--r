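#' Zero-phase Butterworth band-pass filter
#'
#' Second-order Butterworth applied forward and backward (zero phase lag,
#' fourth-order effective magnitude response).
#'
#' @param x Numeric vector.
#' @param band A canonical band name (see [canonical_bands()]) or a numeric
#'   `c(lo, hi)` in Hz.
#' @param fs Sample rate, Hz.
#' @return Filtered numeric vector, same length.
#' @export
bandpass_filter <- function(x, band, fs = 1000) {
  if (is.character(band)) {
    e <- band_edges(band)
    band <- c(e$lo, e$hi)
  }
  if (band[2] >= fs / 2) {
    stop("band edge ", band[2], " Hz is at or above Nyquist (", fs / 2, " Hz)",
         call. = FALSE)
  }
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Analytic signal via the Hilbert transform
#'
#' Instantaneous phase and amplitude of a band-limited signal. Phase is
#' wrapped to \[0, 2 pi) with 0 at the oscillation peak and pi at the trough
#' (cosine convention). The first and last second are filter/edge transients;
#' downstream statistics exclude them via `edge_mask()`.
#'
#' @param x Band-pass filtered numeric vector.
#' @param fs Sample rate, Hz.
#' @return An `analytic_series`: list with `phase`, `amplitude`, `fs`.
#' @export
analytic_signal <- function(x, fs = 1000) {
  if (!all(is.finite(x))) stop("signal must be finite", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("constant signal has undefined instantaneous phase", call. = FALSE)
  }
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(stats::fft(x) * h, inverse = TRUE) / n
  structure(list(phase = wrap_2pi(Arg(z)), amplitude = Mod(z), fs = fs),
            class = "analytic_series")
}

#' @export
print.analytic_series <- function(x, ...) {
  cat("<analytic_series> ", length(x$phase), " samples @ ", x$fs, " Hz\n",
      sep = "")
  invisible(x)
}

#' Mask excluding filter edge transients
#'
#' @param n Signal length in samples.
#' @param fs Sample rate, Hz.
#' @param edge_s Seconds excluded at each end (default 1).
#' @return Logical vector of length `n`.
#' @export
edge_mask <- function(n, fs = 1000, edge_s = 1) {
  m <- rep(TRUE, n)
  k <- min(n, round(edge_s * fs))
  if (k > 0) {
    m[seq_len(k)] <- FALSE
    m[n - seq_len(k) + 1] <- FALSE
  }
  m
}

# Density-rank amplitude reassignment behind the max-MVL normalization:
# phases are histogrammed into n_bins equal bins; samples in denser phase
# bins receive the larger amplitudes, giving (near-)maximal |mean(r e^{i phi})|
# attainable by re-pairing the observed amplitudes with the observed phases.
max_mvl_pairing <- function(phase, amp, n_bins = 64) {
  bin <- pmin(n_bins, floor(phase / (2 * pi) * n_bins) + 1L)
  counts <- tabulate(bin, nbins = n_bins)
  bin_rank <- match(seq_len(n_bins), order(counts, decreasing = TRUE))
  ord <- order(bin_rank[bin])
  r_new <- numeric(length(amp))
  r_new[ord] <- sort(amp, decreasing = TRUE)
  Mod(mean(r_new * exp(1i * phase)))
}

#' Phase-amplitude coupling strength (normalized mean vector length)
#'
#' Computes the mean vector length `MVL = |mean(r exp(i phi))|` between a low
#' band's instantaneous phase and a high band's instantaneous amplitude over
#' the selected samples, the maximum MVL attainable by re-pairing the highest
#' amplitudes with the most common phases, and their ratio `nmvl` in \[0, 1\]
#' (gain-invariant coupling strength). `mean_phase` is the argument of the
#' mean vector.
#'
#' @param low_phase Phase series (radians) of the low band.
#' @param high_amp Amplitude series of the high band (same length).
#' @param state_mask Optional logical vector selecting in-state samples.
#' @param n_bins Phase bins used by the max-MVL pairing (default 64).
#' @return A one-row tibble: `mvl`, `max_mvl`, `nmvl`, `mean_phase`, `n`,
#'   and `clamped` (TRUE when the heuristic max-MVL undershot the observed
#'   MVL and the ratio was clamped to 1).
#' @export
coupling_estimate <- function(low_phase, high_amp, state_mask = NULL,
                              n_bins = 64) {
  stopifnot(length(low_phase) == length(high_amp))
  if (!is.null(state_mask)) {
    low_phase <- low_phase[state_mask]
    high_amp <- high_amp[state_mask]
  }
  if (!length(low_phase)) stop("no in-state samples", call. = FALSE)
  mv <- mean(high_amp * exp(1i * low_phase))
  mvl <- Mod(mv)
  max_mvl <- max_mvl_pairing(low_phase, high_amp, n_bins)
  # a vanishing max-MVL (e.g. constant amplitude with perfectly uniform
  # phases) means no coupling is expressible: define nmvl = 0
  nmvl <- if (max_mvl > mean(high_amp) * 1e-10) mvl / max_mvl else 0
  # the density-rank pairing is a heuristic: with a near-uniform phase
  # histogram it can undershoot the observed MVL, in which case nmvl is
  # clamped to 1 and the record flagged
  clamped <- nmvl > 1
  if (clamped) nmvl <- 1
  tibble::tibble(mvl = mvl, max_mvl = max_mvl, nmvl = nmvl,
                 mean_phase = wrap_2pi(Arg(mv)), n = length(low_phase),
                 clamped = clamped)
}

#' Phase-binned high-frequency power map
#'
#' Mean high-band power per low-band phase bin, expressed per row
#' (frequency/band) as a z-score relative to that row's power distribution:
#' `z_b = (mean(power | phase bin b) - mean(power)) / sd(power)`. Uncoupled
#' signals give |z| near zero (sampling noise only); coupling concentrates
#' power at the preferred phase with |z| of order one.
#'
#' @param low_phase Phase series (radians).
#' @param high_power Numeric vector, or rows x samples matrix (one row per
#'   frequency/band).
#' @param n_phase_bins Number of phase bins (default 36).
#' @param state_mask Optional logical sample mask.
#' @return A rows x phase-bins matrix of z-scores with attribute
#'   `phase_centers`; empty phase bins yield NA.
#' @export
phase_power_map <- function(low_phase, high_power, n_phase_bins = 36,
                            state_mask = NULL) {
  if (!is.matrix(high_power)) high_power <- matrix(high_power, nrow = 1)
  stopifnot(ncol(high_power) == length(low_phase))
  if (!is.null(state_mask)) {
    low_phase <- low_phase[state_mask]
    high_power <- high_power[, state_mask, drop = FALSE]
  }
  bin <- pmin(n_phase_bins, floor(low_phase / (2 * pi) * n_phase_bins) + 1L)
  out <- matrix(NA_real_, nrow(high_power), n_phase_bins)
  for (b in seq_len(n_phase_bins)) {
    sel <- bin == b
    if (any(sel)) out[, b] <- rowMeans(high_power[, sel, drop = FALSE])
  }
  mu <- rowMeans(high_power)
  sds <- apply(high_power, 1, stats::sd)
  z <- (out - mu) / ifelse(sds > 0, sds, NA_real_)
  attr(z, "phase_centers") <- (seq_len(n_phase_bins) - 0.5) * 2 * pi / n_phase_bins
  z
}

#' Band pairs for phase-amplitude coupling
#'
#' All ordered pairs of canonical bands with the low band's center frequency
#' below the high band's.
#'
#' @return A tibble with `low_band` and `high_band` (15 rows).
#' @export
coupling_band_pairs <- function() {
  b <- canonical_bands()
  ctr <- (b$lo + b$hi) / 2
  grid <- expand.grid(low = seq_len(nrow(b)), high = seq_len(nrow(b)))
  grid <- grid[ctr[grid$low] < ctr[grid$high], ]
  tibble::tibble(low_band = b$band[grid$low], high_band = b$band[grid$high])
}

#' State-wise phase-amplitude coupling across a session
#'
#' Filters each channel into the six canonical bands, extracts analytic
#' phase/amplitude, and computes [coupling_estimate()] for every
#' low-center < high-center band pair in every state, per channel. One-second
#' edge transients are excluded.
#'
#' @param lfp Channels x samples matrix at `fs` Hz.
#' @param states Per-bin state labels (tibble with `state` or character).
#' @param fs Sample rate, Hz.
#' @param bin_s Bin length in seconds.
#' @param pairs Tibble of band pairs (default [coupling_band_pairs()]).
#' @param n_bins Phase bins for the max-MVL pairing.
#' @return A tibble: `channel`, `state`, `low_band`, `high_band`, `mvl`,
#'   `max_mvl`, `nmvl`, `mean_phase`, `n`.
#' @export
session_coupling <- function(lfp, states, fs = 1000, bin_s = 8,
                             pairs = coupling_band_pairs(), n_bins = 64) {
  if (!is.matrix(lfp)) lfp <- matrix(lfp, nrow = 1)
  st <- states_vec(states)
  bin_len <- round(bin_s * fs)
  st_samples <- rep(st, each = bin_len)[seq_len(ncol(lfp))]
  edge <- edge_mask(ncol(lfp), fs)
  bands_needed <- unique(c(pairs$low_band, pairs$high_band))
  out <- list()
  for (ch in seq_len(nrow(lfp))) {
    an <- lapply(setNames(bands_needed, bands_needed), function(b) {
      analytic_signal(bandpass_filter(lfp[ch, ], b, fs = fs), fs = fs)
    })
    for (s in intersect(state_levels(), unique(st))) {
      mask <- st_samples == s & edge
      if (!any(mask)) next
      for (p in seq_len(nrow(pairs))) {
        est <- coupling_estimate(an[[pairs$low_band[p]]]$phase,
                                 an[[pairs$high_band[p]]]$amplitude,
                                 state_mask = mask, n_bins = n_bins)
        out[[length(out) + 1]] <- dplyr::bind_cols(
          tibble::tibble(channel = ch, state = s,
                         low_band = pairs$low_band[p],
                         high_band = pairs$high_band[p]),
          est
        )
      }
    }
  }
  dplyr::bind_rows(out)
}
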