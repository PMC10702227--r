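#' Two-window spike discriminator settings
#'
#' @param threshold Negative trigger threshold (same units as the filtered
#'   trace).
#' @param window1,window2 Each `c(delay_ms, min, max)`: the trace must pass
#'   through the amplitude window \[min, max\] at `delay_ms` after the
#'   threshold crossing. Delays must be positive and increasing.
#' @param filter_band Discrimination band-pass in Hz (first-order
#'   Butterworth), default 1000-2000.
#' @return A `discriminator_spec`.
#' @export
discriminator_spec <- function(threshold, window1, window2,
                               filter_band = c(1000, 2000)) {
  if (threshold >= 0) stop("threshold must be negative", call. = FALSE)
  if (window1[1] <= 0 || window2[1] <= window1[1]) {
    stop("window delays must be positive and ordered", call. = FALSE)
  }
  structure(list(threshold = threshold, window1 = window1, window2 = window2,
                 filter_band = filter_band),
            class = "discriminator_spec")
}

#' Detect spikes by two-window discrimination
#'
#' Band-pass filters the wideband trace (first-order Butterworth), finds
#' negative-going threshold crossings, and accepts a spike when the filtered
#' trace passes through both time-delayed amplitude windows. A 1-ms lockout
#' follows each accepted spike so multiphasic waveforms are not
#' double-counted.
#'
#' @param wideband Numeric vector at `wb_rate` Hz (>= 10 kHz).
#' @param spec A [discriminator_spec()].
#' @param wb_rate Sample rate of the wideband trace, Hz.
#' @param snippet_ms `c(pre, post)` snippet extent around the crossing, ms.
#' @return List with `times` (s) and `waveforms` (spikes x samples matrix of
#'   filtered-trace snippets, 1 ms before to 2 ms after the crossing).
#' @export
window_discriminate <- function(wideband, spec, wb_rate = 20000,
                                snippet_ms = c(1, 2)) {
  stopifnot(inherits(spec, "discriminator_spec"))
  if (wb_rate < 10000) stop("wideband rate must be >= 10 kHz", call. = FALSE)
  d1 <- round(spec$window1[1] * wb_rate / 1000)
  d2 <- round(spec$window2[1] * wb_rate / 1000)
  post <- round(snippet_ms[2] * wb_rate / 1000)
  pre <- round(snippet_ms[1] * wb_rate / 1000)
  if (d2 > post) stop("window delays fall outside the snippet span", call. = FALSE)
  bf <- signal::butter(1, spec$filter_band / (wb_rate / 2), type = "pass")
  xf <- signal::filter(bf, wideband)
  xf <- as.numeric(xf)
  n <- length(xf)
  cross <- which(xf[-1] <= spec$threshold & xf[-n] > spec$threshold) + 1L
  cross <- cross[cross > pre & cross + post <= n]
  lockout <- round(1e-3 * wb_rate)
  times <- integer(0)
  last <- -Inf
  for (i in cross) {
    if (i - last < lockout) next
    a1 <- xf[i + d1]
    a2 <- xf[i + d2]
    if (a1 >= spec$window1[2] && a1 <= spec$window1[3] &&
        a2 >= spec$window2[2] && a2 <= spec$window2[3]) {
      times <- c(times, i)
      last <- i
    }
  }
  wf <- if (length(times)) {
    t(vapply(times, function(i) xf[(i - pre):(i + post)],
             numeric(pre + post + 1)))
  } else {
    matrix(0, 0, pre + post + 1)
  }
  list(times = (times - 1) / wb_rate, waveforms = wf)
}

#' Coefficient of determination between two spike waveforms
#'
#' `CoD = 1 - sum((a - b)^2) / sum((a - mean(a))^2)`; equal waveforms give 1,
#' and a flat comparison at `mean(a)` gives 0. Asymmetric in its arguments by
#' construction (`w_a` is the reference).
#'
#' @param w_a,w_b Equal-length numeric waveforms.
#' @return Scalar CoD (unbounded below, at most 1).
#' @export
coefficient_of_determination <- function(w_a, w_b) {
  stopifnot(length(w_a) == length(w_b))
  den <- sum((w_a - mean(w_a))^2)
  if (den == 0) stop("reference waveform has zero variance", call. = FALSE)
  1 - sum((w_a - w_b)^2) / den
}

# Pairwise CoD over sampled (row_a, row_b) index pairs.
pairwise_cod <- function(A, B, n_pairs, seed) {
  with_seed(seed, {
    ia <- sample.int(nrow(A), n_pairs, replace = TRUE)
    ib <- sample.int(nrow(B), n_pairs, replace = TRUE)
  })
  Aa <- A[ia, , drop = FALSE]
  Bb <- B[ib, , drop = FALSE]
  den <- rowSums((Aa - rowMeans(Aa))^2)
  ok <- den > 0
  (1 - rowSums((Aa - Bb)^2) / den)[ok]
}

#' Overnight waveform stability test
#'
#' Compares the distribution of pairwise CoD between a unit's first and last
#' waveforms against the CoD between the unit's first waveforms and a
#' different unit's last waveforms. The unit is stable when the same-unit
#' distribution is significantly higher (one-sided Wilcoxon rank-sum,
#' p < 0.05) and its median exceeds the cross-unit median.
#'
#' @param first_wf,last_wf Waveform matrices (rows = spikes) of the unit,
#'   typically the first and last 1,000 detections.
#' @param other_last_wf Last waveforms of a different, randomly chosen unit.
#' @param seed Integer seed for pair subsampling.
#' @param n_pairs Number of sampled CoD pairs per distribution (default 1e4).
#' @param alpha Significance level (default 0.05).
#' @return List with `stable` (logical), `p_value`, `median_same`,
#'   `median_cross`.
#' @export
waveform_stability_test <- function(first_wf, last_wf, other_last_wf,
                                    seed = 1L, n_pairs = 1e4, alpha = 0.05) {
  if (nrow(first_wf) < 100 || nrow(last_wf) < 100 || nrow(other_last_wf) < 100) {
    stop("need at least 100 waveforms per set", call. = FALSE)
  }
  same <- pairwise_cod(first_wf, last_wf, n_pairs, sub_seed(seed, 1L))
  cross <- pairwise_cod(first_wf, other_last_wf, n_pairs, sub_seed(seed, 2L))
  if (!length(same) || !length(cross) ||
      (stats::sd(same) == 0 && stats::sd(cross) == 0 &&
       same[1] == cross[1])) {
    stop("degenerate CoD distributions", call. = FALSE)
  }
  wt <- suppressWarnings(wilcox.test(same, cross, alternative = "greater"))
  list(
    stable = median(same) > median(cross) && wt$p.value < alpha,
    p_value = wt$p.value,
    median_same = median(same),
    median_cross = median(cross)
  )
}

#' ISI histogram, mode and RS/FS classification
#'
#' Inter-spike-interval histogram on 1-ms bins over 0-500 ms, smoothed with
#' a 3-bin moving average; the mode location classifies the unit: fast
#' spiking (FS) when the peak falls before 10 ms, regular spiking (RS)
#' otherwise.
#'
#' @param spike_times Sorted spike times in seconds.
#' @param max_ms Histogram support in ms (default 500).
#' @return List with `histogram` (tibble: `isi_ms` bin centers, `count`,
#'   `smoothed`), `isi_peak_ms` and `unit_class`.
#' @export
isi_profile <- function(spike_times, max_ms = 500) {
  if (length(spike_times) < 2) stop("need at least 2 spikes", call. = FALSE)
  isi <- diff(spike_times) * 1000
  counts <- tabulate(pmin(max_ms, floor(isi) + 1L), nbins = max_ms)
  sm <- as.numeric(stats::filter(counts, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- counts[is.na(sm)]
  peak_bin <- which.max(sm)
  isi_peak_ms <- peak_bin - 0.5
  tibble_h <- tibble::tibble(isi_ms = seq_len(max_ms) - 0.5, count = counts,
                             smoothed = sm)
  list(histogram = tibble_h, isi_peak_ms = isi_peak_ms,
       unit_class = if (isi_peak_ms < 10) "FS" else "RS")
}

# Per-state normalized ISI density on 1-ms bins; ISIs are attributed to the
# state of the bin containing the leading spike.
state_isi_density <- function(spike_times, st, bin_s, max_ms) {
  lead_bin <- pmin(length(st), floor(spike_times[-length(spike_times)] / bin_s) + 1L)
  isi <- diff(spike_times) * 1000
  lapply(setNames(state_levels(), state_levels()), function(s) {
    x <- isi[st[lead_bin] == s & isi < max_ms]
    if (!length(x)) return(NULL)
    counts <- tabulate(floor(x) + 1L, nbins = max_ms)
    counts / sum(counts)
  })
}

#' State-wise ISI distribution contrast against Move
#'
#' Per-state normalized ISI distribution minus the Move distribution, on the
#' 1-ms time axis and remapped to a frequency axis (f = 1000/ISI, density
#' transformed with the Jacobian 1000/f^2 and interpolated onto a 0.5 Hz
#' grid).
#'
#' @param spike_times Sorted spike times in seconds.
#' @param states Per-bin state labels (tibble or character vector).
#' @param bin_s Bin length in seconds.
#' @param max_ms ISI support in ms.
#' @param max_freq Upper edge of the frequency grid in Hz.
#' @return Tibble: `state`, `axis` ("time" or "frequency"), `x` (ms or Hz),
#'   `delta` (density difference from Move). States without spikes are
#'   omitted (flagged in the `missing_states` attribute).
#' @export
isi_state_contrast <- function(spike_times, states, bin_s = 8, max_ms = 500,
                               max_freq = 100) {
  st <- states_vec(states)
  dens <- state_isi_density(spike_times, st, bin_s, max_ms)
  if (is.null(dens$Move)) stop("no Move spikes to contrast against", call. = FALSE)
  isi_centers <- seq_len(max_ms) - 0.5
  fgrid <- seq(0.5, max_freq, by = 0.5)
  to_freq <- function(p) {
    # density over f: p_f(f) = p_t(1000/f) * 1000 / f^2
    approx(x = 1000 / isi_centers, y = p * 1000 / (1000 / isi_centers)^2 * 1000,
           xout = fgrid, rule = 2)$y
  }
  out <- list()
  missing <- character(0)
  for (s in setdiff(state_levels(), "Move")) {
    if (is.null(dens[[s]])) {
      missing <- c(missing, s)
      next
    }
    dt <- dens[[s]] - dens$Move
    out[[length(out) + 1]] <- tibble::tibble(state = s, axis = "time",
                                             x = isi_centers, delta = dt)
    out[[length(out) + 1]] <- tibble::tibble(
      state = s, axis = "frequency", x = fgrid,
      delta = to_freq(dens[[s]]) - to_freq(dens$Move))
  }
  res <- dplyr::bind_rows(out)
  attr(res, "missing_states") <- missing
  res
}

#' Gaussian-smoothed instantaneous firing rate
#'
#' Convolves the 1-kHz spike delta train with a unit-area Gaussian kernel
#' (default sigma 4 ms, i.e. FWHM about 10 ms); the integral of the rate
#' series equals the spike count.
#'
#' @param spike_times Spike times in seconds.
#' @param duration_s Series duration in seconds.
#' @param sigma_ms Kernel standard deviation in ms.
#' @param fs Output rate, Hz.
#' @return Numeric vector of rates in Hz, length `duration_s * fs`.
#' @export
smoothed_firing_rate <- function(spike_times, duration_s, sigma_ms = 4,
                                 fs = 1000) {
  n <- round(duration_s * fs)
  train <- numeric(n)
  idx <- round(spike_times * fs) + 1L
  idx <- idx[idx >= 1 & idx <= n]
  for (i in idx) train[i] <- train[i] + 1
  if (!any(train > 0)) return(train)
  half <- ceiling(4 * sigma_ms * fs / 1000)
  k <- exp(-((-half:half) / (sigma_ms * fs / 1000))^2 / 2)
  k <- k / sum(k) * fs
  out <- stats::convolve(train, rev(k), type = "open")
  out[(half + 1):(half + n)]
}

#' Cross-correlation of two smoothed firing-rate series
#'
#' Pearson correlation of mean-subtracted rates at lags up to
#' `max_lag_ms`, restricted to in-state samples.
#'
#' @param rate_a,rate_b Rate series at `fs` Hz (equal length).
#' @param state_mask Optional logical vector; `NULL` uses all samples.
#' @param max_lag_ms Maximum lag, ms.
#' @param fs Sample rate, Hz.
#' @return Tibble: `lag_ms`, `correlation` (positive lag: `rate_b` follows
#'   `rate_a`). Zero-variance segments give NA.
#' @export
rate_cross_correlation <- function(rate_a, rate_b, state_mask = NULL,
                                   max_lag_ms = 100, fs = 1000) {
  stopifnot(length(rate_a) == length(rate_b))
  n <- length(rate_a)
  if (is.null(state_mask)) state_mask <- rep(TRUE, n)
  lag_samp <- round(max_lag_ms * fs / 1000)
  lags <- -lag_samp:lag_samp
  cc <- vapply(lags, function(L) {
    if (L >= 0) {
      ia <- seq_len(n - L)
      ib <- ia + L
    } else {
      ib <- seq_len(n + L)
      ia <- ib - L
    }
    m <- state_mask[ia] & state_mask[ib]
    a <- rate_a[ia][m]
    b <- rate_b[ib][m]
    if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, 1.0)
  tibble::tibble(lag_ms = lags / fs * 1000, correlation = cc)
}

#' Per-state firing-rate modulation
#'
#' Percent difference of the firing rate in each state from the unit's
#' overall mean rate: `100 * (rate_state - rate_overall) / rate_overall`.
#'
#' @param spike_times Spike times in seconds.
#' @param states Per-bin state labels.
#' @param bin_s Bin length in seconds.
#' @return Tibble: `state`, `rate_hz`, `modulation_pct`, `occupancy`.
#' @export
state_rate_modulation <- function(spike_times, states, bin_s = 8) {
  st <- states_vec(states)
  total_s <- length(st) * bin_s
  overall <- length(spike_times[spike_times < total_s]) / total_s
  if (overall == 0) stop("unit has no spikes: overall rate is zero", call. = FALSE)
  bins <- pmin(length(st), floor(spike_times / bin_s) + 1L)
  purrr::map_dfr(state_levels(), function(s) {
    t_s <- sum(st == s) * bin_s
    n_s <- sum(st[bins] == s)
    r <- if (t_s > 0) n_s / t_s else NA_real_
    tibble::tibble(state = s, rate_hz = r,
                   modulation_pct = 100 * (r - overall) / overall,
                   occupancy = t_s / total_s)
  })
}
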