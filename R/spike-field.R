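#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler; used by the simulator and the PLV bias
#' analysis. `kappa = 0` reduces to the uniform distribution on the circle.
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param kappa Concentration (>= 0).
#' @return Numeric vector of angles wrapped to \[0, 2 pi).
#' @export
r_vonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (kappa < 1e-9) return(wrap_2pi(runif(n, 0, 2 * pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.3) + 8
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3 - 0.5) * acos(pmax(-1, pmin(1, f)))
    out <- c(out, theta[ok])
  }
  wrap_2pi(out[seq_len(n)] + mu)
}

# Band phase at spike times: nearest-sample lookup (at 1 kHz and bands up to
# 120 Hz the worst-case phase error is < 0.08 rad).
spike_phases <- function(spike_times, analytic, state_mask = NULL) {
  stopifnot(inherits(analytic, "analytic_series"))
  n <- length(analytic$phase)
  idx <- round(spike_times * analytic$fs) + 1L
  idx <- idx[idx >= 1 & idx <= n]
  if (!is.null(state_mask)) idx <- idx[state_mask[idx]]
  list(phase = analytic$phase[idx], amplitude = analytic$amplitude[idx],
       idx = idx)
}

#' Spike-field phase-locking value
#'
#' PLV = |mean(exp(i phi))| over the band phases at in-state spike times;
#' each spike phase becomes a unit vector and the resultant length measures
#' locking (0 = uniform, 1 = all phases equal). The locked phase is the
#' circular mean, wrapped to \[0, 2 pi).
#'
#' @param spike_times Spike times in seconds (unit recorded on the same
#'   channel as the LFP the analytic series came from).
#' @param analytic An `analytic_series` of the band-filtered LFP.
#' @param state_mask Optional logical per-sample mask.
#' @param min_spikes Minimum spikes required (default 50).
#' @param low_n_threshold Spike count below which the estimate is flagged as
#'   potentially biased (default 10,000).
#' @return One-row tibble: `plv`, `locked_phase`, `n_spikes`, `low_n`.
#' @export
phase_locking_value <- function(spike_times, analytic, state_mask = NULL,
                                min_spikes = 50, low_n_threshold = 10000) {
  sp <- spike_phases(spike_times, analytic, state_mask)
  n <- length(sp$phase)
  if (n == 0) stop("no in-state spikes", call. = FALSE)
  if (n < min_spikes) {
    stop("fewer than ", min_spikes, " in-state spikes (", n, ")", call. = FALSE)
  }
  v <- sum(exp(1i * sp$phase))
  tibble::tibble(plv = Mod(v) / n, locked_phase = wrap_2pi(Arg(v)),
                 n_spikes = n, low_n = n < low_n_threshold)
}

#' Spike phase distributions by band-amplitude decile
#'
#' Assigns each in-state spike to a (phase bin, amplitude decile) cell,
#' where deciles are computed from the in-state amplitude distribution of
#' the band, and normalizes each amplitude row to sum 1 -- revealing whether
#' locking is confined to high-amplitude oscillation epochs.
#'
#' @inheritParams phase_locking_value
#' @param n_phase Number of phase bins (default 36).
#' @param n_amp Number of amplitude quantile rows (default 10).
#' @return `n_amp` x `n_phase` matrix of row-normalized spike fractions
#'   (rows = amplitude deciles, low to high; empty rows are NA), with
#'   attributes `phase_centers` and `amp_breaks`.
#' @export
spike_phase_amplitude_distribution <- function(spike_times, analytic,
                                               state_mask = NULL,
                                               n_phase = 36, n_amp = 10) {
  sp <- spike_phases(spike_times, analytic, state_mask)
  if (!length(sp$phase)) stop("no in-state spikes", call. = FALSE)
  amp_all <- if (is.null(state_mask)) analytic$amplitude else
    analytic$amplitude[state_mask]
  breaks <- unique(stats::quantile(amp_all, probs = seq(0, 1, length.out = n_amp + 1)))
  arow <- pmin(length(breaks) - 1L,
               pmax(1L, findInterval(sp$amplitude, breaks, rightmost.closed = TRUE)))
  pcol <- pmin(n_phase, floor(sp$phase / (2 * pi) * n_phase) + 1L)
  M <- matrix(0, n_amp, n_phase)
  for (k in seq_along(arow)) M[arow[k], pcol[k]] <- M[arow[k], pcol[k]] + 1
  rs <- rowSums(M)
  M <- M / ifelse(rs > 0, rs, NA_real_)
  attr(M, "phase_centers") <- (seq_len(n_phase) - 0.5) * 2 * pi / n_phase
  attr(M, "amp_breaks") <- breaks
  M
}

#' Sample-size bias of the phase-locking value
#'
#' Monte-Carlo expectation of the PLV of n von Mises draws as a function of
#' n. The asymptotic PLV is the Bessel ratio I1(kappa)/I0(kappa); for
#' kappa = 0 the finite-sample expectation is sqrt(pi)/(2 sqrt(n)), which
#' drops below 0.01 around n = 10,000 -- the point where spike-count bias
#' becomes negligible.
#'
#' @param kappa von Mises concentration.
#' @param n_grid Increasing vector of sample sizes.
#' @param reps Monte-Carlo repetitions per n (>= 10).
#' @param seed Integer seed.
#' @return Tibble: `n`, `expected_plv`, `asymptotic_plv`, `bias`.
#' @export
plv_bias_curve <- function(kappa, n_grid, reps = 100, seed = 1L) {
  if (reps < 10) stop("reps must be >= 10", call. = FALSE)
  if (is.unsorted(n_grid, strictly = TRUE)) {
    stop("n_grid must be increasing", call. = FALSE)
  }
  asym <- besselI(kappa, 1) / besselI(kappa, 0)
  with_seed(seed, {
    purrr::map_dfr(n_grid, function(n) {
      plvs <- vapply(seq_len(reps), function(r) {
        Mod(mean(exp(1i * r_vonmises(n, 0, kappa))))
      }, 1.0)
      tibble::tibble(n = n, expected_plv = mean(plvs), asymptotic_plv = asym,
                     bias = mean(plvs) - asym)
    })
  })
}

#' Phase locking of every unit to every band, per state
#'
#' Convenience wrapper computing [phase_locking_value()] for each unit of a
#' session against each canonical band of the unit's own channel, in each
#' state.
#'
#' @param session A `somn_session`.
#' @param states Per-bin state labels (default: the session's ground truth).
#' @param bands Character vector of bands (default: all six).
#' @param min_spikes Minimum in-state spikes (estimates below are skipped).
#' @param blank Logical: blank +/-2 ms around each spike out of the LFP
#'   before filtering (see [blank_spikes()]); default off.
#' @return Tibble: `unit`, `channel`, `unit_class`, `band`, `state`, `plv`,
#'   `locked_phase`, `n_spikes`, `low_n`.
#' @export
session_phase_locking <- function(session, states = NULL,
                                  bands = canonical_bands()$band,
                                  min_spikes = 50, blank = FALSE) {
  stopifnot(inherits(session, "somn_session"))
  states <- states %||% session$truth
  st <- states_vec(states)
  fs <- session$rates$lfp
  bin_len <- round(session$cfg$bin_s * fs)
  n <- ncol(session$lfp)
  st_samples <- rep(st, each = bin_len)[seq_len(n)]
  edge <- edge_mask(n, fs)
  out <- list()
  for (u in seq_along(session$spike_times)) {
    uspec <- session$units[[u]]
    uname <- names(session$spike_times)[u]
    x <- session$lfp[uspec$channel, ]
    if (blank) x <- blank_spikes(x, session$spike_times[[u]], fs = fs)
    for (b in bands) {
      an <- analytic_signal(bandpass_filter(x, b, fs = fs), fs = fs)
      for (s in intersect(state_levels(), unique(st))) {
        mask <- st_samples == s & edge
        est <- tryCatch(
          phase_locking_value(session$spike_times[[u]], an, mask,
                              min_spikes = min_spikes),
          error = function(e) NULL)
        if (is.null(est)) next
        out[[length(out) + 1]] <- dplyr::bind_cols(
          tibble::tibble(unit = uname,
                         channel = uspec$channel,
                         unit_class = uspec$unit_type, band = b, state = s),
          est)
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Blank spike waveforms out of an LFP trace
#'
#' Replaces a window around each spike time with linear interpolation, for
#' assessing how much same-channel spike-field estimates owe to bleed-through
#' of the unit's own waveform into the gamma bands. Off by default in all
#' pipelines: removing spikes also removes genuine locked oscillation energy.
#'
#' @param x Numeric LFP vector at `fs` Hz.
#' @param spike_times Spike times in seconds.
#' @param fs Sample rate, Hz.
#' @param window_ms Half-width of the blanked window, ms (default 2).
#' @return The trace with spike windows interpolated away.
#' @export
blank_spikes <- function(x, spike_times, fs = 1000, window_ms = 2) {
  half <- max(1L, round(window_ms * fs / 1000))
  n <- length(x)
  for (t in round(spike_times * fs) + 1L) {
    i0 <- max(1L, t - half)
    i1 <- min(n, t + half)
    x[i0:i1] <- seq(x[i0], x[i1], length.out = i1 - i0 + 1L)
  }
  x
}
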