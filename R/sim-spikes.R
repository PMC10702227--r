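# Refractory/recovery hazard profile g(delta) on a 1-ms grid: zero inside the
# absolute refractory period, then a saturating recovery with a bump at the
# target ISI mode. g -> 1 for large delta so the ISI tail is exponential.
isi_hazard_profile <- function(refractory_ms, isi_peak_ms, G = 3000L) {
  d <- seq_len(G)
  tau <- max(0.5, isi_peak_ms / 6)
  w <- max(1.2, isi_peak_ms / 6)
  rec <- 1 - exp(-pmax(0, d - refractory_ms) / tau)
  bump <- 6 * exp(-(d - isi_peak_ms)^2 / (2 * w^2))
  g <- rec * (1 + bump)
  g[d <= refractory_ms] <- 0
  g
}

# Mean ISI (ms) of the discrete renewal process with per-ms hazard h * g.
renewal_mean_isi <- function(h, g) {
  p <- pmin(1, h * g)
  S <- cumprod(1 - p)
  f <- p * c(1, S[-length(S)])
  tail_mass <- S[length(S)]
  sum(seq_along(g) * f) + tail_mass * (length(g) + 1 / max(h, 1e-12))
}

# Solve the per-step base hazard giving a target rate (Hz) under profile g
# defined on the sample grid at fs Hz.
solve_hazard <- function(rate_hz, g, fs) {
  if (rate_hz <= 0) return(0)
  target <- fs / rate_hz # mean ISI in samples
  gmax <- max(g)
  if (renewal_mean_isi(1 / gmax, g) > target) {
    stop("firing rate ", rate_hz, " Hz cannot be honored with this ",
         "refractory/ISI profile", call. = FALSE)
  }
  uniroot(function(h) renewal_mean_isi(h, g) - target,
          lower = 1e-9, upper = 1 / gmax, tol = 1e-12)$root
}

#' Synthesize a spike train locked to the session's LFP
#'
#' Inhomogeneous discrete-time point process at the LFP rate with
#' state-dependent firing rate, an absolute refractory period, an ISI
#' histogram mode near `unit$isi_peak_ms`, and optional von Mises phase
#' locking: spike probability is multiplied by
#' `exp(kappa * (cos(phase - mu) - 1))` where `phase` is the band-filtered
#' (zero-phase Butterworth + Hilbert) LFP phase of the unit's channel --
#' the same phase the spike-field estimators later read, so planted
#' `(kappa, mu)` are recovered by [phase_locking_value()]. The base hazard is
#' solved per state so that measured rates match `unit$base_rate` despite
#' refractoriness and phase thinning.
#'
#' @inheritParams synthesize_lfp
#' @param lfp Channels x samples matrix (at `cfg$lfp_rate`) containing at
#'   least the unit's channel, as produced by [synthesize_lfp()].
#' @param unit A [unit_spec()].
#' @return Numeric vector of spike times in seconds (strictly increasing,
#'   gaps >= the refractory period).
#' @export
synthesize_spike_train <- function(states, lfp, unit, cfg, seed = cfg$seed) {
  st <- states_vec(states)
  if (!is.matrix(lfp)) lfp <- matrix(lfp, nrow = 1)
  if (unit$channel > nrow(lfp)) stop("unit channel not in lfp", call. = FALSE)
  fs <- cfg$lfp_rate
  bin_len <- round(cfg$bin_s * fs)
  n <- length(st) * bin_len
  g <- isi_hazard_profile(unit$refractory_ms * fs / 1000,
                          unit$isi_peak_ms * fs / 1000,
                          G = as.integer(3 * fs)) # 3-s support

  kappa <- mu <- numeric(4)
  phase <- numeric(0)
  if (!is.null(unit$locking) && nrow(unit$locking)) {
    phase <- numeric(n)
    x <- lfp[unit$channel, ]
    for (r in seq_len(nrow(unit$locking))) {
      row <- unit$locking[r, ]
      s_idx <- match(row$state, state_levels())
      kappa[s_idx] <- row$kappa
      mu[s_idx] <- row$preferred_phase
      ph <- analytic_signal(bandpass_filter(x, row$band, fs = fs))$phase
      mask <- rep(st == row$state, each = bin_len)
      phase[mask] <- ph[mask]
    }
  }

  # per-state hazard compensated for phase thinning: uniform phases are
  # accepted with mean I0(kappa) * exp(-kappa)
  accept <- besselI(kappa, 0, expon.scaled = TRUE)
  h <- vapply(seq_len(4), function(s) {
    r <- unit$base_rate[state_levels()[s]]
    solve_hazard(r / accept[s], g, fs)
  }, 1.0)

  state_idx <- match(st, state_levels()) - 1L
  sp <- spike_thin_cpp(state_idx, bin_len, h, g,
                       phase, kappa, mu, n, sub_seed(seed, 193L))
  (sp - 1) / fs
}

#' Default extracellular spike waveform template
#'
#' A biphasic (negative trough, positive rebound) template sampled at the
#' wideband rate, peak-normalized so the trough is -1.
#'
#' @param wb_rate Wideband sample rate in Hz.
#' @return Numeric vector (about 1.6 ms long).
#' @export
default_waveform_template <- function(wb_rate = 20000) {
  t <- seq(0, 1.6e-3, by = 1 / wb_rate)
  w <- -exp(-((t - 0.4e-3) / 0.12e-3)^2) + 0.45 * exp(-((t - 0.85e-3) / 0.25e-3)^2)
  w / max(abs(w))
}

#' Render a wideband trace with embedded spike waveforms
#'
#' Builds a high-rate extracellular-like trace for exercising the two-window
#' spike discriminator: the (upsampled) LFP plus white noise plus a waveform
#' template inserted at each spike time.
#'
#' @param lfp_channel Numeric vector at `lfp_rate` Hz.
#' @param spike_times Spike times in seconds.
#' @param template Waveform template at `wb_rate` (default
#'   [default_waveform_template()]).
#' @param lfp_rate,wb_rate Input and output sample rates, Hz.
#' @param spike_amp Amplitude multiplying the unit template.
#' @param noise_sd Standard deviation of the added white noise (sets SNR
#'   together with `spike_amp`).
#' @param lfp_gain Gain applied to the upsampled LFP.
#' @param seed Integer seed for the noise.
#' @return Numeric vector at `wb_rate` Hz.
#' @export
render_wideband <- function(lfp_channel, spike_times, template = NULL,
                            lfp_rate = 1000, wb_rate = 20000,
                            spike_amp = 50, noise_sd = 5, lfp_gain = 1,
                            seed = 1L) {
  template <- template %||% (spike_amp * default_waveform_template(wb_rate))
  n <- length(lfp_channel) * round(wb_rate / lfp_rate)
  t_in <- (seq_along(lfp_channel) - 1) / lfp_rate
  t_out <- (seq_len(n) - 1) / wb_rate
  base <- approx(t_in, lfp_channel, xout = t_out, rule = 2)$y * lfp_gain
  with_seed(sub_seed(seed, 7L), {
    x <- base + rnorm(n, sd = noise_sd)
  })
  at <- round(spike_times * wb_rate) + 1L
  for (a in at) {
    i <- a + seq_along(template) - 1L
    ok <- i <= n
    x[i[ok]] <- x[i[ok]] + template[ok]
  }
  x
}
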