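states_vec <- function(states) {
  s <- if (is.data.frame(states)) states$state else states
  assert_states(s)
  s
}

# Expand a per-bin value to per-sample resolution with a linear crossfade of
# fade_len samples centered on each bin boundary where the value changes, so
# state transitions do not introduce step artifacts.
expand_bins <- function(vals, bin_len, fade_len = 1000) {
  v <- rep(vals, each = bin_len)
  if (fade_len > 1 && length(vals) > 1) {
    chg <- which(diff(vals) != 0)
    half <- fade_len %/% 2
    ramp <- seq(0, 1, length.out = fade_len)
    n <- length(v)
    for (b in chg) {
      t0 <- b * bin_len # first sample of bin b+1 (0-based boundary)
      i0 <- max(1L, t0 - half + 1L)
      i1 <- min(n, t0 + half)
      r <- ramp[seq_len(i1 - i0 + 1L)]
      v[i0:i1] <- vals[b] + (vals[b + 1] - vals[b]) * r
    }
  }
  v
}

# 1/f^alpha background noise, unit RMS. Shaped in the frequency domain in
# overlapping chunks (sqrt-Hann windows, 50% overlap-add keeps the output
# stationary), synthesized at fs/L and linearly upsampled.
one_f_noise <- function(n, fs, alpha, L = 4L) {
  m <- ceiling(n / L) + 2L
  rb <- fs / L
  chunk <- min(2^18, 2^ceiling(log2(max(m, 16))))
  hop <- chunk %/% 2
  f <- seq(0, rb, length.out = chunk + 1)[seq_len(chunk)]
  f <- pmin(f, rb - f) # two-sided frequency magnitude
  H <- pmax(f, 0.25)^(-alpha / 2)
  H[1] <- 0
  w <- sqrt(hann(chunk))
  n_chunks <- ceiling(m / hop) + 1L
  out <- numeric(n_chunks * hop + chunk)
  for (k in seq_len(n_chunks)) {
    x <- Re(stats::fft(stats::fft(rnorm(chunk)) * H, inverse = TRUE)) / chunk
    i0 <- (k - 1L) * hop
    out[(i0 + 1):(i0 + chunk)] <- out[(i0 + 1):(i0 + chunk)] + x * w
  }
  out <- out[hop + seq_len(m)] # drop the partially-covered head
  out <- out / stats::sd(out)
  up <- upsample_rotate_cpp(out, numeric(length(out)), as.integer(L),
                            0, fs, n, FALSE)
  up$re
}

# Complex narrowband baseband at fs/L: a constant-envelope phasor whose
# instantaneous frequency wanders around the band center as a slow
# Ornstein-Uhlenbeck process (sd 0.1 x half-width, correlation time 4 s).
# Each oscillation is thus a frequency-jittered rhythm: its band power is
# stationary within a state (state-dependent amplitude and planted coupling
# are applied downstream as explicit envelopes), giving the planted state
# classes stationary spectra, while averaged Welch estimates still show a
# band-centered peak. Scaled so the rotated carrier has unit RMS.
band_baseband <- function(n, fs, L, hw) {
  m <- ceiling(n / L) + 2L
  rb <- fs / L
  sigma_f <- 0.1 * hw
  a <- exp(-1 / (4 * rb))
  eps <- rnorm(m, sd = sigma_f * sqrt(1 - a^2))
  df <- as.numeric(stats::filter(eps, a, method = "recursive"))
  phi <- 2 * pi * cumsum(df) / rb + runif(1, 0, 2 * pi)
  list(re = sqrt(2) * cos(phi), im = sqrt(2) * sin(phi))
}

# Synthesize one fully-formed channel (background + per-state band
# oscillations + planted phase-amplitude coupling). All randomness is drawn
# from `seed`.
synth_one_channel <- function(st, cfg, seed) {
  fs <- cfg$lfp_rate
  bin_len <- round(cfg$bin_s * fs)
  n <- length(st) * bin_len
  fade <- min(bin_len, round(fs)) # transitions cross-faded over <= 1 s
  carriers <- band_carriers(cfg)
  cs <- cfg$coupling_spec
  low_needed <- unique(cs$low_band)

  with_seed(seed, {
    sig <- one_f_noise(n, fs, cfg$noise_exponent)
    sig <- sig + 0.3 * rnorm(n)
    low_phase <- list()
    # low (coupling-source) bands first so their exact instantaneous phase is
    # available when modulating the high bands
    ord <- order(!(carriers$band %in% low_needed))
    for (i in ord) {
      band <- carriers$band[i]
      f0 <- carriers$f0[i]
      hw <- carriers$hw[i]
      L <- max(1L, floor(fs / (8 * hw)))
      bb <- band_baseband(n, fs, L, hw)
      need_comp <- band %in% low_needed
      z <- upsample_rotate_cpp(bb$re, bb$im, L, f0, fs, n, need_comp)
      if (need_comp) {
        low_phase[[band]] <- atan2(z$im, z$re)
        z$im <- NULL
      }
      amp <- cfg$osc_scale * cfg$band_powers[st, band]
      env <- expand_bins(amp, bin_len, fade)
      rows <- which(cs$high_band == band)
      for (r in rows) {
        phl <- low_phase[[cs$low_band[r]]]
        if (is.null(phl)) next
        depth <- ifelse(st == cs$state[r], cs$modulation_depth[r], 0)
        dt <- expand_bins(depth, bin_len, fade)
        env <- env * (1 + dt * cos(phl - cs$preferred_phase[r]))
        rm(dt)
      }
      sig <- sig + z$re * env
      rm(z, env)
    }
    sig
  })
}

#' Synthesize multichannel LFP for a state sequence
#'
#' Each channel is the sum of 1/f^alpha background noise, a white-noise
#' floor, and one narrowband-noise oscillation per canonical band whose
#' amplitude follows the per-state `band_powers` table (cross-faded over at
#' most 1 s at state transitions). For every `coupling_spec` entry active in
#' a state, the high band's instantaneous amplitude is modulated as
#' `1 + depth * cos(phase_low - preferred_phase)` using the exact low-band
#' carrier phase. A shared component mixed at `shared_fraction` of the
#' variance produces inter-channel coherence.
#'
#' @param states Output of [generate_state_sequence()] (or a character vector
#'   of per-bin states).
#' @param cfg A [sim_config()].
#' @param seed Integer seed (defaults to the config seed).
#' @param channels Integer vector of channels to synthesize (default: all).
#'   The result is deterministic per channel, so generating channels one at a
#'   time yields the same samples as generating them together.
#' @param .shared Internal: a precomputed shared-component vector (from a
#'   previous call with the same states/config/seed), so streaming callers
#'   do not regenerate it per channel.
#' @return A `length(channels)` x samples matrix.
#' @export
synthesize_lfp <- function(states, cfg, seed = cfg$seed,
                           channels = seq_len(cfg$n_channels),
                           .shared = NULL) {
  st <- states_vec(states)
  if (!length(st)) stop("states must be nonempty", call. = FALSE)
  # validates band names early
  stopifnot(all(colnames(cfg$band_powers) %in% canonical_bands()$band))
  sf <- cfg$shared_fraction
  shared <- if (sf > 0) {
    .shared %||% synth_one_channel(st, cfg, sub_seed(seed, 0L))
  } else NULL
  n <- length(st) * round(cfg$bin_s * cfg$lfp_rate)
  out <- matrix(0, length(channels), n)
  for (j in seq_along(channels)) {
    ch <- channels[j]
    priv <- if (sf < 1) synth_one_channel(st, cfg, sub_seed(seed, ch)) else 0
    out[j, ] <- sqrt(1 - sf) * priv + if (sf > 0) sqrt(sf) * shared else 0
  }
  out
}
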