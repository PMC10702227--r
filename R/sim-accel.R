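# Per-state accelerometer noise scale (arbitrary g-like units) and movement
# burst rates (events per second). Move is sustained high-amplitude movement
# (no discrete bursts needed on top); quiet states get occasional brief
# bursts -- fidgets at rest, twitches in REM -- and Move > Rest > REM > NREM
# ordering holds for per-bin variance.
accel_state_params <- function() {
  tibble::tibble(
    state = state_levels(),
    base_sd = c(3.0, 0.30, 0.15, 0.05),
    burst_rate = c(0, 0.03, 0.03, 0.005)
  )
}

#' Synthesize a 3-axis accelerometer trace for a state sequence
#'
#' White noise whose standard deviation follows the behavioral state
#' (Move > Rest > REM > NREM), plus exponentially decaying movement bursts
#' whose rate is also state-dependent, mimicking gross movements while awake
#' and brief twitches during sleep.
#'
#' @inheritParams synthesize_lfp
#' @param burst Logical; set `FALSE` for stationary per-state noise with no
#'   movement bursts.
#' @return A 3 x samples matrix at `cfg$accel_rate` Hz.
#' @export
synthesize_accelerometer <- function(states, cfg, seed = cfg$seed,
                                     burst = TRUE) {
  st <- states_vec(states)
  fs <- cfg$accel_rate
  bin_len <- round(cfg$bin_s * fs)
  n <- length(st) * bin_len
  pars <- accel_state_params()
  sd_bin <- pars$base_sd[match(st, pars$state)]
  with_seed(sub_seed(seed, 97L), {
    env <- expand_bins(sd_bin, bin_len, fade_len = round(fs / 2))
    if (burst) {
      rate_bin <- pars$burst_rate[match(st, pars$state)]
      n_events <- stats::rpois(1, sum(rate_bin) * cfg$bin_s)
      if (n_events > 0) {
        # place events in bins proportionally to the per-bin burst rate
        bins <- sample.int(length(st), n_events, replace = TRUE,
                           prob = rate_bin)
        t0 <- (bins - 1) * bin_len + sample.int(bin_len, n_events, replace = TRUE)
        dur <- pmax(0.2, stats::rexp(n_events, 2)) # seconds
        amp <- stats::runif(n_events, 1, 3)
        for (k in seq_len(n_events)) {
          len <- min(n - t0[k], round(dur[k] * fs))
          if (len < 1) next
          i <- t0[k] + seq_len(len)
          env[i] <- env[i] + amp[k] * env[i] * exp(-(seq_len(len) - 1) / (0.3 * fs))
        }
      }
    }
    acc <- matrix(rnorm(3 * n), nrow = 3)
    acc * rep(env, each = 3)
  })
}
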