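# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Dwell times shortened proportionally so short test sessions cycle through
# all four states the way a day-long session does.
short_dwell <- function() {
  tibble::tribble(
    ~state, ~min_minutes, ~max_minutes,
    "Move", 1, 6,
    "Rest", 1, 6,
    "REM",  2, 6,
    "NREM", 8, 22
  )
}

small_cfg <- function(hours = 1, channels = 2, seed = 7, units = list(), ...) {
  sim_config(session_hours = hours, n_channels = channels,
             state_dwell = short_dwell(), units = units, seed = seed, ...)
}

# 1-h, 2-channel session without spikes: the workhorse fixture.
small_session <- function() {
  fixture("small_session", function() {
    generate_session(small_cfg(), eog = FALSE)
  })
}

# A 30-min all-NREM LFP channel with strong planted delta -> high-gamma
# coupling, for CFC tests. The state vector is supplied directly (the
# sequence generator is for >= 1-h sessions).
coupled_channel <- function() {
  fixture("coupled_channel", function() {
    cfg <- sim_config(
      session_hours = 0.5, n_channels = 1, units = list(), seed = 11,
      coupling_spec = tibble::tibble(state = "NREM", low_band = "delta",
                                     high_band = "high_gamma",
                                     modulation_depth = 0.8,
                                     preferred_phase = pi)
    )
    st <- rep("NREM", cfg$n_bins)
    list(cfg = cfg, states = st,
         lfp = synthesize_lfp(st, cfg))
  })
}

# Deterministic von Mises phase series packaged as an analytic series, with
# one "spike" per sample.
vm_analytic <- function(n, mu, kappa, seed = 42, fs = 1000) {
  ph <- somnidyn:::with_seed(seed, r_vonmises(n, mu, kappa))
  structure(list(phase = ph, amplitude = rep(1, n), fs = fs),
            class = "analytic_series")
}
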