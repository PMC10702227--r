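test_that("state sequence respects lights-off construction and dwell bounds", {
  # whole session dark, no awakenings: only NREM and REM can occur
  cfg <- sim_config(session_hours = 3, n_channels = 1, units = list(),
                    lights_off = c(0, 3), awakening_prob = 0, seed = 2)
  st <- generate_state_sequence(cfg)
  expect_setequal(unique(st$state), c("NREM", "REM"))

  # default 24 h: all four states occur; NREM bouts only start in lights-off
  cfg24 <- sim_config(session_hours = 24, n_channels = 1, units = list(),
                      seed = 1)
  st24 <- generate_state_sequence(cfg24)
  expect_setequal(unique(st24$state), c("Move", "Rest", "REM", "NREM"))
  nrem_bins <- which(st24$state == "NREM")
  # tolerate a single dwell overrunning past lights-on
  max_dwell_bins <- max(cfg24$state_dwell$max_minutes) * 60 / cfg24$bin_s
  expect_true(all(st24$lights_off[nrem_bins] |
                    st24$hour[nrem_bins] >= cfg24$lights_off[2] - 1e-9 |
                    nrem_bins <= max_dwell_bins + which.max(st24$lights_off)))

  # dwell-bound oracle: mean NREM run length recomputed from the sequence
  dw <- tibble::tibble(state = c("Move", "Rest", "REM", "NREM"),
                       min_minutes = c(2, 2, 4, 30),
                       max_minutes = c(20, 20, 15, 120))
  cfgd <- sim_config(session_hours = 10000 * 8 / 3600, n_channels = 1,
                     units = list(), lights_off = c(0, 24),
                     awakening_prob = 0, state_dwell = dw, seed = 5)
  std <- generate_state_sequence(cfgd)
  r <- rle(std$state)
  runs <- r$lengths[r$values == "NREM"]
  runs <- runs[-length(runs)] # last run may be truncated by session end
  mean_minutes <- mean(runs) * cfgd$bin_s / 60
  expect_gt(mean_minutes, 30)
  expect_lt(mean_minutes, 120)

  # inverted dwell bounds are a configuration error
  bad <- dw
  bad$min_minutes[4] <- 200
  expect_error(sim_config(session_hours = 2, state_dwell = bad, units = list()),
               "min_minutes")
})

test_that("generated sessions are deterministic and sized correctly", {
  cfg <- small_cfg(hours = 1, channels = 1, seed = 3)
  s1 <- generate_session(cfg, eog = FALSE)
  s2 <- generate_session(cfg, eog = FALSE)
  expect_identical(s1$lfp, s2$lfp)
  expect_identical(s1$accel, s2$accel)
  expect_identical(s1$truth, s2$truth)

  cfg_other <- small_cfg(hours = 1, channels = 1, seed = 4)
  s3 <- generate_session(cfg_other, eog = FALSE)
  expect_false(identical(s1$lfp, s3$lfp))

  expect_equal(ncol(s1$lfp), 3600 * cfg$lfp_rate)
  expect_equal(ncol(s1$accel), 3600 * cfg$accel_rate)
})

test_that("per-state spectral structure is recovered by Welch power", {
  s <- small_session()
  est <- welch_psd_bins(s$lfp)
  f <- normalize_mean_psd(est)
  delta <- rowMeans(f$X[, f$freqs >= 0.5 & f$freqs <= 4])
  st <- s$truth$state
  skip_if(!all(c("NREM", "Move") %in% st))
  expect_gt(mean(delta[st == "NREM"]), mean(delta[st == "Move"]))
  # NREM delta amplitude is planted above wake: raw Welch delta power higher
  M <- apply(est$psd, c(2, 3), mean)
  draw <- rowMeans(M[, f$freqs >= 0.5 & f$freqs <= 4])
  expect_gt(median(draw[st == "NREM"]), 1.3 * median(draw[st == "Move"]))
})

test_that("shared_fraction 1 gives near-unit coherence at oscillation bands", {
  cfg <- small_cfg(hours = 0.25, channels = 2, seed = 8, shared_fraction = 1)
  st <- rep(c("Rest", "NREM"), length.out = cfg$n_bins)
  lfp <- synthesize_lfp(st, cfg)
  expect_equal(lfp[1, ], lfp[2, ])
  co <- magnitude_squared_coherence(lfp[1, ], lfp[2, ])
  expect_true(all(co$coherence > 0.999))
})

test_that("coherence increases monotonically with shared_fraction", {
  med <- vapply(c(0, 0.4, 0.9), function(sf) {
    cfg <- small_cfg(hours = 0.25, channels = 2, seed = 8,
                     shared_fraction = sf)
    st <- rep(c("Rest", "NREM"), length.out = cfg$n_bins)
    lfp <- synthesize_lfp(st, cfg)
    co <- magnitude_squared_coherence(lfp[1, ], lfp[2, ])
    median(co$coherence)
  }, 1.0)
  expect_true(all(diff(med) > 0))
})

test_that("accelerometer variance follows the behavioral state", {
  cfg <- small_cfg(hours = 0.5, seed = 6)
  bin_len <- cfg$bin_s * cfg$accel_rate
  bin_var <- function(acc) {
    rss <- sqrt(colSums(acc^2))
    apply(matrix(rss[seq_len(length(rss) %/% bin_len * bin_len)], bin_len),
          2, var)
  }
  n_bins <- cfg$n_bins
  all_move <- synthesize_accelerometer(rep("Move", n_bins), cfg, seed = 1)
  all_nrem <- synthesize_accelerometer(rep("NREM", n_bins), cfg, seed = 1)
  expect_gt(mean(log(bin_var(all_move))), mean(log(bin_var(all_nrem))))

  # ordering across planted states
  # contiguous blocks so state-transition crossfades do not leak the
  # high-amplitude Move noise into neighboring quiet-state bins
  st <- rep(c("Move", "Rest", "REM", "NREM"), each = ceiling(n_bins / 4))[1:n_bins]
  acc <- synthesize_accelerometer(st, cfg)
  v <- bin_var(acc)
  meds <- tapply(v, st[seq_along(v)], median)
  if (all(c("Move", "REM", "NREM") %in% names(meds))) {
    expect_gt(meds[["Move"]], meds[["REM"]])
    expect_gt(meds[["REM"]], meds[["NREM"]])
  }

  # burst-free mode: stationary noise, near-constant variance within state
  acc2 <- synthesize_accelerometer(rep("Rest", n_bins), cfg, burst = FALSE)
  v2 <- bin_var(acc2)
  expect_lt(sd(v2) / mean(v2), 0.25)
})

test_that("spike trains honor refractoriness, rates and planted locking", {
  cfg <- sim_config(session_hours = 1, n_channels = 1, seed = 12,
                    lights_off = c(0, 1), awakening_prob = 0,
                    state_dwell = tibble::tibble(
                      state = c("Move", "Rest", "REM", "NREM"),
                      min_minutes = c(5, 5, 10, 10),
                      max_minutes = c(10, 10, 15, 15)),
                    units = list())
  st <- generate_state_sequence(cfg)
  lfp <- synthesize_lfp(st, cfg)

  unit <- unit_spec("FS", base_rate = c(Move = 20, Rest = 20, REM = 20, NREM = 10),
                    refractory_ms = 1, isi_peak_ms = 6,
                    locking = tibble::tibble(state = "NREM", band = "delta",
                                             kappa = 1, preferred_phase = pi))
  sp <- synthesize_spike_train(st, lfp, unit, cfg, seed = 3)
  expect_true(all(diff(sp) * 1000 >= unit$refractory_ms))

  # rate recovery: NREM planted at half the REM rate
  mods <- state_rate_modulation(sp, st, bin_s = cfg$bin_s)
  r_rem <- mods$rate_hz[mods$state == "REM"]
  r_nrem <- mods$rate_hz[mods$state == "NREM"]
  expect_equal(r_nrem / r_rem, 0.5, tolerance = 0.12)

  # kappa = 0 (no locking entry) in REM: PLV near the sampling floor
  an <- analytic_signal(bandpass_filter(lfp[1, ], "delta"))
  st_samp <- rep(st$state, each = cfg$bin_s * cfg$lfp_rate)
  m_rem <- st_samp == "REM" & edge_mask(ncol(lfp))
  est0 <- phase_locking_value(sp, an, m_rem)
  expect_lt(est0$plv, 3 / sqrt(est0$n_spikes))

  # kappa = 1 in NREM: PLV near the Bessel ratio, phase near pi
  m_nrem <- st_samp == "NREM" & edge_mask(ncol(lfp))
  est1 <- phase_locking_value(sp, an, m_nrem)
  target <- besselI(1, 1) / besselI(1, 0)
  expect_equal(est1$plv, target, tolerance = 0.12)
  circ_dist <- function(a, b) abs(atan2(sin(a - b), cos(a - b)))
  expect_lt(circ_dist(est1$locked_phase, pi), 0.25)

  # unhonorable rate errors out
  too_fast <- unit_spec("FS", base_rate = c(Move = 900, Rest = 900,
                                            REM = 900, NREM = 900),
                        refractory_ms = 1, isi_peak_ms = 5)
  expect_error(synthesize_spike_train(st, lfp, too_fast, cfg),
               "cannot be honored")
})
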