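test_that("two-window discrimination finds planted templates", {
  wb_rate <- 20000
  tmpl <- 60 * default_waveform_template(wb_rate)
  spike_times <- seq(0.5, 59.5, length.out = 100)
  # noise-free trace: exactly 100 detections near the planted times
  quiet <- render_wideband(numeric(60 * 1000), spike_times, template = tmpl,
                           noise_sd = 0, seed = 1)
  # place windows on the filtered template trajectory
  bf <- signal::butter(1, c(1000, 2000) / (wb_rate / 2), type = "pass")
  tf <- as.numeric(signal::filter(bf, c(tmpl, numeric(200))))
  thr <- min(tf) * 0.7
  cross <- which(tf <= thr)[1]
  d1 <- (which.min(tf) - cross) / wb_rate * 1000
  d2 <- (which.max(tf) - cross) / wb_rate * 1000
  spec <- discriminator_spec(
    threshold = thr,
    window1 = c(max(d1, 0.05), min(tf) * 1.5, min(tf) * 0.5),
    window2 = c(max(d2, d1 + 0.1), max(tf) * 0.5, max(tf) * 1.5))
  det <- window_discriminate(quiet, spec, wb_rate)
  expect_equal(length(det$times), 100)
  match_err <- vapply(det$times, function(t) min(abs(t - spike_times)), 1.0)
  expect_lt(max(match_err), 1e-3)

  # windows moved off the trajectory: nothing accepted
  spec_off <- discriminator_spec(thr, c(max(d1, 0.05), max(tf) * 3,
                                        max(tf) * 4),
                                 spec$window2)
  expect_equal(length(window_discriminate(quiet, spec_off, wb_rate)$times), 0)

  # SNR 5: trough amplitude 60, noise sd 12
  noisy <- render_wideband(numeric(60 * 1000), spike_times, template = tmpl,
                           noise_sd = 12, seed = 2)
  detn <- window_discriminate(noisy, spec, wb_rate)
  hits <- vapply(spike_times, function(t) any(abs(detn$times - t) < 5e-4), TRUE)
  fp <- vapply(detn$times, function(t) all(abs(t - spike_times) > 5e-4), TRUE)
  expect_gte(mean(hits), 0.95)
  expect_lte(sum(fp) / max(1, length(detn$times)), 0.05)
})

test_that("coefficient of determination matches hand-evaluated cases", {
  w <- c(1, 2, 3, 4)
  expect_equal(coefficient_of_determination(w, w), 1)
  expect_equal(coefficient_of_determination(w, rep(mean(w), 4)), 0)
  expect_equal(coefficient_of_determination(w, c(1, 2, 3, 5)), 1 - 1 / 5)
  expect_error(coefficient_of_determination(rep(2, 4), w), "zero variance")
  # asymmetric by construction
  a <- c(0, 1, 0, -1); b <- c(0, 2, 0, -2)
  expect_false(isTRUE(all.equal(coefficient_of_determination(a, b),
                                coefficient_of_determination(b, a))))
})

test_that("waveform stability test separates same-unit from cross-unit", {
  set.seed(5)
  tmpl_a <- default_waveform_template()
  tmpl_b <- rev(tmpl_a) * 0.8
  mk <- function(tmpl, n) t(replicate(n, tmpl + rnorm(length(tmpl), sd = 0.05)))
  first <- mk(tmpl_a, 150); last <- mk(tmpl_a, 150); other <- mk(tmpl_b, 150)
  st <- waveform_stability_test(first, last, other, seed = 1)
  expect_true(st$stable)

  # first/last from different templates: unstable
  st2 <- waveform_stability_test(mk(tmpl_a, 150), mk(tmpl_b, 150),
                                 mk(tmpl_a, 150), seed = 1)
  expect_false(st2$stable)

  # statistically identical same/cross sets: the test cannot reject
  st3 <- waveform_stability_test(mk(tmpl_a, 150), mk(tmpl_a, 150),
                                 mk(tmpl_a, 150), seed = 1)
  expect_false(st3$stable)
  expect_gt(st3$p_value, 0.05)
  expect_error(waveform_stability_test(first[1:50, ], last, other), "100")
})

test_that("ISI profiling classifies RS/FS around the 10 ms boundary", {
  mk_train <- function(peak_ms, n = 4000, seed = 1) {
    somnidyn:::with_seed(seed, cumsum(pmax(1, rnorm(n, peak_ms, 1.2))) / 1000)
  }
  p5 <- isi_profile(mk_train(5))
  expect_equal(p5$unit_class, "FS")
  expect_lt(abs(p5$isi_peak_ms - 5), 1.5)
  p50 <- isi_profile(mk_train(50))
  expect_equal(p50$unit_class, "RS")
  expect_lt(abs(p50$isi_peak_ms - 50), 2.5)
  # strict boundary: mode at 9.5 -> FS, at 10.5 -> RS
  expect_equal(isi_profile(mk_train(9.5, seed = 2))$unit_class, "FS")
  expect_equal(isi_profile(mk_train(10.5, seed = 2))$unit_class, "RS")
  expect_error(isi_profile(0.5), "2 spikes")
})

test_that("ISI state contrast is zero for identical firing, localized for planted rhythm", {
  st <- rep(c("Move", "NREM"), each = 225)
  # identical (exponential-ISI) firing statistics in both states
  somnidyn:::with_seed(11, tms <- cumsum(rexp(150000, 20)))
  tms <- tms[tms < 3600]
  ctr <- isi_state_contrast(tms, st, bin_s = 8)
  expect_lt(max(abs(ctr$delta[ctr$state == "NREM" & ctr$axis == "time"])), 0.02)

  # both densities normalized: contrast integrates to ~0
  expect_lt(abs(sum(ctr$delta[ctr$state == "NREM" & ctr$axis == "time"])), 0.05)

  # planted 8 Hz rhythmic spiking only in NREM: positive peak near 7-10 Hz
  somnidyn:::with_seed(3, {
    t_move <- cumsum(rexp(20000, 20))
    t_move <- t_move[t_move < 1800]
    t_nrem <- 1800 + cumsum(pmax(0.002, rnorm(20000, 0.125, 0.01)))
    t_nrem <- t_nrem[t_nrem < 3600]
  })
  ctr2 <- isi_state_contrast(sort(c(t_move, t_nrem)), st, bin_s = 8)
  fr <- ctr2[ctr2$state == "NREM" & ctr2$axis == "frequency", ]
  peak_f <- fr$x[which.max(fr$delta)]
  expect_true(peak_f >= 7 && peak_f <= 10)
})

test_that("smoothed firing rate integrates to the spike count", {
  r1 <- smoothed_firing_rate(0.5, duration_s = 1)
  expect_equal(sum(r1) / 1000, 1, tolerance = 1e-6)
  expect_equal(length(r1), 1000)

  # homogeneous 20 Hz train over 100 s: mean rate 20 +- 1 Hz
  tms <- seq(0.025, 99.975, by = 0.05)
  r2 <- smoothed_firing_rate(tms, duration_s = 100)
  expect_equal(mean(r2), 20, tolerance = 0.05)
  expect_equal(sum(r2) / 1000, length(tms), tolerance = 1e-6)

  expect_true(all(smoothed_firing_rate(numeric(0), duration_s = 1) == 0))
})

test_that("rate cross-correlation localizes lags and stays small for independent units", {
  set.seed(6)
  a <- smoothed_firing_rate(cumsum(rexp(2000, 10)), duration_s = 150)
  cc_self <- rate_cross_correlation(a, a)
  expect_equal(cc_self$correlation[cc_self$lag_ms == 0], 1, tolerance = 1e-9)
  expect_equal(cc_self$lag_ms[which.max(cc_self$correlation)], 0)

  b <- c(numeric(10), a[1:(length(a) - 10)]) # b follows a by 10 ms
  cc_lag <- rate_cross_correlation(a, b)
  expect_equal(cc_lag$lag_ms[which.max(cc_lag$correlation)], 10)

  ind <- smoothed_firing_rate(cumsum(rexp(2000, 10)), duration_s = 150)
  cc_ind <- rate_cross_correlation(a, ind)
  expect_lt(max(abs(cc_ind$correlation)), 0.05)
})

test_that("state rate modulation matches hand-computed values", {
  st <- rep(c("Move", "Rest", "REM", "NREM"), each = 100) # equal occupancy
  # rates 1, 1, 1, 0.5 Hz: overall 0.875; NREM modulation = -42.857%
  mk <- function(t0, rate, dur) t0 + seq(1 / rate / 2, dur, by = 1 / rate)
  tms <- sort(c(mk(0, 1, 799), mk(800, 1, 799), mk(1600, 1, 799),
                mk(2400, 0.5, 799)))
  mods <- state_rate_modulation(tms, st, bin_s = 8)
  expect_equal(mods$modulation_pct[mods$state == "NREM"],
               100 * (0.5 - 0.875) / 0.875, tolerance = 1)
  expect_equal(mods$modulation_pct[mods$state == "Move"],
               100 * (1 - 0.875) / 0.875, tolerance = 1)
  # occupancy-weighted mean of modulations is zero
  expect_equal(sum(mods$modulation_pct * mods$occupancy), 0, tolerance = 1)

  # uniform rate: zero modulation everywhere
  tu <- seq(0.5, 3199.5, by = 1)
  mu <- state_rate_modulation(tu, st, bin_s = 8)
  expect_true(all(abs(mu$modulation_pct) < 1))
  expect_error(state_rate_modulation(numeric(0), st), "no spikes")
})
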