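#' Specification of a simulated single unit
#'
#' Describes one synthetic unit: its cell class, per-state firing rates,
#' inter-spike-interval (ISI) structure and optional phase locking to an LFP
#' band of its home channel.
#'
#' @param unit_type `"RS"` (regular spiking) or `"FS"` (fast spiking).
#' @param base_rate Named numeric of target firing rates in Hz, one per state
#'   (`Move`, `Rest`, `REM`, `NREM`).
#' @param refractory_ms Absolute refractory period in ms (> 0).
#' @param isi_peak_ms Target mode of the ISI histogram in ms. FS units must
#'   have a mode below 10 ms, RS units at or above 10 ms.
#' @param locking Optional tibble/data.frame with columns `state`, `band`,
#'   `kappa` (von Mises concentration, >= 0) and `preferred_phase` (radians);
#'   spike probability in that state is modulated by
#'   exp(kappa * cos(phase - preferred_phase)) evaluated on the band-filtered
#'   LFP phase of the unit's channel.
#' @param channel 1-based LFP channel the unit lives on.
#' @param waveform_template Optional numeric vector: spike waveform at the
#'   wideband rate used by [render_wideband()]. Defaults to a biphasic
#'   (negative trough, positive rebound) template.
#'
#' @return An object of class `unit_spec`.
#' @export
unit_spec <- function(unit_type = c("RS", "FS"),
                      base_rate = c(Move = 8, Rest = 6, REM = 5, NREM = 3.5),
                      refractory_ms = 1.5,
                      isi_peak_ms = if (unit_type[1] == "FS") 6 else 40,
                      locking = NULL,
                      channel = 1L,
                      waveform_template = NULL) {
  unit_type <- match.arg(unit_type)
  if (refractory_ms <= 0) stop("refractory_ms must be > 0", call. = FALSE)
  if (isi_peak_ms <= refractory_ms) {
    stop("isi_peak_ms must exceed the refractory period", call. = FALSE)
  }
  if (unit_type == "FS" && isi_peak_ms >= 10) {
    stop("FS units require isi_peak_ms < 10", call. = FALSE)
  }
  if (unit_type == "RS" && isi_peak_ms < 10) {
    stop("RS units require isi_peak_ms >= 10", call. = FALSE)
  }
  if (!all(state_levels() %in% names(base_rate))) {
    stop("base_rate must be named with all four states", call. = FALSE)
  }
  if (any(base_rate < 0)) stop("base_rate must be >= 0", call. = FALSE)
  if (!is.null(locking)) {
    locking <- tibble::as_tibble(locking)
    stopifnot(all(c("state", "band", "kappa", "preferred_phase") %in% names(locking)))
    assert_states(locking$state)
    band_edges(locking$band)
    if (any(locking$kappa < 0)) stop("kappa must be >= 0", call. = FALSE)
  }
  structure(
    list(
      unit_type = unit_type,
      base_rate = base_rate[state_levels()],
      refractory_ms = refractory_ms,
      isi_peak_ms = isi_peak_ms,
      locking = locking,
      channel = as.integer(channel),
      waveform_template = waveform_template
    ),
    class = "unit_spec"
  )
}

default_band_powers <- function(beta_center = 22.5) {
  # Relative narrowband oscillation amplitudes per state, shaped after the
  # qualitative spectral signatures of each behavioral state: strong delta in
  # NREM, elevated theta/alpha in REM, a beta peak while awake.
  m <- rbind(
    Move = c(delta = 0.8, theta = 0.8, alpha = 0.7, beta = 1.3,
             low_gamma = 1.30, high_gamma = 1.10),
    Rest = c(delta = 0.9, theta = 0.7, alpha = 1.0, beta = 2.0,
             low_gamma = 0.60, high_gamma = 0.50),
    REM  = c(delta = 1.0, theta = 1.7, alpha = 1.3, beta = 1.0,
             low_gamma = 0.60, high_gamma = 0.50),
    NREM = c(delta = 2.0, theta = 1.0, alpha = 0.9, beta = 0.8,
             low_gamma = 0.50, high_gamma = 0.45)
  )
  m
}

default_coupling_spec <- function() {
  tibble::tibble(
    state = c("NREM", "Move", "REM", "Rest"),
    low_band = c("delta", "delta", "theta", "delta"),
    high_band = c("high_gamma", "high_gamma", "beta", "alpha"),
    modulation_depth = c(0.6, 0.5, 0.5, 0.4),
    preferred_phase = c(pi, pi / 2, 0, 0)
  )
}

default_state_dwell <- function() {
  # min/max dwell in minutes per state; NREM/REM alternation gives nocturnal
  # cycles in the 30 min - 2 h range.
  tibble::tribble(
    ~state, ~min_minutes, ~max_minutes,
    "Move",  2,  20,
    "Rest",  2,  20,
    "REM",   4,  15,
    "NREM", 25,  75
  )
}

default_units <- function() {
  list(
    unit_spec("RS",
              base_rate = c(Move = 8, Rest = 6.5, REM = 5, NREM = 3.5),
              isi_peak_ms = 40, channel = 1L,
              locking = tibble::tibble(state = "NREM", band = "delta",
                                       kappa = 0.8, preferred_phase = pi)),
    unit_spec("RS",
              base_rate = c(Move = 10, Rest = 8, REM = 6, NREM = 4.5),
              isi_peak_ms = 25, channel = 2L,
              locking = tibble::tibble(state = c("NREM", "Move"),
                                       band = c("delta", "beta"),
                                       kappa = c(1.0, 0.4),
                                       preferred_phase = c(pi, pi))),
    unit_spec("FS",
              base_rate = c(Move = 20, Rest = 16, REM = 12, NREM = 8),
              refractory_ms = 1, isi_peak_ms = 6, channel = 1L,
              locking = tibble::tibble(state = "NREM", band = "delta",
                                       kappa = 1.0, preferred_phase = pi)),
    unit_spec("FS",
              base_rate = c(Move = 16, Rest = 13, REM = 10, NREM = 7),
              refractory_ms = 1, isi_peak_ms = 5, channel = 3L,
              locking = NULL)
  )
}

#' Configuration of a synthetic recording session
#'
#' Bundles every knob of the synthetic-session generator: session length and
#' stream rates, the lights-off interval that gates nocturnal NREM/REM
#' cycling, per-state dwell-time bounds, the state-by-band oscillation
#' amplitude table, planted phase-amplitude couplings, cross-channel shared
#' signal fraction, background 1/f exponent and the simulated units.
#'
#' @param session_hours Session length in hours (default 24).
#' @param lfp_rate LFP sample rate in Hz; signals are synthesized directly at
#'   the 1 kHz analysis rate by default.
#' @param n_channels Number of LFP channels (default 8).
#' @param accel_rate Accelerometer rate in Hz (default 100).
#' @param bin_s Epoch length in seconds (default 8).
#' @param lights_off Two-element numeric, hours into the session when lights
#'   are off. `NULL` (default) uses the second half of the session.
#' @param state_dwell Tibble with `state`, `min_minutes`, `max_minutes`.
#' @param band_powers 4 x 6 matrix (states x bands) of relative oscillation
#'   amplitudes; see `default_band_powers()`.
#' @param coupling_spec Tibble with `state`, `low_band`, `high_band`,
#'   `modulation_depth` in \[0, 1\] and `preferred_phase` (radians).
#' @param shared_fraction Fraction in \[0, 1\] of signal variance shared across
#'   channels; controls inter-channel coherence.
#' @param noise_exponent Exponent alpha of the 1/f^alpha background.
#' @param osc_scale Global amplitude scale of the band oscillations relative
#'   to the unit-RMS background.
#' @param beta_center Center frequency (Hz) of the beta carrier. Exposed
#'   because the wake beta peak location is animal-dependent.
#' @param nap_prob Probability that a daytime Rest bout is followed by a short
#'   REM nap.
#' @param awakening_prob Probability that a nocturnal NREM->REM transition is
#'   preceded by a brief Rest/Move awakening.
#' @param units List of [unit_spec()] objects (may be empty).
#' @param seed Integer seed; every generator derives its own deterministic
#'   sub-seed from it.
#'
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(session_hours = 2, n_channels = 2, units = list())
#' cfg$n_bins
sim_config <- function(session_hours = 24,
                       lfp_rate = 1000,
                       n_channels = 8,
                       accel_rate = 100,
                       bin_s = 8,
                       lights_off = NULL,
                       state_dwell = default_state_dwell(),
                       band_powers = default_band_powers(),
                       coupling_spec = default_coupling_spec(),
                       shared_fraction = 0.4,
                       noise_exponent = 1,
                       osc_scale = 0.35,
                       beta_center = 22.5,
                       nap_prob = 0.15,
                       awakening_prob = 0.25,
                       units = default_units(),
                       seed = 1L) {
  if (session_hours <= 0) stop("session_hours must be > 0", call. = FALSE)
  if (lfp_rate <= 0 || accel_rate <= 0 || bin_s <= 0) {
    stop("rates and bin_s must be > 0", call. = FALSE)
  }
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must be in [0, 1]", call. = FALSE)
  }
  lights_off <- lights_off %||% c(session_hours / 2, session_hours)
  if (length(lights_off) != 2 || lights_off[1] >= lights_off[2]) {
    stop("lights_off must be an increasing 2-vector of hours", call. = FALSE)
  }
  state_dwell <- tibble::as_tibble(state_dwell)
  assert_states(state_dwell$state)
  if (any(state_dwell$min_minutes > state_dwell$max_minutes)) {
    stop("state_dwell: min_minutes must not exceed max_minutes", call. = FALSE)
  }
  if (any(state_dwell$min_minutes <= 0)) {
    stop("state_dwell bounds must be positive", call. = FALSE)
  }
  stopifnot(is.matrix(band_powers))
  if (!all(rownames(band_powers) %in% state_levels()) ||
      !all(colnames(band_powers) %in% canonical_bands()$band)) {
    stop("band_powers must be a states x canonical-bands matrix", call. = FALSE)
  }
  coupling_spec <- tibble::as_tibble(coupling_spec)
  if (nrow(coupling_spec)) {
    assert_states(coupling_spec$state)
    lo <- band_edges(coupling_spec$low_band)
    hi <- band_edges(coupling_spec$high_band)
    if (any((lo$lo + lo$hi) / 2 >= (hi$lo + hi$hi) / 2)) {
      stop("coupling_spec: low_band center must be below high_band center",
           call. = FALSE)
    }
    if (any(coupling_spec$modulation_depth < 0 | coupling_spec$modulation_depth > 1)) {
      stop("modulation_depth must be in [0, 1]", call. = FALSE)
    }
  }
  for (u in units) stopifnot(inherits(u, "unit_spec"))
  if (length(units) && max(vapply(units, function(u) u$channel, 1L)) > n_channels) {
    stop("unit channel index exceeds n_channels", call. = FALSE)
  }

  n_bins <- floor(session_hours * 3600 / bin_s)
  structure(
    list(
      session_hours = session_hours,
      lfp_rate = lfp_rate,
      n_channels = as.integer(n_channels),
      accel_rate = accel_rate,
      bin_s = bin_s,
      lights_off = lights_off,
      state_dwell = state_dwell,
      band_powers = band_powers,
      coupling_spec = coupling_spec,
      shared_fraction = shared_fraction,
      noise_exponent = noise_exponent,
      osc_scale = osc_scale,
      beta_center = beta_center,
      nap_prob = nap_prob,
      awakening_prob = awakening_prob,
      units = units,
      seed = as.integer(seed),
      n_bins = n_bins
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$session_hours, " h, ", x$n_channels, " LFP ch @ ",
      x$lfp_rate, " Hz, ", x$n_bins, " bins of ", x$bin_s, " s, ",
      length(x$units), " units, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Carrier center frequency and half-bandwidth used for each band's
# narrowband-noise oscillation.
band_carriers <- function(cfg) {
  b <- canonical_bands()
  f0 <- c(delta = 2.25, theta = 6, alpha = 10, beta = cfg$beta_center,
          low_gamma = 50, high_gamma = 95)
  hw <- c(delta = 1.6, theta = 1.9, alpha = 1.9, beta = 6,
          low_gamma = 15, high_gamma = 18)
  tibble::tibble(band = b$band, f0 = unname(f0[b$band]), hw = unname(hw[b$band]))
}
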