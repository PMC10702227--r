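#' Generate a complete synthetic recording session
#'
#' Orchestrates the state-sequence, LFP, accelerometer, EOG and spike-train
#' generators into one in-memory session with ground-truth labels.
#' Deterministic: the same config (including its seed) always yields a
#' bit-identical session.
#'
#' @param cfg A [sim_config()].
#' @param eog Logical; also synthesize a 2-channel EOG-like stream whose
#'   variance is high awake, elevated in REM and low in NREM.
#' @return A `somn_session`: list with `lfp` (channels x samples), `accel`
#'   (3 x samples), optional `eog`, `rates`, `lights_off` (hours),
#'   `truth` (per-bin state tibble), `spike_times` (list, seconds per unit),
#'   `units`, `cfg` and `seed`.
#' @export
#' @examples
#' s <- generate_session(sim_config(session_hours = 1, n_channels = 2,
#'                                  units = list(), seed = 7))
#' dim(s$lfp)
generate_session <- function(cfg, eog = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  states <- generate_state_sequence(cfg)
  lfp <- synthesize_lfp(states, cfg)
  accel <- synthesize_accelerometer(states, cfg)
  eog_mat <- if (eog) synthesize_eog(states, cfg) else NULL
  spikes <- list()
  if (length(cfg$units)) {
    spikes <- lapply(seq_along(cfg$units), function(i) {
      synthesize_spike_train(states, lfp, cfg$units[[i]], cfg,
                             seed = sub_seed(cfg$seed, 1000L + i))
    })
    names(spikes) <- paste0("unit", seq_along(spikes))
  }
  structure(
    list(
      lfp = lfp,
      accel = accel,
      eog = eog_mat,
      rates = list(lfp = cfg$lfp_rate, accel = cfg$accel_rate, eog = 100),
      lights_off = cfg$lights_off,
      truth = states,
      spike_times = spikes,
      units = cfg$units,
      cfg = cfg,
      seed = cfg$seed
    ),
    class = "somn_session"
  )
}

# EOG-like stream: 1-20 Hz noise, variance very high awake, elevated in REM
# (rapid eye movements), low in NREM.
synthesize_eog <- function(states, cfg, seed = cfg$seed) {
  st <- states_vec(states)
  fs <- 100
  bin_len <- round(cfg$bin_s * fs)
  n <- length(st) * bin_len
  sds <- c(Move = 1, Rest = 0.8, REM = 0.5, NREM = 0.08)
  with_seed(sub_seed(seed, 55L), {
    env <- expand_bins(unname(sds[st]), bin_len, fade_len = fs)
    bf <- signal::butter(2, c(1, 20) / (fs / 2), type = "pass")
    rbind(signal::filtfilt(bf, rnorm(n)) * env,
          signal::filtfilt(bf, rnorm(n)) * env)
  })
}

#' @export
print.somn_session <- function(x, ...) {
  cat("<somn_session> ", x$cfg$session_hours, " h: ", nrow(x$lfp),
      " LFP ch @ ", x$rates$lfp, " Hz, ", length(x$spike_times),
      " unit(s), seed ", x$seed, "\n", sep = "")
  occ <- table(x$truth$state)
  cat("  truth occupancy: ",
      paste(names(occ), sprintf("%.1f%%", 100 * occ / sum(occ)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Streaming feature extraction for long sessions. The signal is synthesized
# in blocks of whole bins, one channel at a time, and each block-channel is
# immediately reduced to its per-bin Welch density. Because Welch segments
# never cross bin boundaries, block-wise synthesis yields exactly the same
# per-bin spectra as a single pass would, while peak memory stays at a few
# hundred MB regardless of session length.
session_features_streaming <- function(cfg, states = NULL,
                                       block_bins = 675L) {
  states <- states %||% generate_state_sequence(cfg)
  st <- states_vec(states)
  n_bins <- length(st)
  freqs <- NULL
  acc_psd <- NULL
  blocks <- split(seq_len(n_bins),
                  ceiling(seq_len(n_bins) / block_bins))
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    st_b <- st[idx]
    shared <- if (cfg$shared_fraction > 0) {
      synth_one_channel(st_b, cfg, sub_seed(cfg$seed, 65536L + b * 64L))
    } else NULL
    for (ch in seq_len(cfg$n_channels)) {
      lfp <- synthesize_lfp(st_b, cfg,
                            seed = sub_seed(cfg$seed, 65536L + b * 64L),
                            channels = ch, .shared = shared)
      est <- welch_psd_bins(lfp, fs = cfg$lfp_rate, bin_s = cfg$bin_s)
      rm(lfp)
      M <- est$psd[1, , ]
      if (is.null(acc_psd)) {
        freqs <- est$freqs
        acc_psd <- matrix(0, n_bins, length(freqs))
      }
      acc_psd[idx, ] <- acc_psd[idx, ] + M
    }
    rm(shared)
    gc(FALSE)
  }
  M <- acc_psd / cfg$n_channels
  features <- structure(
    list(freqs = freqs, X = normalize_feature_matrix(M, freqs),
         bin_s = cfg$bin_s),
    class = "somn_features"
  )
  accel <- synthesize_accelerometer(states, cfg)
  list(features = features, accel = accel, truth = states, cfg = cfg)
}
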