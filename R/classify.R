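#' Classify behavioral states for a whole session
#'
#' Runs the full unsupervised pipeline: (down)sampled LFP -> per-bin Welch
#' spectra -> channel-averaged normalized features -> stacked sparse
#' autoencoder -> 32-d latent code + accelerometer feature (33rd dimension)
#' -> k-means (k = 4) with outlier-excluded initialization -> rule-based
#' cluster-to-state assignment -> +/- 2-bin majority filter.
#'
#' `x` may be a [generate_session()] result or a [sim_config()]; in the
#' latter case the LFP is synthesized channel-by-channel and reduced to
#' spectral features on the fly, so day-long sessions do not need the full
#' multichannel signal in memory.
#'
#' @param x A `somn_session` or `sim_config`.
#' @param ae_cfg An [autoencoder_config()]; its seed is overridden by `seed`.
#' @param seed Integer seed driving autoencoder initialization, k-means
#'   restarts and majority-filter tie breaks.
#' @param ... Unused.
#' @return A `somn_classification`: per-bin tibble in `$states` (`bin`,
#'   `hour`, `cluster`, `state_raw`, `state`, and `truth` when available),
#'   plus the trained encoder, k-means fit, label map, features, per-state
#'   mean spectra, occupancy and low-occupancy flags.
#' @export
classify_session <- function(x, ae_cfg = autoencoder_config(), seed = 1L, ...) {
  UseMethod("classify_session")
}

#' @export
classify_session.somn_session <- function(x, ae_cfg = autoencoder_config(),
                                          seed = 1L, ...) {
  lfp <- x$lfp
  if (x$rates$lfp > 1000) lfp <- downsample_to_1khz(lfp, x$rates$lfp)
  est <- welch_psd_bins(lfp, fs = min(x$rates$lfp, 1000), bin_s = x$cfg$bin_s)
  features <- normalize_mean_psd(est)
  classify_features(features, x$accel, accel_rate = x$rates$accel,
                    bin_s = x$cfg$bin_s, ae_cfg = ae_cfg, seed = seed,
                    truth = x$truth$state)
}

#' @export
classify_session.sim_config <- function(x, ae_cfg = autoencoder_config(),
                                        seed = 1L, ...) {
  if (x$session_hours < 1) stop("session must be >= 1 h", call. = FALSE)
  sf <- session_features_streaming(x)
  classify_features(sf$features, sf$accel, accel_rate = x$accel_rate,
                    bin_s = x$bin_s, ae_cfg = ae_cfg, seed = seed,
                    truth = sf$truth$state)
}

# Core of the classifier, operating on precomputed features; shared by the
# session methods and k-fold validation.
classify_features <- function(features, accel, accel_rate = 100, bin_s = 8,
                              ae_cfg = autoencoder_config(), seed = 1L,
                              truth = NULL) {
  ae_cfg$seed <- sub_seed(seed, 11L)
  encoder <- train_autoencoder(features, ae_cfg)
  latent <- encode_features(encoder, features)
  accel_raw <- accelerometer_feature(accel, rate = accel_rate, bin_s = bin_s)
  n_bins <- nrow(latent)
  if (length(accel_raw) < n_bins) {
    stop("accelerometer does not cover all LFP bins", call. = FALSE)
  }
  accel_raw <- accel_raw[seq_len(n_bins)]
  accel_scaled <- scale_accel_column(accel_raw, latent)
  table33 <- cbind(latent, accel = accel_scaled)
  km <- kmeans_cluster(table33, k = 4, seed = sub_seed(seed, 12L))
  map <- label_clusters(km$cluster, features, accel_raw)
  raw_states <- unname(map[as.character(km$cluster)])
  smoothed <- majority_filter(raw_states, seed = sub_seed(seed, 13L))

  states <- tibble::tibble(
    bin = seq_len(n_bins),
    hour = (seq_len(n_bins) - 1) * bin_s / 3600,
    cluster = km$cluster,
    state_raw = raw_states,
    state = smoothed
  )
  if (!is.null(truth)) states$truth <- truth[seq_len(n_bins)]
  occupancy <- prop.table(table(factor(smoothed, levels = state_levels())))
  X <- feature_matrix(features)
  spectra <- lapply(setNames(state_levels(), state_levels()), function(s) {
    sel <- smoothed == s
    if (any(sel)) colMeans(X[sel, , drop = FALSE]) else rep(NA_real_, ncol(X))
  })
  structure(
    list(states = states, encoder = encoder, kmeans = km, label_map = map,
         features = features, accel_raw = accel_raw, latent = latent,
         occupancy = occupancy,
         state_spectra = spectra, freqs = features$freqs, bin_s = bin_s,
         low_occupancy = names(occupancy)[occupancy < 0.01],
         seed = seed, ae_cfg = ae_cfg),
    class = "somn_classification"
  )
}

scale_accel_column <- function(accel_raw, latent) {
  target <- max(apply(latent, 2, stats::sd))
  s <- stats::sd(accel_raw)
  if (s > 0) (accel_raw - mean(accel_raw)) / s * target else accel_raw - mean(accel_raw)
}

#' @export
print.somn_classification <- function(x, ...) {
  cat("<somn_classification> ", nrow(x$states), " bins of ", x$bin_s, " s\n",
      sep = "")
  occ <- x$occupancy
  cat("  occupancy: ", paste(names(occ), sprintf("%.1f%%", 100 * occ),
                             collapse = ", "), "\n", sep = "")
  if ("truth" %in% names(x$states)) {
    cat("  accuracy vs truth: ",
        sprintf("%.1f%%", 100 * mean(x$states$state == x$states$truth)), "\n",
        sep = "")
  }
  if (length(x$low_occupancy)) {
    cat("  low-occupancy labels (<1%): ",
        paste(x$low_occupancy, collapse = ", "),
        " -- state may be genuinely absent\n", sep = "")
  }
  invisible(x)
}

#' @method tidy somn_classification
#' @export
tidy.somn_classification <- function(x, ...) x$states

#' @method glance somn_classification
#' @export
glance.somn_classification <- function(x, ...) {
  out <- tibble::tibble(
    n_bins = nrow(x$states),
    move = unname(x$occupancy["Move"]),
    rest = unname(x$occupancy["Rest"]),
    rem = unname(x$occupancy["REM"]),
    nrem = unname(x$occupancy["NREM"]),
    final_loss = tail(x$encoder$loss, 1)
  )
  if ("truth" %in% names(x$states)) {
    out$accuracy <- mean(x$states$state == x$states$truth)
    rec <- vapply(state_levels(), function(s) {
      sel <- x$states$truth == s
      if (any(sel)) mean(x$states$state[sel] == s) else NA_real_
    }, 1.0)
    out$min_recall <- min(rec, na.rm = TRUE)
  }
  out
}

#' k-fold self-consistency validation of the classification
#'
#' Splits the bins into `k` random groups; for each fold the full pipeline
#' (autoencoder, accelerometer scaling, k-means, cluster labeling) is
#' retrained on the other k-1 groups and the held-out bins are assigned to
#' the nearest retrained centroid. Training error is the per-bin state
#' disagreement with the all-data classification on the training bins; test
#' error likewise on the held-out bins (states compared by name, so label
#' alignment follows the cluster-assignment rule, not cluster indices).
#' Repeated `reps` times with fresh random splits.
#'
#' @param fit A `somn_classification` from [classify_session()].
#' @param k Number of folds (default 20).
#' @param reps Bootstrap repetitions (default 50).
#' @param seed Integer seed.
#' @param fold_epochs Autoencoder epochs for the per-fold retraining. The
#'   reconstruction loss plateaus long before the 300 epochs used for the
#'   reference classification, so folds train shorter by default.
#' @return A `somn_validation`: per-fold tibble plus summary accessors
#'   ([glance()] reports mean errors in percent and total minutes).
#' @export
kfold_validate <- function(fit, k = 20, reps = 50, seed = 1L,
                           fold_epochs = 20) {
  stopifnot(inherits(fit, "somn_classification"))
  X <- feature_matrix(fit$features)
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of bins", call. = FALSE)
  ref <- fit$states$state_raw
  accel_raw <- fit$accel_raw
  rows <- list()
  for (r in seq_len(reps)) {
    groups <- with_seed(sub_seed(seed, 500L + r),
                        sample(rep(seq_len(k), length.out = n)))
    for (j in seq_len(k)) {
      test <- groups == j
      train <- !test
      # folds retrain with the reference run's own hyperparameters and
      # seeds: the cross-validation measures sensitivity to the held-out
      # data, not to re-randomized initializations
      ae_cfg <- fit$ae_cfg
      ae_cfg$epochs <- as.integer(fold_epochs)
      enc <- train_autoencoder(X[train, , drop = FALSE], ae_cfg)
      lat_tr <- encode_features(enc, X[train, , drop = FALSE])
      mu <- mean(accel_raw[train])
      s <- stats::sd(accel_raw[train])
      target <- max(apply(lat_tr, 2, stats::sd))
      af <- if (s > 0) (accel_raw - mu) / s * target else accel_raw - mu
      tab_tr <- cbind(lat_tr, accel = af[train])
      km <- kmeans_cluster(tab_tr, k = 4, seed = sub_seed(fit$seed, 12L))
      map <- label_clusters(km$cluster,
                            structure(list(X = X[train, , drop = FALSE],
                                           freqs = fit$freqs),
                                      class = "somn_features"),
                            accel_raw[train])
      st_tr <- unname(map[as.character(km$cluster)])
      lat_te <- encode_features(enc, X[test, , drop = FALSE])
      cl_te <- nearest_center(cbind(lat_te, accel = af[test]), km$centers)
      st_te <- unname(map[as.character(cl_te)])
      rows[[length(rows) + 1]] <- tibble::tibble(
        rep = r, fold = j,
        train_error = mean(st_tr != ref[train]),
        test_error = mean(st_te != ref[test]),
        n_train = sum(train), n_test = sum(test)
      )
    }
  }
  structure(
    list(folds = dplyr::bind_rows(rows), k = k, reps = reps,
         n_bins = n, bin_s = fit$bin_s),
    class = "somn_validation"
  )
}

#' @export
print.somn_validation <- function(x, ...) {
  g <- glance(x)
  cat("<somn_validation> k = ", x$k, ", reps = ", x$reps, "\n", sep = "")
  cat(sprintf("  mean training error: %.2f%% (%.1f min)\n",
              g$train_error_pct, g$train_error_minutes))
  cat(sprintf("  mean test error:     %.2f%% (%.1f min)\n",
              g$test_error_pct, g$test_error_minutes))
  invisible(x)
}

#' @method tidy somn_validation
#' @export
tidy.somn_validation <- function(x, ...) x$folds

#' @method glance somn_validation
#' @export
glance.somn_validation <- function(x, ...) {
  total_min <- x$n_bins * x$bin_s / 60
  tibble::tibble(
    k = x$k, reps = x$reps,
    train_error_pct = 100 * mean(x$folds$train_error),
    test_error_pct = 100 * mean(x$folds$test_error),
    train_error_minutes = mean(x$folds$train_error) * total_min,
    test_error_minutes = mean(x$folds$test_error) * total_min
  )
}
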