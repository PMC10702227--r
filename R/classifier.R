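#' Per-bin accelerometer feature
#'
#' Root-sum-of-squares across the three axes, per-bin variance, log10
#' compression, and (when a latent matrix is supplied) centering to zero mean
#' with the column standard deviation rescaled to the largest latent-column
#' standard deviation, so the accelerometer can join the latent space as its
#' 33rd dimension on a comparable scale.
#'
#' @param accel 3 x samples accelerometer matrix.
#' @param rate Accelerometer rate, Hz.
#' @param bin_s Bin length in seconds.
#' @param latent Optional bins x latent matrix; when given, the returned
#'   column is centered and rescaled as above.
#' @return Numeric vector, one value per bin. Attribute `floored` flags bins
#'   whose variance was zero and was floored before the log.
#' @export
accelerometer_feature <- function(accel, rate = 100, bin_s = 8, latent = NULL) {
  stopifnot(is.matrix(accel), nrow(accel) == 3)
  rss <- sqrt(colSums(accel^2))
  bin_len <- round(bin_s * rate)
  n_bins <- floor(length(rss) / bin_len)
  if (!is.null(latent) && nrow(latent) != n_bins) {
    stop("accel does not cover the same bins as the latent matrix", call. = FALSE)
  }
  v <- apply(matrix(rss[seq_len(n_bins * bin_len)], bin_len), 2, stats::var)
  floored <- v <= 0
  v[floored] <- .Machine$double.eps
  lv <- log10(v)
  if (!is.null(latent)) {
    target <- max(apply(latent, 2, stats::sd))
    s <- stats::sd(lv)
    lv <- if (s > 0) (lv - mean(lv)) / s * target else lv - mean(lv)
  }
  attr(lv, "floored") <- which(floored)
  lv
}

# k-means++ seeding within a candidate matrix.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    i <- sample.int(n, 1, prob = p)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

nearest_center <- function(x, centers) {
  cross <- x %*% t(centers)
  d2 <- outer(rowSums(x^2), rowSums(centers^2), `+`) - 2 * cross
  max.col(-d2, ties.method = "first")
}

#' k-means clustering with outlier-excluded initialization
#'
#' Centroids are fit on the subset of points whose mean pairwise Euclidean
#' distance to all points is at or below the 90th percentile (outliers are
#' excluded from centroid finding), using k-means++ seeding and Lloyd
#' iterations with multiple restarts (best inertia kept). Every point --
#' including excluded outliers -- is then assigned to its nearest centroid.
#'
#' @param x Numeric matrix (bins x dimensions), e.g. a latent table.
#' @param k Number of clusters (default 4).
#' @param seed Integer seed.
#' @param restarts Number of k-means++ restarts (default 10).
#' @param percentile Inclusion percentile for initialization (default 0.9).
#' @return A `somn_kmeans`: list with `cluster` (per row), `centers`,
#'   `inertia` and `init_included` (logical per row).
#' @export
kmeans_cluster <- function(x, k = 4, seed = 1L, restarts = 10,
                           percentile = 0.9) {
  x <- as.matrix(x)
  if (k > nrow(unique(x))) stop("k exceeds the number of distinct points",
                                call. = FALSE)
  mpd <- mean_pairwise_dist_cpp(x)
  keep <- mpd <= stats::quantile(mpd, percentile)
  xs <- x[keep, , drop = FALSE]
  best <- NULL
  # restarts are compared by inertia on the initialization subset: points
  # excluded as outliers do not steer the solution choice either
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- kmeanspp_centers(xs, k)
      km <- tryCatch(
        stats::kmeans(xs, centers = init, iter.max = 100,
                      algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) {
          suppressWarnings(stats::kmeans(xs, centers = init, iter.max = 100,
                                         algorithm = "Lloyd"))
        })
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  if (is.null(best)) stop("k-means failed on all restarts", call. = FALSE)
  structure(
    list(cluster = nearest_center(x, best$centers), centers = best$centers,
         inertia = best$tot.withinss, init_included = keep),
    class = "somn_kmeans"
  )
}

#' Assign behavioral states to clusters
#'
#' Sequential argmax with removal: the cluster with the highest mean
#' accelerometer feature becomes Move; of the remainder, the highest mean
#' delta (0.5-4 Hz) power becomes NREM; of the remainder, the highest mean
#' beta (15-30 Hz) power becomes Rest; the last cluster is REM.
#'
#' @param clusters Integer cluster id per bin (exactly 4 distinct values).
#' @param features `somn_features` (or bins x freqs matrix with frequencies
#'   attached via `freqs`).
#' @param accel_feature Numeric per-bin accelerometer feature.
#' @param freqs Frequency grid (taken from `features` when omitted).
#' @return Named character vector: state per cluster id (names = cluster id),
#'   with attribute `rule_order` recording the assignment sequence.
#' @export
label_clusters <- function(clusters, features, accel_feature, freqs = NULL) {
  X <- feature_matrix(features)
  freqs <- freqs %||% features$freqs
  ids <- sort(unique(clusters))
  if (length(ids) != 4) stop("exactly 4 non-empty clusters required", call. = FALSE)
  delta <- band_edges("delta")
  beta <- band_edges("beta")
  dsel <- freqs >= delta$lo & freqs <= delta$hi
  bsel <- freqs >= beta$lo & freqs <= beta$hi
  stats_tbl <- vapply(ids, function(id) {
    sel <- clusters == id
    c(accel = mean(accel_feature[sel]),
      delta = mean(X[sel, dsel]),
      beta = mean(X[sel, bsel]))
  }, c(accel = 0, delta = 0, beta = 0))
  remaining <- seq_along(ids)
  map <- character(length(ids))
  pick <- function(row) remaining[which.max(stats_tbl[row, remaining])]
  i <- pick("accel"); map[i] <- "Move"; remaining <- setdiff(remaining, i)
  i <- pick("delta"); map[i] <- "NREM"; remaining <- setdiff(remaining, i)
  i <- pick("beta");  map[i] <- "Rest"; remaining <- setdiff(remaining, i)
  map[remaining] <- "REM"
  names(map) <- ids
  attr(map, "rule_order") <- c("Move", "NREM", "Rest", "REM")
  map
}

#' Majority-filter a state sequence
#'
#' Sliding 5-bin (+/- 2 bins, i.e. +/- 16 s for 8-s bins) majority vote.
#' Windows are truncated at the sequence ends. Ties keep the original
#' classification when it is part of the tie, otherwise a seeded random
#' choice among the tied states.
#'
#' @param states Character vector of per-bin states.
#' @param half_width Bins on each side (default 2).
#' @param seed Integer seed for tie breaking.
#' @return Character vector, same length.
#' @export
majority_filter <- function(states, half_width = 2, seed = 1L) {
  n <- length(states)
  out <- states
  with_seed(seed, {
    for (i in seq_len(n)) {
      w <- states[max(1, i - half_width):min(n, i + half_width)]
      counts <- table(w)
      top <- names(counts)[counts == max(counts)]
      if (length(top) == 1) {
        out[i] <- top
      } else if (states[i] %in% top) {
        out[i] <- states[i]
      } else {
        out[i] <- sample(top, 1)
      }
    }
  })
  out
}
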