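#' Friedman test with rank-based Tukey post-hoc comparisons
#'
#' Compares a measure across the four states with Friedman's test (paired,
#' non-parametric: the same channels/units are sampled in every state),
#' followed by all-pairs comparisons of mean ranks against the studentized
#' range distribution (Nemenyi/Tukey-style honest significant differences):
#' `q = |R_i - R_j| / sqrt(k (k+1) / (12 n))`, `p = ptukey(q, k, Inf)`.
#'
#' @param values Numeric matrix or data frame, rows = paired observations
#'   (channels/units), columns = the four states. No missing cells.
#' @param measure Optional name of the measure being compared.
#' @param alpha Significance level for flagging pairs (default 0.05).
#' @return A `somn_comparison`: Friedman chi-squared and p, mean ranks, and
#'   a pairwise tibble (`state_a`, `state_b`, `q`, `p_value`, `significant`).
#' @export
friedman_with_posthoc <- function(values, measure = NULL, alpha = 0.05) {
  values <- as.matrix(values)
  if (ncol(values) != 4) {
    stop("paired design across exactly 4 states required", call. = FALSE)
  }
  if (nrow(values) < 5) stop("need at least 5 paired rows", call. = FALSE)
  if (anyNA(values)) stop("missing cells: paired design required", call. = FALSE)
  if (is.null(colnames(values))) colnames(values) <- state_levels()
  ft <- stats::friedman.test(values)
  k <- ncol(values)
  n <- nrow(values)
  ranks <- t(apply(values, 1, rank))
  mean_ranks <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (12 * n))
  pairs <- utils::combn(colnames(values), 2)
  posthoc <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    q <- abs(mean_ranks[a] - mean_ranks[b]) / se
    p <- stats::ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
    tibble::tibble(state_a = a, state_b = b, q = unname(q),
                   p_value = unname(p), significant = p < alpha)
  })
  structure(
    list(measure = measure, values = values,
         friedman_chi2 = unname(ft$statistic), friedman_p = ft$p.value,
         mean_ranks = mean_ranks, posthoc = posthoc, alpha = alpha),
    class = "somn_comparison"
  )
}

#' @export
print.somn_comparison <- function(x, ...) {
  cat("<somn_comparison>", if (!is.null(x$measure)) x$measure else "", "\n")
  cat(sprintf("  Friedman chi^2 = %.3f, p = %.3g (n = %d rows)\n",
              x$friedman_chi2, x$friedman_p, nrow(x$values)))
  sig <- x$posthoc[x$posthoc$significant, ]
  if (nrow(sig)) {
    cat("  significant pairs: ",
        paste(sig$state_a, "vs", sig$state_b, collapse = ", "), "\n")
  } else {
    cat("  no significant pairwise differences\n")
  }
  invisible(x)
}

#' @method tidy somn_comparison
#' @export
tidy.somn_comparison <- function(x, ...) x$posthoc

#' @method glance somn_comparison
#' @export
glance.somn_comparison <- function(x, ...) {
  tibble::tibble(measure = x$measure %||% NA_character_,
                 friedman_chi2 = x$friedman_chi2,
                 friedman_p = x$friedman_p,
                 n_rows = nrow(x$values),
                 n_significant_pairs = sum(x$posthoc$significant))
}

values_by_state <- function(tbl, row_var, value_var) {
  wide <- tidyr::pivot_wider(tbl[, c(row_var, "state", value_var)],
                             names_from = "state",
                             values_from = dplyr::all_of(value_var))
  wide <- wide[, c(row_var, intersect(state_levels(), names(wide)))]
  m <- as.matrix(wide[, -1])
  rownames(m) <- as.character(wide[[1]])
  m
}

#' Run the full analysis pipeline on a synthetic session
#'
#' simulate -> classify -> (optionally) cross-validate -> per-state
#' coherence -> phase-amplitude coupling -> unit profiles and rates ->
#' spike-field phase locking -> state-wise Friedman comparisons. Optionally
#' writes CSV/JSON outputs.
#'
#' @param cfg A [sim_config()] (or an existing `somn_session`).
#' @param seed Analysis seed (classifier, validation, tie breaks).
#' @param validate Logical: run [kfold_validate()] (k = 20)?
#' @param validate_reps Repetitions for the validation step.
#' @param coherence_pairs Maximum number of channel pairs for the per-state
#'   coherence summary (pairs are taken in order).
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @return A `somn_results` list: `session`, `classification`, `validation`,
#'   `coherence`, `coupling`, `units`, `phase_locking`, `comparisons`.
#' @export
run_pipeline <- function(cfg, seed = 1L, validate = FALSE, validate_reps = 5,
                         coherence_pairs = 6, out_dir = NULL) {
  session <- if (inherits(cfg, "somn_session")) cfg else generate_session(cfg)
  fit <- classify_session(session, seed = seed)
  states <- fit$states$state
  validation <- if (validate) {
    kfold_validate(fit, k = 20, reps = validate_reps, seed = seed)
  } else NULL

  # per-state mean coherence over a subset of channel pairs
  fs <- session$rates$lfp
  bin_len <- round(session$cfg$bin_s * fs)
  st_samples <- rep(states, each = bin_len)[seq_len(ncol(session$lfp))]
  prs <- utils::combn(nrow(session$lfp), 2)
  prs <- prs[, seq_len(min(ncol(prs), coherence_pairs)), drop = FALSE]
  coherence <- purrr::map_dfr(seq_len(ncol(prs)), function(i) {
    purrr::map_dfr(intersect(state_levels(), unique(states)), function(s) {
      co <- tryCatch(
        magnitude_squared_coherence(session$lfp[prs[1, i], ],
                                    session$lfp[prs[2, i], ],
                                    fs = fs, state_mask = st_samples == s),
        error = function(e) NULL)
      if (is.null(co)) return(NULL)
      dplyr::mutate(co, chan_a = prs[1, i], chan_b = prs[2, i], state = s)
    })
  })

  coupling <- session_coupling(session$lfp, states, fs = fs,
                               bin_s = session$cfg$bin_s)

  units <- purrr::map_dfr(seq_along(session$spike_times), function(u) {
    tm <- session$spike_times[[u]]
    prof <- isi_profile(tm)
    mods <- state_rate_modulation(tm, states, bin_s = session$cfg$bin_s)
    tibble::tibble(unit = names(session$spike_times)[u],
                   true_class = session$units[[u]]$unit_type,
                   unit_class = prof$unit_class,
                   isi_peak_ms = prof$isi_peak_ms,
                   n_spikes = length(tm),
                   rate_move = mods$rate_hz[mods$state == "Move"],
                   rate_rest = mods$rate_hz[mods$state == "Rest"],
                   rate_rem = mods$rate_hz[mods$state == "REM"],
                   rate_nrem = mods$rate_hz[mods$state == "NREM"])
  })

  plv <- if (length(session$spike_times)) {
    session_phase_locking(session, states = states)
  } else tibble::tibble()

  comparisons <- list()
  if (nrow(coupling)) {
    for (p in split(coupling, paste(coupling$low_band, coupling$high_band,
                                    sep = "->"))) {
      if (length(unique(p$state)) == 4 && nrow(p) >= 4 * 5) {
        m <- values_by_state(p, "channel", "nmvl")
        if (!anyNA(m)) {
          nm <- paste0("nmvl ", p$low_band[1], "->", p$high_band[1])
          comparisons[[nm]] <- friedman_with_posthoc(m, measure = nm)
        }
      }
    }
  }

  res <- structure(
    list(session = session, classification = fit, validation = validation,
         coherence = coherence, coupling = coupling, units = units,
         phase_locking = plv, comparisons = comparisons, seed = seed),
    class = "somn_results"
  )
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' @export
print.somn_results <- function(x, ...) {
  cat("<somn_results>\n")
  print(x$classification)
  if (!is.null(x$validation)) print(x$validation)
  cat("  coupling rows: ", nrow(x$coupling), "; units: ", nrow(x$units),
      "; PLV rows: ", nrow(x$phase_locking), "; comparisons: ",
      length(x$comparisons), "\n", sep = "")
  invisible(x)
}

#' Write pipeline results as CSV/JSON
#'
#' @param res A `somn_results` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$classification$states,
                   file.path(out_dir, "states.csv"), row.names = FALSE)
  if (nrow(res$coherence)) {
    utils::write.csv(res$coherence, file.path(out_dir, "coherence.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(res$coupling, file.path(out_dir, "cfc.csv"),
                   row.names = FALSE)
  if (nrow(res$units)) {
    utils::write.csv(res$units, file.path(out_dir, "units.csv"),
                     row.names = FALSE)
  }
  if (nrow(res$phase_locking)) {
    utils::write.csv(res$phase_locking, file.path(out_dir, "plv.csv"),
                     row.names = FALSE)
  }
  summary <- list(
    seed = res$seed,
    occupancy = as.list(res$classification$occupancy),
    validation = if (!is.null(res$validation)) {
      as.list(glance(res$validation))
    },
    comparisons = lapply(res$comparisons, function(cmp) as.list(glance(cmp)))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
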