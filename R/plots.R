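#' Hypnogram and occupancy plot of a classification
#'
#' @param object A `somn_classification`.
#' @param ... Unused.
#' @return A ggplot: per-bin state over session time.
#' @method autoplot somn_classification
#' @export
autoplot.somn_classification <- function(object, ...) {
  df <- object$states
  df$state <- factor(df$state, levels = rev(state_levels()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$state)) +
    ggplot2::geom_step(ggplot2::aes(group = 1), linewidth = 0.3) +
    ggplot2::labs(x = "time (h)", y = NULL, title = "Classified states") +
    ggplot2::theme_minimal()
}

#' Per-state mean spectra of a classified session
#'
#' @param fit A `somn_classification`.
#' @return A ggplot of normalized mean power by frequency, one line per state.
#' @export
plot_state_spectra <- function(fit) {
  stopifnot(inherits(fit, "somn_classification"))
  df <- purrr::map_dfr(names(fit$state_spectra), function(s) {
    tibble::tibble(state = s, freq = fit$freqs, power = fit$state_spectra[[s]])
  })
  df <- df[is.finite(df$power), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$freq, .data$power,
                                   color = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "normalized power",
                  title = "State-wise mean spectra") +
    ggplot2::theme_minimal()
}

#' Tile plot of normalized MVL by band pair and state
#'
#' @param coupling Output of [session_coupling()].
#' @return A ggplot: median nmvl per (low band, high band), faceted by state.
#' @export
plot_coupling <- function(coupling) {
  df <- dplyr::summarise(
    dplyr::group_by(coupling, .data$state, .data$low_band, .data$high_band),
    nmvl = median(.data$nmvl), .groups = "drop")
  bl <- canonical_bands()$band
  df$low_band <- factor(df$low_band, levels = bl)
  df$high_band <- factor(df$high_band, levels = bl)
  ggplot2::ggplot(df, ggplot2::aes(.data$low_band, .data$high_band,
                                   fill = .data$nmvl)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~state) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "phase band", y = "amplitude band",
                  title = "Phase-amplitude coupling (nMVL)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Validation error distributions
#'
#' @param object A `somn_validation`.
#' @param ... Unused.
#' @return A ggplot of per-fold training/test error.
#' @method autoplot somn_validation
#' @export
autoplot.somn_validation <- function(object, ...) {
  df <- tidyr::pivot_longer(object$folds, c("train_error", "test_error"),
                            names_to = "kind", values_to = "error")
  ggplot2::ggplot(df, ggplot2::aes(.data$kind, 100 * .data$error)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "error (%)",
                  title = "k-fold self-consistency") +
    ggplot2::theme_minimal()
}

#' Phase-locking summary plot
#'
#' @param plv Output of [session_phase_locking()].
#' @return A ggplot of PLV by band and state, one point per unit.
#' @export
plot_phase_locking <- function(plv) {
  plv$band <- factor(plv$band, levels = canonical_bands()$band)
  plv$state <- factor(plv$state, levels = state_levels())
  ggplot2::ggplot(plv, ggplot2::aes(.data$state, .data$plv,
                                    color = .data$unit_class)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.15),
                        alpha = 0.7) +
    ggplot2::facet_wrap(~band) +
    ggplot2::labs(x = NULL, y = "PLV", color = "class",
                  title = "Spike-field phase locking") +
    ggplot2::theme_minimal()
}
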