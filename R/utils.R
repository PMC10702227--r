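#' Canonical frequency bands
#'
#' The six bands used throughout the package: delta (0.5-4 Hz), theta (4-8),
#' alpha (8-12), beta (15-30), low gamma (30-70) and high gamma (70-120).
#'
#' @return A tibble with columns `band`, `lo`, `hi` (Hz).
#' @export
#' @examples
#' canonical_bands()
canonical_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "low_gamma", "high_gamma"),
    lo   = c(0.5, 4, 8, 15, 30, 70),
    hi   = c(4, 8, 12, 30, 70, 120)
  )
}

band_edges <- function(band) {
  b <- canonical_bands()
  i <- match(band, b$band)
  if (any(is.na(i))) {
    stop("unknown band name(s): ", paste(band[is.na(i)], collapse = ", "),
         "; valid bands are ", paste(b$band, collapse = ", "), call. = FALSE)
  }
  b[i, , drop = FALSE]
}

state_levels <- function() c("Move", "Rest", "REM", "NREM")

#' @noRd
assert_states <- function(states) {
  if (!all(states %in% state_levels())) {
    stop("state labels must be one of ", paste(state_levels(), collapse = ", "),
         call. = FALSE)
  }
  invisible(states)
}

# Deterministic sub-seed derivation: keeps all derived seeds < 2^31 and spreads
# consecutive (seed, i) pairs across the integer range.
sub_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647 * 7919 + i * 104729) %% 2147483629 + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Trapezoidal integral on an arbitrary grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

wrap_2pi <- function(phi) phi %% (2 * pi)

hann <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))

`%||%` <- function(a, b) if (is.null(a)) b else a
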