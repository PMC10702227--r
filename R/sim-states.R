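#' Generate a semi-Markov behavioral state sequence
#'
#' Produces a per-bin sequence over the four states (Move, Rest, REM, NREM) on
#' the configured epoch grid. During lights-off the sequence alternates
#' NREM/REM bouts (with dwell times drawn uniformly from the configured
#' per-state bounds), yielding nocturnal sleep cycles in the tens-of-minutes
#' to hours range, interrupted by occasional brief Rest/Move awakenings.
#' During lights-on the animal alternates Move/Rest bouts with optional short
#' REM naps after rest.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; defaults to the config seed.
#'
#' @return A tibble with one row per bin: `bin`, `hour` (bin start, hours into
#'   the session), `lights_off` (logical) and `state`.
#' @export
#' @examples
#' st <- generate_state_sequence(sim_config(session_hours = 6, units = list()))
#' table(st$state)
generate_state_sequence <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$session_hours < 1) stop("session_hours must be >= 1", call. = FALSE)
  dw <- cfg$state_dwell
  if (any(dw$min_minutes > dw$max_minutes)) {
    stop("state_dwell bounds inverted", call. = FALSE)
  }
  bins_per_min <- 60 / cfg$bin_s
  dwell_bins <- function(state) {
    r <- dw[dw$state == state, ]
    mins <- runif(1, r$min_minutes, r$max_minutes)
    max(1L, as.integer(round(mins * bins_per_min)))
  }
  n <- cfg$n_bins
  hour_of <- function(bin) (bin - 1) * cfg$bin_s / 3600
  is_night <- function(bin) {
    h <- hour_of(bin)
    h >= cfg$lights_off[1] && h < cfg$lights_off[2]
  }

  states <- character(n)
  with_seed(seed, {
    pos <- 1L
    # phase tracks position inside the nocturnal cycle
    night_next <- "NREM"
    day_next <- "Move"
    while (pos <= n) {
      if (is_night(pos)) {
        st <- night_next
        len <- dwell_bins(st)
        if (st == "NREM") {
          night_next <- "REM"
        } else {
          # after REM: possibly a brief awakening before the next NREM bout
          if (runif(1) < cfg$awakening_prob) {
            st_aw <- if (runif(1) < 0.2) "Move" else "Rest"
            end <- min(n, pos + len - 1L)
            states[pos:end] <- st
            pos <- end + 1L
            if (pos > n) break
            len <- max(1L, as.integer(round(runif(1, 0.5, 3) * bins_per_min)))
            st <- st_aw
          }
          night_next <- "NREM"
        }
        end <- min(n, pos + len - 1L)
        states[pos:end] <- st
        pos <- end + 1L
      } else {
        st <- day_next
        len <- dwell_bins(st)
        day_next <- if (st == "Move") "Rest" else "Move"
        end <- min(n, pos + len - 1L)
        states[pos:end] <- st
        pos <- end + 1L
        if (st == "Rest" && pos <= n && !is_night(pos) &&
            runif(1) < cfg$nap_prob) {
          len <- max(1L, as.integer(round(runif(1, 2, 8) * bins_per_min)))
          end <- min(n, pos + len - 1L)
          states[pos:end] <- "REM"
          pos <- end + 1L
        }
      }
    }
  })
  bin <- seq_len(n)
  tibble::tibble(
    bin = bin,
    hour = (bin - 1) * cfg$bin_s / 3600,
    lights_off = vapply(bin, is_night, logical(1)),
    state = states
  )
}
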