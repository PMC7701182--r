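#' @keywords internal
abort_crd <- function(msg, class = "crd_error") {
  stop(errorCondition(msg, class = c(class, "crd_error")))
}

#' Game configuration for a collective risk dilemma
#'
#' Bundles all game-level constants of one treatment of the multi-round
#' threshold public goods game: `N` players each start with an endowment of
#' `E` monetary units and can contribute one of `actions` units per round.
#' If the group's cumulative contribution reaches the collective threshold
#' `tau` before the game ends, every player keeps the remainder of their
#' endowment; otherwise each loses that remainder with probability `r`.
#' The ending round is random: rounds `1..m0` are always played, and after
#' round `m0` (and after every later round) the game stops with probability
#' `w`, so the length is `m0` plus a geometric tail.
#'
#' The fair share `F = E/2` — the equal per-player total that exactly meets
#' the threshold when everyone gives it — is always derived from `E`, never
#' stored; use [fair_share()].
#'
#' @param N group size (players), at least 2.
#' @param E initial endowment per player (monetary units).
#' @param actions ordered set of allowed per-round contributions; must
#'   include 0.
#' @param tau collective threshold (monetary units).
#' @param r risk: probability of losing the remaining endowment when the
#'   threshold is missed, in \[0, 1\].
#' @param m0 first round at which the game may end (the game always runs at
#'   least `m0` rounds).
#' @param w per-check termination probability after round `m0`, in (0, 1\].
#'   `w = 1` gives a fixed-length game of exactly `m0` rounds.
#'
#' @return An object of class `crd_config`.
#' @seealso [treatment_config()] for the shipped presets.
#' @examples
#' cfg <- game_config()          # the no-uncertainty baseline
#' fair_share(cfg)               # 20
#' @export
game_config <- function(N = 6, E = 40, actions = c(0, 2, 4), tau = 120,
                        r = 0.9, m0 = 10, w = 1) {
  if (!is.numeric(N) || length(N) != 1 || N < 2 || N != round(N))
    abort_crd("N must be a single integer >= 2", "crd_config_error")
  if (!is.numeric(E) || length(E) != 1 || E <= 0)
    abort_crd("E must be a single positive number", "crd_config_error")
  if (!is.numeric(actions) || length(actions) < 1 || any(actions < 0) ||
      !(0 %in% actions))
    abort_crd("actions must be non-negative and include 0", "crd_config_error")
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0)
    abort_crd("tau must be a single positive number", "crd_config_error")
  if (!is.numeric(r) || length(r) != 1 || r < 0 || r > 1)
    abort_crd("r must be a probability in [0, 1]", "crd_config_error")
  if (!is.numeric(m0) || length(m0) != 1 || m0 < 1 || m0 != round(m0))
    abort_crd("m0 must be a single integer >= 1", "crd_config_error")
  if (!is.numeric(w) || length(w) != 1 || w <= 0 || w > 1)
    abort_crd("w must be a probability in (0, 1]", "crd_config_error")
  structure(
    list(N = as.integer(N), E = E, actions = sort(unique(actions)),
         tau = tau, r = r, m0 = as.integer(m0), w = w),
    class = "crd_config"
  )
}

#' Treatment presets
#'
#' The three timing-uncertainty treatments: `NU` (no uncertainty, fixed 10
#' rounds), `LU` (low uncertainty, `m0 = 8`, `w = 1/3`) and `HU` (high
#' uncertainty, `m0 = 6`, `w = 1/5`). All three have a mean length of 10
#' rounds; the treatments differ only in the variance of the ending round.
#'
#' @param treatment one of `"NU"`, `"LU"`, `"HU"`.
#' @param ... overrides passed on to [game_config()].
#' @return A `crd_config`.
#' @examples
#' treatment_config("HU")
#' @export
treatment_config <- function(treatment = c("NU", "LU", "HU"), ...) {
  treatment <- match.arg(treatment)
  preset <- switch(treatment,
    NU = list(m0 = 10, w = 1),
    LU = list(m0 = 8,  w = 1 / 3),
    HU = list(m0 = 6,  w = 1 / 5)
  )
  args <- utils::modifyList(preset, list(...))
  do.call(game_config, args)
}

#' Fair share
#'
#' Half the endowment, `E/2`: the per-player total that exactly meets the
#' threshold when all `N` players give it (with the default parameters,
#' `6 * 20 = 120 = tau`).
#'
#' @param config a `crd_config`.
#' @return The fair share in monetary units.
#' @export
fair_share <- function(config) {
  stopifnot(inherits(config, "crd_config"))
  config$E / 2
}

#' @export
print.crd_config <- function(x, ...) {
  cat("Collective risk dilemma configuration\n")
  cat(sprintf("  N = %d players, endowment E = %g, actions {%s}\n",
              x$N, x$E, paste(x$actions, collapse = ", ")))
  cat(sprintf("  threshold tau = %g, risk r = %g\n", x$tau, x$r))
  cat(sprintf("  timing: m0 = %d, w = %.4g (mean length %.4g rounds)\n",
              x$m0, x$w, expected_rounds(x$m0, x$w)))
  invisible(x)
}
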