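#' Distribution of the ending round
#'
#' Rounds `1..m0` are always played; after round `m0` and after each later
#' round the game stops with probability `w`. The ending round `M` therefore
#' satisfies `P(M = m0 + k) = w * (1 - w)^k` for `k >= 0` (a shifted
#' geometric distribution). Masses at rounds `>= tail_round` are aggregated
#' analytically into `tail_mass = (1 - w)^(tail_round - m0)` rather than
#' truncated, so the returned object always carries total mass exactly 1.
#'
#' `tail_round` is typically the round from which play is provably static
#' (see [static_round()]): beyond it the game's outcome no longer depends on
#' the exact ending round, so one aggregated mass suffices for exact
#' expectations.
#'
#' @param m0 first round at which the game may end (integer >= 1).
#' @param w per-check termination probability in (0, 1].
#' @param tail_round round at and beyond which probability mass is
#'   aggregated; defaults to `m0 + 40`. Values below `m0` are treated
#'   as `m0` (all mass in the tail).
#' @return An object of class `crd_termination` with fields `rounds`
#'   (explicit support `m0 .. tail_round - 1`), `probs`, `tail_round`,
#'   `tail_mass`, `m0`, `w`.
#' @examples
#' termination_distribution(8, 1/3)   # LU: P(8) = 1/3, P(9) = 2/9, ...
#' termination_distribution(10, 1)    # NU: point mass at round 10
#' @export
termination_distribution <- function(m0, w, tail_round = m0 + 40) {
  if (!is.numeric(m0) || length(m0) != 1 || m0 < 1 || m0 != round(m0))
    abort_crd("m0 must be a single integer >= 1", "crd_config_error")
  if (!is.numeric(w) || length(w) != 1 || w <= 0 || w > 1)
    abort_crd("w must be a probability in (0, 1]", "crd_config_error")
  tail_round <- max(as.integer(tail_round), as.integer(m0))
  rounds <- if (tail_round > m0) seq.int(m0, tail_round - 1L) else integer(0)
  probs <- w * (1 - w)^(rounds - m0)
  structure(
    list(rounds = rounds, probs = probs,
         tail_round = tail_round,
         tail_mass = (1 - w)^(tail_round - m0),
         m0 = as.integer(m0), w = w),
    class = "crd_termination"
  )
}

#' Expected number of rounds
#'
#' Closed form `m0 + (1 - w)/w` for the mean ending round. All three
#' shipped treatments have mean 10: the fixed-length game trivially, and
#' the uncertain ones because `(8, 1/3)` and `(6, 1/5)` both add a
#' geometric tail with mean `(1 - w)/w = 2` and `4` respectively.
#'
#' @inheritParams termination_distribution
#' @return Mean game length in rounds.
#' @export
expected_rounds <- function(m0, w) {
  if (!is.numeric(w) || length(w) != 1 || w <= 0 || w > 1)
    abort_crd("w must be a probability in (0, 1]", "crd_config_error")
  if (!is.numeric(m0) || length(m0) != 1 || m0 < 1)
    abort_crd("m0 must be >= 1", "crd_config_error")
  m0 + (1 - w) / w
}

#' Exact mean of a termination distribution
#'
#' Sums the explicit masses and adds the analytic contribution of the
#' aggregated geometric tail (the tail, conditioned on reaching
#' `tail_round`, is again geometric with mean `tail_round + (1-w)/w`).
#' Used to cross-check [expected_rounds()] numerically.
#'
#' @param td a `crd_termination`.
#' @return Mean ending round.
#' @export
termination_mean <- function(td) {
  stopifnot(inherits(td, "crd_termination"))
  sum(td$rounds * td$probs) +
    td$tail_mass * (td$tail_round + (1 - td$w) / td$w)
}

#' Sample realized game lengths
#'
#' Draws ending rounds `m0 + Geometric(w)`; one draw per group, as in the
#' experiment where a single (virtual) dice sequence governed each group's
#' game.
#'
#' @param n number of draws.
#' @inheritParams termination_distribution
#' @return Integer vector of game lengths.
#' @export
sample_game_length <- function(n, m0, w) {
  as.integer(m0 + stats::rgeom(n, w))
}

#' @export
print.crd_termination <- function(x, ...) {
  cat(sprintf("Ending-round distribution: m0 = %d, w = %.4g\n", x$m0, x$w))
  cat(sprintf("  explicit support %s..%s, tail mass %.3g at rounds >= %d\n",
              if (length(x$rounds)) min(x$rounds) else "-",
              if (length(x$rounds)) max(x$rounds) else "-",
              x$tail_mass, x$tail_round))
  invisible(x)
}
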