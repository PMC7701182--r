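#' Population configuration for the evolutionary model
#'
#' A well-mixed population of `Z` individuals, each committed to one of the
#' five strategies, plays the collective risk dilemma in randomly sampled
#' groups of `N` and revises its strategy by pairwise comparison: a focal
#' individual copies a randomly chosen model with probability
#' `1 / (1 + exp(-beta * (payoff_model - payoff_focal)))` (the Fermi rule),
#' where `beta` is the selection strength.
#'
#' @param Z population size (must exceed the group size `N`).
#' @param beta selection strength (per monetary unit of payoff), >= 0.
#' @param game a `crd_config`.
#' @param profiles named list of the five strategies, as returned by
#'   [default_strategies()].
#' @return An object of class `crd_population` (carries an internal cache
#'   of group outcomes keyed by group composition).
#' @examples
#' pop <- population_config(Z = 50, beta = 0.004,
#'                          game = treatment_config("HU"))
#' @export
population_config <- function(Z = 50, beta = 0.004, game = game_config(),
                              profiles = default_strategies(game)) {
  stopifnot(inherits(game, "crd_config"))
  if (!is.numeric(Z) || length(Z) != 1 || Z <= game$N || Z != round(Z))
    abort_crd("Z must be an integer larger than the group size N",
              "crd_config_error")
  if (!is.numeric(beta) || length(beta) != 1 || beta < 0)
    abort_crd("beta must be >= 0", "crd_config_error")
  if (is.null(names(profiles)) || any(names(profiles) == ""))
    abort_crd("profiles must be a named list", "crd_config_error")
  structure(
    list(Z = as.integer(Z), beta = beta, game = game, profiles = profiles,
         cache = new.env(parent = emptyenv())),
    class = "crd_population"
  )
}

# Expected outcome for one group composition, cached. `counts` is a named
# integer vector over the population's strategies summing to N. Returns the
# full crd_outcome plus per-strategy payoff (all players of a strategy are
# interchangeable in a deterministic game).
#' @keywords internal
group_outcome <- function(counts, pop) {
  key <- paste(names(counts), counts, sep = "=", collapse = ",")
  hit <- pop$cache[[key]]
  if (!is.null(hit)) return(hit)
  kinds <- rep(names(counts), counts)
  profs <- pop$profiles[kinds]
  out <- expected_outcome(unname(profs), pop$game)
  first_idx <- match(names(counts)[counts > 0], kinds)
  per_strategy <- stats::setNames(out$expected_payoffs[first_idx],
                                  names(counts)[counts > 0])
  res <- list(outcome = out, per_strategy_payoff = per_strategy)
  assign(key, res, envir = pop$cache)
  res
}

#' Expected payoffs in a two-strategy population state
#'
#' Expected payoff of an `A`-player and a `B`-player when the population
#' holds `k` copies of `A` and `Z - k` of `B`, and each player's `N - 1`
#' co-players are drawn uniformly without replacement from the remaining
#' `Z - 1` individuals (hypergeometric group composition), each composition
#' scored by [expected_outcome()].
#'
#' @param A,B strategy names (must be names of `pop$profiles`).
#' @param k number of `A`-players, `1 <= k <= Z - 1`.
#' @param pop a `crd_population`.
#' @return Named numeric vector `c(payoff_A, payoff_B)`.
#' @export
pairwise_payoff <- function(A, B, k, pop) {
  stopifnot(inherits(pop, "crd_population"))
  Z <- pop$Z; N <- pop$game$N
  if (k < 1 || k > Z - 1 || k != round(k))
    abort_crd("k must be an integer in 1..Z-1", "crd_config_error")
  if (!all(c(A, B) %in% names(pop$profiles)))
    abort_crd("unknown strategy name", "crd_config_error")

  pay_focal <- function(focal, n_same) {
    other <- if (focal == A) B else A
    # j = number of same-strategy co-players among the N-1 sampled
    j <- 0:(N - 1)
    wts <- stats::dhyper(j, n_same - 1, Z - n_same, N - 1)
    tot <- 0
    for (jj in j[wts > 0]) {
      counts <- stats::setNames(integer(2), c(focal, other))
      counts[focal] <- jj + 1L
      counts[other] <- N - 1L - jj
      if (focal == other) counts <- stats::setNames(N, focal)  # A == B
      go <- group_outcome(counts, pop)
      tot <- tot + wts[jj + 1] * go$per_strategy_payoff[[focal]]
    }
    tot
  }
  if (A == B) {
    p <- group_outcome(stats::setNames(as.integer(N), A), pop)
    v <- p$per_strategy_payoff[[A]]
    return(c(payoff_A = v, payoff_B = v))
  }
  c(payoff_A = pay_focal(A, k), payoff_B = pay_focal(B, Z - k))
}

#' Fixation probability under the Fermi rule
#'
#' Probability that a single `A`-mutant takes over a population of `Z - 1`
#' `B`-residents under pairwise-comparison (Fermi) imitation with selection
#' strength `beta`. Uses the standard birth-death closed form
#' `rho = 1 / (1 + sum_i prod_{j<=i} exp(-beta * (pi_A(j) - pi_B(j))))`,
#' evaluated in log space so large `Z * beta` cannot overflow.
#'
#' @inheritParams pairwise_payoff
#' @return Fixation probability in `[0, 1]`.
#' @examples
#' pop <- population_config(Z = 12, beta = 0, game = treatment_config("NU"))
#' fixation_probability("always4", "always0", pop)  # neutral drift: 1/12
#' @export
fixation_probability <- function(A, B, pop) {
  stopifnot(inherits(pop, "crd_population"))
  if (A == B) abort_crd("A and B must differ", "crd_config_error")
  Z <- pop$Z
  dpi <- vapply(seq_len(Z - 1), function(k) {
    p <- pairwise_payoff(A, B, k, pop)
    p[["payoff_A"]] - p[["payoff_B"]]
  }, numeric(1))
  # log of the partial products, then log-sum-exp over {0, partials}
  lp <- cumsum(-pop$beta * dpi)
  m <- max(0, lp)
  exp(-(m + log(exp(-m) + sum(exp(lp - m)))))
}

#' Small-mutation-limit stationary distribution
#'
#' In the rare-mutation regime the population is monomorphic almost always:
#' a mutant either fixes or goes extinct before the next mutation arises.
#' The dynamics then reduce to a Markov chain over the monomorphic
#' states, with transition `s -> s'` proportional to the fixation
#' probability of a single `s'`-mutant among `s`-residents (mutations to
#' each of the other `n - 1` strategies being equally likely). This
#' computes the full pairwise fixation matrix and the stationary
#' distribution of the embedded chain.
#'
#' @param pop a `crd_population`.
#' @return An object of class `crd_evo` with fields `fixation` (matrix,
#'   rows = resident, columns = mutant), `stationary` (named probability
#'   vector) and `transition` (the embedded chain).
#' @export
stationary_distribution <- function(pop) {
  stopifnot(inherits(pop, "crd_population"))
  strat <- names(pop$profiles)
  n <- length(strat)
  fix <- matrix(0, n, n, dimnames = list(resident = strat, mutant = strat))
  for (res in strat) for (mut in strat) {
    if (res != mut) fix[res, mut] <- fixation_probability(mut, res, pop)
  }
  trans <- fix / (n - 1)
  diag(trans) <- 1 - rowSums(trans)
  # stationary vector: left null space of (T - I), normalized
  Amat <- rbind(t(trans) - diag(n), rep(1, n))
  b <- c(rep(0, n), 1)
  v <- stats::setNames(as.numeric(qr.solve(Amat, b)), strat)
  v[v < 0 & v > -1e-12] <- 0
  if (any(v < 0) || abs(sum(v) - 1) > 1e-8)
    abort_crd("stationary solve failed to produce a distribution",
              "crd_numeric_error")
  v <- v / sum(v)
  structure(list(fixation = fix, stationary = v, transition = trans),
            class = "crd_evo")
}

#' Model-level summary metrics
#'
#' Fills in the three quantities the evolutionary model is summarized by:
#'
#' * `eta` — expected fraction of successful groups: the success
#'   probability of a monomorphic group of each strategy, weighted by the
#'   stationary distribution (consistent with the small-mutation limit,
#'   where the population is monomorphic almost always).
#' * `reciprocal_prevalence` — stationary mass of the reciprocal strategy
#'   among the strategies that contribute toward the target
#'   (`always2, always4, compensator, reciprocal`), i.e. excluding the
#'   free-rider.
#' * `polarization` — `1 - P(|C - F| <= tol)` where the distribution of
#'   per-player total contributions `C` is generated by sampling groups
#'   multinomially from the stationary strategy mixture, drawing each
#'   group's length from the termination distribution and replaying the
#'   game. With the default `tol = 0`, this is the fraction of players
#'   whose total contribution differs from the fair share.
#'
#' @param evo a `crd_evo` from [stationary_distribution()].
#' @param pop the `crd_population` it was computed for.
#' @param n_groups number of groups sampled for the polarization estimate.
#' @param tol half-width (monetary units) of the "fair" band around `F`.
#' @return The `crd_evo` with fields `eta`, `reciprocal_prevalence` and
#'   `polarization` added.
#' @export
model_metrics <- function(evo, pop, n_groups = 1e4, tol = 0) {
  stopifnot(inherits(evo, "crd_evo"), inherits(pop, "crd_population"))
  strat <- names(pop$profiles)
  mono_success <- vapply(strat, function(s) {
    group_outcome(stats::setNames(as.integer(pop$game$N), s),
                  pop)$outcome$success_probability
  }, numeric(1))
  evo$eta <- sum(evo$stationary * mono_success)

  contributing <- setdiff(strat, "always0")
  cmass <- sum(evo$stationary[contributing])
  evo$reciprocal_prevalence <-
    if (cmass > 0 && "reciprocal" %in% strat)
      unname(evo$stationary["reciprocal"] / cmass)
    else NA_real_

  evo$polarization <- polarization_index(evo$stationary, pop,
                                         n_groups = n_groups, tol = tol)
  evo
}

#' Polarization of total contributions under a strategy mixture
#'
#' Samples `n_groups` groups whose members are drawn independently from
#' `mixture`, draws each group's realized length from the termination
#' distribution, replays the deterministic game, and returns the fraction
#' of players whose total contribution `C` falls outside the band
#' `|C - F| <= tol` around the fair share. A variance-based alternative
#' (`method = "variance"`: `Var(C) / F^2`, capped at 1) is included for
#' sensitivity checks.
#'
#' Deterministic given the RNG state; seed with [set.seed()] for
#' reproducibility.
#'
#' @param mixture named probability vector over the population's
#'   strategies.
#' @param pop a `crd_population`.
#' @param n_groups number of sampled groups.
#' @param tol band half-width in monetary units.
#' @param method `"band"` (default) or `"variance"`.
#' @return Polarization index in `[0, 1]`.
#' @export
polarization_index <- function(mixture, pop, n_groups = 1e4, tol = 0,
                               method = c("band", "variance")) {
  method <- match.arg(method)
  stopifnot(inherits(pop, "crd_population"))
  strat <- names(pop$profiles)
  mixture <- mixture[strat]
  if (any(is.na(mixture)) || abs(sum(mixture) - 1) > 1e-8)
    abort_crd("mixture must be a probability vector over the strategies",
              "crd_config_error")
  N <- pop$game$N
  Fshare <- fair_share(pop$game)

  comps <- stats::rmultinom(n_groups, N, mixture)  # strategies x groups
  lens <- sample_game_length(n_groups, pop$game$m0, pop$game$w)

  # replay each distinct composition once; C_i is constant past the static
  # round, so clamp the sampled length into the computed trace
  comp_key <- apply(comps, 2, paste, collapse = ",")
  Cs <- numeric(0)
  for (key in unique(comp_key)) {
    idx <- which(comp_key == key)
    counts <- stats::setNames(as.integer(strsplit(key, ",")[[1]]), strat)
    go <- group_outcome(counts, pop)
    tr <- go$outcome$trace
    H <- ncol(tr$player_cum)
    M <- pmin(lens[idx], H)
    Cs <- c(Cs, as.numeric(tr$player_cum[, M, drop = FALSE]))
  }
  if (method == "variance") {
    return(min(1, stats::var(Cs) * (length(Cs) - 1) / length(Cs) / Fshare^2))
  }
  1 - mean(abs(Cs - Fshare) <= tol)
}

#' Run the evolutionary model for one treatment
#'
#' Convenience wrapper: builds the population for a treatment preset,
#' computes the small-mutation-limit stationary distribution and the
#' summary metrics.
#'
#' @param treatment `"NU"`, `"LU"` or `"HU"`.
#' @param Z,beta population size and selection strength.
#' @param n_groups groups sampled for the polarization index.
#' @param overrides strategy parameter overrides, see
#'   [default_strategies()].
#' @return A `crd_evo` with metrics filled in.
#' @examples
#' \donttest{
#' set.seed(1)
#' evolve_treatment("NU", n_groups = 2000)
#' }
#' @export
evolve_treatment <- function(treatment, Z = 50, beta = 0.004,
                             n_groups = 1e4, overrides = list()) {
  game <- treatment_config(treatment)
  pop <- population_config(Z = Z, beta = beta, game = game,
                           profiles = default_strategies(game, overrides))
  evo <- stationary_distribution(pop)
  model_metrics(evo, pop, n_groups = n_groups)
}

#' @export
print.crd_evo <- function(x, ...) {
  cat("Small-mutation-limit evolutionary analysis\n")
  cat("  stationary distribution:\n")
  print(round(x$stationary, 4))
  if (!is.null(x$eta)) {
    cat(sprintf("  eta = %.4g, reciprocal prevalence = %.4g, polarization = %.4g\n",
                x$eta, x$reciprocal_prevalence, x$polarization))
  }
  invisible(x)
}
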