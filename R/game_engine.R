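#' Deterministic replay of one group
#'
#' Plays rounds `1..horizon` for a group of `N` deterministic strategies.
#' Each round every player applies [decide()] to the public history (the
#' other players' previous-round total and the cumulative group total);
#' actions are recorded simultaneously. Once the cumulative total reaches
#' the threshold all subsequent actions are 0 (the strategies stop).
#'
#' @param profiles list of `N` `crd_strategy` objects.
#' @param config a `crd_config` with matching `N`.
#' @param horizon number of rounds to play (>= 1).
#' @return An object of class `crd_trace` with fields `actions`
#'   (`N x horizon` matrix), `cum_total` (per-round cumulative group total),
#'   `player_cum` (`N x horizon` matrix of cumulative per-player
#'   contributions `C_i(t)`) and `success_round` (first round at which the
#'   cumulative total reaches the threshold, or `NA`).
#' @examples
#' cfg <- treatment_config("NU")
#' tr <- play_group(rep(list(strategy_profile("always4")), 6), cfg, 10)
#' tr$success_round   # 5: 6 players x 4 units x 5 rounds = 120
#' @export
play_group <- function(profiles, config, horizon) {
  stopifnot(inherits(config, "crd_config"))
  N <- config$N
  if (length(profiles) != N)
    abort_crd(sprintf("need %d profiles, got %d", N, length(profiles)),
              "crd_config_error")
  if (horizon < 1) abort_crd("horizon must be >= 1", "crd_config_error")
  horizon <- as.integer(horizon)

  actions <- matrix(0, nrow = N, ncol = horizon)
  remaining <- rep(config$E, N)
  prev <- rep(0, N)
  cum <- 0
  cum_total <- numeric(horizon)
  success_round <- NA_integer_

  for (t in seq_len(horizon)) {
    others_prev <- sum(prev) - prev
    a <- numeric(N)
    for (i in seq_len(N)) {
      a[i] <- decide(profiles[[i]], t, others_prev[i], cum, remaining[i],
                     config)
      if (!(a[i] %in% config$actions) || a[i] > remaining[i] + 1e-9)
        abort_crd("strategy emitted an infeasible action",
                  "crd_contract_error")
    }
    actions[, t] <- a
    remaining <- remaining - a
    cum <- cum + sum(a)
    cum_total[t] <- cum
    if (is.na(success_round) && cum >= config$tau) success_round <- t
    prev <- a
  }

  player_cum <- t(apply(actions, 1, cumsum))
  if (horizon == 1L) player_cum <- matrix(actions[, 1], nrow = N)
  structure(
    list(actions = actions, cum_total = cum_total, player_cum = player_cum,
         success_round = success_round),
    class = "crd_trace"
  )
}

#' Round from which play is provably static
#'
#' Returns the smallest round `M*` such that the trace of the group is
#' constant for every horizon `>= M*`: either the target has been met by
#' `M*` (all strategies stop) or no player ever contributes again. Because
#' the strategies are deterministic and memory-one, two consecutive
#' all-zero rounds imply all-zero play forever; the static round is then
#' the last round with a positive group contribution (or round 1 when no
#' one ever contributes). Exact expectations over the geometric ending
#' round reduce to finitely many explicit rounds plus one analytic tail at
#' `M*`.
#'
#' @inheritParams play_group
#' @return Integer round index `M* >= 1`.
#' @export
static_round <- function(profiles, config) {
  stopifnot(inherits(config, "crd_config"))
  N <- config$N
  pos <- config$actions[config$actions > 0]
  # Each positive round consumes >= min positive action from someone; allow
  # alternating zero rounds in between, plus slack.
  cap <- if (length(pos) == 0) 2L else
    as.integer(2 * ceiling(N * config$E / min(pos)) + 2)

  remaining <- rep(config$E, N)
  prev <- rep(0, N)
  cum <- 0
  last_positive <- 0L
  prev_zero <- FALSE
  for (t in seq_len(cap)) {
    others_prev <- sum(prev) - prev
    a <- vapply(seq_len(N), function(i)
      decide(profiles[[i]], t, others_prev[i], cum, remaining[i], config),
      numeric(1))
    remaining <- remaining - a
    cum <- cum + sum(a)
    if (sum(a) > 0) last_positive <- t
    if (cum >= config$tau) return(t)
    all_zero <- all(a == 0)
    if (all_zero && prev_zero) return(max(last_positive, 1L))
    prev_zero <- all_zero
    prev <- a
  }
  abort_crd("play did not become static within the search bound",
            "crd_contract_error")
}

#' Exact expected outcome over the random ending round
#'
#' Plays the group deterministically once up to its static round, then
#' takes the expectation of success, payoffs and total contributions
#' exactly over the ending-round distribution: explicit geometric masses
#' for rounds `m0 .. M* - 1` plus the analytic tail mass at `M*` (beyond
#' which the trace no longer changes). The payoff of player `i` when the
#' game ends at round `M` is `E - C_i(M)` if the group reached the
#' threshold by `M`, and `(1 - r) * (E - C_i(M))` otherwise — the disaster
#' is applied in expectation, which is what the evolutionary model
#' consumes.
#'
#' @inheritParams play_group
#' @return An object of class `crd_outcome` with fields
#'   `success_probability`, `expected_payoffs` (length `N`),
#'   `expected_contributions` (length `N`), `expected_rounds`, and the
#'   underlying `trace` and `static_round`.
#' @examples
#' cfg <- treatment_config("LU")
#' out <- expected_outcome(rep(list(strategy_profile("always2")), 6), cfg)
#' out$success_probability   # 4/9: success only if the game lasts 10 rounds
#' @export
expected_outcome <- function(profiles, config) {
  ms <- static_round(profiles, config)
  horizon <- max(ms, config$m0)
  tr <- play_group(profiles, config, horizon)
  td <- termination_distribution(config$m0, config$w, tail_round = horizon)

  rounds <- c(td$rounds, td$tail_round)
  probs <- c(td$probs, td$tail_mass)
  keep <- probs > 0
  rounds <- rounds[keep]; probs <- probs[keep]

  success_p <- 0
  payoffs <- numeric(config$N)
  contribs <- numeric(config$N)
  for (j in seq_along(rounds)) {
    M <- min(rounds[j], horizon)
    succ <- tr$cum_total[M] >= config$tau
    Ci <- tr$player_cum[, M]
    pay <- if (succ) config$E - Ci else (1 - config$r) * (config$E - Ci)
    success_p <- success_p + probs[j] * as.numeric(succ)
    payoffs <- payoffs + probs[j] * pay
    contribs <- contribs + probs[j] * Ci
  }
  structure(
    list(success_probability = success_p,
         expected_payoffs = payoffs,
         expected_contributions = contribs,
         expected_rounds = expected_rounds(config$m0, config$w),
         static_round = ms, trace = tr),
    class = "crd_outcome"
  )
}

#' Monte Carlo estimate of the expected outcome
#'
#' Independent stochastic check of [expected_outcome()]: samples ending
#' rounds from the geometric termination law, reads success and payoffs off
#' the deterministic trace at each sampled round, and averages. Intended as
#' a testing oracle; the exact expectation is what production code should
#' use.
#'
#' @inheritParams play_group
#' @param n_samples number of sampled ending rounds.
#' @return List with `success_probability`, `expected_payoffs`, their
#'   standard errors (`se_success`, `se_payoffs`) and `n_samples`.
#' @export
mc_outcome <- function(profiles, config, n_samples = 1e5) {
  ms <- static_round(profiles, config)
  horizon <- max(ms, config$m0)
  tr <- play_group(profiles, config, horizon)
  M <- pmin(sample_game_length(n_samples, config$m0, config$w), horizon)
  succ <- tr$cum_total[M] >= config$tau
  # payoff of player i at sampled round M
  pay <- matrix(0, nrow = n_samples, ncol = config$N)
  for (i in seq_len(config$N)) {
    Ci <- tr$player_cum[i, M]
    pay[, i] <- ifelse(succ, config$E - Ci,
                       (1 - config$r) * (config$E - Ci))
  }
  list(
    success_probability = mean(succ),
    se_success = stats::sd(succ) / sqrt(n_samples),
    expected_payoffs = colMeans(pay),
    se_payoffs = apply(pay, 2, stats::sd) / sqrt(n_samples),
    n_samples = n_samples
  )
}

#' @export
print.crd_trace <- function(x, ...) {
  cat(sprintf("Game trace: %d players, %d rounds, %s\n",
              nrow(x$actions), ncol(x$actions),
              if (is.na(x$success_round)) "target not met"
              else sprintf("target met at round %d", x$success_round)))
  invisible(x)
}

#' @export
print.crd_outcome <- function(x, ...) {
  cat(sprintf("Expected outcome: P(success) = %.4g, mean payoff = %.4g\n",
              x$success_probability, mean(x$expected_payoffs)))
  invisible(x)
}
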