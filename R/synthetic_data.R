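#' Specification of a synthetic cohort
#'
#' Describes an experiment-shaped cohort with known ground truth: the
#' treatment preset, the number of groups, a mixture over the five
#' strategies from which each player's behavior is drawn, and a
#' trembling-hand noise level (`noise_eps`: the probability that a
#' player's intended action is replaced by a uniform draw from the action
#' set, keeping actions on the experimental grid). Realized game lengths
#' are drawn per group, one dice sequence per group as in the experiment.
#'
#' @param treatment `"NU"`, `"LU"` or `"HU"`.
#' @param n_groups number of groups (6 players each by default).
#' @param mixture named probability vector over
#'   `always0, always2, always4, compensator, reciprocal`; defaults to
#'   uniform.
#' @param noise_eps action-replacement probability in `[0, 1]`.
#' @param seed RNG seed; the same spec always generates byte-identical
#'   output.
#' @param overrides strategy parameter overrides (see
#'   [default_strategies()]).
#' @return An object of class `crd_cohort_spec`.
#' @export
cohort_spec <- function(treatment = "NU", n_groups = 12,
                        mixture = NULL, noise_eps = 0, seed = 1,
                        overrides = list()) {
  kinds <- c("always0", "always2", "always4", "compensator", "reciprocal")
  if (is.null(mixture)) mixture <- stats::setNames(rep(1 / 5, 5), kinds)
  mixture <- mixture[kinds]
  mixture[is.na(mixture)] <- 0
  names(mixture) <- kinds
  if (abs(sum(mixture) - 1) > 1e-8)
    abort_crd("mixture must sum to 1", "crd_config_error")
  if (noise_eps < 0 || noise_eps > 1)
    abort_crd("noise_eps must be in [0, 1]", "crd_config_error")
  if (n_groups < 1) abort_crd("n_groups must be >= 1", "crd_config_error")
  structure(
    list(treatment = match.arg(treatment, c("NU", "LU", "HU")),
         n_groups = as.integer(n_groups), mixture = mixture,
         noise_eps = noise_eps, seed = as.integer(seed),
         overrides = overrides),
    class = "crd_cohort_spec"
  )
}

#' Generate a synthetic cohort with planted ground truth
#'
#' For each group: draws six strategies from the mixture, draws the
#' realized game length from the treatment's termination distribution,
#' and replays the game with [decide()] plus trembling-hand noise. Noise
#' replaces the intended action by a uniform draw from the action set
#' (clipped to the remaining endowment); once the target is reached all
#' actions are 0, noise-free — reaching the target ends the dilemma, so
#' post-target decisions carry no behavioral signal.
#'
#' @param spec a `crd_cohort_spec`.
#' @param config optional `crd_config`; defaults to the spec's treatment
#'   preset.
#' @return List with `table` (a validated `crd_table`) and `truth`
#'   (tibble: `group_id`, `player_id`, `strategy`, `length`).
#' @examples
#' g <- generate_cohort(cohort_spec("NU", n_groups = 2,
#'                                  mixture = c(always2 = 1)))
#' success_fraction(g$table, "NU")$fraction   # 1: 6 x 2 x 10 = 120
#' @export
generate_cohort <- function(spec, config = NULL) {
  stopifnot(inherits(spec, "crd_cohort_spec"))
  if (is.null(config)) config <- treatment_config(spec$treatment)
  profiles <- default_strategies(config, spec$overrides)
  kinds <- names(profiles)

  set.seed(spec$seed)
  rows <- vector("list", spec$n_groups)
  truth <- vector("list", spec$n_groups)
  for (g in seq_len(spec$n_groups)) {
    gid <- sprintf("%s_g%02d", spec$treatment, g)
    assigned <- sample(kinds, config$N, replace = TRUE, prob = spec$mixture)
    len <- sample_game_length(1, config$m0, config$w)
    acts <- play_group_noisy(profiles[assigned], config, len,
                             spec$noise_eps)
    rows[[g]] <- tibble(
      treatment = spec$treatment, group_id = gid,
      player_id = rep(sprintf("%s_p%d", gid, seq_len(config$N)), len),
      round = rep(seq_len(len), each = config$N),
      action = as.numeric(acts)
    )
    truth[[g]] <- tibble(
      group_id = gid, player_id = sprintf("%s_p%d", gid, seq_len(config$N)),
      strategy = assigned, length = len
    )
  }
  tab <- dplyr::bind_rows(rows)
  # rows were built round-major; restore player-major column order
  list(table = as_experiment_table(tab, config),
       truth = dplyr::bind_rows(truth))
}

# replay with trembling-hand noise; returns N x len action matrix
# (column-major round order flattening matches generate_cohort's rows)
#' @keywords internal
play_group_noisy <- function(profiles, config, len, eps) {
  N <- config$N
  actions <- matrix(0, nrow = N, ncol = len)
  remaining <- rep(config$E, N)
  prev <- rep(0, N)
  cum <- 0
  for (t in seq_len(len)) {
    others_prev <- sum(prev) - prev
    a <- numeric(N)
    for (i in seq_len(N)) {
      ai <- decide(profiles[[i]], t, others_prev[i], cum, remaining[i],
                   config)
      if (eps > 0 && cum < config$tau && stats::runif(1) < eps) {
        ai <- clip_action(sample(config$actions, 1), remaining[i],
                          config$actions)
      }
      a[i] <- ai
    }
    actions[, t] <- a
    remaining <- remaining - a
    cum <- cum + sum(a)
    prev <- a
  }
  actions
}

#' Hand-built fixture tables for the analysis edge cases
#'
#' Small deterministic tables (no RNG) exercising the analysis stages:
#'
#' * `nu_all_fair` — two NU groups where everyone gives 2 every round:
#'   all totals equal the fair share.
#' * `planted_two_all2` — one NU group with exactly two constant-2 players
#'   among four varied players.
#' * `hu_early` — two successful HU groups that front-load contributions.
#' * `polarized` — one NU group, half the players give nothing and half
#'   give everything.
#'
#' @return Named list of `crd_table` objects.
#' @export
fixture_suite <- function() {
  cfg <- game_config()
  from_matrix <- function(m, treatment, gid) {
    N <- nrow(m); len <- ncol(m)
    tibble(treatment = treatment, group_id = gid,
           player_id = rep(sprintf("%s_p%d", gid, seq_len(N)), each = len),
           round = rep(seq_len(len), N),
           action = as.numeric(t(m)))
  }
  all2 <- matrix(2, 6, 10)
  nu_all_fair <- dplyr::bind_rows(from_matrix(all2, "NU", "f1"),
                                  from_matrix(all2, "NU", "f2"))

  varied <- rbind(
    rep(2, 10),                               # constant 2
    rep(2, 10),                               # constant 2
    c(4, 4, 4, 4, 4, 0, 0, 0, 0, 0),          # front loader
    c(0, 0, 0, 0, 0, 4, 4, 4, 4, 4),          # back loader
    c(4, 0, 4, 0, 4, 0, 4, 0, 4, 0),          # alternator
    c(0, 4, 0, 4, 0, 4, 0, 4, 0, 4)           # alternator
  )
  planted_two_all2 <- from_matrix(varied, "NU", "v1")

  # everyone front-loads 4s; target met at round 6, trailing zeros after
  early <- rbind(
    matrix(rep(c(4, 4, 4, 2, 2, 2, 0, 0), 4), nrow = 4, byrow = TRUE),
    matrix(rep(c(4, 4, 4, 4, 4, 4, 0, 0), 2), nrow = 2, byrow = TRUE)
  )
  hu_early <- dplyr::bind_rows(from_matrix(early, "HU", "h1"),
                               from_matrix(early, "HU", "h2"))

  polar <- rbind(matrix(0, 3, 10), matrix(4, 3, 10))
  polarized <- from_matrix(polar, "NU", "pz1")

  lapply(list(nu_all_fair = nu_all_fair,
              planted_two_all2 = planted_two_all2,
              hu_early = hu_early,
              polarized = polarized),
         as_experiment_table, config = cfg)
}
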