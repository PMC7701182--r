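#' The five model strategies
#'
#' @description
#' The behavioral model uses five deterministic, memory-one strategies:
#'
#' * `always0`, `always2`, `always4` — unconditional: contribute 0, 2 or 4
#'   every round.
#' * `reciprocal` — group-level conditional cooperation: contribute
#'   `high_action` as long as the other group members contributed (their
#'   previous-round total is at least `theta`), otherwise `low_action`.
#'   Opens with `first_action` in round 1, when no history exists.
#' * `compensator` — the mirror image: contribute `high_action` when the
#'   others did *not* contribute (previous-round total below `theta`),
#'   otherwise `low_action`. Round 1 counts as "no previous contribution",
#'   so a compensator opens generously.
#'
#' All five stop contributing once the collective target is reached.
#'
#' Defaults: `theta = 2 * (N - 1)` (the others averaging at least the low
#' positive action counts as "the group contributed"), `high_action = 4`,
#' `low_action = 0`, and `first_action = 4` for the reciprocator (an
#' optimistic opener, so that a homogeneous reciprocal group can succeed).
#'
#' @param kind one of `"always0"`, `"always2"`, `"always4"`,
#'   `"compensator"`, `"reciprocal"`.
#' @param theta others'-previous-round-total threshold (monetary units) for
#'   the conditional kinds; ignored by the unconditional ones.
#' @param first_action round-1 action of the reciprocator.
#' @param high_action,low_action the two actions a conditional rule
#'   switches between.
#' @param config optional `crd_config` used for the `theta` default and to
#'   validate that the actions belong to the action set.
#' @return An object of class `crd_strategy`.
#' @examples
#' strategy_profile("reciprocal")
#' strategy_profile("compensator", theta = 8)
#' @export
strategy_profile <- function(kind, theta = NULL, first_action = 4,
                             high_action = 4, low_action = 0,
                             config = NULL) {
  kinds <- c("always0", "always2", "always4", "compensator", "reciprocal")
  if (!is.character(kind) || length(kind) != 1 || !(kind %in% kinds))
    abort_crd(sprintf("unknown strategy kind '%s'", paste(kind, collapse = ",")),
              "crd_config_error")
  N <- if (is.null(config)) 6L else config$N
  if (is.null(theta)) theta <- 2 * (N - 1)
  if (theta < 0) abort_crd("theta must be >= 0", "crd_config_error")
  if (!is.null(config)) {
    for (a in c(first_action, high_action, low_action))
      if (!(a %in% config$actions))
        abort_crd(sprintf("action %g not in the action set", a),
                  "crd_config_error")
  }
  structure(
    list(kind = kind, theta = theta, first_action = first_action,
         high_action = high_action, low_action = low_action),
    class = "crd_strategy"
  )
}

#' Default set of the five strategies
#'
#' @param config a `crd_config` (sets the `theta` default through `N`).
#' @param overrides named list of per-kind argument overrides, e.g.
#'   `list(reciprocal = list(theta = 8))`.
#' @return Named list of five `crd_strategy` objects in the canonical order
#'   `always0, always2, always4, compensator, reciprocal`.
#' @export
default_strategies <- function(config = game_config(), overrides = list()) {
  kinds <- c("always0", "always2", "always4", "compensator", "reciprocal")
  out <- lapply(kinds, function(k) {
    args <- c(list(kind = k, config = config), overrides[[k]])
    do.call(strategy_profile, args)
  })
  names(out) <- kinds
  out
}

#' One strategy decision
#'
#' Pure function mapping a strategy and the public state of the game to the
#' player's next contribution. Every strategy returns 0 once the cumulative
#' group total has reached the threshold. The chosen action is clipped to
#' the player's remaining endowment: if the rule requests more than remains,
#' the largest feasible action in the action set is contributed instead.
#'
#' @param profile a `crd_strategy`.
#' @param round round index (1-based).
#' @param others_prev_total total contributed by the other `N - 1` players
#'   in the previous round (0 in round 1).
#' @param cum_group_total cumulative group contribution before this round.
#' @param remaining the player's remaining endowment.
#' @param config a `crd_config`.
#' @return A single action from the action set.
#' @examples
#' cfg <- game_config()
#' decide(strategy_profile("compensator"), round = 2,
#'        others_prev_total = 0, cum_group_total = 0,
#'        remaining = 36, config = cfg)   # 4: the others gave nothing
#' @export
decide <- function(profile, round, others_prev_total, cum_group_total,
                   remaining, config) {
  stopifnot(inherits(profile, "crd_strategy"), inherits(config, "crd_config"))
  if (cum_group_total >= config$tau) return(0)
  a <- switch(profile$kind,
    always0 = 0,
    always2 = 2,
    always4 = 4,
    reciprocal =
      if (round == 1) profile$first_action
      else if (others_prev_total >= profile$theta) profile$high_action
      else profile$low_action,
    compensator =
      if (others_prev_total < profile$theta) profile$high_action
      else profile$low_action,
    abort_crd(sprintf("unknown strategy kind '%s'", profile$kind),
              "crd_config_error")
  )
  clip_action(a, remaining, config$actions)
}

# Largest action in the set not exceeding min(requested, remaining).
# With the default endowment (40, divisible by every action) clipping never
# triggers mid-game for the shipped strategies; it matters for nonstandard
# configurations only.
#' @keywords internal
clip_action <- function(a, remaining, actions) {
  feasible <- actions[actions <= min(a, remaining)]
  if (length(feasible) == 0) 0 else max(feasible)
}

#' @export
print.crd_strategy <- function(x, ...) {
  if (startsWith(x$kind, "always")) {
    cat(sprintf("Strategy: %s (unconditional)\n", x$kind))
  } else {
    cat(sprintf("Strategy: %s (theta = %g, high = %g, low = %g%s)\n",
                x$kind, x$theta, x$high_action, x$low_action,
                if (x$kind == "reciprocal")
                  sprintf(", opens with %g", x$first_action) else ""))
  }
  invisible(x)
}
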