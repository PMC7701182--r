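#' Validate and construct an experiment table
#'
#' The canonical long format of a behavioral collective-risk-dilemma
#' dataset: one row per decision, with columns `treatment` (`NU`/`LU`/`HU`),
#' `group_id`, `player_id`, `round` and `action`. Checked invariants:
#' actions belong to the action set; per-player totals never exceed the
#' endowment; every player of a group covers the same contiguous round
#' range `1..length`; `player_id` values are unique to their group.
#' Violations raise an error with row-level diagnostics.
#'
#' @param df a data frame with the canonical columns.
#' @param config a `crd_config` providing the action set and endowment.
#' @return The validated table, classed `crd_table`.
#' @export
as_experiment_table <- function(df, config = game_config()) {
  req <- c("treatment", "group_id", "player_id", "round", "action")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    abort_crd(paste0("missing columns: ", paste(missing_cols, collapse = ", ")),
              "crd_schema_error")
  df <- as_tibble(df)[req]
  df$treatment <- as.character(df$treatment)
  df$group_id <- as.character(df$group_id)
  df$player_id <- as.character(df$player_id)
  df$round <- as.integer(df$round)

  bad <- which(!(df$action %in% config$actions))
  if (length(bad) > 0)
    abort_crd(sprintf("invalid action %s at row(s) %s",
                      paste(unique(df$action[bad]), collapse = ","),
                      paste(utils::head(bad, 5), collapse = ", ")),
              "crd_schema_error")

  totals <- df %>%
    group_by(.data$treatment, .data$group_id, .data$player_id) %>%
    summarise(C = sum(.data$action), .groups = "drop")
  over <- totals %>% filter(.data$C > config$E)
  if (nrow(over) > 0)
    abort_crd(sprintf("player %s (group %s) contributes %g > endowment %g",
                      over$player_id[1], over$group_id[1], over$C[1],
                      config$E),
              "crd_schema_error")

  per_player <- df %>%
    group_by(.data$treatment, .data$group_id, .data$player_id) %>%
    summarise(n_rounds = dplyr::n(), max_round = max(.data$round),
              contiguous = identical(sort(.data$round),
                                     seq_len(max(.data$round))),
              .groups = "drop")
  if (any(!per_player$contiguous)) {
    p <- per_player[which(!per_player$contiguous)[1], ]
    abort_crd(sprintf("player %s (group %s): rounds not contiguous from 1",
                      p$player_id, p$group_id),
              "crd_schema_error")
  }
  lens <- per_player %>%
    group_by(.data$treatment, .data$group_id) %>%
    summarise(k = dplyr::n_distinct(.data$max_round), .groups = "drop")
  if (any(lens$k > 1)) {
    g <- lens[which(lens$k > 1)[1], ]
    abort_crd(sprintf("group %s (%s): players disagree on realized length",
                      g$group_id, g$treatment),
              "crd_schema_error")
  }
  structure(arrange(df, .data$treatment, .data$group_id, .data$round,
                    .data$player_id),
            class = c("crd_table", class(tibble())),
            config = config)
}

#' Read an experiment table from delimited text
#'
#' Reads a header-ed delimited file and maps its columns onto the canonical
#' schema via `schema_map`, a named character vector from canonical names
#' to source column names (e.g. `c(action = "contribution")`). Unmapped
#' canonical names are assumed to be present verbatim. The result is
#' validated by [as_experiment_table()].
#'
#' @param path file path.
#' @param schema_map named character vector, canonical -> source column.
#' @param config a `crd_config`.
#' @param sep field separator.
#' @return A `crd_table`.
#' @export
load_table <- function(path, schema_map = NULL, config = game_config(),
                       sep = ",") {
  if (!file.exists(path))
    abort_crd(sprintf("no such file: %s", path), "crd_io_error")
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema_map)) {
    missing_src <- setdiff(unname(schema_map), names(raw))
    if (length(missing_src) > 0)
      abort_crd(paste0("schema_map source columns not found: ",
                       paste(missing_src, collapse = ", ")),
                "crd_schema_error")
    for (canon in names(schema_map)) names(raw)[names(raw) == schema_map[[canon]]] <- canon
  }
  as_experiment_table(raw, config)
}

#' Schema-map template for the public data deposit
#'
#' The study's behavioral dataset is deposited at Dryad
#' (doi:10.5061/dryad.5qfttdz2t). This returns a template mapping the
#' canonical fields to the deposit's column names, to be adjusted on first
#' download if the deposit uses different headers; [load_table()] validates
#' rather than assumes the mapping.
#'
#' @return Named character vector suitable for `schema_map`.
#' @export
dryad_schema_map <- function() {
  c(treatment = "treatment", group_id = "group", player_id = "player",
    round = "round", action = "action")
}

# realized length and success per group
#' @keywords internal
group_summary <- function(table, config = attr(table, "config")) {
  table %>%
    group_by(.data$treatment, .data$group_id) %>%
    summarise(length = max(.data$round), total = sum(.data$action),
              .groups = "drop") %>%
    mutate(success = .data$total >= config$tau)
}

# per-player totals joined with group success
#' @keywords internal
player_summary <- function(table, config = attr(table, "config")) {
  gs <- group_summary(table, config)
  table %>%
    group_by(.data$treatment, .data$group_id, .data$player_id) %>%
    summarise(C = sum(.data$action), .groups = "drop") %>%
    left_join(gs, by = c("treatment", "group_id"))
}

#' Per-round mean group contributions with confidence interval
#'
#' For each round, the mean over groups of the group's total contribution
#' in that round, with a t-based confidence interval across groups. Under
#' timing uncertainty later rounds are observed for fewer groups (only
#' those whose game lasted that long); the group count per round is
#' reported. A round observed in a single group gets its mean with an
#' `NA` interval.
#'
#' @param table a `crd_table`.
#' @param treatment treatment label to select.
#' @param conf_level confidence level, default 0.95.
#' @return Tibble with `round`, `mean`, `n_groups`, `ci_low`, `ci_high`.
#' @export
per_round_means <- function(table, treatment, conf_level = 0.95) {
  tr <- treatment
  gt <- table %>%
    filter(.data$treatment == tr) %>%
    group_by(.data$group_id, .data$round) %>%
    summarise(total = sum(.data$action), .groups = "drop")
  if (nrow(gt) == 0) abort_crd("no rows for treatment", "crd_empty_error")
  gt %>%
    group_by(.data$round) %>%
    summarise(mean = mean(.data$total), n_groups = dplyr::n(),
              sd = stats::sd(.data$total), .groups = "drop") %>%
    mutate(
      half = ifelse(.data$n_groups > 1,
                    stats::qt(1 - (1 - conf_level) / 2, .data$n_groups - 1) *
                      .data$sd / sqrt(.data$n_groups), NA_real_),
      ci_low = .data$mean - .data$half,
      ci_high = .data$mean + .data$half
    ) %>%
    select("round", "mean", "n_groups", "ci_low", "ci_high")
}

#' Fraction of successful groups
#'
#' A group is successful when its cumulative contribution reaches the
#' threshold by its realized final round. The point estimate comes with an
#' exact (Clopper-Pearson) binomial confidence interval.
#'
#' @inheritParams per_round_means
#' @param config game configuration (defaults to the one attached to the
#'   table).
#' @return List with `fraction`, `n_success`, `n_groups`, `ci_low`,
#'   `ci_high`.
#' @export
success_fraction <- function(table, treatment,
                             config = attr(table, "config"),
                             conf_level = 0.95) {
  tr <- treatment
  gs <- group_summary(table, config) %>% filter(.data$treatment == tr)
  if (nrow(gs) == 0) abort_crd("no groups for treatment", "crd_empty_error")
  x <- sum(gs$success); n <- nrow(gs)
  ci <- stats::binom.test(x, n, conf.level = conf_level)$conf.int
  list(fraction = x / n, n_success = x, n_groups = n,
       ci_low = ci[1], ci_high = ci[2])
}

#' Fairness classification of total contributions
#'
#' Splits players by their total contribution `C` relative to the fair
#' share `F = E/2`: below, equal or above. By default only players in
#' successful groups are considered, matching the usual presentation.
#'
#' @inheritParams success_fraction
#' @param successful_only restrict to players of successful groups
#'   (`TRUE`), failed groups (`FALSE`) or all (`NA`).
#' @return Tibble with `category` (`below`/`equal`/`above`), `count`,
#'   `fraction`.
#' @export
fairness_classification <- function(table, treatment,
                                    config = attr(table, "config"),
                                    successful_only = TRUE) {
  tr <- treatment
  ps <- player_summary(table, config) %>% filter(.data$treatment == tr)
  if (!is.na(successful_only))
    ps <- ps %>% filter(.data$success == successful_only)
  if (nrow(ps) == 0) abort_crd("empty player selection", "crd_empty_error")
  Fs <- fair_share(config)
  cat_levels <- c("below", "equal", "above")
  cats <- factor(ifelse(ps$C < Fs, "below",
                        ifelse(ps$C == Fs, "equal", "above")),
                 levels = cat_levels)
  tibble(category = cat_levels,
         count = as.integer(table(cats)),
         fraction = as.numeric(table(cats)) / nrow(ps))
}

#' First- and second-half contributions relative to half the fair share
#'
#' Splits each game into a first half of `m0 / 2` rounds (5, 4 and 3 for
#' the NU, LU and HU presets) and a second half running from there to the
#' realized end, then classifies each player's half-contribution against
#' `F / 2`. Groups shorter than the first half are excluded and counted in
#' the `excluded` attribute.
#'
#' @inheritParams fairness_classification
#' @return Tibble with `half` (`first`/`second`), `category`, `count`,
#'   `fraction`.
#' @export
half_split <- function(table, treatment, config = attr(table, "config"),
                       successful_only = TRUE) {
  tr <- treatment
  first_len <- floor(config$m0 / 2)
  gs <- group_summary(table, config) %>% filter(.data$treatment == tr)
  if (!is.na(successful_only))
    gs <- gs %>% filter(.data$success == successful_only)
  keep <- gs %>% filter(.data$length >= first_len)
  excluded <- nrow(gs) - nrow(keep)
  if (nrow(keep) == 0) abort_crd("empty group selection", "crd_empty_error")

  df <- table %>%
    filter(.data$treatment == tr, .data$group_id %in% keep$group_id) %>%
    mutate(half = ifelse(.data$round <= first_len, "first", "second")) %>%
    group_by(.data$group_id, .data$player_id, .data$half) %>%
    summarise(Ch = sum(.data$action), .groups = "drop")
  # players with no rows in a half (game ended exactly at first_len)
  # contribute 0 in that half
  halfF <- fair_share(config) / 2
  cat_levels <- c("below", "equal", "above")
  out <- lapply(c("first", "second"), function(h) {
    sub <- df %>% filter(.data$half == h)
    n_players <- length(unique(paste(df$group_id, df$player_id)))
    vals <- rep(0, n_players)
    keys <- unique(paste(df$group_id, df$player_id))
    vals[match(paste(sub$group_id, sub$player_id), keys)] <- sub$Ch
    cats <- factor(ifelse(vals < halfF, "below",
                          ifelse(vals == halfF, "equal", "above")),
                   levels = cat_levels)
    tibble(half = h, category = cat_levels,
           count = as.integer(table(cats)),
           fraction = as.numeric(table(cats)) / n_players)
  })
  res <- dplyr::bind_rows(out)
  attr(res, "excluded_groups") <- excluded
  res
}

#' Conditional-response table
#'
#' For every decision from round 2 on, computes `x`, the total contributed
#' by the focal player's `N - 1` group members in the previous round, and
#' aggregates per observed `x`: the mean focal contribution, the number of
#' observations and the frequency of each action. This is the raw material
#' of the reciprocity analysis — a positive dependence of contribution on
#' `x` indicates group reciprocity, a negative one compensation.
#'
#' @inheritParams fairness_classification
#' @param successful_only `TRUE`, `FALSE` or `NA` (all groups).
#' @return A tibble of class `crd_conditional` with `x`, `mean_action`,
#'   `n`, and `freq_<a>` columns for each action `a`.
#' @export
conditional_table <- function(table, treatment,
                              config = attr(table, "config"),
                              successful_only = NA) {
  obs <- conditional_observations(table, treatment, config, successful_only)
  if (nrow(obs) == 0) abort_crd("no conditional observations", "crd_empty_error")
  ct <- obs %>%
    group_by(.data$x) %>%
    summarise(mean_action = mean(.data$action), n = dplyr::n(),
              .groups = "drop")
  for (a in config$actions) {
    fr <- obs %>%
      group_by(.data$x) %>%
      summarise(f = mean(.data$action == a), .groups = "drop")
    ct[[paste0("freq_", a)]] <- fr$f[match(ct$x, fr$x)]
  }
  structure(arrange(ct, .data$x),
            class = c("crd_conditional", class(tibble())))
}

# one row per focal decision at round >= 2: action and others' previous total
#' @keywords internal
conditional_observations <- function(table, treatment,
                                     config = attr(table, "config"),
                                     successful_only = NA) {
  tr <- treatment
  df <- table %>% filter(.data$treatment == tr)
  if (!is.na(successful_only)) {
    gs <- group_summary(table, config) %>%
      filter(.data$treatment == tr, .data$success == successful_only)
    df <- df %>% filter(.data$group_id %in% gs$group_id)
  }
  rt <- df %>%
    group_by(.data$group_id, .data$round) %>%
    summarise(round_total = sum(.data$action), .groups = "drop")
  df %>%
    left_join(rt, by = c("group_id", "round")) %>%
    group_by(.data$group_id, .data$player_id) %>%
    arrange(.data$round, .by_group = TRUE) %>%
    mutate(x = dplyr::lag(.data$round_total) - dplyr::lag(.data$action)) %>%
    ungroup() %>%
    filter(!is.na(.data$x)) %>%
    select("group_id", "player_id", "round", "action", "x")
}

#' Weighted linear regression on a conditional-response table
#'
#' Weighted least squares of the per-bin mean contribution on the others'
#' previous-round total `x`, with weights equal to the bin observation
#' counts. The slope sign is the reciprocity indicator: positive for
#' reciprocal (conditional-cooperation) response, negative for
#' compensating response.
#'
#' @param ct a `crd_conditional` (or any data frame with `x`,
#'   `mean_action`, `n`).
#' @return An object of class `crd_regfit`: list with `slope`,
#'   `intercept`, `se_slope`, `se_intercept`, `p_slope`, `weights`, `fit`.
#' @export
weighted_regression <- function(ct) {
  if (length(unique(ct$x)) < 2)
    abort_crd("need at least 2 distinct x bins for a regression",
              "crd_empty_error")
  fit <- stats::lm(mean_action ~ x, data = ct, weights = ct$n)
  sm <- summary(fit)$coefficients
  structure(
    list(slope = unname(sm["x", "Estimate"]),
         intercept = unname(sm["(Intercept)", "Estimate"]),
         se_slope = unname(sm["x", "Std. Error"]),
         se_intercept = unname(sm["(Intercept)", "Std. Error"]),
         p_slope = unname(sm["x", "Pr(>|t|)"]),
         weights = ct$n, fit = fit),
    class = "crd_regfit"
  )
}

#' @export
print.crd_regfit <- function(x, ...) {
  cat(sprintf("Weighted regression: slope %.4g (SE %.3g, p %.3g), intercept %.4g\n",
              x$slope, x$se_slope, x$p_slope, x$intercept))
  invisible(x)
}

#' Count players who chose one action in every round
#'
#' E.g. the number of participants who always contributed 2 — the
#' round-level fair share — throughout their game.
#'
#' @inheritParams fairness_classification
#' @param action the action to test for.
#' @return Integer count.
#' @export
constant_contributor_count <- function(table, treatment, action,
                                       config = attr(table, "config"),
                                       successful_only = NA) {
  tr <- treatment
  df <- table %>% filter(.data$treatment == tr)
  if (!is.na(successful_only)) {
    gs <- group_summary(table, config) %>%
      filter(.data$treatment == tr, .data$success == successful_only)
    df <- df %>% filter(.data$group_id %in% gs$group_id)
  }
  cc <- df %>%
    group_by(.data$group_id, .data$player_id) %>%
    summarise(const = all(.data$action == !!action), .groups = "drop")
  sum(cc$const)
}

#' Rule-based behavioral profile classification
#'
#' Approximates the clustering of participants into strategic profiles by
#' a transparent rule: over a player's pre-success rounds (decisions after
#' the target is met are uninformative trailing zeros), a constant action
#' `a` gives `unconditional-a`; otherwise the player's own conditional
#' slope — ordinary regression of their action on the others'
#' previous-round total — classifies them as `reciprocal-like` (slope above
#' `slope_cutoff`), `compensator-like` (below `-slope_cutoff`) or `other`.
#' Histories too short to estimate a slope fall into `other`.
#'
#' @inheritParams fairness_classification
#' Decisions carrying no behavioral signal are discarded before
#' classifying: rounds after the group met the target, and rounds where
#' the player's remaining endowment no longer covers the smallest positive
#' action (forced zeros).
#'
#' @param slope_cutoff absolute slope (units contributed per unit of
#'   others' contribution) below which a player counts as unconditional
#'   "other"; reported with the output.
#' @param pre_success_only drop rounds after the group met the target.
#' @return Tibble with `group_id`, `player_id`, `class`, `slope` and an
#'   attribute `slope_cutoff`.
#' @export
classify_profile <- function(table, treatment,
                             config = attr(table, "config"),
                             slope_cutoff = 0.05,
                             pre_success_only = TRUE) {
  tr <- treatment
  df <- table %>% filter(.data$treatment == tr)
  if (nrow(df) == 0) abort_crd("no rows for treatment", "crd_empty_error")
  # first round at which cumulative total reaches the threshold, per group
  succ_round <- df %>%
    group_by(.data$group_id, .data$round) %>%
    summarise(rt = sum(.data$action), .groups = "drop_last") %>%
    arrange(.data$round, .by_group = TRUE) %>%
    mutate(cum = cumsum(.data$rt)) %>%
    summarise(success_round = if (any(.data$cum >= config$tau))
      min(.data$round[.data$cum >= config$tau]) else Inf,
      .groups = "drop")
  obs <- conditional_observations(table, tr, config, NA) %>%
    left_join(succ_round, by = "group_id")
  if (pre_success_only) obs <- obs %>% filter(.data$round <= .data$success_round)

  # drop forced zeros: rounds the player could no longer afford the
  # smallest positive action
  min_pos <- min(config$actions[config$actions > 0])
  affordable <- df %>%
    group_by(.data$group_id, .data$player_id) %>%
    arrange(.data$round, .by_group = TRUE) %>%
    mutate(remaining = config$E - cumsum(.data$action) + .data$action) %>%
    ungroup() %>%
    filter(.data$remaining >= min_pos) %>%
    select("group_id", "player_id", "round")
  obs <- obs %>%
    dplyr::semi_join(affordable, by = c("group_id", "player_id", "round"))

  # round-1 actions (no x), needed for the constancy check
  r1 <- df %>% filter(.data$round == 1) %>%
    select("group_id", "player_id", "action")

  players <- distinct(df, .data$group_id, .data$player_id)
  out <- lapply(seq_len(nrow(players)), function(i) {
    g <- players$group_id[i]; p <- players$player_id[i]
    po <- obs %>% filter(.data$group_id == g, .data$player_id == p)
    a1 <- r1$action[r1$group_id == g & r1$player_id == p]
    acts <- c(a1, po$action)
    if (length(unique(acts)) == 1) {
      return(tibble(group_id = g, player_id = p,
                    class = paste0("unconditional-", acts[1]),
                    slope = NA_real_))
    }
    if (nrow(po) < 2 || length(unique(po$x)) < 2) {
      return(tibble(group_id = g, player_id = p, class = "other",
                    slope = NA_real_))
    }
    sl <- unname(stats::coef(stats::lm(action ~ x, data = po))["x"])
    cls <- if (sl >= slope_cutoff) "reciprocal-like"
           else if (sl <= -slope_cutoff) "compensator-like"
           else "other"
    tibble(group_id = g, player_id = p, class = cls, slope = sl)
  })
  res <- dplyr::bind_rows(out)
  attr(res, "slope_cutoff") <- slope_cutoff
  res
}
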