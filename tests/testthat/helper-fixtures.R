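# Shared builders for tests: tables from action matrices, strategy shortcuts.

# action matrix (players x rounds) -> canonical long table rows
table_from_matrix <- function(m, treatment = "NU", gid = "g1") {
  N <- nrow(m); len <- ncol(m)
  tibble::tibble(
    treatment = treatment, group_id = gid,
    player_id = rep(sprintf("%s_p%d", gid, seq_len(N)), each = len),
    round = rep(seq_len(len), N),
    action = as.numeric(t(m))
  )
}

experiment_table <- function(..., config = game_config()) {
  as_experiment_table(dplyr::bind_rows(...), config)
}

homogeneous <- function(kind, n = 6, config = game_config(), ...) {
  rep(list(strategy_profile(kind, config = config, ...)), n)
}
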