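# Run configuration template. Every section is optional; values omitted
# here fall back to the package defaults (the three shipped treatment
# presets, the default strategy parameters, Z = 50, beta = 0.004).

game:
  NU: {m0: 10, w: 1.0}
  LU: {m0: 8, w: 0.3333333333333333}
  HU: {m0: 6, w: 0.2}
  # shared constants may be overridden per treatment:
  # NU: {N: 6, E: 40, actions: [0, 2, 4], tau: 120, r: 0.9, m0: 10, w: 1.0}

strategies:
  # per-kind overrides, e.g.:
  # reciprocal: {theta: 10, first_action: 4, high_action: 4, low_action: 0}
  # compensator: {theta: 10, high_action: 4, low_action: 0}

population:
  Z: 50
  beta: 0.004
  n_groups: 10000   # groups sampled for the polarization index

cohort:
  treatment: NU
  n_groups: 12
  mixture: {always0: 0.2, always2: 0.2, always4: 0.2,
            compensator: 0.2, reciprocal: 0.2}
  noise_eps: 0.0
  seed: 1

# column mapping used by `analyze` for non-canonical input headers:
# schema_map: {treatment: treatment, group_id: group, player_id: player,
#              round: round, action: action}
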