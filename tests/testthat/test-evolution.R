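small_pop <- function(treatment = "NU", Z = 12, beta = 0.05) {
  game <- treatment_config(treatment)
  population_config(Z = Z, beta = beta, game = game)
}

test_that("pairwise payoffs are symmetric and match closed forms", {
  pop <- small_pop()
  p <- pairwise_payoff("always2", "always2", 5, pop)
  expect_equal(p[["payoff_A"]], p[["payoff_B"]])
  # mutual defection: everyone keeps (1 - r) * E = 4
  p0 <- pairwise_payoff("always0", "always0", 5, pop)
  expect_equal(unname(p0), c(4, 4))
})

test_that("pairwise payoffs match brute-force hypergeometric enumeration", {
  pop <- small_pop("LU")
  for (k in c(1, 4, 11)) {
    p <- pairwise_payoff("always4", "always0", k, pop)
    expect_equal(p[["payoff_A"]],
                 oracle_focal_payoff("always4", "always0", k, pop),
                 tolerance = 1e-12)
    expect_equal(p[["payoff_B"]],
                 oracle_focal_payoff("always0", "always4", pop$Z - k, pop),
                 tolerance = 1e-12)
  }
  # k = Z - 1: the A payoff is computed over compositions rich in A
  p <- pairwise_payoff("reciprocal", "always2", 11, pop)
  expect_equal(p[["payoff_A"]],
               oracle_focal_payoff("reciprocal", "always2", 11, pop),
               tolerance = 1e-12)
})

test_that("near-homogeneous populations approach the homogeneous payoff", {
  # at k = Z - 1 an A player faces mostly A's (though one B remains in the
  # sampling pool), at k = 1 almost only B's: the payoff at k = Z - 1 must
  # be the closer of the two to the homogeneous-group payoff
  pop <- small_pop("NU")
  hi <- pairwise_payoff("always4", "always0", pop$Z - 1, pop)[["payoff_A"]]
  lo <- pairwise_payoff("always4", "always0", 1, pop)[["payoff_A"]]
  hom <- pairwise_payoff("always4", "always4", 1, pop)[["payoff_A"]]
  expect_equal(hom, 20)
  expect_lt(abs(hi - hom), abs(lo - hom))
})

test_that("neutral drift fixes with probability 1/Z", {
  pop <- small_pop(beta = 0)
  for (pair in list(c("always4", "always0"), c("reciprocal", "compensator"))) {
    expect_equal(fixation_probability(pair[1], pair[2], pop), 1 / 12,
                 tolerance = 1e-12)
  }
  # equal payoff profiles at positive beta drift neutrally too: add a
  # behavioral clone of always-4 and let it invade the original
  game <- treatment_config("NU")
  profs <- default_strategies(game)
  profs$clone4 <- profs$always4
  pop3 <- population_config(Z = 12, beta = 0.1, game = game,
                            profiles = profs)
  expect_equal(fixation_probability("clone4", "always4", pop3), 1 / 12,
               tolerance = 1e-12)
})

test_that("closed-form fixation matches the absorbing-chain linear solve", {
  for (tr in c("NU", "HU")) {
    pop <- small_pop(tr, Z = 12, beta = 0.05)
    strat <- names(pop$profiles)
    for (pair in list(c("always4", "always0"),
                      c("reciprocal", "always2"),
                      c("compensator", "always0"))) {
      expect_equal(fixation_probability(pair[1], pair[2], pop),
                   oracle_fixation_bd(pair[1], pair[2], pop),
                   tolerance = 1e-10)
    }
  }
})

test_that("stationary distribution is a distribution, uniform when neutral", {
  pop <- small_pop(beta = 0)
  evo <- stationary_distribution(pop)
  expect_equal(sum(evo$stationary), 1, tolerance = 1e-10)
  expect_equal(unname(evo$stationary), rep(1 / 5, 5), tolerance = 1e-10)
  expect_true(all(evo$fixation >= 0 & evo$fixation <= 1))

  pop2 <- small_pop("HU", beta = 0.05)
  evo2 <- stationary_distribution(pop2)
  expect_equal(sum(evo2$stationary), 1, tolerance = 1e-10)
  expect_true(all(evo2$stationary >= 0))
})

test_that("behaviorally identical strategies share stationary mass", {
  game <- treatment_config("NU")
  profs <- default_strategies(game)[c("always0", "always4")]
  profs$clone4 <- profs$always4
  pop <- population_config(Z = 12, beta = 0.05, game = game,
                           profiles = profs)
  evo <- stationary_distribution(pop)
  expect_equal(unname(evo$stationary["always4"]),
               unname(evo$stationary["clone4"]), tolerance = 1e-10)
})

test_that("SML stationary agrees with simulating the rare-mutation process", {
  set.seed(2024)
  pop <- small_pop("NU", Z = 12, beta = 0.05)
  evo <- stationary_distribution(pop)
  mc <- oracle_sml_mc(pop, n_transitions = 40000, n_batches = 20)
  for (s in names(evo$stationary)) {
    expect_lt(abs(evo$stationary[[s]] - mc$stationary[[s]]),
              3 * max(mc$se[[s]], 0.005))
  }
})

test_that("model metrics behave on degenerate stationary distributions", {
  pop <- small_pop("NU")
  evo <- stationary_distribution(pop)
  # point mass on the free rider: no group ever succeeds, everyone at C = 0
  evo$stationary <- stats::setNames(c(1, 0, 0, 0, 0), names(pop$profiles))
  set.seed(1)
  m <- model_metrics(evo, pop, n_groups = 200)
  expect_equal(m$eta, 0)
  expect_equal(m$polarization, 1)
  expect_equal(m$reciprocal_prevalence, NA_real_)
  # point mass on always-4 under no uncertainty: everyone contributes F
  evo$stationary <- stats::setNames(c(0, 0, 1, 0, 0), names(pop$profiles))
  set.seed(1)
  m4 <- model_metrics(evo, pop, n_groups = 200)
  expect_equal(m4$eta, 1)
  expect_equal(m4$polarization, 0)
})

test_that("always-2 against itself is strictly worse under uncertainty", {
  # the mechanism behind its loss of stability: a homogeneous always-2
  # group is certain to succeed without timing uncertainty, succeeds with
  # probability 4/9 under LU and less under HU
  succ <- vapply(c("NU", "LU", "HU"), function(tr) {
    cfg <- treatment_config(tr)
    expected_outcome(homogeneous("always2", config = cfg),
                     cfg)$success_probability
  }, numeric(1))
  expect_equal(unname(succ["NU"]), 1)
  expect_equal(unname(succ["LU"]), 4 / 9, tolerance = 1e-12)
  expect_lt(succ["HU"], succ["LU"])
  pay <- vapply(c("NU", "LU", "HU"), function(tr) {
    cfg <- treatment_config(tr)
    pop <- population_config(Z = 12, beta = 0.05, game = cfg)
    pairwise_payoff("always2", "always2", 6, pop)[["payoff_A"]]
  }, numeric(1))
  expect_true(pay["NU"] > pay["LU"] && pay["LU"] > pay["HU"])
})

test_that("k out of range is rejected", {
  pop <- small_pop()
  expect_error(pairwise_payoff("always2", "always0", 0, pop),
               class = "crd_config_error")
  expect_error(pairwise_payoff("always2", "always0", 12, pop),
               class = "crd_config_error")
})
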