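cfg <- game_config()

test_that("table validation accepts canonical fixtures and names bad rows", {
  tab <- experiment_table(table_from_matrix(matrix(2, 6, 10)))
  expect_s3_class(tab, "crd_table")
  expect_equal(nrow(tab), 60)

  bad <- table_from_matrix(matrix(2, 6, 10))
  bad$action[7] <- 3
  expect_error(as_experiment_table(bad, cfg), "invalid action 3",
               class = "crd_schema_error")

  over <- table_from_matrix(matrix(4, 6, 11))  # 44 > endowment
  expect_error(as_experiment_table(over, cfg), "endowment",
               class = "crd_schema_error")

  gap <- table_from_matrix(matrix(2, 6, 10))
  gap <- gap[gap$round != 4 | gap$player_id != "g1_p1", ]
  expect_error(as_experiment_table(gap, cfg), "contiguous",
               class = "crd_schema_error")

  short_player <- tibble::tibble(
    treatment = "NU", group_id = "g1", player_id = "g1_p6",
    round = 1:9, action = 2)
  ragged <- dplyr::bind_rows(table_from_matrix(matrix(2, 5, 10)),
                             short_player)
  expect_error(as_experiment_table(ragged, cfg), "realized length",
               class = "crd_schema_error")
})

test_that("load_table reads delimited text through a schema map", {
  tab <- experiment_table(table_from_matrix(matrix(2, 6, 10)))
  src <- as.data.frame(tab)
  names(src) <- c("Treat", "Group", "Subject", "Period", "Contribution")
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path), add = TRUE)
  utils::write.csv(src, path, row.names = FALSE)
  got <- load_table(path, schema_map = c(
    treatment = "Treat", group_id = "Group", player_id = "Subject",
    round = "Period", action = "Contribution"))
  expect_equal(nrow(got), 60)
  expect_error(load_table(path, schema_map = c(action = "nonexistent")),
               class = "crd_schema_error")
  expect_error(load_table("does/not/exist.csv"), class = "crd_io_error")
})

test_that("per-round means use a t-interval over groups", {
  m1 <- matrix(0, 6, 10); m1[1, 1] <- 2; m1[2, 1] <- 4; m1[3, 1] <- 4
  m2 <- matrix(0, 6, 10); m2[1, 1] <- 4; m2[2, 1] <- 4; m2[3, 1] <- 2
  m2[4, 1] <- 4
  tab <- experiment_table(table_from_matrix(m1, gid = "a"),
                          table_from_matrix(m2, gid = "b"))
  res <- per_round_means(tab, "NU")
  expect_equal(res$mean[res$round == 1], 12)   # totals 10 and 14
  # textbook two-observation t interval
  tt <- t.test(c(10, 14))
  expect_equal(res$ci_low[res$round == 1], tt$conf.int[1])
  expect_equal(res$ci_high[res$round == 1], tt$conf.int[2])
  # constant rounds have zero-width intervals
  expect_equal(res$ci_low[res$round == 2], 0)
  expect_equal(res$ci_high[res$round == 2], 0)
})

test_that("single-group rounds yield a mean with a flagged (NA) interval", {
  tab <- experiment_table(table_from_matrix(matrix(2, 6, 10)))
  res <- per_round_means(tab, "NU")
  expect_equal(res$mean, rep(12, 10))
  expect_true(all(is.na(res$ci_low)))
})

test_that("success fractions come with an exact binomial interval", {
  mats <- c(rep(list(matrix(2, 6, 10)), 8), rep(list(matrix(0, 6, 10)), 4))
  tabs <- lapply(seq_along(mats), function(i)
    table_from_matrix(mats[[i]], gid = paste0("g", i)))
  tab <- do.call(experiment_table, tabs)
  sf <- success_fraction(tab, "NU")
  expect_equal(sf$fraction, 8 / 12, tolerance = 1e-12)
  expect_equal(sf$n_groups, 12)
  # Clopper-Pearson limits via the beta closed form
  expect_equal(sf$ci_low, qbeta(0.025, 8, 5), tolerance = 1e-10)
  expect_equal(sf$ci_high, qbeta(0.975, 9, 4), tolerance = 1e-10)

  all_succ <- experiment_table(table_from_matrix(matrix(2, 6, 10)))
  expect_equal(success_fraction(all_succ, "NU")$fraction, 1)
  none <- experiment_table(table_from_matrix(matrix(0, 6, 10)))
  expect_equal(success_fraction(none, "NU")$fraction, 0)
})

test_that("fairness classification partitions players around F", {
  tab <- experiment_table(table_from_matrix(matrix(2, 6, 10)))
  fc <- fairness_classification(tab, "NU")
  expect_equal(fc$fraction, c(0, 1, 0))          # everyone at C = F = 20

  fx <- fixture_suite()
  pol <- fairness_classification(fx$polarized, "NU", successful_only = NA)
  expect_equal(pol$fraction[pol$category == "below"], 0.5)
  expect_equal(pol$fraction[pol$category == "above"], 0.5)
  expect_equal(sum(pol$fraction), 1)
})

test_that("half splits compare half-contributions to F/2 per treatment half", {
  # constant-2 NU player: both halves exactly F/2 = 10
  tab <- experiment_table(table_from_matrix(matrix(2, 6, 10)))
  hs <- half_split(tab, "NU")
  expect_equal(hs$fraction[hs$category == "equal"], c(1, 1))

  # front loader: 4,4,4,0,... gives 12 > 10 in the NU first half
  m <- matrix(2, 6, 10)
  m[1, ] <- c(4, 4, 4, 0, 0, 0, 0, 0, 0, 0)
  hs2 <- half_split(experiment_table(table_from_matrix(m)), "NU",
                    successful_only = NA)
  first <- hs2[hs2$half == "first", ]
  expect_equal(first$fraction[first$category == "above"], 1 / 6)

  # planted early-giver HU cohort: above-share larger in the first half
  fx <- fixture_suite()
  hs3 <- half_split(fx$hu_early, "HU", config = treatment_config("HU"))
  above <- hs3[hs3$category == "above", ]
  expect_gt(above$fraction[above$half == "first"],
            above$fraction[above$half == "second"])
})

test_that("conditional tables aggregate responses to others' previous totals", {
  tab <- experiment_table(table_from_matrix(matrix(2, 6, 10)))
  ct <- conditional_table(tab, "NU")
  expect_equal(ct$x, 10)                # single bin: five others gave 2
  expect_equal(ct$mean_action, 2)
  expect_equal(ct$freq_2, 1)
  expect_equal(ct$n, 6 * 9)             # rounds 2..10

  # homogeneous reciprocal group: x = 20 while contributing, x drops after
  nu <- treatment_config("NU")
  tr <- play_group(homogeneous("reciprocal", config = nu), nu, 10)
  rtab <- experiment_table(table_from_matrix(tr$actions))
  ct2 <- conditional_table(rtab, "NU")
  expect_equal(ct2$mean_action[ct2$x == 20],
               mean(c(rep(4, 4 * 6), rep(0, 6))))  # rounds 2..5 give 4, round 6 gives 0
  expect_true(all(ct2$freq_0 + ct2$freq_2 + ct2$freq_4 == 1))
})

test_that("weighted regression recovers exact linear inputs and planted signs", {
  ct <- tibble::tibble(x = c(0, 10, 20), mean_action = 1 + 0.1 * c(0, 10, 20),
                       n = c(5, 5, 5))
  fit <- suppressWarnings(weighted_regression(ct))  # exact fit warns in summary.lm
  expect_equal(fit$slope, 0.1, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)

  flat <- tibble::tibble(x = c(0, 10, 20), mean_action = c(2, 2, 2),
                         n = c(3, 9, 1))
  expect_equal(suppressWarnings(weighted_regression(flat))$slope, 0,
               tolerance = 1e-12)

  one_bin <- tibble::tibble(x = 10, mean_action = 2, n = 54)
  expect_error(weighted_regression(one_bin), class = "crd_empty_error")

  # weights matter: a weighted fit differs from the unweighted one
  ct2 <- tibble::tibble(x = c(0, 10, 20), mean_action = c(0, 4, 2),
                        n = c(100, 100, 1))
  wfit <- weighted_regression(ct2)
  ufit <- stats::lm(mean_action ~ x, data = ct2)
  expect_false(isTRUE(all.equal(wfit$slope, unname(coef(ufit)["x"]))))
  expect_equal(wfit$slope,
               unname(coef(stats::lm(mean_action ~ x, data = ct2,
                                     weights = n))["x"]))
})

test_that("constant contributors are counted exactly", {
  fx <- fixture_suite()
  expect_equal(constant_contributor_count(fx$planted_two_all2, "NU", 2), 2)
  expect_equal(constant_contributor_count(fx$planted_two_all2, "NU", 0), 0)
  tab <- experiment_table(table_from_matrix(matrix(2, 6, 10)))
  expect_equal(constant_contributor_count(tab, "NU", 2), 6)
  expect_equal(constant_contributor_count(tab, "NU", 2,
                                          successful_only = TRUE), 6)
  expect_equal(constant_contributor_count(tab, "NU", 2,
                                          successful_only = FALSE), 0)
})

test_that("profile classification recovers planted behaviors", {
  tab <- experiment_table(table_from_matrix(matrix(2, 6, 10)))
  cl <- classify_profile(tab, "NU")
  expect_true(all(cl$class == "unconditional-2"))

  # simulated conditional players inside a mixed group
  nu <- treatment_config("NU")
  profs <- c(list(strategy_profile("reciprocal", config = nu),
                  strategy_profile("compensator", config = nu)),
             homogeneous("always4", n = 2, config = nu),
             homogeneous("always0", n = 2, config = nu))
  tr <- play_group(profs, nu, 10)
  mtab <- experiment_table(table_from_matrix(tr$actions))
  cl2 <- classify_profile(mtab, "NU")
  expect_equal(cl2$class[1], "reciprocal-like")
  expect_equal(cl2$class[2], "compensator-like")
  expect_equal(cl2$class[3], "unconditional-4")
  expect_equal(cl2$class[5], "unconditional-0")
})

test_that("analysis outputs are deterministic in the input table", {
  fx <- fixture_suite()
  a <- conditional_table(fx$planted_two_all2, "NU")
  b <- conditional_table(fx$planted_two_all2, "NU")
  expect_identical(a, b)
})
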