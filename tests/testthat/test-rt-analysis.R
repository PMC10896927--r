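test_that("outlier filter keeps the closed interval and reports fractions", {
  tr <- data.frame(rt_ms = c(200, 250, 1500, 2000, 2500))
  rep <- filter_outliers(tr)
  expect_equal(sort(rep$trials$rt_ms), c(250, 1500, 2000))
  expect_equal(rep$n_below_low, 1)
  expect_equal(rep$n_above_high, 1)
  expect_equal(rep$fraction_below, 0.2)
  # idempotence
  rep2 <- filter_outliers(rep$trials)
  expect_equal(rep2$trials, rep$trials)
  expect_equal(rep2$n_below_low + rep2$n_above_high, 0)
  # empty input
  empty <- filter_outliers(tr[0, , drop = FALSE])
  expect_equal(empty$n_input, 0)
  expect_equal(empty$fraction_below, 0)
  expect_error(filter_outliers(tr, low = 2000, high = 250), "smaller")
})

test_that("condition summary uses correct trials for RT and all trials for PC", {
  tr <- data.frame(subject_id = "S001", item_id = "PAST01", domain = "time",
                   category = "past", match = c("match", "match"),
                   congruency = "not_applicable", block_index = 1L,
                   half = "first", rt_ms = c(700, 900), correct = c(TRUE, FALSE))
  cs <- condition_summary(tr, "match")
  expect_equal(cs$mean_rt, 700)
  expect_equal(cs$pc, 50)
  expect_error(condition_summary(tr, "colour"), "unknown factor")
})

test_that("noise-free generator gives exactly the parameterized cell contrasts", {
  trials <- generate_rt_experiment(design_exp1(n_subjects = 4, items_per_category = 2),
                                   det_params(match_effect = 170,
                                              congruency_effect = 48,
                                              domain_effect = 158))
  cs <- condition_summary(trials, c("match", "congruency", "domain"))
  agg <- tapply(cs$mean_rt, cs$match, mean)
  expect_equal(agg[["mismatch"]] - agg[["match"]], 170)
  e <- estimate_effect(trials, "match", n_permutations = 200, seed = 1)
  expect_equal(e$estimate, 170)
  expect_equal(e$type, "between")
  e2 <- estimate_effect(trials, "domain", n_permutations = 200, seed = 1)
  expect_equal(e2$estimate, 158)
  expect_equal(e2$type, "within")
})

test_that("permutation estimate is zero and p is 1 for identical level means", {
  tr <- expand.grid(subject_id = c("S001", "S002"), item_id = "PAST01",
                    match = c("match", "mismatch"), stringsAsFactors = FALSE)
  tr$domain <- "time"; tr$category <- "past"; tr$congruency <- "not_applicable"
  tr$block_index <- 1L; tr$half <- "first"; tr$rt_ms <- 500; tr$correct <- TRUE
  e <- estimate_effect(tr, "match", n_permutations = 100, seed = 1)
  expect_equal(e$estimate, 0)
  expect_equal(e$permutation_p, 1)
})

test_that("swapping level labels flips the estimate's sign", {
  trials <- generate_rt_experiment(small_design(8, 3), rt_gen_params(seed = 12))
  e1 <- estimate_effect(trials, "match", n_permutations = 200, seed = 5)
  flipped <- trials
  flipped$match <- ifelse(trials$match == "match", "mismatch", "match")
  e2 <- estimate_effect(flipped, "match", n_permutations = 200, seed = 5)
  expect_equal(e2$estimate, -e1$estimate)
  expect_equal(e2$permutation_p, e1$permutation_p)
})

test_that("estimate converges to the generator parameter at large n", {
  trials <- generate_rt_experiment(
    design_exp2(n_subjects = 200, items_per_category = 8),
    rt_gen_params(match_effect = 170, congruency_effect = 0, domain_effect = 0,
                  practice_slope = 0, seed = 77))
  e <- estimate_effect(filter_outliers(trials)$trials, "match",
                       n_permutations = 300, seed = 1)
  expect_lt(abs(e$estimate - 170), 3 * 4.2 / sqrt(5))  # SEM scales ~ 1/sqrt(n)
  expect_lt(e$permutation_p, 0.01)
})

test_that("permutation estimate agrees with a mixed-model cross-check", {
  skip_if_not_installed("lme4")
  trials <- generate_rt_experiment(
    design_exp2(n_subjects = 30),
    rt_gen_params(match_effect = 170, congruency_effect = 0, domain_effect = 0,
                  practice_slope = 0, seed = 14))
  flt <- filter_outliers(trials)$trials
  e <- estimate_effect(flt, "match", 500, seed = 1)
  mm <- suppressMessages(mixed_model_check(flt, "match"))
  expect_lt(abs(e$estimate - mm), 5)
})

test_that("missing levels raise inference errors", {
  trials <- generate_rt_experiment(small_design(4, 2), rt_gen_params(seed = 1))
  only_match <- trials[trials$match == "match", ]
  expect_error(estimate_effect(only_match, "match", 100, seed = 1), "missing")
  expect_error(estimate_effect(trials, "congruency", 100, seed = 1), "missing")
  expect_error(estimate_effect(trials, "match", 100), "seed")
})

test_that("half split reports the cell differences with the printed signs", {
  trials <- generate_rt_experiment(small_design(4, 2),
                                   det_params(match_effect = 100,
                                              error_mismatch_increment = 0))
  hs <- half_split(trials, n_permutations = 100, seed = 1)
  expect_equal(hs$cells$rt_effect, c(100, 100))
  expect_equal(hs$cells$half, c("first", "second"))
  # identical halves: interaction difference 0, p = 1
  expect_equal(hs$interaction_p_rt, 1)
})

test_that("a practice-modulated match effect is detected in the interaction", {
  trials <- generate_rt_experiment(design_exp2(n_subjects = 24),
                                   rt_gen_params(match_effect = 120,
                                                 practice_slope = 0, seed = 21))
  # enlarge the match effect in the second half only
  boost <- trials$half == "second" & trials$match == "mismatch"
  trials$rt_ms[boost] <- trials$rt_ms[boost] + 120
  hs <- half_split(filter_outliers(trials)$trials, n_permutations = 500, seed = 2)
  expect_gt(hs$cells$rt_effect[2], hs$cells$rt_effect[1])
  expect_lt(hs$interaction_p_rt, 0.05)
  expect_error(half_split(trials[trials$half == "first", ], 100, seed = 1), "half")
})

test_that("speed-accuracy check distinguishes genuine effects from trade-offs", {
  trials <- generate_rt_experiment(small_design(6, 3),
                                   det_params(match_effect = 150,
                                              error_mismatch_increment = 0))
  # mismatch slower; make it also less accurate -> consistent
  trials$correct[trials$match == "mismatch"][1:10] <- FALSE
  rep <- speed_accuracy_check(trials, "match")
  expect_true(rep$consistent)
  # now make the slower condition the more accurate one -> trade-off
  tr2 <- generate_rt_experiment(small_design(6, 3),
                                det_params(match_effect = 150,
                                           error_mismatch_increment = 0))
  tr2$correct[tr2$match == "match"][1:10] <- FALSE
  expect_false(speed_accuracy_check(tr2, "match")$consistent)
  # equal accuracy counts as consistent (weak inequality)
  tr3 <- generate_rt_experiment(small_design(6, 3),
                                det_params(match_effect = 150,
                                           error_mismatch_increment = 0))
  expect_true(speed_accuracy_check(tr3, "match")$consistent)
})
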