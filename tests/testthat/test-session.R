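cfg <- psi_config()

test_that("session plans have the required structure", {
  set.seed(51)
  plan <- build_session()
  expect_equal(nrow(plan), 11L * 48L + 48L)
  expect_equal(sum(plan$is_catch), 48L)
  expect_equal(sum(!plan$is_catch), 528L)
  expect_equal(sum(plan$catch_orientation == "parallel", na.rm = TRUE), 24L)
  expect_equal(sum(plan$catch_orientation == "orthogonal", na.rm = TRUE), 24L)
  counts <- table(plan$condition[!plan$is_catch])
  expect_true(all(counts == 48L))
  expect_equal(sort(names(counts)), sort(condition_table()$condition))
  # interleaved, not blocked: no condition occupies one contiguous run
  runs <- rle(plan$condition[!plan$is_catch])
  expect_gt(length(runs$lengths), 11L)
  # per-condition slot indices count each staircase's trials 1..48
  for (cn in c("no_surround", "near_0"))
    expect_equal(plan$stair_trial[plan$condition %in% cn], 1:48)
  set.seed(52)
  p1 <- build_session()
  set.seed(52)
  p2 <- build_session()
  expect_identical(p1, p2)
  expect_error(build_session(n_catch = 47L), "even")
})

test_that("last-three-estimate extraction is exact and guarded", {
  expect_equal(extract_condition_estimate(c(-10, -10, -10, -10)), -10)
  expect_equal(extract_condition_estimate(c(-5, -8, -9, -10)), -9)
  expect_error(extract_condition_estimate(c(-5, -8)), "at least 3")
})

test_that("a default observer's session recovers the model's condition structure", {
  res <- run_session(observer_params(), config = cfg, seed = 53)
  expect_s3_class(res, "session_result")
  expect_length(res$estimates, 11L)
  expect_equal(nrow(res$trials), 576L)
  expect_lt(abs(res$estimates[["no_surround"]]), 2)
  expect_lt(res$estimates[["near_0"]], res$estimates[["near_90"]])
  expect_gt(res$summary$catch_accuracy, 0.9)
  expect_true(res$summary$included)
  # catch trials never touch a staircase: staircase rows count to 48 each
  st <- res$trials[!res$trials$is_catch, ]
  expect_true(all(table(st$condition) == 48L))
  expect_true(all(st$decrement >= -75 & st$decrement <= 15))
  expect_true(all(res$trials$decrement[res$trials$is_catch] == -50))
})

test_that("the batched cohort engine reproduces per-observer sessions exactly", {
  coh <- sample_cohort(cohort_spec(sizes = c(HC = 2L, PSZ = 1L)), seed = 54)
  batch <- normsupp:::run_cohort_sessions(coh, cfg, keep_trials = TRUE)
  for (i in 1:3) {
    single <- run_session(cohort_observer(coh, i), config = cfg,
                          seed = coh$seed[i])
    num <- vapply(single$summary, is.numeric, logical(1L))
    expect_equal(unlist(single$summary[num]),
                 unlist(batch$summary[i, num]), tolerance = 1e-9)
    expect_identical(single$summary$included, batch$summary$included[i])
    tr_b <- batch$trials[batch$trials$observer_id == coh$observer_id[i], ]
    expect_equal(single$trials$decrement, tr_b$decrement)
    expect_equal(single$trials$response, tr_b$response)
  }
})

test_that("session estimates track the generative PSEs", {
  coh <- sample_cohort(cohort_spec(sizes = c(HC = 50L)), seed = 55)
  batch <- normsupp:::run_cohort_sessions(coh, cfg)
  for (cn in paste0("near_", c(0, 20, 45, 70, 90))) {
    truth <- vapply(seq_len(nrow(coh)), function(i)
      true_pses(cohort_observer(coh, i))[[cn]], numeric(1L))
    err <- abs(batch$summary[[cn]] - truth)
    expect_lt(median(err), 3)
  }
})

test_that("inclusion rules flag catch failures first, then missing suppression", {
  s <- data.frame(catch_accuracy = c(0.70, 1.0, 1.0, 0.74),
                  near_0 = c(-20, 3, -20, 3),
                  near_20 = c(-10, -10, -10, -10))
  out <- apply_exclusions(s)
  expect_equal(out$included, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$exclusion_reason,
               c("catch_fail", "no_suppression", "none", "catch_fail"))
  # strictly better than 75%: exactly 0.75 fails
  s2 <- data.frame(catch_accuracy = 0.75, near_0 = -1, near_20 = -1)
  expect_false(apply_exclusions(s2)$included)
})

test_that("less noisy observers are never excluded more often", {
  spec_lo <- cohort_spec(sizes = c(HC = 24L), beta_true = 0.04)
  spec_hi <- cohort_spec(sizes = c(HC = 24L), beta_true = 0.5)
  coh_lo <- sample_cohort(spec_lo, seed = 56)
  coh_hi <- sample_cohort(spec_hi, seed = 56)   # matched seeds
  r_lo <- normsupp:::run_cohort_sessions(coh_lo, cfg)
  r_hi <- normsupp:::run_cohort_sessions(coh_hi, cfg)
  expect_lte(sum(!r_hi$summary$included), sum(!r_lo$summary$included))
  # and the noisy group really is excluded sometimes (catch failures)
  expect_gt(sum(!r_lo$summary$included), 0L)
})

test_that("the five-SD outlier rule matches direct computation", {
  expect_true(all(!flag_outliers(rep(-5, 10))))
  v <- c(rep(0, 100), 60)
  f <- flag_outliers(v)
  expect_identical(which(f), 101L)
  expect_identical(flag_outliers(v + 17), f)   # translation invariance
  expect_identical(flag_outliers(v, n_sd = 15), rep(FALSE, 101))
  expect_error(flag_outliers(c(1, 2)), "at least 3")
  # NA values are ignored, never flagged
  f2 <- flag_outliers(c(NA, v))
  expect_identical(which(f2), 102L)
})
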