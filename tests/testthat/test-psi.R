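cfg_default <- psi_config()

test_that("initial posterior is uniform with the grid-mean threshold", {
  st <- psi_init(cfg_default)
  expect_equal(length(st$posterior), 61L * 99L)
  expect_true(all(abs(st$posterior - 1 / (61 * 99)) < 1e-15))
  expect_equal(psi_threshold(st), -10)
  expect_equal(st$trial_count, 0L)
  expect_length(st$estimate_history, 0L)
  expect_error(psi_config(alpha = numeric(0)), "alpha")
  expect_error(psi_config(alpha = c(0, 1, 3)), "uniform")
  expect_error(psi_config(delta = 0.6), "delta")
})

test_that("posterior update matches the hand-computed two-cell example", {
  c2 <- psi_config(alpha = c(-10, 0), beta = 1,
                   intensity = c(-20, -5, 10), delta = 0)
  st <- psi_update(psi_init(c2), -5, "reference_higher", c2)
  l1 <- plogis(1 * (-5 - -10)); l2 <- plogis(1 * (-5 - 0))
  expect_equal(st$posterior, c(l1, l2) / (l1 + l2), tolerance = 1e-12)
  expect_equal(psi_threshold(st), -10 * l1 / (l1 + l2), tolerance = 1e-12)
  expect_equal(tail(st$estimate_history, 1), psi_threshold(st))
  expect_equal(st$trial_count, 1L)
  expect_error(psi_update(st, -7, "reference_higher", c2), "grid")
})

test_that("an uninformative trial leaves the posterior unchanged", {
  c3 <- psi_config(alpha = c(-10, 0), beta = c(1, 2),
                   intensity = seq(-20, 60, by = 10), delta = 0)
  st0 <- psi_init(c3)
  st <- psi_update(st0, 60, "reference_higher", c3)
  expect_true(max(abs(st$posterior - st0$posterior)) < 1e-12)
})

test_that("posterior stays normalized through a long staircase", {
  set.seed(31)
  obs <- observer_params(beta_true = 0.4, lapse_true = 0.05)
  st <- psi_init(cfg_default)
  for (t in 1:48) {
    x <- psi_select(st, cfg_default)
    expect_true(x %in% cfg_default$intensity)
    st <- psi_update(st, x, respond_trial(obs, x, -15), cfg_default)
    expect_lt(abs(sum(st$posterior) - 1), 1e-10)
  }
  expect_equal(st$trial_count, 48L)
  expect_length(st$estimate_history, 48L)
  expect_true(all(st$x_history >= -75 & st$x_history <= 15))
})

test_that("stimulus selection agrees with the brute-force entropy oracle", {
  # spec's small hand-enumerable case
  c2 <- psi_config(alpha = c(-10, 0), beta = 1,
                   intensity = c(-20, -5, 10), delta = 0)
  st <- psi_init(c2)
  expect_equal(psi_select(st, c2),
               oracle_psi_select(matrix(st$posterior, 2, 1), c(-10, 0), 1,
                                 c(-20, -5, 10), delta = 0))
  # randomized small grids, random (non-uniform) posteriors, both families
  set.seed(33)
  for (case in 1:12) {
    na <- sample(2:5, 1); nb <- sample(1:3, 1); nx <- sample(2:5, 1)
    alpha <- sort(runif(1, -30, -10) + (0:(na - 1)) * runif(1, 2, 8))
    beta <- sort(runif(1, 0.2, 1) + (0:(nb - 1)) * runif(1, 0.2, 1))
    xg <- sort(runif(1, -40, -10) + (0:(nx - 1)) * runif(1, 5, 15))
    delta <- sample(c(0, 0.08), 1)
    fam <- sample(c("logistic", "gaussian"), 1)
    cc <- psi_config(alpha = alpha, beta = beta, intensity = xg,
                     delta = delta, family = fam)
    st <- psi_init(cc)
    post <- matrix(rexp(na * nb), na, nb)
    post <- post / sum(post)
    st$posterior <- as.vector(post)
    expect_equal(psi_select(st, cc),
                 oracle_psi_select(post, alpha, beta, xg, delta, fam),
                 info = paste("case", case))
  }
})

test_that("a point-mass posterior yields zero entropy and the smallest-x tie-break", {
  c2 <- psi_config(alpha = c(-10, 0, 10), beta = 1,
                   intensity = c(-20, -5, 10), delta = 0)
  st <- psi_init(c2)
  post <- rep(0, 3)
  post[2] <- 1
  st$posterior <- post
  expect_equal(psi_select(st, c2), -20)
  expect_equal(psi_threshold(st), 0)
  st$posterior <- c(0, 0, 0)
  expect_error(psi_select(st, c2), "degenerate")
})

test_that("point-mass threshold estimates are exact", {
  st <- psi_init(cfg_default)
  p <- rep(0, length(st$posterior))
  p[which(st$alpha_cell == -22)[1]] <- 1
  st$posterior <- p
  expect_equal(psi_threshold(st), -22)
})

test_that("staircases converge to the observer's PSE", {
  # near-deterministic observer: last-3 mean within the grid's precision
  set.seed(35)
  det <- observer_params(beta_true = 50, lapse_true = 0)
  st <- run_staircase(det, -20, 48, cfg_default)
  expect_lt(abs(mean(tail(st$estimate_history, 3)) + 20), 2)
  # zero-trial staircase returns the prior mean
  expect_equal(psi_threshold(psi_init(cfg_default)), -10)
  expect_error(run_staircase(det, -20, 0), "n_trials")
  # 100 replicates at realistic noise: small mean bias
  set.seed(36)
  U <- matrix(runif(48 * 100), 48, 100)
  b <- normsupp:::psi_run_batch(rep(-20, 100), rep(0.5, 100), rep(0.04, 100),
                                48, cfg_default, U)
  last3 <- colMeans(b$estimate_history[46:48, ])
  expect_lt(abs(mean(last3) + 20), 1.5)
  expect_true(all(b$x >= -75 & b$x <= 15))
})

test_that("estimate spread shrinks as trials accumulate (matched seeds)", {
  set.seed(37)
  n <- 150
  U <- matrix(runif(96 * n), 96, n)
  b48 <- normsupp:::psi_run_batch(rep(-20, n), rep(0.5, n), rep(0.04, n),
                                  48, cfg_default, U)
  b96 <- normsupp:::psi_run_batch(rep(-20, n), rep(0.5, n), rep(0.04, n),
                                  96, cfg_default, U)
  v48 <- var(colMeans(b48$estimate_history[46:48, ]))
  v96 <- var(colMeans(b96$estimate_history[94:96, ]))
  expect_lt(v96 / v48, 0.75)
})

test_that("batched staircases reproduce the sequential path", {
  set.seed(38)
  U <- matrix(runif(48 * 3), 48, 3)
  b <- normsupp:::psi_run_batch(c(-25, -10, -2), rep(0.6, 3), rep(0.04, 3),
                                48, cfg_default, U)
  for (j in 1:3) {
    st <- psi_init(cfg_default)
    for (t in 1:48) {
      x <- psi_select(st, cfg_default)
      pr <- normsupp:::p_reference_higher(x, c(-25, -10, -2)[j], 0.6, 0.04)
      r <- if (U[t, j] < pr) "reference_higher" else "target_higher"
      st <- psi_update(st, x, r, cfg_default)
    }
    expect_equal(st$x_history, b$x[, j])
    expect_equal(st$estimate_history, b$estimate_history[, j],
                 tolerance = 1e-9)
  }
})
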