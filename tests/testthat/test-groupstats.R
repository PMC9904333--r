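test_that("Huynh-Feldt epsilon has its closed-form limits", {
  S_cs <- diag(4) * 0.6 + 0.4
  expect_equal(as.numeric(hf_epsilon(S_cs, n = 20, g = 1)), 1)
  # one dominant contrast: epsilon collapses to the 1/(k-1) bound
  S_bad <- diag(c(10, 1e-4, 1e-4))
  expect_equal(as.numeric(hf_epsilon(S_bad, n = 20, g = 1)), 0.5,
               tolerance = 0.01)
  expect_error(hf_epsilon(matrix(c(1, 2, 0, 1), 2), 10), "symmetric")
})

test_that("Huynh-Feldt epsilon matches an independent formula evaluation", {
  set.seed(71)
  for (case in 1:10) {
    k <- sample(3:5, 1)
    S <- random_spd(k)
    n <- sample(10:40, 1)
    g <- sample(1:3, 1)
    expect_equal(as.numeric(hf_epsilon(S, n, g)),
                 oracle_hf_epsilon(S, n, g), tolerance = 1e-10)
  }
})

null_long <- function(n_per_group = 10, k = 3, groups = 3) {
  n <- n_per_group * groups
  data.frame(observer_id = rep(sprintf("s%03d", 1:n), each = k),
             condition = rep(paste0("c", 1:k), n),
             estimate = rnorm(k * n),
             group = rep(rep(paste0("g", 1:groups), each = n_per_group),
                         each = k),
             logmar = rep(rnorm(n), each = k))
}

test_that("the repeated-measures ANCOVA has the split-plot layout", {
  set.seed(72)
  d <- null_long()
  a <- rm_ancova(d)
  expect_s3_class(a, "anova_table")
  expect_setequal(a$effect, c("logmar", "group", "condition",
                              "logmar:condition", "group:condition"))
  eps <- attr(a, "epsilon")
  expect_true(eps >= 0.5 && eps <= 1)
  grp <- a[a$effect == "group", ]
  expect_equal(grp$df1, 2)
  expect_equal(grp$df2, 30 - 4)    # n - (intercept + covariate + g-1)
  expect_true(all(a$F >= 0) && all(a$p >= 0 & a$p <= 1))
  # covariate omitted on request
  a2 <- rm_ancova(d, covariate = NULL)
  expect_setequal(a2$effect, c("group", "condition", "group:condition"))
  expect_equal(a2[a2$effect == "group", "df2"], 30 - 3)
  expect_error(rm_ancova(d[d$group == "g1", ]), "groups")
})

test_that("an injected condition effect is detected with high power", {
  set.seed(73)
  hits <- logical(200)
  for (r in seq_len(200)) {
    d <- null_long(n_per_group = 20, groups = 2)
    d$estimate <- rnorm(nrow(d), sd = 5)
    d$estimate[d$condition == "c1"] <- d$estimate[d$condition == "c1"] - 15
    a <- rm_ancova(d)
    hits[r] <- a$p[a$effect == "condition"] < 0.001
  }
  expect_gt(mean(hits), 0.95)
})

test_that("one-way ANCOVA is translation invariant and absorbs the covariate", {
  set.seed(74)
  g <- rep(c("a", "b", "c"), each = 12)
  cv <- rnorm(36)
  y <- 0.5 * cv + rnorm(36)
  a1 <- ancova_oneway(y, g, cv)
  a2 <- ancova_oneway(y + 100, g, cv)
  expect_equal(a1$F, a2$F, tolerance = 1e-10)
  expect_equal(a1$df1, 2)
  # null with a covariate-driven response: p uniform
  ps <- replicate(400, {
    cv <- rnorm(36); y <- 2 * cv + rnorm(36, sd = 0.3)
    ancova_oneway(y, sample(g), cv)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_error(ancova_oneway(y[1:3], g[1:3], cv[1:3]), "groups")
})

test_that("a group shift at study-like sample sizes is detected", {
  set.seed(75)
  sizes <- c(PSZ = 31, PBD = 29, HC = 29, PSZrel = 28, PBDrel = 21)
  g <- rep(names(sizes), sizes)
  hits <- replicate(200, {
    cv <- rnorm(length(g), 0.1, 0.13)
    y <- rnorm(length(g), sd = 3)
    y[g == "PSZ"] <- y[g == "PSZ"] + 5
    ancova_oneway(y, g, cv)$p < 0.05
  })
  expect_gt(mean(hits), 0.8)
})

test_that("the moderation test targets the interaction block", {
  set.seed(76)
  sizes <- c(PSZ = 31, PBD = 29, HC = 29, PSZrel = 28, PBDrel = 21)
  g <- rep(names(sizes), sizes)
  cv <- rnorm(length(g), 0.1, 0.13)
  m <- moderation_test(rnorm(length(g)), g, cv)
  expect_equal(m$df1, 4)   # 5 groups -> 4 numerator df
  expect_equal(m$df2, length(g) - 10)
  split <- attr(m, "split")
  expect_true(all(c("group", "acuity", "mean_value") %in% names(split)))
  # power: acuity slope present in one group only
  hits <- replicate(200, {
    cv <- rnorm(length(g), 0.1, 0.13)
    y <- rnorm(length(g), sd = 3)
    y[g == "PSZ"] <- y[g == "PSZ"] + 30 * cv[g == "PSZ"]
    moderation_test(y, g, cv)$p < 0.05
  })
  expect_gt(mean(hits), 0.8)
  # inestimable when a group has constant acuity
  cv2 <- cv
  cv2[g == "HC"] <- 0.1
  expect_error(moderation_test(rnorm(length(g)), g, cv2), "inestimable")
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  # hand application: {0.01, 0.02, 0.03} with m = 3 -> all 0.03
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  set.seed(77)
  g <- rep(c("a", "b", "c", "d", "e"), each = 10)
  y <- rnorm(50) + 3 * (g == "a")
  cv <- rnorm(50)
  pw <- pairwise_fdr(y, g, cv)
  expect_equal(nrow(pw), 10L)
  ord <- order(pw$p)
  expect_true(all(diff(pw$p_adj[ord]) >= -1e-12))
  expect_true(all(pw$p_adj >= pw$p - 1e-12))
  # a single comparison is unadjusted
  pw2 <- pairwise_fdr(y[g %in% c("a", "b")], g[g %in% c("a", "b")])
  expect_equal(pw2$p_adj, pw2$p)
  # the planted group separates from the others
  expect_true(all(pw$p_adj[pw$group1 == "a"] < 0.05))
})

test_that("the BIC Bayes-factor approximation favors real effects", {
  set.seed(78)
  x <- rep(0:1, each = 40)
  y1 <- rnorm(80) + 2 * x
  y0 <- rnorm(80)
  bf_effect <- bic_bayes_factor(lm(y1 ~ x), lm(y1 ~ 1))
  bf_null <- bic_bayes_factor(lm(y0 ~ x), lm(y0 ~ 1))
  expect_gt(bf_effect, 3)
  expect_lt(bf_null, 1)
})
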