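test_that("standardized mean difference behaves as the balance diagnostic", {
  x <- c(1, 2, 3, 4)
  expect_equal(smd(x, x), 0)
  expect_equal(smd(x, x + 1), -smd(x + 1, x))
  set.seed(5)
  a <- rnorm(1e5, 1, 1); b <- rnorm(1e5, 0, 1)
  expect_equal(smd(a, b), 1.0, tolerance = 0.02)
  expect_error(smd(c(1, 1), c(1, 1)), "pooled")
  # constant weights reduce to the unweighted value
  expect_equal(smd(a[1:100], b[1:100], rep(2, 100), rep(2, 100)),
               smd(a[1:100], b[1:100]))
})

test_that("matching picks exact covariate duplicates and balances to zero", {
  set.seed(6)
  n <- 12
  participants <- data.frame(
    id = sprintf("P%02d", 1:n), sex = rep(c("male", "female"), each = n / 2),
    age = runif(n, 50, 75), bmi = runif(n, 24, 38),
    baseline_hba1c = runif(n, 53, 80), stringsAsFactors = FALSE)
  # registry: two exact duplicates of each participant plus decoys far away
  dup <- participants[rep(1:n, each = 2), ]
  reg <- toy_registry(sprintf("R%03d", 1:(2 * n)), dup$sex, dup$age, dup$bmi,
                      dup$baseline_hba1c)
  decoy <- toy_registry(sprintf("D%03d", 1:(2 * n)), dup$sex, dup$age + 30,
                        dup$bmi + 15, dup$baseline_hba1c + 40)
  m <- match_controls(participants, rbind(reg, decoy), ratio = 2, seed = 1)
  expect_equal(nrow(m$pairs), 2 * n)
  expect_true(all(table(m$pairs$participant_id) == 2))
  expect_true(all(grepl("^R", m$pairs$control_id)))
  expect_false(any(duplicated(m$pairs$control_id)))
  expect_equal(m$balance$smd_post, rep(0, 3), tolerance = 1e-9)
})

test_that("matching reduces covariate shift and errors on shortfall", {
  cfg <- small_config()
  participants <- generate_cohort(cfg)$participants
  reg <- generate_registry(cfg)
  reg$bmi <- reg$bmi + 2
  reg$age <- reg$age + 3
  worst_pre <- worst_post <- numeric()
  for (s in 1:5) {
    m <- match_controls(participants, reg, ratio = 2, seed = s)
    worst_pre <- c(worst_pre, max(abs(m$balance$smd_pre)))
    worst_post <- c(worst_post, max(abs(m$balance$smd_post)))
  }
  expect_true(all(worst_post < worst_pre))
  expect_error(match_controls(participants, reg[reg$id %in% unique(reg$id)[1:20], ],
                              ratio = 2, seed = 1),
               "insufficient eligible controls")
})

test_that("index dates respect the two-year post-diagnosis rule", {
  cfg <- small_config()
  reg <- generate_registry(cfg)
  participants <- generate_cohort(cfg)$participants
  m <- match_controls(participants, reg, ratio = 2, seed = 2)
  expect_true(all(m$index_dates >= 730))
})

test_that("propensity probabilities track the separating feature and are reproducible", {
  set.seed(30)
  n <- 200
  x <- rnorm(n)
  y <- as.integer(x + rnorm(n, 0, 0.3) > 0)
  X <- data.frame(x = x, junk = rnorm(n))
  fit <- estimate_propensity(X, y, max_trees = 80, cv_folds = 3, seed = 3)
  expect_true(all(fit$probabilities > 0 & fit$probabilities < 1))
  expect_gt(mean(fit$probabilities[y == 1]), mean(fit$probabilities[y == 0]))
  expect_lte(fit$n_trees, 80)
  fit2 <- estimate_propensity(X, y, max_trees = 80, cv_folds = 3, seed = 3)
  expect_identical(fit, fit2)
  # missing values are split on observed values, not dropped
  Xna <- X; Xna$x[1:20] <- NA
  expect_silent(fitna <- estimate_propensity(Xna, y, max_trees = 40,
                                             cv_folds = 3, seed = 3))
  expect_length(fitna$probabilities, n)
  expect_error(estimate_propensity(X, rep(1, n), seed = 1), "both classes")
})

test_that("the three weighting schemes assign the stated weights", {
  expect_equal(ipw_weights("user_vs_nonuser", 0.5, TRUE), 2.0)
  expect_equal(ipw_weights("user_vs_nonuser", 0.2, FALSE), 1.25)
  expect_equal(ipw_weights("dropout_adjust", c(0.7, 0.3), c(FALSE, FALSE)),
               c(1, 1))
  expect_equal(ipw_weights("adherence_adjust", 0.25, TRUE), 4)
  expect_error(ipw_weights("user_vs_nonuser", 1.2, TRUE), "probabilities")
})

test_that("weighted group difference equals the closed-form weighted means", {
  set.seed(31)
  y <- rnorm(80)
  g <- rep(c(FALSE, TRUE), 40)
  w <- runif(80, 0.5, 3)
  res <- weighted_group_difference(y, g, w)
  oracle <- sum(w[g] * y[g]) / sum(w[g]) - sum(w[!g] * y[!g]) / sum(w[!g])
  expect_equal(res$estimate, oracle, tolerance = 1e-10)
  # unit weights give the plain difference of means
  res1 <- weighted_group_difference(y, g)
  expect_equal(res1$estimate, mean(y[g]) - mean(y[!g]), tolerance = 1e-10)
  # rescaling all weights changes nothing
  res2 <- weighted_group_difference(y, g, 2 * w)
  expect_equal(res2$estimate, res$estimate)
  expect_equal(res2$se, res$se, tolerance = 1e-10)
  expect_error(weighted_group_difference(y, rep(TRUE, 80)), "two groups")
})

test_that("endpoint contrast is the Welch t-test on a minus b", {
  a <- c(1, 2, 3, 4)
  res <- endpoint_contrast(a, a)
  expect_equal(res$estimate, 0)
  expect_equal(res$p_value, 1)
  res2 <- endpoint_contrast(a + 5, a)
  expect_equal(res2$estimate, 5)
  expect_error(endpoint_contrast(1, a), "at least 2")
})

test_that("interaction test recovers the cell-means contrast", {
  # saturated truth {0,0,0,d}
  d <- 3.7
  g <- rep(c(0, 0, 1, 1), each = 10)
  s <- rep(c(0, 1, 0, 1), each = 10)
  y <- d * g * s
  fit <- interaction_test(y + rnorm(40, 0, 1e-8), g == 1, s == 1)
  expect_equal(fit$interaction, d, tolerance = 1e-4)
  # balanced design: estimate equals the difference-in-differences of means
  set.seed(32)
  y2 <- rnorm(40, 1 + 0.5 * g + 0.8 * s + 1.4 * g * s)
  fit2 <- interaction_test(y2, g == 1, s == 1)
  dd <- (mean(y2[g == 1 & s == 1]) - mean(y2[g == 1 & s == 0])) -
    (mean(y2[g == 0 & s == 1]) - mean(y2[g == 0 & s == 0]))
  expect_equal(fit2$interaction, dd, tolerance = 1e-10)
  expect_error(interaction_test(y2, g == 1, rep(TRUE, 40)), "cells")
})

test_that("interaction test keeps its nominal type-I error under the null", {
  set.seed(33)
  rejections <- mean(replicate(400, {
    g <- rep(0:1, each = 20); s <- rbinom(40, 1, 0.5)
    if (length(unique(s[g == 0])) < 2 || length(unique(s[g == 1])) < 2) return(NA)
    interaction_test(rnorm(40, 1 + 0.3 * g + 0.2 * s), g == 1, s == 1)$p_value < 0.05
  }), na.rm = TRUE)
  expect_lt(abs(rejections - 0.05), 0.035)
})

test_that("mediation decomposition recovers full mediation and the identity", {
  set.seed(34)
  n <- 300
  x <- rnorm(n)
  m <- 0.8 * x + rnorm(n, 0, 0.3)
  y <- -0.625 * m + rnorm(n, 0, 0.3)   # fully mediated, a*b = -0.5
  res <- mediation(x, m, y, n_boot = 500, seed = 2)
  expect_equal(res$effects$indirect, -0.5, tolerance = 0.07)
  expect_equal(res$effects$prop_mediated, 1, tolerance = 0.1)
  expect_equal(res$effects$total, res$effects$direct + res$effects$indirect,
               tolerance = 1e-12)
  # total equals the reduced-model exposure coefficient
  expect_equal(res$effects$total, unname(coef(lm(y ~ x))[2]), tolerance = 1e-9)
  # with moderators
  z <- rnorm(n)
  res2 <- mediation(x, m, y + 0.3 * z, moderators = data.frame(z = z),
                    n_boot = 200, seed = 2)
  expect_equal(res2$effects$total,
               unname(coef(lm(y + 0.3 * z ~ x + scale(z, scale = FALSE)))[2]),
               tolerance = 1e-9)
})

test_that("null mediation bootstrap intervals cover zero at the nominal rate", {
  set.seed(35)
  cover <- replicate(60, {
    n <- 100
    x <- rnorm(n)
    m <- rnorm(n)                 # a = 0 truth
    y <- 0.5 * x + rnorm(n)
    res <- mediation(x, m, y, n_boot = 200, seed = sample.int(1e6, 1))
    ci <- res$boot_ci["indirect", ]
    ci[1] <= 0 && 0 <= ci[2]
  })
  expect_gte(mean(cover), 0.85)
})

test_that("sample-size formula reproduces both design calculations", {
  expect_equal(sample_size_two_groups(2, 6, 0.05, 0.80, 1),
               list(n_cases = 142, n_controls = 142))
  expect_equal(sample_size_two_groups(5, 7, 0.05, 0.80, 2),
               list(n_cases = 24, n_controls = 48))
  # pre-ceiling n scales linearly in sd^2
  z2 <- (qnorm(0.975) + qnorm(0.8))^2
  expect_equal(2 * z2 * (2 * 6)^2 / 2^2, 4 * (2 * z2 * 6^2 / 2^2))
  expect_error(sample_size_two_groups(0, 6), "delta")
  expect_error(sample_size_two_groups(2, 6, alpha = 1.5), "alpha")
})

test_that("empirical power is calibrated under the null and monotone in delta", {
  p0 <- empirical_power(50, 50, 0, 6, reps = 4000, seed = 10)
  expect_lt(abs(p0 - 0.05), 3 * sqrt(0.05 * 0.95 / 4000))
  p <- vapply(c(1, 2, 3), function(d)
    empirical_power(100, 100, d, 6, reps = 2000, seed = 11), numeric(1))
  expect_true(all(diff(p) > 0))
})

test_that("constant propensities make every scheme reduce to the unweighted contrast", {
  set.seed(36)
  y <- rnorm(60); g <- rep(c(TRUE, FALSE), 30)
  base <- weighted_group_difference(y, g)$estimate
  for (scheme in c("dropout_adjust", "adherence_adjust", "user_vs_nonuser")) {
    w <- ipw_weights(scheme, rep(0.4, 60), g)
    expect_equal(weighted_group_difference(y, g, w)$estimate, base,
                 tolerance = 1e-10)
  }
})
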