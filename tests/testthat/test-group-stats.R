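test_that("hellinger matches closed forms and is a bounded metric", {
  p <- dist_on(c("F-T" = 0.5, "T-F" = 0.5))
  q <- dist_on(c("F-T" = 1))
  expect_equal(hellinger(p, p), 0)
  expect_equal(hellinger(p, q), sqrt(1 - sqrt(0.5)), tolerance = 1e-12)

  disjoint <- dist_on(c("Q-T" = 1))
  expect_equal(hellinger(q, disjoint), 1)

  # symmetry and range over random distributions
  set.seed(3)
  for (i in 1:25) {
    a <- rexp(56); a <- a / sum(a)
    b <- rexp(56); b <- b / sum(b)
    expect_equal(hellinger(a, b), hellinger(b, a))
    expect_gte(hellinger(a, b), 0)
    expect_lte(hellinger(a, b), 1)
  }

  expect_error(hellinger(rep(1, 56), rep(1 / 56, 56)), "normalized")
  expect_error(hellinger(c(0.5, 0.5), rep(1 / 56, 56)), "same length")
})

test_that("permutation test is consistent, reproducible, and add-one bounded", {
  set.seed(29)
  mm <- format_markov_matrices(0.12)
  a <- sim_tables(mm$frequency, 20)
  b <- sim_tables(mm$probability, 20)
  res <- permutation_test(a, b, n_perm = 299, seed = 71)
  expect_equal(res$hd_observed, hellinger(pool_group(a), pool_group(b)))
  expect_gte(res$p_value, 1 / 300)
  expect_lte(res$p_value, 1)
  expect_equal(res$group_sizes, c(20L, 20L))

  again <- permutation_test(a, b, n_perm = 299, seed = 71)
  expect_identical(res$p_value, again$p_value)
  expect_identical(res$null_distances, again$null_distances)

  lab <- permutation_test(a, b, n_perm = 299, seed = 71,
                          mode = "label_permutation")
  expect_equal(lab$resample_mode, "label_permutation")
  expect_equal(lab$hd_observed, res$hd_observed)

  expect_error(permutation_test(list(), b), "non-empty")
})

test_that("label-permutation p-values are super-uniform under the null", {
  # reduced-n audit: 120 null experiments at n_perm = 99, 12 per group
  mm <- format_markov_matrices(0)
  set.seed(530)
  pvals <- replicate(120, {
    a <- sim_tables(mm$frequency, 12)
    b <- sim_tables(mm$frequency, 12)
    permutation_test(a, b, n_perm = 99, seed = sample.int(2^30, 1),
                     mode = "label_permutation")$p_value
  })
  # super-uniformity: P(p <= alpha) <= alpha + Monte-Carlo slack
  for (alpha in c(0.05, 0.10, 0.25)) {
    expect_lte(mean(pvals <= alpha),
               alpha + 3 * sqrt(alpha * (1 - alpha) / 120))
  }
})

test_that("transition odds ratios match the 2x2 oracle", {
  res <- transition_odds_ratio(20, 100, 10, 100)
  expect_equal(res$odds_ratio, 2.25)  # (0.2/0.8)/(0.1/0.9)
  expect_equal(res$max_frequency, 20)
  expect_false(res$haldane)
  # Wald CI on the log scale
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90)
  expect_equal(res$ci_low, 2.25 * exp(-qnorm(0.975) * se))
  expect_equal(res$ci_high, 2.25 * exp(qnorm(0.975) * se))

  expect_equal(transition_odds_ratio(5, 50, 10, 100)$odds_ratio, 1)

  # swapping groups gives the reciprocal
  set.seed(31)
  for (i in 1:20) {
    a <- sample(1:40, 1); b <- sample(1:40, 1)
    r1 <- transition_odds_ratio(a, 50, b, 60)
    r2 <- transition_odds_ratio(b, 60, a, 50)
    expect_equal(r1$odds_ratio, 1 / r2$odds_ratio)
    expect_equal(r1$ci_low, 1 / r2$ci_high)
  }

  # Haldane correction engages on zero cells and keeps the CI finite
  rz <- transition_odds_ratio(0, 50, 10, 100)
  expect_true(rz$haldane)
  expect_true(is.finite(rz$ci_low) && is.finite(rz$ci_high))
  expect_true(rz$ci_low <= rz$odds_ratio && rz$odds_ratio <= rz$ci_high)
})

test_that("odds-ratio CI coverage is near nominal at moderate counts", {
  set.seed(37)
  p1 <- 0.15; p2 <- 0.08
  true_or <- (p1 / (1 - p1)) / (p2 / (1 - p2))
  cover <- replicate(400, {
    a <- rbinom(1, 300, p1); b <- rbinom(1, 300, p2)
    r <- transition_odds_ratio(a, 300, b, 300)
    r$ci_low <= true_or && true_or <= r$ci_high
  })
  expect_gte(mean(cover), 0.91)
  expect_lte(mean(cover), 0.99)
})

test_that("discriminative screening obeys the CI and frequency rules", {
  set.seed(43)
  tabs <- sim_tables(format_markov_matrices(0)$frequency, 25)
  g <- pool_group(tabs)
  self <- screen_discriminative(g, g)
  expect_equal(nrow(self), 56)
  expect_equal(sum(self$discriminative), 0)
  expect_true(all(self$odds_ratio == 1))

  # results sorted by |log OR| descending
  h <- pool_group(sim_tables(format_markov_matrices(0)$frequency, 25))
  sc <- screen_discriminative(g, h)
  expect_true(all(diff(abs(log(sc$odds_ratio))) <= 1e-12))
  # flag requires both CI exclusion of 1 and the frequency threshold
  expect_true(all(!sc$discriminative |
                    ((sc$ci_low > 1 | sc$ci_high < 1) &
                       sc$max_frequency >= 30)))
  # an extreme OR below the frequency threshold is not flagged
  high <- screen_discriminative(g, h, min_frequency = 10000L)
  expect_equal(sum(high$discriminative), 0)
})

test_that("chi-squared association agrees with the stats oracle", {
  tab <- matrix(c(30, 11, 48, 67), 2)
  res <- chi_squared_association(tab)
  oracle <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(res$chi_squared, unname(oracle$statistic))
  expect_equal(res$p_raw, oracle$p.value)
  expect_equal(res$df, 1L)
  expect_equal(res$cramers_v, sqrt(res$chi_squared / sum(tab)))

  same <- matrix(c(20, 20, 30, 30), 2)
  res0 <- chi_squared_association(same)
  expect_equal(res0$chi_squared, 0)
  expect_equal(res0$cramers_v, 0)

  # Bonferroni multiplies and caps at 1
  res4 <- chi_squared_association(tab, n_comparisons = 4L)
  expect_equal(res4$p_adjusted, min(1, res4$p_raw * 4))
  expect_equal(chi_squared_association(same, 10L)$p_adjusted, 1)
  expect_gte(res4$p_adjusted, res4$p_raw)

  expect_error(chi_squared_association(matrix(c(0, 0, 5, 7), 2)),
               "degenerate")
})

test_that("correctness model recovers reference-coded odds ratios", {
  sim_records <- function(n, b_fmt, b_dgm, b_num) {
    fmt <- rep(c("frequency", "probability"), each = n / 2)
    dgm <- rep(rep(c("experience_matched", "fixed_values"), each = n / 4), 2)
    num <- rnorm(n)
    eta <- qlogis(0.39) + b_fmt * (fmt == "probability") +
      b_dgm * (dgm == "fixed_values") + b_num * num
    data.frame(correct = runif(n) < plogis(eta), format = fmt, dgm = dgm,
               numeracy = num)
  }
  set.seed(47)
  fit <- fit_correctness_model(sim_records(2000, -1.4, -1.9, 0.5))
  co <- fit$coefficients
  expect_equal(fit$scale, "odds_ratio")
  or_fmt <- co[co$term == "formatprobability", ]
  expect_true(or_fmt$ci_low <= exp(-1.4) && exp(-1.4) <= or_fmt$ci_high)
  expect_false(fit$separation)

  # constant response is an error, perfect separation is flagged
  const <- sim_records(100, 0, 0, 0)
  const$correct <- TRUE
  expect_error(fit_correctness_model(const), "constant response")
  sep <- sim_records(200, 0, 0, 0)
  sep$correct <- sep$format == "frequency"
  fit_sep <- fit_correctness_model(sep)
  expect_true(fit_sep$separation)
  expect_true(all(is.na(fit_sep$coefficients$ci_low)))
})

test_that("error model recovers planted linear coefficients", {
  set.seed(53)
  n <- 400
  fmt <- rep(c("frequency", "probability"), each = n / 2)
  led <- rnorm(n, 0, 1)
  y <- 0.26 * (fmt == "probability") + 0.10 * led + rnorm(n, 0, 0.3)
  fit <- fit_error_model(data.frame(log_relative_error = y, format = fmt,
                                    log_experience_deviation = led))
  co <- fit$coefficients
  b_fmt <- co[co$term == "formatprobability", ]
  b_led <- co[co$term == "log_experience_deviation", ]
  expect_true(b_fmt$ci_low <= 0.26 && 0.26 <= b_fmt$ci_high)
  expect_true(b_led$ci_low <= 0.10 && 0.10 <= b_led$ci_high)
  expect_equal(fit$scale, "model_scale")

  expect_error(fit_error_model(data.frame(log_relative_error = rep(1, 10),
                                          format = "frequency",
                                          log_experience_deviation = 0)),
               "constant response")
})
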