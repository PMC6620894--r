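test_that("posterior reproduces the worked examples and boundary cases", {
  # mammography task: 1% base rate, 80% sensitivity, 9.6% false positives
  expect_equal(round(100 * posterior(0.01, 0.80, 0.096), 1), 7.8)
  # fire-and-alarm task at the cohort medians
  expect_equal(posterior(0.1, 0.5, 0.27), 0.05 / 0.293, tolerance = 1e-12)
  # no false alarms: evidence is conclusive
  expect_equal(posterior(0.3, 0.6, 0), 1)
  # symmetric likelihoods leave a 50/50 prior untouched
  for (t in c(0.2, 0.5, 0.9)) expect_equal(posterior(0.5, t, t), 0.5)
})

test_that("posterior rejects degenerate and invalid inputs", {
  expect_error(posterior(0, 0.5, 0), "degenerate")
  expect_error(posterior(-0.1, 0.5, 0.2), "probability")
  expect_error(posterior(0.1, 1.5, 0.2), "probability")
})

test_that("sequential_posterior matches the chips oracle and is exchangeable", {
  # independent closed-form oracle: prior odds times likelihood ratio
  chips_oracle <- function(prior, ph, pnh, k, n) {
    lr <- (ph / pnh)^k * ((1 - ph) / (1 - pnh))^(n - k)
    odds <- prior / (1 - prior) * lr
    odds / (1 + odds)
  }
  draws <- rep(c(TRUE, FALSE), c(6, 4))
  expect_equal(sequential_posterior(0.5, 0.7, 0.3, draws),
               chips_oracle(0.5, 0.7, 0.3, 6, 10), tolerance = 1e-12)
  expect_equal(sequential_posterior(0.5, 0.7, 0.3, draws), 49 / 58,
               tolerance = 1e-12)

  # order invariance over random shuffles
  set.seed(41)
  for (i in 1:20) {
    d <- sample(c(TRUE, FALSE), 15, replace = TRUE)
    expect_equal(sequential_posterior(0.3, 0.8, 0.4, d),
                 sequential_posterior(0.3, 0.8, 0.4, sample(d)))
  }

  expect_equal(sequential_posterior(0.37, 0.7, 0.3, logical(0)), 0.37)
  expect_equal(sequential_posterior(0.5, 0.7, 0.3, c(TRUE, FALSE)), 0.5)
  expect_error(sequential_posterior(0.5, 1, 0.3, TRUE), "strictly inside")
})

test_that("frequency trees scale and conserve counts", {
  tr <- build_frequency_tree(1 / 5, 9 / 10, 0.1, population = 1000L)
  expect_equal(tr$nodes[["F"]], 200)   # 1/5 of 1000
  expect_equal(tr$nodes[["FA"]], 180)  # 9/10 of the 200 fire events

  tr0 <- build_frequency_tree(0, 0.5, 0.2)
  expect_equal(unname(tr0$nodes[c("F", "nF", "FA", "FnA")]), c(0, 1000, 0, 0))

  tr3 <- build_frequency_tree(1 / 3, 0.5, 0.2)
  expect_equal(tr3$nodes[["F"]], 333)
  expect_equal(tr3$nodes[["nF"]], 667)

  # conservation property over random triples and populations
  set.seed(99)
  for (i in 1:50) {
    tri <- runif(3)
    pop <- sample(c(10L, 100L, 997L, 1000L), 1)
    tr <- build_frequency_tree(tri[1], tri[2], tri[3], population = pop)
    n <- tr$nodes
    expect_identical(n[["F"]] + n[["nF"]], n[["T"]])
    expect_identical(n[["FA"]] + n[["FnA"]], n[["F"]])
    expect_identical(n[["nFA"]] + n[["nFnA"]], n[["nF"]])
    expect_true(all(n >= 0))
    # node-count posterior agrees with the triple posterior to leaf
    # rounding: each leaf is off by at most ~1 event, so the ratio is off
    # by at most ~2 / (positive-evidence count)
    pos <- n[["FA"]] + n[["nFA"]]
    if (pos > 0 && tri[2] * tri[1] > 0) {
      expect_lte(abs(true_posterior(tr, from_nodes = TRUE) -
                       posterior(tri[1], tri[2], tri[3])),
                 2.5 / pos)
    }
  }
})

test_that("probability trees renormalize each split to 100", {
  tr <- build_probability_tree(0.1, 0.5, 0.27)
  expect_equal(tr$nodes[["F"]], 10)
  expect_equal(tr$nodes[["nF"]], 90)
  expect_equal(tr$nodes[["FA"]], 50)
  set.seed(7)
  for (i in 1:25) {
    tri <- runif(3)
    n <- build_probability_tree(tri[1], tri[2], tri[3])$nodes
    expect_equal(n[["F"]] + n[["nF"]], 100, tolerance = 1e-9)
    expect_equal(n[["FA"]] + n[["FnA"]], 100, tolerance = 1e-9)
    expect_equal(n[["nFA"]] + n[["nFnA"]], 100, tolerance = 1e-9)
  }
})

test_that("strict-rounding correctness uses the floor/ceiling percent band", {
  # independent band oracle
  band_oracle <- function(ans_pct, truth) {
    t_pct <- 100 * truth
    ans_pct >= floor(t_pct) && ans_pct <= ceiling(t_pct)
  }
  tr <- build_probability_tree(0.01, 0.80, 0.096)  # truth 7.76% -> band [7, 8]
  expect_true(band_oracle(8, true_posterior(tr)))
  expect_true(correctness(answer(8, 100), tr))
  expect_true(correctness(answer(7, 100), tr))
  expect_true(correctness(answer(7.764, 100), tr))
  expect_false(correctness(answer(6.9, 100), tr))
  expect_false(correctness(answer(50, 100), tr))

  # random audit against the oracle
  set.seed(11)
  for (i in 1:50) {
    tri <- c(runif(1, 0.01, 0.5), runif(1, 0.2, 0.99), runif(1, 0.01, 0.5))
    tr <- build_probability_tree(tri[1], tri[2], tri[3])
    a_pct <- runif(1, 0, 100)
    expect_identical(correctness(answer(a_pct, 100), tr),
                     band_oracle(a_pct, true_posterior(tr)))
  }
})

test_that("log metrics evaluate, flag zero estimates, and bound correct answers", {
  expect_equal(log_relative_error(0.17, 0.17), 0)
  expect_equal(log_relative_error(0.9, 0.09), 1)
  expect_equal(log_relative_error(0.45, 0.17), log10(0.45 / 0.17))
  expect_equal(log_experience_deviation(0.07, 0.17), log10(0.07 / 0.17))

  fl <- log_relative_error(0, 0.17)
  expect_true(isTRUE(attr(fl, "floored")))
  expect_equal(as.numeric(fl), log10((1 / 10000) / 0.17))

  # a strict-rounding-correct answer has a bounded log error
  set.seed(23)
  for (i in 1:30) {
    pt <- runif(1, 0.02, 0.95)
    band <- c(floor(100 * pt), ceiling(100 * pt)) / 100
    pe <- runif(1, max(band[1], 0.001), band[2])
    lre <- log_relative_error(pe, pt)
    expect_true(abs(lre) <= max(abs(log10(band / pt))) + 1e-12)
  }
})

test_that("strategy classification follows the fixed priority order", {
  tr <- build_frequency_tree(0.1, 0.5, 0.27)  # PPV 50/293 = 17.06%
  expect_equal(classify_strategy(answer(500, 1000), tr)$label,
               "sensitivity_confusion")
  expect_equal(classify_strategy(answer(50, 1000), tr)$label,
               "total_denominator")
  ppv <- true_posterior(tr)
  expect_equal(classify_strategy(answer(ppv * 293, 293), tr)$label,
               "correct_ppv")
  expect_equal(classify_strategy(answer(33, 100), tr)$label, "other")

  # probability format cannot produce total_denominator
  trp <- build_probability_tree(0.1, 0.5, 0.27)
  expect_equal(classify_strategy(answer(5, 100), trp)$label, "other")
  # tolerance is honoured
  expect_equal(classify_strategy(answer(50.4, 100), trp, tol = 0.005)$label,
               "sensitivity_confusion")
  expect_equal(classify_strategy(answer(51, 100), trp, tol = 0.005)$label,
               "other")
})

test_that("answers enforce the numerator <= denominator rule", {
  expect_error(answer(11, 10), "numerator cannot exceed")
  expect_error(answer(-1, 10), "non-negative")
  expect_error(answer(NaN, 10), "finite")
  expect_equal(as_probability(answer(80, 1000)), 0.08)
})
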