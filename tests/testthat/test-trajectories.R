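test_that("eligibility applies the floor, count and medication filters", {
  rule <- eligibility_rule()
  expect_false(is_eligible(c(0, 100, 300), c(51, 50, 49), rule = rule))
  expect_false(is_eligible(c(0, 100), c(60, 58), rule = rule))
  expect_true(is_eligible(c(0, 100, 300, 500), c(60, 59, 58, 57), rule = rule))
  expect_false(is_eligible(c(0, 100, 300), c(60, 59, 58),
                           med_change = c(FALSE, TRUE, FALSE), rule = rule))
  # measurements beyond the frame do not count
  expect_false(is_eligible(c(0, 100, 2000), c(60, 59, 58), rule = rule))
  expect_error(is_eligible(c(0, 300, 100), c(60, 59, 58), rule = rule), "increasing")
})

test_that("the four progression patterns classify as stated", {
  expect_equal(classify_pattern(60, c(58, 57, 55)), "sustained_decrease")
  expect_equal(classify_pattern(60, c(62, 63, 65)), "sustained_increase")
  expect_equal(classify_pattern(60, c(58, 61, 57)), "oscillatory_decreasing")
  # one below allowed in the sustained-decrease pattern when rest equal baseline
  expect_equal(classify_pattern(60, c(60, 59, 60)), "sustained_decrease")
  # exactly half above baseline -> oscillatory increasing
  expect_equal(classify_pattern(60, c(58, 62, 57, 63)), "oscillatory_increasing")
  # all equal to baseline matches no rule
  expect_equal(classify_pattern(60, c(60, 60)), "unclassifiable")
  expect_error(classify_pattern(60, numeric()), "follow-up")
})

test_that("classification is exhaustive, exclusive and respects monotone/mirror properties", {
  set.seed(7)
  labels <- c("sustained_decrease", "sustained_increase",
              "oscillatory_decreasing", "oscillatory_increasing", "unclassifiable")
  for (i in 1:2000) {
    b <- sample(50:75, 1)
    f <- sample((b - 4):(b + 4), sample(1:8, 1), replace = TRUE)
    lab <- classify_pattern(b, f)
    expect_true(lab %in% labels)
    if (!any(f == b) && sum(f > b) != length(f) / 2) {
      # the exact half-half split is asymmetric by construction (rule 4
      # admits "half or more") and is excluded along with ties
      mirror <- classify_pattern(b, 2 * b - f)
      swapped <- c(sustained_decrease = "sustained_increase",
                   sustained_increase = "sustained_decrease",
                   oscillatory_decreasing = "oscillatory_increasing",
                   oscillatory_increasing = "oscillatory_decreasing",
                   unclassifiable = "unclassifiable")
      expect_equal(unname(swapped[lab]), mirror)
    }
  }
  # strictly monotone series of any length fall in the sustained categories
  for (k in c(1, 2, 5, 9)) {
    expect_equal(classify_pattern(70, 70 - seq_len(k)), "sustained_decrease")
    expect_equal(classify_pattern(70, 70 + seq_len(k)), "sustained_increase")
  }
})

test_that("pattern tables conserve counts and detect symmetry under pure noise", {
  labs <- rep("sustained_decrease", 10)
  tab <- pattern_table(labs)
  expect_equal(tab$proportion[tab$label == "sustained_decrease"], 1)
  expect_equal(sum(tab$n), 10)
  set.seed(11)
  labs <- vapply(1:10000, function(i) {
    classify_pattern(60, 60 + rnorm(5, 0, 3))
  }, character(1))
  tab <- pattern_table(labs)
  expect_equal(sum(tab$proportion), 1, tolerance = 1e-12)
  p_dec <- tab$proportion[tab$label == "sustained_decrease"]
  p_inc <- tab$proportion[tab$label == "sustained_increase"]
  # symmetric noise with no treatment effect: the two sustained rates agree
  # within Monte-Carlo error
  expect_lt(abs(p_dec - p_inc), 3 * sqrt(2 * 0.05 / 10000) + 0.01)
})

test_that("Fisher comparison equals hypergeometric enumeration", {
  expect_equal(compare_sustained_rates(10, 5, 10, 5)$p_value, 1.0)
  expect_equal(compare_sustained_rates(5, 5, 5, 0)$p_value, 2 / choose(10, 5),
               tolerance = 1e-12)
  set.seed(21)
  for (i in 1:50) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    expect_equal(compare_sustained_rates(n1, k1, n2, k2)$p_value,
                 fisher_enum_p(k1, n1 - k1, k2, n2 - k2), tolerance = 1e-12)
  }
  expect_error(compare_sustained_rates(5, 6, 5, 0), "0 <= k <= n")
})

test_that("classify_visit_patterns filters ineligible series and labels the rest", {
  visits <- rbind(
    data.frame(id = "a", day = c(0, 100, 200, 300), hba1c = c(60, 59, 58, 57),
               med_change = FALSE),
    data.frame(id = "b", day = c(0, 100), hba1c = c(60, 59), med_change = FALSE),
    data.frame(id = "c", day = c(0, 100, 200), hba1c = c(49, 48, 47),
               med_change = FALSE),
    data.frame(id = "d", day = c(0, 100, 200), hba1c = c(60, 62, 64),
               med_change = c(FALSE, TRUE, FALSE))
  )
  out <- classify_visit_patterns(visits)
  expect_equal(out$id, "a")
  expect_equal(out$label, "sustained_decrease")
  expect_equal(out$n_measurements, 4)
})
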