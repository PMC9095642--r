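test_that("quarterly periods count completions in half-open intervals", {
  qp <- quarterly_periods(c(0, 91, 182), c(63, 60, 61), c(10, 20, 100))
  expect_equal(nrow(qp), 2)
  expect_equal(qp$themes_completed, c(2, 1))
  expect_equal(qp$delta_hba1c, c(-3, 1))
  # an event exactly on a visit day belongs to the period ending that day
  qp2 <- quarterly_periods(c(0, 91, 182), c(63, 60, 61), c(91, 92))
  expect_equal(qp2$themes_completed, c(1, 1))
  # no completions at all
  qp3 <- quarterly_periods(c(0, 91, 182), c(63, 60, 61))
  expect_equal(qp3$themes_completed, c(0, 0))
  # a missing bounding HbA1c drops the period, not the neighbour
  qp4 <- quarterly_periods(c(0, 91, 182), c(63, NA, 61), c(10, 100))
  expect_equal(nrow(qp4), 0)
  expect_error(quarterly_periods(c(0, 91, 91), c(63, 60, 61)), "duplicate")
})

test_that("exposure bins split at 0, 1-4 and >= 5 themes", {
  bins <- exposure_response_bins(c(0, 0, 3, 7), c(1, 2, -1, -4))
  expect_equal(bins$n, c(2, 1, 1))
  expect_equal(bins$mean_delta, c(1.5, -1, -4))
  expect_equal(bins$sem[1], sd(c(1, 2)) / sqrt(2))
  # boundary membership: 4 is in "1-4", 5 in ">=5"
  b2 <- exposure_response_bins(c(4, 5), c(1, 1))
  expect_equal(b2$n, c(0, 1, 1))
  expect_true(is.na(b2$mean_delta[1]))
  # conservation of the period count
  set.seed(3)
  k <- rpois(200, 3)
  b3 <- exposure_response_bins(k, rnorm(200))
  expect_equal(sum(b3$n), 200)
})

test_that("BCT scores multiply responder counts by dominance weights", {
  catalog <- structure(list(themes = list(
    theme01 = c(A = 0.5, B = 0.3, C = 0.2)
  )), class = "theme_catalog")
  periods <- data.frame(id = sprintf("p%d", 1:4), quarter_index = 1,
                        delta_hba1c = c(-1, -2, -0.5, 0))
  periods$themes <- I(replicate(4, "theme01", simplify = FALSE))
  sc <- bct_scores(periods, catalog)
  expect_equal(sc$responder_score[match(c("A", "B", "C"), sc$bct)],
               c(1.5, 0.9, 0.6))
  expect_equal(sc$nonresponder_score[match(c("A", "B", "C"), sc$bct)],
               c(0.5, 0.3, 0.2))
  # no completions -> empty score table
  p0 <- periods
  p0$themes <- I(replicate(4, character(), simplify = FALSE))
  expect_equal(nrow(bct_scores(p0, catalog)), 0)
  # unknown theme id is a data error
  pbad <- periods
  pbad$themes <- I(replicate(4, "theme99", simplify = FALSE))
  expect_error(bct_scores(pbad, catalog), "unknown theme")
})

test_that("scores are additive over quarters and total to the responder count", {
  cat <- generate_theme_catalog(12)
  set.seed(12)
  mk <- function(q) {
    p <- data.frame(id = sprintf("p%d", 1:30), quarter_index = q,
                    delta_hba1c = rnorm(30))
    p$themes <- I(lapply(1:30, function(i)
      sample(names(cat$themes), sample(0:3, 1))))
    p
  }
  q1 <- mk(1); q2 <- mk(2)
  both <- rbind(q1, q2)
  s_both <- bct_scores(both, cat)
  s1 <- bct_scores(q1, cat); s2 <- bct_scores(q2, cat)
  merged <- merge(s1, s2, by = "bct", all = TRUE)
  merged[is.na(merged)] <- 0
  merged <- merged[match(s_both$bct, merged$bct), ]
  expect_equal(s_both$responder_score,
               merged$responder_score.x + merged$responder_score.y)
  # weights sum to 1 per theme, so summed scores equal the raw
  # participant-period counts
  n_resp <- sum(vapply(seq_len(nrow(both)), function(i)
    length(unique(both$themes[[i]])) * (both$delta_hba1c[i] < 0), numeric(1)))
  expect_equal(sum(s_both$responder_score), n_resp, tolerance = 1e-9)
})

test_that("chi-square on the score table matches the expected-counts oracle", {
  # perfect homogeneity
  sc <- data.frame(bct = c("A", "B"), responder_score = c(10, 20),
                   nonresponder_score = c(5, 10))
  res <- bct_chi_square(sc)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # hand-computed Pearson statistic for the 2x2 score table [[10,10],[20,5]]
  sc2 <- data.frame(bct = c("A", "B"), responder_score = c(10, 10),
                    nonresponder_score = c(20, 5))
  res2 <- bct_chi_square(sc2)
  expect_equal(res2$statistic, 4.5, tolerance = 1e-9)
  expect_equal(res2$df, 1)
  # random integer tables against the base chisq.test oracle
  set.seed(4)
  for (i in 1:20) {
    K <- sample(2:6, 1)
    tab <- matrix(rpois(2 * K, 8) + 1, nrow = 2)
    sck <- data.frame(bct = paste0("b", 1:K), responder_score = tab[1, ],
                      nonresponder_score = tab[2, ])
    ours <- bct_chi_square(sck)
    oracle <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(oracle$statistic), tolerance = 1e-9)
    expect_equal(ours$p_value, oracle$p.value, tolerance = 1e-9)
  }
  # linearity caveat: scaling weights scales the statistic proportionally
  sc3 <- sc2
  sc3$responder_score <- sc3$responder_score * 2.5
  sc3$nonresponder_score <- sc3$nonresponder_score * 2.5
  expect_equal(suppressWarnings(bct_chi_square(sc3))$statistic,
               2.5 * res2$statistic, tolerance = 1e-9)
  # zero-total columns are excluded with a warning
  sc4 <- rbind(sc2, data.frame(bct = "Z", responder_score = 0,
                               nonresponder_score = 0))
  expect_warning(res4 <- bct_chi_square(sc4), "zero total")
  expect_equal(res4$statistic, res2$statistic)
})
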