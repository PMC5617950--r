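test_that("degenerate signed-rank inputs behave as defined", {
  x <- c(1, 2, 3)
  res <- wilcoxon_signed_rank(x, x)
  expect_equal(res$p_value, 1)
  expect_equal(res$n_used, 0L)

  res <- wilcoxon_signed_rank(1:5, rep(0, 5), alternative = "greater")
  expect_equal(res$p_value, 1 / 32)
  expect_equal(res$method, "exact")
  expect_equal(res$statistic, 0)  # min of the two rank sums

  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("exact p-values equal full sign enumeration and stats references", {
  set.seed(100)
  for (n in c(4, 6, 8, 11)) {
    x <- rnorm(n)
    y <- rnorm(n)
    for (alt in c("two_sided", "greater", "less")) {
      res <- wilcoxon_signed_rank(x, y, alternative = alt)
      expect_equal(res$method, "exact")
      expect_equal(res$p_value, enum_signrank_p(x, y, alt),
                   tolerance = 1e-13, info = paste(n, alt))
      # independent reference: R's exact test (tie-free data)
      ralt <- c(two_sided = "two.sided", greater = "greater", less = "less")[alt]
      ref <- stats::wilcox.test(x, y, paired = TRUE, alternative = ralt,
                                exact = TRUE)
      expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-13)
    }
    # W+ matches R's V statistic
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(wilcoxon_signed_rank(x, y)$w_plus, unname(ref$statistic))
  }
})

test_that("exact null with midranks sums to one and p-values sit on the 2^-n grid", {
  set.seed(101)
  # ties in |differences| force midranks
  x <- c(3, 5, 5, 9, 2, 7, 7, 1)
  y <- c(1, 3, 7, 4, 4, 3, 3, 2)
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, enum_signrank_p(x, y, "two_sided"),
               tolerance = 1e-13)
  # tie-free exact p-values are multiples of 2^-n (two-sided doubles them)
  x2 <- rnorm(9); y2 <- rnorm(9)
  p <- wilcoxon_signed_rank(x2, y2, alternative = "greater")$p_value
  expect_equal(p * 2^9, round(p * 2^9), tolerance = 1e-9)
})

test_that("normal approximation agrees with the exact law and with wilcox.test", {
  set.seed(42)
  x <- rnorm(15); y <- rnorm(15)
  approx <- wilcoxon_signed_rank(x, y, exact_cutoff = 0)
  exact <- wilcoxon_signed_rank(x, y)
  expect_equal(approx$method, "normal_approx")
  expect_lt(abs(approx$p_value - exact$p_value), 0.02)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(approx$p_value, unname(ref$p.value), tolerance = 1e-12)
  # tied data (forces R's approximation too)
  xt <- c(2, 2, 5, 5, 5, 8, 1, 4, 4, 6, 9, 9, 3, 3, 7)
  yt <- c(1, 3, 2, 2, 7, 2, 2, 1, 1, 2, 3, 1, 1, 1, 2)
  reft <- suppressWarnings(stats::wilcox.test(xt, yt, paired = TRUE,
                                              exact = FALSE, correct = TRUE))
  expect_equal(wilcoxon_signed_rank(xt, yt, exact_cutoff = 0)$p_value,
               unname(reft$p.value), tolerance = 1e-12)
})

test_that("the test is invariant to adding a constant to both pair members", {
  set.seed(77)
  x <- rnorm(10); y <- rnorm(10)
  p0 <- wilcoxon_signed_rank(x, y)$p_value
  expect_equal(wilcoxon_signed_rank(x + 5, y + 5)$p_value, p0)
  expect_equal(wilcoxon_signed_rank(x - 2.5, y - 2.5)$p_value, p0)
})

test_that("group evaluation pairs own vs other posteriors per term", {
  keys <- sprintf("k%02d", 1:6)
  scores <- data.frame(
    key = keys, stem = keys, negated = FALSE, display = keys,
    df_mut = 10L, df_wt = 5L,
    p_mut = 0.6, p_wt = 0.4, stringsAsFactors = FALSE
  )
  set <- structure(list(cohort = "MUTANT", threshold = 0.5, k = 6L,
                        terms = scores), class = "predictor_set")
  ev <- evaluate_predictor_group(scores, set, alternative = "greater")
  expect_equal(ev$mean_own, 0.6)
  expect_equal(ev$mean_other, 0.4)
  # constant positive differences: one-sided exact p = (1/2)^n
  expect_equal(ev$wilcoxon$p_value, (1 / 2)^6)
  expect_true(ev$mean_own >= ev$mean_other)

  # singleton set: exact one-sided p = 0.5
  set1 <- structure(list(cohort = "MUTANT", threshold = 0.5, k = 1L,
                         terms = scores[3, ]), class = "predictor_set")
  scores1 <- scores; scores1$p_mut[3] <- 0.75; scores1$p_wt[3] <- 0.25
  ev1 <- evaluate_predictor_group(scores1, set1, alternative = "greater")
  expect_equal(ev1$wilcoxon$n_used, 1L)
  expect_equal(ev1$wilcoxon$p_value, 0.5)

  empty <- structure(list(cohort = "MUTANT", threshold = 0.5, k = 0L,
                          terms = scores[0, ]), class = "predictor_set")
  expect_error(evaluate_predictor_group(scores, empty), "empty")
})
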