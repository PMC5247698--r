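test_that("mFPA brackets partition [0,100] with boundaries assigned upward", {
  x <- c(0, 4.999, 5, 9.999, 10, 19.999, 20, 100)
  expect_equal(as.character(categorize_mfpa(x)),
               c("<5", "<5", "5-9.9", "5-9.9", "10-19.9", "10-19.9",
                 ">=20", ">=20"))
  # every value maps to exactly one bracket
  set.seed(3)
  v <- runif(500, 0, 100)
  expect_false(any(is.na(categorize_mfpa(v))))
  expect_error(categorize_mfpa(-0.1), "0, 100")
  expect_error(categorize_mfpa(101), "0, 100")
})

test_that("Spearman handles monotone transforms, reversals and ties", {
  expect_equal(spearman(1:3, c(1, 4, 9))$rs, 1.0)
  expect_equal(spearman(1:3, c(3, 2, 1))$rs, -1.0)
  set.seed(4)
  x <- rnorm(40); y <- x + rnorm(40)
  base <- spearman(x, y)
  expect_equal(spearman(exp(x), y)$rs, base$rs)       # strictly monotone in x
  expect_equal(spearman(x, y^3 + 10)$rs, base$rs)     # and in y
  expect_equal(base$rs, cor(x, y, method = "spearman"))
  expect_error(spearman(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman(1:3, 1:4), "equal length")
})

test_that("Spearman p-values match cor.test in both regimes", {
  set.seed(5)
  x8 <- rnorm(8); y8 <- rnorm(8)
  expect_equal(spearman(x8, y8)$p,
               cor.test(x8, y8, method = "spearman")$p.value)
  x50 <- rnorm(50); y50 <- x50 + rnorm(50, 0, 2)
  expect_equal(spearman(x50, y50)$p,
               cor.test(x50, y50, method = "spearman")$p.value)
})

test_that("Mann-Whitney U reflects separation and enumerates exactly", {
  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(sep$method, "exact")
  # identical groups: every assignment deviates at least as much -> p = 1
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1.0)
})

test_that("exact Mann-Whitney p equals the independent wilcox.test oracle", {
  set.seed(6)
  for (na in 2:6) for (nb in 2:6) {
    repeat {  # tie-free draw
      a <- round(rnorm(na), 3); b <- round(rnorm(nb, 0.5), 3)
      if (!anyDuplicated(c(a, b))) break
    }
    ours <- mann_whitney(a, b)
    oracle <- wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$p, oracle$p.value, tolerance = 1e-12,
                 info = sprintf("na=%d nb=%d", na, nb))
    expect_equal(ours$U, unname(oracle$statistic))
  }
})

test_that("large-sample Mann-Whitney uses the corrected normal approximation", {
  set.seed(7)
  a <- rnorm(30); b <- rnorm(25, 0.4)
  ours <- mann_whitney(a, b)
  expect_equal(ours$method, "asymptotic")
  expect_equal(ours$p, wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Kruskal-Wallis matches direct rank arithmetic and kruskal.test", {
  expect_equal(kruskal_wallis(list(c(5, 5), c(5, 5), c(5, 5)))$H, 0)
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  # direct: H = 12/(N(N+1)) * sum(R_j^2/n_j) - 3(N+1) with R = (3, 7, 11)
  h_direct <- 12 / (6 * 7) * (9 / 2 + 49 / 2 + 121 / 2) - 3 * 7
  expect_equal(kruskal_wallis(g)$H, h_direct)
  expect_equal(kruskal_wallis(g)$H,
               unname(kruskal.test(unlist(g), rep(1:3, each = 2))$statistic))
  expect_error(kruskal_wallis(list(1:3, 4:6)), "mann_whitney")
  expect_error(kruskal_wallis(list(1:3, 4:6, numeric(0))), "non-empty")
})

test_that("seeded Monte-Carlo Kruskal-Wallis p agrees with the chi-square p", {
  set.seed(8)
  g <- list(rnorm(30), rnorm(30), rnorm(30))
  kw <- kruskal_wallis(g, exact = "montecarlo", n_perm = 4000L, seed = 9)
  expect_lt(abs(kw$p_montecarlo - kw$p), 0.01)
  # seeded: same call, same p
  kw2 <- kruskal_wallis(g, exact = "montecarlo", n_perm = 4000L, seed = 9)
  expect_identical(kw$p_montecarlo, kw2$p_montecarlo)
})

test_that("ROC endpoints, separation, and the concordance identity hold", {
  r <- roc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auroc, 1.0)
  expect_equal(r$points$sensitivity[1], 0)                 # +Inf threshold
  expect_equal(r$points$specificity[1], 1)
  expect_equal(tail(r$points$sensitivity, 1), 1)           # -Inf threshold
  expect_true(all(diff(r$points$sensitivity) >= 0))        # monotone sweep
  expect_error(roc(1:5, rep(TRUE, 5)), "both label classes")
  # ties: AUROC equals concordance including half-credit for equal scores
  sc <- c(1, 2, 2, 3); lb <- c(0, 0, 1, 1)
  expect_equal(roc(sc, lb)$auroc, concordance_oracle(sc, lb), tolerance = 1e-12)
})

test_that("AUROC agrees with pROC on a realistic cohort", {
  co <- generate_cohort(cohort_spec(seed = 31))
  lab <- co$mfpa_pct >= 5
  ours <- roc(co$alt_u_l, lab)$auroc
  ref <- suppressMessages(pROC::auc(pROC::roc(lab, co$alt_u_l, quiet = TRUE,
                                              direction = "<")))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("sensitivity and specificity follow the score >= cutoff convention", {
  ss <- sensitivity_specificity(c(10, 20, 30, 40), c(0, 0, 1, 1), 25)
  expect_equal(ss$sensitivity, 1.0); expect_equal(ss$specificity, 1.0)
  ss <- sensitivity_specificity(c(10, 20, 30, 40), c(0, 0, 1, 1), 50)
  expect_equal(ss$sensitivity, 0.0); expect_equal(ss$specificity, 1.0)
  # 2x2 table TP=9 FN=1 TN=5 FP=5
  scores <- c(rep(1, 9), 0, rep(0, 5), rep(1, 5))
  labels <- c(rep(1, 10), rep(0, 10))
  ss <- sensitivity_specificity(scores, labels, 1)
  expect_equal(ss$sensitivity, 0.9); expect_equal(ss$specificity, 0.5)
  expect_error(sensitivity_specificity(1:4, rep(1, 4), 2), "both label classes")
})
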