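test_that("confusion counting follows the >= positive rule", {
  cm <- ngn_confusion(c(0.9, 0.1), c("pos", "neg"), 0.5)
  expect_identical(unclass(cm)[c("tp", "tn", "fp", "fn")],
                   list(tp = 1L, tn = 1L, fp = 0L, fn = 0L))
  # ties at the threshold are positive
  cm <- ngn_confusion(c(0.5, 0.5), c("pos", "neg"), 0.5)
  expect_identical(cm$tp, 1L)
  expect_identical(cm$fp, 1L)
  cm <- ngn_confusion(c(0.6, 0.6, 0.4, 0.2), c("pos", "neg", "pos", "neg"))
  expect_identical(unclass(cm)[c("tp", "fp", "fn", "tn")],
                   list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  expect_error(ngn_confusion(0.5, c("pos", "neg")), "length")
})

test_that("classification metrics match direct formula evaluation", {
  perfect <- ngn_classification_metrics(list(tp = 4, tn = 3, fp = 0, fn = 0))
  expect_equal(perfect[c("Q", "SE", "SP", "MCC")],
               list(Q = 1, SE = 1, SP = 1, MCC = 1))
  m <- ngn_classification_metrics(list(tp = 3, tn = 2, fp = 1, fn = 1))
  expect_equal(m$MCC, 5 / 12)
  # zero-denominator convention
  z <- ngn_classification_metrics(list(tp = 5, fn = 0, tn = 0, fp = 5))
  expect_identical(z$MCC, 0)
  expect_error(ngn_classification_metrics(list(tp = 0, tn = 0, fp = 0,
                                               fn = 0)), "empty")
  # randomized agreement with the oracle, plus range and symmetry laws
  set.seed(71)
  for (i in 1:50) {
    cnt <- as.list(rpois(4, 5) + c(1, 1, 0, 0))
    names(cnt) <- c("tp", "tn", "fp", "fn")
    m <- ngn_classification_metrics(cnt)
    o <- oracle_class_metrics(cnt$tp, cnt$tn, cnt$fp, cnt$fn)
    expect_equal(m, o)
    expect_true(all(unlist(m[c("Q", "SE", "SP")]) >= 0 &
                    unlist(m[c("Q", "SE", "SP")]) <= 1))
    expect_true(m$MCC >= -1 && m$MCC <= 1)
    inv <- ngn_classification_metrics(list(tp = cnt$fn, fn = cnt$tp,
                                           tn = cnt$fp, fp = cnt$tn))
    expect_equal(inv$MCC, -m$MCC)
  }
})

test_that("q2 is PRESS normalized against the test-set SD", {
  t <- c(0.3, 0.5, 0.7)
  expect_equal(ngn_q2(t, t)$q2, 1)
  expect_equal(ngn_q2(rep(mean(t), 3), t)$q2, 0)
  r <- ngn_q2(c(1, 0), c(0, 1))
  expect_equal(r$press, 2)
  expect_equal(r$sd, 0.5)
  expect_equal(r$q2, -3)
  expect_error(ngn_q2(c(0.1, 0.2), c(0.5, 0.5)), "identical")
  expect_error(ngn_q2(0.1, 0.5), "at least 2")
  # invariance under a common affine rescaling
  set.seed(72)
  for (i in 1:20) {
    p <- runif(8); t <- runif(8)
    a <- runif(1, 0.5, 3); b <- runif(1, -2, 2)
    expect_equal(ngn_q2(a * p + b, a * t + b)$q2, ngn_q2(p, t)$q2)
    expect_equal(ngn_q2(p, t)$q2, oracle_q2(p, t))
  }
})

test_that("Epsilon sums absolute residuals", {
  t <- c(0.3, 0.6)
  expect_equal(ngn_epsilon(t, t)$epsilon, 0)
  e1 <- ngn_epsilon(0.4, 0.5)
  expect_equal(e1$epsilon, 0.1)
  expect_equal(e1$epsilon_sd, 0)           # single pair: spread reported as 0
  e2 <- ngn_epsilon(c(0.4, 0.2), c(0.5, 0.5))
  expect_equal(e2$epsilon, 0.4)
  expect_equal(e2$epsilon_sd, sd(c(0.1, 0.3)))
  # signed mode allows cancellation
  expect_equal(ngn_epsilon(c(0.4, 0.6), c(0.5, 0.5), signed = TRUE)$epsilon, 0)
  expect_error(ngn_epsilon(1, c(1, 2)), "length")
})

test_that("the correlation coefficient matches its formula", {
  x <- c(1, 2, 3)
  expect_equal(ngn_cc(x, x), 1)
  expect_equal(ngn_cc(x, -x), -1)
  expect_equal(ngn_cc(x, c(2, 4, 7)), oracle_pearson(x, c(2, 4, 7)))
  expect_equal(ngn_cc(x, c(2, 4, 7)), 15 / sqrt(228), tolerance = 1e-12)
  expect_error(ngn_cc(c(1, 1, 1), x), "zero variance")
})

test_that("normalization maps endpoints exactly and preserves order", {
  v <- c(3, 10, 5.2, 7, 0.48)
  out <- ngn_normalize(v, 0.2, 0.8)
  expect_equal(out[which.min(v)], 0.2)
  expect_equal(out[which.max(v)], 0.8)
  expect_identical(order(out), order(v))
  # midpoint maps to midpoint
  expect_equal(ngn_normalize(c(0, 5, 10))[2], 0.5)
  expect_error(ngn_normalize(c(2, 2, 2)), "identical")
  set.seed(73)
  for (i in 1:20) {
    v <- rnorm(10)
    out <- ngn_normalize(v, 0.2, 0.8)
    expect_true(all(diff(out[order(v)]) >= 0))
    expect_equal(range(out), c(0.2, 0.8))
  }
})

test_that("Wilcoxon signed-rank matches exhaustive enumeration", {
  expect_error(ngn_wilcoxon(1:5, 1:5), "no information")
  # six uniformly positive differences
  w <- ngn_wilcoxon(2:7, 1:6, alternative = "greater")
  expect_equal(w$p, 1 / 64)
  expect_equal(w$W, 21)
  # randomized instances, with and without ties, against the oracle
  set.seed(74)
  for (i in 1:40) {
    n <- sample(2:10, 1)
    a <- round(runif(n), sample(1:2, 1))   # rounding provokes ties
    b <- round(runif(n), 1)
    if (all(a == b)) next
    for (alt in c("two.sided", "greater", "less")) {
      got <- ngn_wilcoxon(a, b, alternative = alt)
      ora <- oracle_wilcoxon(a, b, alternative = alt)
      expect_equal(got$W, ora$W)
      expect_equal(got$p, ora$p, info = paste("n =", n, alt))
    }
  }
})

test_that("exact Wilcoxon p agrees with the stats package when tie-free", {
  set.seed(75)
  for (i in 1:10) {
    n <- sample(6:10, 1)
    a <- rnorm(n); b <- rnorm(n)       # continuous: no ties, no zeros
    got <- ngn_wilcoxon(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(got$p, ref$p.value)
    expect_equal(got$W, unname(ref$statistic))
  }
})

test_that("the large-sample normal approximation tracks the exact tail", {
  set.seed(76)
  a <- rnorm(40); b <- rnorm(40)
  got <- ngn_wilcoxon(a, b)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("threshold labeling follows the documented direction", {
  # benzodiazepine-receptor-style activities, threshold 7.0 pIC50
  expect_identical(ngn_label_by_threshold(c(9.5, 4.2), 7.0), c("pos", "neg"))
  expect_identical(ngn_label_by_threshold(7.0, 7.0), "pos")   # tie rule
  expect_identical(ngn_label_by_threshold(c(9.5, 4.2), 7.0, "le"),
                   c("neg", "pos"))
})
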