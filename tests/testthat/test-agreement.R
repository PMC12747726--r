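test_that("relative percent difference identities", {
  expect_equal(rpd(5, 5), 0)
  expect_equal(rpd(3, 1), 100)
  expect_equal(rpd(0.02, 0.03), 40)
  expect_equal(rpd(0, 0), 0)
  expect_equal(rpd(2, 6), rpd(6, 2))                       # symmetry
  expect_equal(rpd(2 * 7, 6 * 7), rpd(2, 6))               # scale invariance
  expect_equal(rpd(c(1, 2), c(1, 4)), c(0, 200 / 3))       # vectorized
})

test_that("Bland-Altman bias and limits", {
  expect_equal(blandAltman(c(1, 2, 3), c(1, 2, 3)),
               list(bias = 0, upLim = 0, lowLim = 0))
  expect_equal(blandAltman(c(1, 2, 3), c(2, 3, 4)),
               list(bias = 1, upLim = 1, lowLim = 1))
  ba <- blandAltman(c(0, 0, 0), c(-1, 0, 1))               # sd(d) = 1
  expect_equal(ba$bias, 0)
  expect_equal(ba$upLim, 1.96)
  expect_equal(ba$lowLim, -1.96)
  expect_error(blandAltman(1:4, 1:3), "lengths")
})

test_that("regression slope and Pearson correlation", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(slopeAndPcc(x, 2 * x + 3), list(slope = 2, pcc = 1))
  expect_equal(slopeAndPcc(x, -x), list(slope = -1, pcc = -1))
  set.seed(8)
  y <- 1.3 * x + rnorm(5)
  got <- slopeAndPcc(x, y)
  # normal-equations oracle
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$slope, b)
  expect_equal(got$pcc, r)
  expect_equal(slopeAndPcc(x, y, throughOrigin = TRUE)$slope,
               sum(x * y) / sum(x^2))
  expect_error(slopeAndPcc(rep(1, 5), 1:5), "constant")
})

test_that("Wilcoxon rank-sum: exact enumeration and approximation", {
  w <- wilcoxonRankSum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(w$statistic, 0)
  expect_equal(w$p.value, 0.1)          # 2/20 arrangements as extreme
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  # exact path vs random-permutation oracle, with ties
  set.seed(3)
  g1 <- c(1.2, 3.1, 3.1, 5.0); g2 <- c(2.0, 3.1, 6.4, 7.7, 8.1)
  got <- wilcoxonRankSum(g1, g2)$p.value
  pooled <- c(g1, g2); n1 <- length(g1)
  mid <- n1 * length(g2) / 2
  uStat <- function(idx) sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  obs <- abs(uStat(seq_len(n1)) - mid)
  perm <- replicate(4000, abs(uStat(sample(9, n1)) - mid))
  expect_lt(abs(got - mean(perm >= obs - 1e-12)), 0.03)
  # monotone-transform invariance of the pooled data
  expect_equal(wilcoxonRankSum(exp(g1), exp(g2))$p.value, got)
  # large-sample path agrees with stats::wilcox.test
  set.seed(4)
  a <- rnorm(30); b <- rnorm(25, 0.4)
  expect_equal(wilcoxonRankSum(a, b)$p.value,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  expect_error(wilcoxonRankSum(1, c(1, 2)), "at least 2")
})

test_that("paired t-test handles degenerate differences", {
  x <- c(1, 2, 3, 4)
  expect_equal(pairedT(x, x)$p.value, 1)
  expect_error(pairedT(x, x + 1), "zero-variance")
  set.seed(5)
  y <- x + rnorm(4, 0.5)
  got <- pairedT(x, y)
  d <- y - x
  tOracle <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(got$t, tOracle)
  expect_equal(got$p.value, 2 * pt(-abs(tOracle), df = 3))
})

test_that("ART ANOVA detects an injected location effect", {
  set.seed(12)
  n <- 60
  loc <- rep(c("ICA", "MCA", "ACA"), c(20, 25, 15))
  df <- data.frame(case = rep(seq_len(n), 2),
                   loc = rep(loc, 2),
                   model = rep(c("newtonian", "cy"), each = n))
  df$y <- rnorm(2 * n) + 2 * (df$loc == "ACA")
  res <- artAnova(df$y, df$loc, df$model, df$case)
  expect_equal(res$effect, c("location", "model", "location:model"))
  expect_lt(res$p[res$effect == "location"], 0.001)
  expect_gt(res$p[res$effect == "model"], 0.05)
})

test_that("ART ANOVA holds its size under the null", {
  set.seed(31)
  p <- replicate(60, {
    n <- 40
    loc <- rep(c("ICA", "MCA", "ACA"), c(14, 16, 10))
    y <- rnorm(2 * n)
    artAnova(y, rep(loc, 2), rep(c("a", "b"), each = n), rep(1:n, 2))$p
  })
  rates <- rowMeans(p < 0.05)
  expect_true(all(rates < 0.17))   # loose gate; the tight one runs at scale
})

test_that("ART ANOVA rejects unpaired designs", {
  expect_error(artAnova(rnorm(5), rep("ICA", 5),
                        c("a", "a", "b", "b", "b"), c(1, 2, 1, 2, 3)),
               "exactly one row")
})

test_that("agreement report reproduces its component statistics", {
  set.seed(6)
  x <- data.frame(m1 = rnorm(20, 5), m2 = runif(20, 1, 3))
  y <- data.frame(m1 = x$m1 * 0.9 + rnorm(20, 0, 0.2),
                  m2 = x$m2 + 0.3)
  rep <- agreementReport(x, y)
  expect_equal(rep$metric, c("m1", "m2"))
  expect_equal(rep$slope[1], slopeAndPcc(x$m1, y$m1)$slope)
  expect_equal(rep$pcc[2], cor(x$m2, y$m2))
  expect_equal(rep$bias[2], 0.3)
  expect_equal(rep$rpdMean[1], mean(rpd(x$m1, y$m1)))
  self <- agreementReport(x, x)
  expect_equal(self$rpdMean, c(0, 0))
  expect_equal(self$slope, c(1, 1))
  expect_equal(self$pcc, c(1, 1))
  expect_equal(self$bias, c(0, 0))
})
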