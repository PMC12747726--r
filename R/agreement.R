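# Paired-model agreement statistics: relative percent difference, linear
# regression slope, Pearson correlation, Bland-Altman limits, rank tests,
# and the aligned-rank-transform factorial ANOVA.

#' Relative percent difference
#'
#' Symmetric paired discrepancy: `100 |a - b| / ((|a| + |b|) / 2)`,
#' vectorized; defined as 0 where both magnitudes are 0.
#'
#' @param a,b paired metric values.
#' @return percent differences, same length as the inputs.
#' @export
rpd <- function(a, b) {
  den <- (abs(a) + abs(b)) / 2
  out <- ifelse(den == 0, 0, 100 * abs(a - b) / den)
  as.numeric(out)
}

#' Bland-Altman agreement limits
#'
#' For paired measurements, `d = y - x`, bias = mean(d), and 95% limits of
#' agreement bias +/- 1.96 sd(d) (sample sd, n - 1 denominator).
#'
#' @param x,y paired vectors (length >= 3).
#' @return list with `bias`, `upLim`, `lowLim`.
#' @export
blandAltman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 pairs")
  d <- y - x
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, upLim = bias + 1.96 * s, lowLim = bias - 1.96 * s)
}

#' Regression slope and Pearson correlation of paired metrics
#'
#' Ordinary least squares of `y` on `x` with a free intercept
#' (`throughOrigin = TRUE` forces the line through the origin), plus the
#' Pearson correlation coefficient.
#'
#' @param x,y paired vectors (length >= 3, `x` not constant).
#' @param throughOrigin drop the intercept (default `FALSE`).
#' @return list with `slope` and `pcc`.
#' @export
slopeAndPcc <- function(x, y, throughOrigin = FALSE) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (var(x) == 0) stop("x is constant; slope undefined")
  fit <- if (throughOrigin) lm(y ~ x + 0) else lm(y ~ x)
  list(slope = unname(coef(fit)[["x"]]), pcc = cor(x, y))
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Mid-rank handling of ties throughout. When the pooled sample size is at
#' most `exactMax` the two-sided p-value is computed by exact enumeration of
#' all group assignments (valid under ties); otherwise the normal
#' approximation with continuity correction is used.
#'
#' @param g1,g2 numeric group samples (each length >= 2).
#' @param exactMax largest pooled n for exact enumeration (default 12).
#' @return list with `statistic` (Mann-Whitney U of `g1`) and `p.value`.
#' @export
wilcoxonRankSum <- function(g1, g2, exactMax = 12) {
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2 || n2 < 2) stop("both groups need at least 2 values")
  pooled <- c(g1, g2)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exactMax) {
    mid <- n1 * n2 / 2
    obsDev <- abs(u - mid)
    sets <- combn(n1 + n2, n1)
    us <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mid) >= obsDev - 1e-12)
  } else {
    p <- suppressWarnings(
      wilcox.test(g1, g2, exact = FALSE, correct = TRUE)$p.value)
  }
  list(statistic = u, p.value = p)
}

#' Paired t-test on model differences
#'
#' Standard two-sided paired t-test on `d = y - x`. All-zero differences
#' give p = 1 (no difference); zero-variance nonzero differences are
#' degenerate and rejected.
#'
#' @param x,y paired vectors (length >= 3).
#' @return list with `t` and `p.value`.
#' @export
pairedT <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 pairs")
  d <- y - x
  if (var(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p.value = 1))
    stop("zero-variance nonzero differences: paired t undefined")
  }
  ht <- t.test(y, x, paired = TRUE)
  list(t = unname(ht$statistic), p.value = ht$p.value)
}

#' Aligned rank transform two-factor ANOVA
#'
#' Nonparametric factorial ANOVA for a location (between-case) by
#' rheology-model (within-case) design. For each effect, responses are
#' aligned by removing the estimated (cell-mean) contributions of every
#' other effect, ranked with mid-rank ties, and submitted to a fixed-effects
#' two-factor ANOVA on the ranks; only the aligned effect's F and p are
#' reported from each fit. `caseId` is used to validate the paired design
#' (every case must appear under both model levels); rows are treated as
#' exchangeable within cells by the test itself.
#'
#' @param values metric values, one row per case x model combination.
#' @param location factor with levels ICA/MCA/ACA (or any location coding).
#' @param model factor with two levels (e.g. newtonian / non-newtonian).
#' @param caseId case identifier; every case must appear once per model
#'   level.
#' @return data.frame with one row per effect (`location`, `model`,
#'   `location:model`) and columns `F` and `p`.
#' @examples
#' coh <- expand.grid(case = 1:30, model = c("newt", "cy"))
#' coh$loc <- rep(rep(c("ICA", "MCA", "ACA"), each = 10), 2)
#' coh$y <- rnorm(60)
#' artAnova(coh$y, coh$loc, coh$model, coh$case)
#' @export
artAnova <- function(values, location, model, caseId) {
  location <- droplevels(as.factor(location))
  model <- droplevels(as.factor(model))
  caseId <- as.factor(caseId)
  tab <- table(caseId, model)
  if (any(tab != 1))
    stop("every case must contribute exactly one row per model level")
  grand <- mean(values)
  cellMean <- ave(values, location, model)
  locMean <- ave(values, location)
  modMean <- ave(values, model)
  resid <- values - cellMean
  aligned <- list(
    location = resid + (locMean - grand),
    model = resid + (modMean - grand),
    `location:model` = resid + (cellMean - locMean - modMean + grand)
  )
  effects <- names(aligned)
  out <- data.frame(effect = effects, F = NA_real_, p = NA_real_)
  for (k in seq_along(effects)) {
    rk <- rank(aligned[[k]])
    an <- summary(aov(rk ~ location * model))[[1]]
    out$F[k] <- an[k, "F value"]
    out$p[k] <- an[k, "Pr(>F)"]
  }
  out
}

#' Paired-model agreement report
#'
#' Builds one agreement row per metric from two aligned per-case tables
#' (e.g. Newtonian as `x`, non-Newtonian as `y`): per-case RPD mean and SD,
#' regression slope, Pearson correlation, and the Bland-Altman bias and 95%
#' limits.
#'
#' @param x,y data.frames of per-case metric columns, same column names and
#'   row order.
#' @param metrics columns to report (default: all shared numeric columns).
#' @return data.frame with columns `metric`, `meanX`, `sdX`, `meanY`,
#'   `sdY`, `rpdMean`, `rpdSd`, `slope`, `pcc`, `bias`, `upLim`, `lowLim`.
#' @export
agreementReport <- function(x, y, metrics = NULL) {
  if (is.null(metrics))
    metrics <- intersect(names(x)[vapply(x, is.numeric, logical(1))],
                         names(y)[vapply(y, is.numeric, logical(1))])
  rows <- lapply(metrics, function(m) {
    xv <- x[[m]]; yv <- y[[m]]
    r <- rpd(xv, yv)
    sl <- if (length(xv) >= 3 && var(xv) > 0 && var(yv) > 0)
      slopeAndPcc(xv, yv) else list(slope = NA_real_, pcc = NA_real_)
    ba <- blandAltman(xv, yv)
    data.frame(metric = m, meanX = mean(xv), sdX = sd(xv),
               meanY = mean(yv), sdY = sd(yv),
               rpdMean = mean(r), rpdSd = sd(r),
               slope = sl$slope, pcc = sl$pcc,
               bias = ba$bias, upLim = ba$upLim, lowLim = ba$lowLim)
  })
  do.call(rbind, rows)
}
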