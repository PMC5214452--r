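# Statistical machinery: ROC/AUC, intervals, exact tests, rank methods,
# logistic likelihood-ratio tests.

test_that("rocAuc equals the Mann-Whitney pair-counting statistic", {
  expect_equal(rocAuc(c(1, 2, 10, 20), c("control", "control",
                                         "case", "case"))$auc, 1)
  expect_equal(rocAuc(rep(5, 6), rep(c("case", "control"), 3))$auc, 0.5)
  # 5 wins + 2 ties over 9 pairs
  r <- rocAuc(c(1, 2, 3, 2, 3, 4),
              c(rep("control", 3), rep("case", 3)))
  expect_equal(r$auc, 7 / 9, tolerance = 1e-15)
  set.seed(71)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    v <- sample(1:8, n, replace = TRUE)      # heavy ties
    case <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(case) || all(case)) next
    expect_equal(rocAuc(v, ifelse(case, "case", "control"))$auc,
                 bruteAucPairs(v, case), tolerance = 1e-12)
  }
  expect_error(rocAuc(1:3, rep("case", 3)), "at least one")
})

test_that("rocAuc agrees with the reference ROC library", {
  set.seed(72)
  for (i in 1:10) {
    v <- rnorm(40)
    case <- rbinom(40, 1, 0.4) == 1
    if (!any(case) || all(case)) next
    mine <- rocAuc(v, ifelse(case, "case", "control"))$auc
    ref <- as.numeric(pROC::auc(
      pROC::roc(response = case, predictor = v, quiet = TRUE,
                direction = "<", levels = c(FALSE, TRUE))))
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("ROC curves run monotonically from (0,0) to (1,1)", {
  set.seed(73)
  v <- c(rnorm(15), rnorm(10, 1))
  r <- rocAuc(v, rep(c("control", "case"), c(15, 10)))
  cv <- r$curve
  expect_equal(cv$fpr[1], 0); expect_equal(cv$tpr[1], 0)
  expect_equal(cv$fpr[nrow(cv)], 1); expect_equal(cv$tpr[nrow(cv)], 1)
  expect_true(all(diff(cv$fpr) >= 0))
  expect_true(all(diff(cv$tpr) >= 0))
})

test_that("DeLong intervals are label-symmetric and truncate at 1", {
  set.seed(74)
  v <- c(rnorm(30), rnorm(30, 1))
  lab <- rep(c("control", "case"), each = 30)
  ci <- aucCI(rocAuc(v, lab))
  swapped <- aucCI(rocAuc(v, rep(c("case", "control"), each = 30)))
  expect_equal(swapped, c(1 - ci[2], 1 - ci[1]), tolerance = 1e-10)
  sep <- c(rnorm(50), rnorm(50, 30))
  sepLab <- rep(c("control", "case"), each = 50)
  expect_warning(ciSep <- aucCI(rocAuc(sep, sepLab)), "degenerate")
  expect_equal(ciSep[2], 1)
})

test_that("optimal cutoff minimizes distance to the perfect corner", {
  # oracle: exhaustive search over all curve points
  exhaustive <- function(r) {
    cv <- r$curve[is.finite(r$curve$cutoff), ]
    d <- sqrt((1 - cv$sens)^2 + (1 - cv$spec)^2)
    cv$cutoff[d == min(d)]
  }
  vals <- c(-99.9, -99, -50, -80, -95)
  labs <- c("control", "control", "case", "case", "case")
  r <- rocAuc(vals, labs)
  cut <- optimalCutoff(r)
  expect_true(cut$cutoff %in% exhaustive(r))
  expect_equal(cut$cutoff, -95)
  expect_equal(cut$sens, 1)
  expect_equal(cut$spec, 1)
  expect_equal(cut$distance, 0)
  set.seed(75)
  for (i in 1:25) {
    v <- round(rnorm(20), 1)
    case <- rbinom(20, 1, 0.5) == 1
    if (!any(case) || all(case)) next
    r <- rocAuc(v, ifelse(case, "case", "control"))
    cut <- optimalCutoff(r)
    best <- exhaustive(r)
    expect_true(cut$cutoff %in% best)
    expect_equal(cut$distance,
                 min(sqrt((1 - r$curve$sens)^2 + (1 - r$curve$spec)^2)))
  }
  # separable singleton classes
  r1 <- rocAuc(c(0, 1), c("control", "case"))
  expect_equal(optimalCutoff(r1)$distance, 0)
})

test_that("Clopper-Pearson bounds invert the binomial tail tests", {
  expect_equal(clopperPearson(0, 10)[1], 0)
  expect_equal(clopperPearson(10, 10)[2], 1)
  for (kn in list(c(6, 45), c(16, 39), c(11, 30), c(3, 8), c(52, 82))) {
    ci <- clopperPearson(kn[1], kn[2])
    # at the lower bound the upper-tail probability is exactly alpha/2
    expect_lt(abs(pbinom(kn[1] - 1, kn[2], ci[1],
                         lower.tail = FALSE) - 0.025), 1e-10)
    expect_lt(abs(pbinom(kn[1], kn[2], ci[2]) - 0.025), 1e-10)
  }
  expect_error(clopperPearson(1, 0))
})

test_that("Fisher exact p-values match enumeration", {
  # balanced diagonal table: only the two extreme tables are as unlikely
  expect_equal(fisherExact(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)),
               2 / choose(10, 5), tolerance = 1e-12)
  # proportional rows carry no association
  expect_equal(fisherExact(matrix(c(2, 4, 3, 6), 2, byrow = TRUE)), 1)
  expect_warning(p0 <- fisherExact(matrix(c(0, 0, 3, 6), 2, byrow = TRUE)),
                 "zero margin")
  expect_equal(p0, 1)
  # the hormone-receptor association table
  expect_equal(round(fisherExact(matrix(c(22, 12, 28, 54), 2,
                                        byrow = TRUE)), 3), 0.004)
  set.seed(76)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 5), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisherExact(tab), enumFisher2x2(tab), tolerance = 1e-9)
  }
})

test_that("2x3 Fisher agrees with Freeman-Halton enumeration", {
  for (tab in list(matrix(c(3, 1, 4, 2, 5, 0), 2),
                   matrix(c(1, 6, 2, 2, 4, 1), 2),
                   matrix(c(11, 19, 6, 39, 16, 23), 2, byrow = TRUE))) {
    expect_equal(fisherExact(tab), enumFisher2xK(tab), tolerance = 1e-7)
  }
})

test_that("rank-sum p-values are exact for small untied samples", {
  expect_equal(wilcoxonRankSum(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  expect_equal(wilcoxonRankSum(c(5, 7, 9), c(5, 7, 9)), 1)
  # power under a 2-SD shift
  set.seed(77)
  rej <- mean(replicate(200, {
    wilcoxonRankSum(rnorm(50), rnorm(50, 2)) < 0.05
  }))
  expect_gte(rej, 0.99)
})

test_that("group summaries use linear-interpolation quantiles", {
  g <- groupSummary(c(1, 2, 3, 4))
  expect_equal(c(g$q1, g$q3), c(1.75, 3.25))
  expect_true(g$q1 <= g$median && g$median <= g$q3)
  expect_equal(g$n, 4L)
})

test_that("median differences use the Hodges-Lehmann estimator", {
  expect_equal(medianDifferenceCI(c(1, 2, 3), c(1, 2, 3))$estimate, 0)
  md <- medianDifferenceCI(c(10, 20, 30), c(1, 2, 3))
  # oracle: median of all pairwise differences
  expect_equal(md$estimate,
               median(as.vector(outer(c(10, 20, 30), c(1, 2, 3), "-"))))
  expect_equal(md$estimate, 18)
  expect_true(md$low <= md$estimate && md$estimate <= md$high)
})

test_that("logistic LRT recovers effects and flags degeneracies", {
  expect_equal(logisticLrtOr(rep(2, 20), rep(c(TRUE, FALSE), 10)),
               list(p = 1, or = 1, orLow = NA_real_, orHigh = NA_real_,
                    separated = FALSE))
  # slope recovery: simulated logistic data, beta = 0.8 per unit
  set.seed(78)
  hits <- replicate(200, {
    x <- rnorm(500)
    y <- rbinom(500, 1, plogis(-0.3 + 0.8 * x)) == 1
    fit <- logisticLrtOr(x, y, scale = 1)
    se <- (log(fit$orHigh) - log(fit$or)) / qnorm(0.975)
    abs(log(fit$or) - 0.8) < 3 * se
  })
  expect_gte(mean(hits), 0.99)
  # complete separation is reported
  sepfit <- logisticLrtOr(c(1:5, 11:15), rep(c(FALSE, TRUE), each = 5))
  expect_true(sepfit$separated)
})
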