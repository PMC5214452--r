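# ROC/AUC machinery and the supporting inferential statistics.
#
# Orientation convention throughout: patients with pCR are controls
# (negative outcome), non-pCR are cases (positive outcome), and a test is
# positive when the predictor value is >= the cutoff.

#' Mann-Whitney AUC of a case/control predictor
#'
#' The AUC equals the Mann-Whitney statistic
#' (#\{case > control\} + 0.5 #\{ties\}) / (n_case n_control),
#' computed via midranks.  The ROC curve is traced over all distinct
#' cutoffs with the rule "positive if value >= cutoff".
#'
#' @param values numeric predictor values.
#' @param labels "case"/"control" (character or factor), or a logical
#'   vector with TRUE = case.
#' @return A list of class "RocResult": `auc`, `curve` (data.frame with
#'   cutoff, fpr, tpr, sens, spec, from (0,0) to (1,1)), `nCase`,
#'   `nControl`, and the inputs (used by [aucCI()]).
#' @examples
#' rocAuc(c(1, 2, 3, 2, 3, 4), c(rep("control", 3), rep("case", 3)))$auc
#' @export
rocAuc <- function(values, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "case", "control")
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels),
            all(labels %in% c("case", "control")), all(is.finite(values)))
  case <- labels == "case"
  n1 <- sum(case); n0 <- sum(!case)
  if (n1 == 0L || n0 == 0L)
    stop("ROC analysis requires at least one case and one control")
  r <- rank(values)
  auc <- (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cuts <- c(Inf, sort(unique(values), decreasing = TRUE))
  tpr <- vapply(cuts, function(c) mean(values[case] >= c), numeric(1))
  fpr <- vapply(cuts, function(c) mean(values[!case] >= c), numeric(1))
  structure(
    list(auc = auc,
         curve = data.frame(cutoff = cuts, fpr = fpr, tpr = tpr,
                            sens = tpr, spec = 1 - fpr),
         nCase = n1, nControl = n0, values = values, case = case),
    class = "RocResult")
}

#' DeLong confidence interval for an AUC
#'
#' Variance-based interval from DeLong's method (as implemented in pROC,
#' the standard tool for this analysis), truncated to \[0, 1\].  A
#' degenerate zero variance collapses the interval to the point estimate
#' with a warning.
#'
#' @param roc a "RocResult" from [rocAuc()].
#' @param level confidence level.
#' @return numeric(2): lower and upper bounds.
#' @export
aucCI <- function(roc, level = 0.95) {
  stopifnot(inherits(roc, "RocResult"))
  if (roc$nCase < 2L || roc$nControl < 2L)
    stop("DeLong interval requires at least two cases and two controls")
  r <- pROC::roc(response = factor(ifelse(roc$case, "case", "control"),
                                   levels = c("control", "case")),
                 predictor = roc$values,
                 levels = c("control", "case"), direction = "<",
                 quiet = TRUE)
  ci <- suppressWarnings(
    as.numeric(pROC::ci.auc(r, conf.level = level, method = "delong")))
  out <- pmin(pmax(c(ci[1], ci[3]), 0), 1)
  if (out[1] == out[2])
    warning("degenerate AUC variance: interval collapsed to the estimate")
  out
}

#' Optimal ROC cutoff closest to perfect classification
#'
#' The cutoff minimizing the Euclidean distance to the (sensitivity = 1,
#' specificity = 1) corner of the ROC curve; ties are broken in favor of
#' higher sensitivity (conservative for detecting residual disease).
#'
#' @param roc a "RocResult".
#' @return list: `cutoff`, `sens`, `spec`, `distance`.
#' @export
optimalCutoff <- function(roc) {
  stopifnot(inherits(roc, "RocResult"))
  cv <- roc$curve[is.finite(roc$curve$cutoff), ]
  d <- sqrt((1 - cv$sens)^2 + (1 - cv$spec)^2)
  best <- which(d == min(d))
  if (length(best) > 1L) best <- best[which.max(cv$sens[best])]
  list(cutoff = cv$cutoff[best], sens = cv$sens[best],
       spec = cv$spec[best], distance = d[best])
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a proportion; the lower bound is 0 when
#' k = 0 and the upper bound 1 when k = n.
#'
#' @param k successes.
#' @param n trials (> 0).
#' @param level confidence level.
#' @return numeric(2): lower and upper bounds as proportions.
#' @examples
#' round(100 * clopperPearson(6, 45))   # 5 27
#' @export
clopperPearson <- function(k, n, level = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  as.numeric(binom.test(k, n, conf.level = level)$conf.int)
}

#' Fisher exact test for a 2 x K contingency table
#'
#' Exact two-sided p-value summing the probabilities of all tables with
#' the observed margins that are no more probable than the observed one
#' (Freeman-Halton for K > 2).  A zero margin gives p = 1 with a warning.
#'
#' @param tab 2 x K matrix of non-negative integer counts.
#' @return the p-value.
#' @examples
#' fisherExact(matrix(c(22, 12, 28, 54), 2, byrow = TRUE))  # ~0.004
#' @export
fisherExact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 2L, all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin: the table carries no information, p = 1")
    return(1)
  }
  fisher.test(tab)$p.value
}

#' Wilcoxon rank-sum test
#'
#' Two-sided p-value; exact when the combined sample size is at most 20
#' and there are no ties, otherwise the normal approximation with tie
#' correction.
#'
#' @param x,y numeric samples.
#' @return the p-value.
#' @export
wilcoxonRankSum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  exact <- (length(x) + length(y)) <= 20 &&
    !anyDuplicated(c(x, y))
  suppressWarnings(wilcox.test(x, y, exact = exact)$p.value)
}

#' Median and interquartile range of one group
#'
#' Quantiles use linear interpolation (the type-7 convention).
#'
#' @param values numeric vector.
#' @return list of class "GroupSummary": `median`, `q1`, `q3`, `n`.
#' @export
groupSummary <- function(values) {
  values <- values[is.finite(values)]
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(median = q[2], q1 = q[1], q3 = q[3], n = length(values)),
            class = "GroupSummary")
}

#' Hodges-Lehmann median difference with rank-inverted interval
#'
#' Estimate: median of all pairwise differences x_i - y_j; the interval
#' inverts the Wilcoxon rank-sum test.
#'
#' @param x,y numeric samples (each of size >= 2).
#' @param level confidence level.
#' @return list: `estimate`, `low`, `high`.
#' @export
medianDifferenceCI <- function(x, y, level = 0.95) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  w <- suppressWarnings(
    wilcox.test(x, y, conf.int = TRUE, conf.level = level))
  list(estimate = unname(w$estimate),
       low = w$conf.int[1], high = w$conf.int[2])
}

#' Logistic likelihood-ratio test and odds ratio
#'
#' Single-covariate logistic model for P(non-pCR); p-value from the
#' likelihood-ratio test against the intercept-only model (chi-squared, 1
#' df); odds ratio per `scale` predictor units (default: 10 percentage
#' points of percent FTV change) with a Wald interval.  Complete
#' separation (no finite MLE) is detected and flagged; a zero-variance
#' predictor returns p = 1, OR = 1.
#'
#' @param predictor numeric covariate.
#' @param outcome logical (TRUE = non-pCR / case) or a "case"/"control"
#'   vector.
#' @param scale predictor units per odds-ratio step.
#' @param level confidence level for the OR interval.
#' @return list: `p`, `or`, `orLow`, `orHigh`, `separated`.
#' @export
logisticLrtOr <- function(predictor, outcome, scale = 10, level = 0.95) {
  if (!is.logical(outcome)) outcome <- as.character(outcome) == "case"
  stopifnot(length(predictor) == length(outcome),
            all(is.finite(predictor)))
  if (!any(outcome) || all(outcome))
    stop("both outcome classes must be present")
  if (diff(range(predictor)) == 0)
    return(list(p = 1, or = 1, orLow = NA_real_, orHigh = NA_real_,
                separated = FALSE))
  x <- predictor / scale
  separated <- FALSE
  full <- withCallingHandlers(
    glm(outcome ~ x, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!full$converged) {
    # a near-zero deviance is separation (no finite MLE), not a failure
    if (full$deviance < 1e-6) separated <- TRUE
    else stop("logistic fit did not converge (deviance ",
              format(full$deviance), ")")
  }
  null <- glm(outcome ~ 1, family = binomial())
  lrt <- as.numeric(2 * (logLik(full) - logLik(null)))
  p <- pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
  beta <- coef(full)[["x"]]
  se <- sqrt(vcov(full)["x", "x"])
  # a huge slope with huge SE is the Wald signature of separation
  if (abs(beta) > 15) separated <- TRUE
  z <- qnorm(1 - (1 - level) / 2)
  list(p = p, or = exp(beta),
       orLow = exp(beta - z * se), orHigh = exp(beta + z * se),
       separated = separated)
}
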