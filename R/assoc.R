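## Case-control statistical toolkit: Pearson chi-square (with Cohen's w),
## a-priori chi-square power, odds ratios, ROC/AUC, independent t-tests.

#' Pearson chi-square test of a contingency table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square with
#' df = (r-1)(c-1), plus Cohen's effect size w = sqrt(chi2 / n).
#'
#' @param table r x c matrix of non-negative counts.
#' @return list with `chi2`, `df`, `p`, `w`, `n` and `expected`.
#' @export
#' @examples chi2Contingency(rbind(c(10, 20), c(20, 10)))
chi2Contingency <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0)) stop("empty row in contingency table: ",
                         paste(which(rs == 0), collapse = ", "))
  if (any(cs == 0)) stop("empty column in contingency table: ",
                         paste(which(cs == 0), collapse = ", "))
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("need at least 2 rows and 2 columns")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  n <- sum(table)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, w = sqrt(unname(ct$statistic) / n), n = n,
       expected = ct$expected)
}

#' Sample size for a chi-square test at given effect size and power
#'
#' Solves for the N at which a Pearson chi-square test with noncentrality
#' lambda = N * w^2 first reaches the target power: the power function
#' `P[chi2_nc(df, N w^2) > chi2_crit(1 - alpha, df)]` is strictly increasing
#' in N, so the exact crossing is found by root search and the minimal
#' integer N by ceiling (checked against the boundary).
#'
#' @param w Cohen's effect size (> 0).
#' @param df degrees of freedom.
#' @param alpha significance level.
#' @param power target power.
#' @return list with `n_exact`, `n_min`, and `power_at_n_min`.
#' @export
#' @examples chi2PowerN(w = 0.1)$n_min  # 785
chi2PowerN <- function(w, df = 1, alpha = 0.05, power = 0.80) {
  stopifnot(w > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  crit <- stats::qchisq(1 - alpha, df)
  powerAt <- function(n) stats::pchisq(crit, df, ncp = n * w^2, lower.tail = FALSE)
  upper <- 10 / w^2
  while (powerAt(upper) < power) upper <- upper * 2
  nExact <- stats::uniroot(function(n) powerAt(n) - power,
                           lower = .Machine$double.eps, upper = upper,
                           tol = 1e-10)$root
  nMin <- ceiling(nExact)
  if (nMin > 1 && powerAt(nMin - 1) >= power) nMin <- nMin - 1
  list(n_exact = nExact, n_min = as.integer(nMin), power_at_n_min = powerAt(nMin))
}

#' Odds ratio with Woolf (log-method) confidence interval
#'
#' `oddsRatio` takes the 2x2 cell counts (a = exposed cases, b = unexposed
#' cases, c = exposed controls, d = unexposed controls); OR = ad/bc with CI
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. The Haldane-Anscombe
#' +0.5 correction is applied iff any cell is zero. `oddsRatioFromProps`
#' converts two proportions directly: `(p1/(1-p1)) / (p2/(1-p2))`.
#'
#' @param a,b,c,d 2x2 counts.
#' @param conf confidence level.
#' @return list with `or`, `lower`, `upper`, `conf` (or a bare OR for
#'   `oddsRatioFromProps`).
#' @export
#' @examples oddsRatioFromProps(0.317, 0.245)  # 1.43
oddsRatio <- function(a, b, c, d, conf = 0.95) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  if (any(c(a, b, c, d) == 0)) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1/a + 1/b + 1/c + 1/d)
  list(or = or, lower = exp(log(or) - z * se), upper = exp(log(or) + z * se),
       conf = conf)
}

#' @rdname oddsRatio
#' @param p1,p2 the two proportions (in (0,1)).
#' @export
oddsRatioFromProps <- function(p1, p2) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1)
  (p1 / (1 - p1)) / (p2 / (1 - p2))
}

#' ROC AUC with confidence interval and test against no discrimination
#'
#' AUC is the Mann-Whitney pair-counting statistic: the probability that a
#' randomly chosen positive scores above a randomly chosen negative, with
#' ties counted 1/2 (computed via midranks). The CI uses the Hanley-McNeil
#' standard error by default (DeLong available); the p-value is the normal
#' approximation of AUC - 0.5.
#'
#' @param scoresPos scores of the positive class (e.g. athletes).
#' @param scoresNeg scores of the negative class.
#' @param conf confidence level.
#' @param method `"hanley"` (default) or `"delong"` for the SE.
#' @return list with `auc`, `lower`, `upper`, `se`, `p`, `n_pos`, `n_neg`.
#' @export
#' @examples rocAuc(c(3, 5), c(1, 4))$auc  # 0.75
rocAuc <- function(scoresPos, scoresNeg, conf = 0.95,
                   method = c("hanley", "delong")) {
  method <- match.arg(method)
  scoresPos <- scoresPos[!is.na(scoresPos)]
  scoresNeg <- scoresNeg[!is.na(scoresNeg)]
  n1 <- length(scoresPos); n2 <- length(scoresNeg)
  if (n1 < 1 || n2 < 1) stop("both score lists must be non-empty")
  r <- rank(c(scoresPos, scoresNeg))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  if (method == "hanley") {
    q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                  (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  } else {
    ## DeLong structural components
    v10 <- vapply(scoresPos, function(x)
      mean((x > scoresNeg) + 0.5 * (x == scoresNeg)), 0)
    v01 <- vapply(scoresNeg, function(y)
      mean((scoresPos > y) + 0.5 * (scoresPos == y)), 0)
    se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n2)
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se) else
    as.numeric(auc == 0.5)
  list(auc = auc, lower = max(0, auc - z * se), upper = min(1, auc + z * se),
       se = se, p = p, n_pos = n1, n_neg = n2)
}

#' Independent two-sample t-test
#'
#' Student's pooled-variance two-sided test by default; Welch's unequal
#' variance form with `welch = TRUE`.
#'
#' @param x,y numeric score vectors (each n >= 2).
#' @param welch use the Welch correction.
#' @return list with `t`, `df`, `p`, and the two group means.
#' @export
tTestInd <- function(x, y, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
  if (stats::sd(c(x, y)) == 0)
    return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                mean_x = mean(x), mean_y = mean(y)))
  tt <- stats::t.test(x, y, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_x = mean(x), mean_y = mean(y))
}
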