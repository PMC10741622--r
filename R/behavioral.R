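# Behavioral measures: weighted checklist percent, NASA-TLX totals, and
# inter-rater reliability via the two-way random-effects, absolute-agreement,
# single-rater intraclass correlation.

#' Weighted checklist percent
#'
#' Each checklist item is rated on a 3-point scale (Yes = 2, Maybe = 1,
#' No = 0) and carries a positive weight. The score is the total weighted
#' rating divided by the total possible weighted score:
#' `sum(w * rating) / sum(w * 2)`. Invariant under uniform weight rescaling
#' and monotone in every rating.
#'
#' @param weights positive item weights (recycled scalar allowed).
#' @param ratings item ratings, each in \{0, 1, 2\}.
#' @return fraction in [0, 1].
#' @examples
#' weightedPercent(c(1, 3), c(2, 1))  # (2 + 3) / (2 + 6) = 0.625
#' @export
weightedPercent <- function(weights, ratings) {
  if (!length(ratings)) stop("at least one checklist item is required")
  weights <- rep_len(weights, length(ratings))
  if (any(weights <= 0)) stop("item weights must be positive")
  if (!all(ratings %in% c(0, 1, 2)))
    stop("checklist ratings must be 0, 1, or 2")
  sum(weights * ratings) / sum(weights * 2)
}

#' NASA-TLX total and rescaled fraction
#'
#' Six subscales on a 0-20 visual-analog scale are summed into a total
#' cognitive-load score on 0-120, and rescaled to a fraction of the
#' possible maximum.
#'
#' @param subscales numeric vector of six values in [0, 20].
#' @return list: `total` (0-120) and `fraction` (`total / 120`).
#' @examples
#' tlxTotal(rep(10, 6))  # total 60, fraction 0.5
#' @export
tlxTotal <- function(subscales) {
  if (length(subscales) != 6) stop("NASA-TLX has exactly 6 subscales")
  if (any(subscales < 0) || any(subscales > 20))
    stop("TLX subscales must lie in [0, 20]")
  total <- sum(subscales)
  list(total = total, fraction = total / 120)
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' Single-rater ICC(2,1) from the two-way random-effects ANOVA
#' decomposition of a complete subjects-by-raters matrix:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{MS_R} the between-subjects, \eqn{MS_C} the between-raters, and
#' \eqn{MS_E} the residual mean square. The F statistic is
#' \eqn{MS_R / MS_E} with degrees of freedom \eqn{(n-1, (n-1)(k-1))}; the
#' 95% confidence interval is the standard F-based interval for the
#' absolute-agreement form (Satterthwaite denominator degrees of freedom).
#'
#' @param ratings numeric matrix, subjects x raters, no missing cells.
#' @param conf confidence level (default 0.95).
#' @return list: `icc`, `F`, `df1`, `df2`, `p`, `ci` (length-2), `ms`
#'   (named mean squares).
#' @examples
#' m <- cbind(r1 = c(9, 6, 8, 7), r2 = c(2, 1, 4, 1))
#' iccAbsoluteAgreement(m)$icc
#' @export
iccAbsoluteAgreement <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 raters")
  if (anyNA(ratings)) stop("rating matrix must have no missing cells")
  grand <- mean(ratings)
  rowm <- rowMeans(ratings); colm <- colMeans(ratings)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(rowm, colm, `+`) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr == 0 && mse == 0)
    stop("ICC undefined: zero subject and residual variance")
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  fstat <- msr / mse
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  p <- pf(fstat, df1, df2, lower.tail = FALSE)

  if (mse == 0 || icc >= 1) {        # perfect agreement: degenerate interval
    return(list(icc = icc, F = fstat, df1 = df1, df2 = df2, p = p,
                ci = c(lower = icc, upper = icc),
                ms = c(subjects = msr, raters = msc, residual = mse)))
  }

  # McGraw & Wong (1996) interval for ICC(A,1)
  alpha <- 1 - conf
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fL <- qf(1 - alpha / 2, df1, v)
  fU <- qf(1 - alpha / 2, v, df1)
  lower <- n * (msr - fL * mse) /
    (fL * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fU * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fU * msr)
  list(icc = icc, F = fstat, df1 = df1, df2 = df2, p = p,
       ci = c(lower = lower, upper = upper),
       ms = c(subjects = msr, raters = msc, residual = mse))
}
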