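# Group comparisons and penalized linear modeling: independent-samples
# t-tests (from raw data or printed summaries), feature-wise group reports,
# Pearson screening, Lasso with 5-fold CV at the minimum-MSE lambda, and the
# naive OLS refit on the selected variables.

.tFromSummary <- function(m1, s1, n1, m2, s2, n2, variant) {
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- if (se > 0) (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1)) else
      n1 + n2 - 2
  }
  d <- m1 - m2
  if (se == 0) {
    t <- if (d == 0) 0 else sign(d) * Inf
  } else t <- d / se
  p <- if (is.infinite(t)) 0 else 2 * pt(-abs(t), df)
  if (d == 0 && se == 0) p <- 1
  list(t = t, df = df, p = p)
}

#' Independent-samples t-test
#'
#' Pooled-variance (default) or Welch two-sample t-test, two-sided. The
#' pooled form uses \eqn{t = (\bar x - \bar y) / (s_p \sqrt{1/n_x + 1/n_y})}
#' with \eqn{df = n_x + n_y - 2}; Welch uses the Satterthwaite df. With zero
#' variance in both groups and equal means, p = 1 by convention.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @param variant `"pooled"` or `"welch"`.
#' @param feature optional feature name carried into the result.
#' @return list: `feature`, `mean1`, `sd1`, `n1`, `mean2`, `sd2`, `n2`,
#'   `t`, `df`, `p`, `variant`.
#' @export
ttestIndependent <- function(x, y, variant = c("pooled", "welch"),
                             feature = "") {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  res <- .tFromSummary(mean(x), sd(x), length(x), mean(y), sd(y), length(y),
                       variant)
  c(list(feature = feature, mean1 = mean(x), sd1 = sd(x), n1 = length(x),
         mean2 = mean(y), sd2 = sd(y), n2 = length(y)),
    res, list(variant = variant))
}

#' t-test from printed summary statistics
#'
#' Recomputes a two-sample t-test from group means, SDs and sizes, e.g. to
#' reproduce published p-values from a summary table. Uses the same formulas
#' as [ttestIndependent()], so a pooled test from raw data agrees exactly
#' with this function applied to that data's own summaries.
#'
#' @param m1,s1,n1 mean, SD, size of group 1.
#' @param m2,s2,n2 mean, SD, size of group 2.
#' @param variant `"pooled"` or `"welch"`.
#' @return list as in [ttestIndependent()].
#' @examples
#' # printed summaries 0.30 (0.35) vs 0.03 (0.03), n = 8 each
#' ttestFromSummary(0.30, 0.35, 8, 0.03, 0.03, 8)$p  # ~0.047
#' @export
ttestFromSummary <- function(m1, s1, n1, m2, s2, n2,
                             variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (s1 < 0 || s2 < 0) stop("SDs must be nonnegative")
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  c(list(feature = "", mean1 = m1, sd1 = s1, n1 = n1,
         mean2 = m2, sd2 = s2, n2 = n2),
    .tFromSummary(m1, s1, n1, m2, s2, n2, variant),
    list(variant = variant))
}

#' Feature-wise group comparison report
#'
#' One independent-samples t-test per feature (experienced minus novice),
#' sorted by task and band. By default no multiplicity correction is
#' applied (matching common practice in small exploratory studies);
#' Benjamini-Hochberg adjustment is available via `adjust = "BH"`. The
#' delta band is computed upstream but excluded from the default report.
#'
#' @param table a [FeatureTable-class] with group labels in `colData`.
#' @param variant `"pooled"` or `"welch"`.
#' @param alpha significance level for the `significant` flag.
#' @param adjust `"none"` or `"BH"`.
#' @param includeDelta include delta-band features in the report.
#' @param kinds feature kinds to test (default coherence and PSD).
#' @return data.frame: task, band, kind, feature, meanExperienced,
#'   sdExperienced, meanNovice, sdNovice, t, df, p (and pAdjusted if
#'   requested), significant.
#' @export
compareGroups <- function(table, variant = c("pooled", "welch"),
                          alpha = 0.05, adjust = c("none", "BH"),
                          includeDelta = FALSE, kinds = c("coh", "psd")) {
  variant <- match.arg(variant)
  adjust <- match.arg(adjust)
  grp <- colData(table)$group
  if (min(table(grp)) < 2) stop("each group needs >= 2 participants")
  keep <- rowData(table)$kind %in% kinds
  if (!includeDelta) keep <- keep & rowData(table)$band != "delta"
  v <- assay(table)[keep, , drop = FALSE]
  rd <- rowData(table)[keep, , drop = FALSE]
  ex <- grp == "experienced"
  rows <- lapply(seq_len(nrow(v)), function(i) {
    r <- ttestIndependent(v[i, ex], v[i, !ex], variant,
                          feature = rownames(v)[i])
    data.frame(task = rd$task[i], band = rd$band[i], kind = rd$kind[i],
               feature = r$feature, meanExperienced = r$mean1,
               sdExperienced = r$sd1, meanNovice = r$mean2,
               sdNovice = r$sd2, t = r$t, df = r$df, p = r$p)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    out$pAdjusted <- stats::p.adjust(out$p, "BH")
    out$significant <- out$pAdjusted < alpha
  } else out$significant <- out$p < alpha
  taskOrder <- c("reading", "answer1", "answer2", "baseline")
  bandOrder <- eegBands()$band
  out[order(match(out$task, taskOrder), match(out$band, bandOrder),
            out$feature), ]
}

#' Screen features by Pearson correlation with an outcome
#'
#' Keeps the features whose Pearson correlation test against the outcome has
#' p below `alpha`. Constant features are excluded with a warning; a
#' constant outcome yields an empty set with a warning.
#'
#' @param table a [FeatureTable-class] or a features-x-observations matrix.
#' @param outcome numeric vector, one value per participant/observation.
#' @param alpha screening level.
#' @return character vector of screened-in feature names.
#' @export
pearsonScreen <- function(table, outcome, alpha = 0.05) {
  v <- if (is(table, "SummarizedExperiment")) assay(table) else as.matrix(table)
  if (length(outcome) != ncol(v))
    stop("outcome length must match participant count")
  if (length(outcome) < 3) stop("screening needs n >= 3")
  if (sd(outcome) == 0) {
    warning("outcome is constant; no feature can correlate with it")
    return(character())
  }
  const <- apply(v, 1, sd) == 0
  if (any(const))
    warning(sum(const), " constant feature(s) excluded from screening")
  keep <- vapply(which(!const), function(i)
    cor.test(v[i, ], outcome)$p.value < alpha, TRUE)
  rownames(v)[which(!const)[keep]]
}

#' Lasso with k-fold cross-validated penalty selection
#'
#' Fits the L1-penalized linear model over a log-spaced lambda grid (100
#' values from the smallest all-zero lambda down to 1e-4 of it), picks the
#' lambda minimizing the mean cross-validated MSE over `folds` random folds
#' (seeded, hence deterministic), and reports the nonzero coefficients at
#' that lambda. Predictors are standardized internally before penalization.
#'
#' @param X observations x features numeric matrix (named columns).
#' @param y numeric outcome.
#' @param folds number of CV folds (default 5); must not exceed n.
#' @param lambda optional explicit lambda grid.
#' @param seed fold-assignment seed.
#' @return list: `lambda` (chosen), `selected` (names), `coefficients`
#'   (at the chosen lambda, incl. intercept), `cvLambda`, `cvMSE`, `fit`
#'   (the glmnet path), `seed`.
#' @export
lassoCV <- function(X, y, folds = 5, lambda = NULL, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < folds) stop("need at least as many observations as folds")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = n))
  cv <- glmnet::cv.glmnet(X, y, foldid = foldid, lambda = lambda,
                          nlambda = 100, lambda.min.ratio = 1e-4,
                          standardize = TRUE)
  co <- as.matrix(coef(cv, s = "lambda.min"))[, 1]
  sel <- names(co)[-1][co[-1] != 0]
  list(lambda = cv$lambda.min, selected = sel, coefficients = co,
       cvLambda = cv$lambda, cvMSE = cv$cvm, fit = cv$glmnet.fit,
       seed = seed)
}

#' OLS refit on Lasso-selected features
#'
#' Ordinary least squares restricted to the selected columns, reporting
#' coefficients, standard errors, naive (not selection-adjusted) p-values,
#' and R-squared. Aliased (rank-deficient) columns are dropped with a
#' warning. With an empty selection the intercept-only model is returned
#' (R-squared 0).
#'
#' @param X observations x features matrix.
#' @param y outcome.
#' @param selected names of selected columns.
#' @param outcome outcome label carried into the fit.
#' @param lambda,cvLambda,cvMSE,seed CV bookkeeping carried into the fit.
#' @return A [ModelFit-class].
#' @export
postLassoOLS <- function(X, y, selected, outcome = "outcome",
                         lambda = NA_real_, cvLambda = numeric(),
                         cvMSE = numeric(), seed = NA_real_) {
  X <- as.matrix(X)
  selected <- intersect(selected, colnames(X))
  df <- if (length(selected))
    data.frame(y = y, X[, selected, drop = FALSE], check.names = FALSE)
  else data.frame(y = y)
  fit <- lm(y ~ ., data = df)
  if (length(selected) && any(is.na(coef(fit)))) {
    drop <- names(coef(fit))[is.na(coef(fit))]
    warning("dropping aliased column(s): ", paste(drop, collapse = ", "))
    selected <- setdiff(selected, drop)
    df <- data.frame(y = y, X[, selected, drop = FALSE], check.names = FALSE)
    fit <- lm(y ~ ., data = df)
  }
  sm <- summary(fit)
  tab <- as.data.frame(sm$coefficients[, c(1, 2, 4), drop = FALSE])
  names(tab) <- c("estimate", "std.error", "p.value")
  tab <- cbind(term = rownames(tab), tab)
  rownames(tab) <- NULL
  r2 <- if (length(selected)) sm$r.squared else 0
  new("ModelFit", outcome = outcome, selected = selected,
      coefficients = tab, r2 = r2, lambda = lambda,
      cvLambda = cvLambda, cvMSE = cvMSE, seed = seed,
      nobs = length(y))
}

#' Screen, select and refit an outcome model
#'
#' The full modeling stage: Pearson screening of candidate features against
#' the outcome, Lasso with CV-selected lambda on the screened set, then the
#' naive OLS refit on the selected variables.
#'
#' @param table normalized [FeatureTable-class] (or matrix features x
#'   observations).
#' @param outcome numeric outcome, one per participant.
#' @param outcomeName label for the fit.
#' @param alpha screening level.
#' @param folds,seed CV parameters.
#' @return A [ModelFit-class]; its `selected` slot is a subset of the
#'   screened features.
#' @export
fitOutcomeModel <- function(table, outcome, outcomeName = "outcome",
                            alpha = 0.05, folds = 5, seed = 1) {
  v <- if (is(table, "SummarizedExperiment")) assay(table) else as.matrix(table)
  screened <- pearsonScreen(v, outcome, alpha)
  if (!length(screened))
    return(postLassoOLS(t(v), outcome, character(), outcome = outcomeName,
                        seed = seed))
  X <- t(v[screened, , drop = FALSE])
  las <- lassoCV(X, outcome, folds = min(folds, length(outcome)), seed = seed)
  postLassoOLS(X, outcome, las$selected, outcome = outcomeName,
               lambda = las$lambda, cvLambda = las$cvLambda,
               cvMSE = las$cvMSE, seed = seed)
}
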