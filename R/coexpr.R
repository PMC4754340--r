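# Expression analytics: eQTL/exon-usage regression, correlation tests, the
# genotype-dependent coexpression LRT, and inverse-variance pooling of
# correlation differences.

#' Collapse dosages into a two-level genotype class
#'
#' Class 1 for carriers of the effect allele (dose >= 0.5, the imputed-dosage
#' convention), class 0 otherwise; missing dosages stay missing.  Collapsing
#' carriers into one class reflects designs where the homozygous-risk class
#' is too rare to model separately.
#'
#' @param dose numeric dosages in [0, 2] (NA allowed).
#' @return integer vector of 0/1 (NA preserved).
#' @examples
#' genotypeClass(c(0, 1, 2, 0, 0.4, 0.5, NA))
#' @export
genotypeClass <- function(dose) {
  if (any(dose < 0 | dose > 2, na.rm = TRUE)) {
    .tfStop("dosages must lie in [0, 2]", "tagfun_param_error")
  }
  out <- ifelse(dose >= 0.5, 1L, 0L)
  out[is.na(dose)] <- NA_integer_
  out
}

#' Correlation test with asymptotic t and optional bootstrap P
#'
#' Pearson or Spearman correlation, tested two-sided via
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n - 2 df (Spearman uses average ranks
#' for ties, significance via the same t approximation).  With
#' `bootstrapB > 0` a percentile-bootstrap P (sign-crossing of the resampled
#' correlation) is reported alongside.
#'
#' @param x,y numeric vectors (pairs with missing values dropped; n >= 4).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param bootstrapB number of bootstrap resamples (0 = none).
#' @param seed seed for the bootstrap (required when `bootstrapB > 0`).
#' @return list with `r`, `p`, `n`, `method`, `perfect_fit`, and
#'   `p_bootstrap` when requested.
#' @examples
#' set.seed(1); x <- rnorm(30)
#' correlationTest(x, x + rnorm(30))
#' @export
correlationTest <- function(x, y, method = c("pearson", "spearman"),
                            bootstrapB = 0, seed = NULL) {
  method <- match.arg(method)
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) .tfStop("need at least 4 complete pairs", "tagfun_size_error")
  if (sd(x) == 0 || sd(y) == 0) {
    .tfStop("constant input", "tagfun_degenerate_error")
  }
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  r <- cor(x, y)
  perfect <- abs(r) >= 1 - 1e-15
  if (perfect) {
    p <- 1e-300  # reported as < 1e-15; t statistic diverges
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    p <- max(p, 1e-300)
  }
  out <- list(r = r, p = p, n = n, method = method, perfect_fit = perfect)
  if (bootstrapB > 0) {
    if (is.null(seed)) .tfStop("bootstrap needs a seed", "tagfun_param_error")
    rb <- .withSeed(seed, vapply(seq_len(bootstrapB), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      suppressWarnings(cor(x[idx], y[idx]))
    }, numeric(1)))
    rb <- rb[!is.na(rb)]
    out$p_bootstrap <-
      min(1, 2 * min(mean(rb <= 0), mean(rb >= 0)) + 1 / length(rb))
  }
  out
}

#' Genotype-dependent coexpression likelihood-ratio test
#'
#' Tests whether the correlation between a target gene's and a TF's
#' expression differs between two genotype classes by comparing nested
#' linear models: reduced, target ~ tf + class; full, target ~ tf + class +
#' tf:class.  Both expression vectors are standardized internally (mean 0,
#' variance 1), which makes the interaction coefficient interpretable as the
#' difference in correlation between classes.  The Gaussian LRT statistic is
#' \eqn{n \ln(RSS_{reduced}/RSS_{full})} on 1 df; the one-sided P halves the
#' two-sided P when the interaction attenuates the class-1 (risk) slope
#' toward zero — the prespecified direction — and is 1 minus the half
#' otherwise.  An exact F test is available behind `fTest`.
#'
#' @param target,tf numeric expression vectors.
#' @param class01 genotype class per sample (0/1, e.g. from
#'   [genotypeClass()]); both classes need >= 3 samples.
#' @param fTest use the F statistic and its exact null instead of the
#'   chi-square LRT (default FALSE).
#' @return A `CoexprResult`: list with per-class Pearson correlations
#'   `r_class0`/`r_class1`, interaction estimate `delta_hat` and `delta_se`,
#'   `lrt_stat`, `p_two_sided`, `p_one_sided`, `n_class0`, `n_class1`.
#' @examples
#' cls <- rep(c(0, 1), each = 100)
#' xy <- simExpression(cls, rClass0 = 0.5, rClass1 = 0.1, seed = 1)
#' coexprLrt(xy$target, xy$tf, cls)
#' @export
coexprLrt <- function(target, tf, class01, fTest = FALSE) {
  keep <- complete.cases(target, tf, class01)
  target <- target[keep]; tf <- tf[keep]; cls <- class01[keep]
  if (any(!cls %in% c(0, 1))) {
    .tfStop("class01 must contain only 0/1", "tagfun_param_error")
  }
  n0 <- sum(cls == 0); n1 <- sum(cls == 1)
  if (n0 < 3L || n1 < 3L) {
    .tfStop("each genotype class needs at least 3 samples",
            "tagfun_size_error")
  }
  if (sd(target) == 0 || sd(tf) == 0) {
    .tfStop("constant expression", "tagfun_degenerate_error")
  }
  y <- as.vector(scale(target))
  x <- as.vector(scale(tf))
  n <- length(y)
  Xr <- cbind(1, x, cls)
  Xf <- cbind(Xr, x * cls)
  fitR <- stats::lm.fit(Xr, y)
  fitF <- stats::lm.fit(Xf, y)
  rssR <- sum(fitR$residuals^2)
  rssF <- sum(fitF$residuals^2)
  lrt <- max(0, n * log(rssR / rssF))
  if (fTest) {
    fstat <- (rssR - rssF) / (rssF / (n - 4L))
    pTwo <- stats::pf(fstat, 1L, n - 4L, lower.tail = FALSE)
  } else {
    pTwo <- pchisq(lrt, df = 1, lower.tail = FALSE)
  }
  delta <- unname(fitF$coefficients[4L])
  sigma2 <- rssF / (n - 4L)
  xtxInv <- chol2inv(chol(crossprod(Xf)))
  deltaSe <- sqrt(sigma2 * xtxInv[4L, 4L])
  slope0 <- unname(fitF$coefficients[2L])
  # attenuation: interaction pulls the class-1 slope toward zero
  attenuating <- sign(delta) == -sign(slope0) && delta != 0
  pOne <- if (attenuating) pTwo / 2 else 1 - pTwo / 2
  out <- list(
    r_class0 = cor(target[cls == 0], tf[cls == 0]),
    r_class1 = cor(target[cls == 1], tf[cls == 1]),
    delta_hat = delta, delta_se = deltaSe,
    lrt_stat = lrt, p_two_sided = pTwo, p_one_sided = pOne,
    n_class0 = n0, n_class1 = n1)
  class(out) <- "CoexprResult"
  out
}

#' @export
print.CoexprResult <- function(x, ...) {
  cat("Genotype-dependent coexpression LRT\n")
  cat(sprintf("  r (class 0, n=%d): %.3f   r (class 1, n=%d): %.3f\n",
              x$n_class0, x$r_class0, x$n_class1, x$r_class1))
  cat(sprintf("  correlation difference: %.3f (SE %.3f)\n",
              x$delta_hat, x$delta_se))
  cat(sprintf("  LRT = %.3f, P(two-sided) = %.3g, P(one-sided) = %.3g\n",
              x$lrt_stat, x$p_two_sided, x$p_one_sided))
  invisible(x)
}

#' Pool correlation differences across populations
#'
#' Inverse-variance fixed-effects combination of the per-population
#' interaction estimates (correlation differences) from [coexprLrt()];
#' delegates to [fixedEffectsMeta()] on the raw (not exponentiated) scale.
#'
#' @param results list of `CoexprResult` objects.
#' @return a meta record as from [fixedEffectsMeta()]; `or`/`ci_lo`/`ci_hi`
#'   are on the correlation-difference scale.
#' @export
correlationDifferenceMeta <- function(results) {
  if (!length(results)) .tfStop("no results supplied", "tagfun_size_error")
  beta <- vapply(results, function(r) r$delta_hat, numeric(1))
  se <- vapply(results, function(r) r$delta_se, numeric(1))
  fixedEffectsMeta(beta, se, exponentiate = FALSE)
}

#' Additive expression-on-dosage regression
#'
#' Ordinary least squares of (optionally log2-transformed) expression on
#' effect-allele dose plus covariates, with a t test on the dose
#' coefficient.  Serves both the cis-eQTL stage and exon-usage association.
#'
#' @param expr numeric expression values.
#' @param dose effect-allele dosages (non-constant).
#' @param covariates optional data.frame/matrix of covariates.
#' @param log2Transform regress on log2(expr) (values must be positive).
#' @return list with `beta`, `se`, `p`, `intercept`, `rss`, `n`, and logical
#'   `degenerate` (perfect fit: p reported as 0).
#' @examples
#' additiveExpressionAssoc(c(1.0, 0.8, 0.6, 1.1, 0.9, 0.7),
#'                         c(0, 1, 2, 0, 1, 2))
#' @export
additiveExpressionAssoc <- function(expr, dose, covariates = NULL,
                                    log2Transform = FALSE) {
  df <- data.frame(expr = as.numeric(expr), dose = as.numeric(dose))
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df <- df[complete.cases(df), , drop = FALSE]
  if (length(unique(df$dose)) < 2L) {
    .tfStop("dose is constant among analysed samples",
            "tagfun_degenerate_error")
  }
  if (log2Transform) {
    if (any(df$expr <= 0)) {
      .tfStop("log2 transform needs positive expression values",
              "tagfun_param_error")
    }
    df$expr <- log2(df$expr)
  }
  if (nrow(df) <= ncol(df) + 1L) {
    .tfStop("too few samples for the model", "tagfun_size_error")
  }
  fit <- lm(expr ~ ., data = df)
  rss <- sum(residuals(fit)^2)
  sm <- summary(fit)$coefficients
  degenerate <- rss < 1e-12 || !is.finite(sm["dose", "Std. Error"]) ||
    sm["dose", "Std. Error"] == 0
  list(beta = unname(coef(fit)["dose"]),
       se = if (degenerate) 0 else sm["dose", "Std. Error"],
       p = if (degenerate) 0 else sm["dose", "Pr(>|t|)"],
       intercept = unname(coef(fit)["(Intercept)"]),
       rss = rss, n = nrow(df), degenerate = degenerate)
}

#' Expression-presence filter
#'
#' Keeps the genes whose expression exceeds `minValue` in strictly more than
#' `minFraction` of samples — the screen applied to candidate TFs before
#' coexpression testing (e.g. RPKM > 0.01 in > 75% of samples).
#'
#' @param values numeric matrix, samples x genes (column names = gene ids).
#' @param minValue expression floor (default 0.01).
#' @param minFraction strict sample-fraction bound (default 0.75).
#' @return character vector of retained gene ids.
#' @export
expressionPresenceFilter <- function(values, minValue = 0.01,
                                     minFraction = 0.75) {
  values <- as.matrix(values)
  if (ncol(values) == 0L || nrow(values) == 0L) return(character())
  frac <- colMeans(values > minValue, na.rm = TRUE)
  colnames(values)[frac > minFraction]
}
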