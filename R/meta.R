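# Fixed-effects inverse-variance meta-analysis, heterogeneity statistics,
# genomic control, and CI <-> SE conversion for printed odds-ratio tables.

#' Recover the log-scale SE from a printed OR and 95% CI
#'
#' \code{se = (ln(hi) - ln(lo)) / (2 z)} with z = 1.959964 at the 0.95 level.
#' Printed Wald CIs are symmetric on the log scale; a CI whose log-midpoint
#' deviates from the printed OR beyond what 2-decimal rounding explains
#' (\code{|ln(or^2 / (lo * hi))| > 0.02}) raises an asymmetry warning, since
#' the recovered SE is then only approximate.
#'
#' @param orPoint point odds ratio.
#' @param ciLo,ciHi confidence-interval bounds (0 < lo <= or <= hi).
#' @param level confidence level (default 0.95).
#' @return standard error on the log-OR scale.
#' @examples
#' seFromCi(1.71, 1.42, 2.05)  # ~ 0.0937
#' @export
seFromCi <- function(orPoint, ciLo, ciHi, level = 0.95) {
  if (any(c(orPoint, ciLo, ciHi) <= 0)) {
    .tfStop("OR and CI bounds must be positive", "tagfun_param_error")
  }
  if (ciLo == ciHi) {
    if (orPoint != ciLo) {
      .tfStop("degenerate CI does not contain the point OR",
              "tagfun_param_error")
    }
    warning("degenerate CI (lo = hi): SE is 0", call. = FALSE)
    return(0)
  }
  if (ciLo > ciHi) .tfStop("ciLo must not exceed ciHi", "tagfun_param_error")
  if (orPoint < ciLo || orPoint > ciHi) {
    .tfStop("point OR lies outside the CI", "tagfun_param_error")
  }
  z <- qnorm(1 - (1 - level) / 2)
  asym <- abs(log(orPoint^2 / (ciLo * ciHi)))
  if (asym > 0.02) {
    warning(sprintf(
      "CI asymmetric on the log scale beyond printed-rounding tolerance (%.3f > 0.02)",
      asym), call. = FALSE)
  }
  (log(ciHi) - log(ciLo)) / (2 * z)
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Combines per-study log-OR estimates with weights \eqn{w_i = 1/se_i^2}:
#' \eqn{\hat\beta = \sum w_i \beta_i / \sum w_i}, \eqn{se = 1/\sqrt{\sum w_i}},
#' two-sided P from the normal.  Heterogeneity is summarised by Cochran's
#' \eqn{Q = \sum w_i (\beta_i - \hat\beta)^2} (chi-square with k - 1 df) and
#' \eqn{I^2 = \max(0, (Q - (k-1))/Q) \times 100} (floored at zero).
#'
#' @param beta per-study effects on the log scale.
#' @param se per-study standard errors (> 0).
#' @param labels optional study labels (unused in the arithmetic).
#' @param exponentiate report `or`/`ci_lo`/`ci_hi` as exp(beta) (default);
#'   set FALSE when the effects are not log odds ratios (e.g. correlation
#'   differences), in which case those columns stay on the raw scale.
#' @return One-row data.frame (a meta record) with columns `k`, `beta`, `se`,
#'   `or`, `ci_lo`, `ci_hi`, `p`, `q`, `q_p`, `i2`.
#' @examples
#' # two studies: combined OR and P
#' fixedEffectsMeta(beta = c(0.53649, 0.55389), se = c(0.09367, 0.10224))
#' @export
fixedEffectsMeta <- function(beta, se, labels = NULL, exponentiate = TRUE) {
  if (length(beta) == 0L) .tfStop("no studies supplied", "tagfun_size_error")
  if (length(beta) != length(se)) {
    .tfStop("beta and se must have equal length", "tagfun_param_error")
  }
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(se <= 0)) {
    .tfStop("all se must be positive and effects finite",
            "tagfun_param_error")
  }
  k <- length(beta)
  w <- 1 / se^2
  betaComb <- sum(w * beta) / sum(w)
  seComb <- 1 / sqrt(sum(w))
  p <- 2 * pnorm(-abs(betaComb / seComb))
  q <- sum(w * (beta - betaComb)^2)
  qP <- if (k > 1L) pchisq(q, df = k - 1L, lower.tail = FALSE) else NA_real_
  i2 <- if (q > 0) max(0, (q - (k - 1L)) / q) * 100 else 0
  lo <- betaComb - .Z95 * seComb
  hi <- betaComb + .Z95 * seComb
  tr <- if (exponentiate) exp else identity
  data.frame(k = k, beta = betaComb, se = seComb,
             or = tr(betaComb), ci_lo = tr(lo), ci_hi = tr(hi),
             p = p, q = q, q_p = qP, i2 = i2)
}

#' Genomic-control inflation factor
#'
#' \eqn{\lambda_{GC}} = median association chi-square divided by the null
#' median of the 1-df chi-square distribution (0.45494).  P-value input is
#' converted to 1-df chi-square quantiles first.
#'
#' @param x numeric vector of 1-df chi-square statistics, or of two-sided
#'   P-values with `type = "p"`.
#' @param type `"chisq"` (default) or `"p"`.
#' @return the inflation factor (1 under the null).
#' @examples
#' lambdaGc(simNullChisq(10000, seed = 7))
#' @export
lambdaGc <- function(x, type = c("chisq", "p")) {
  type <- match.arg(type)
  x <- x[!is.na(x)]
  if (length(x) == 0L) .tfStop("no statistics supplied", "tagfun_size_error")
  chi2 <- if (type == "p") qchisq(x, df = 1, lower.tail = FALSE) else x
  if (any(chi2 < 0)) .tfStop("chi-square statistics must be non-negative",
                             "tagfun_param_error")
  median(chi2) / qchisq(0.5, df = 1)
}

#' Exclude meta-analysis records with high heterogeneity
#'
#' Removes records whose I-squared exceeds `i2Max` percent (default 50), the
#' conventional screen for cross-study inconsistency.
#'
#' @param records data.frame of meta records with an `i2` column.
#' @param i2Max maximum tolerated I-squared, in percent.
#' @return list with `records` (retained rows) and `nExcluded`.
#' @export
heterogeneityFilter <- function(records, i2Max = 50) {
  if (!"i2" %in% names(records)) {
    .tfStop("records must have an `i2` column", "tagfun_param_error")
  }
  keep <- records$i2 <= i2Max
  list(records = records[keep, , drop = FALSE], nExcluded = sum(!keep))
}

#' Meta-analyse studies given as printed OR (95% CI) cells
#'
#' Convenience wrapper: converts each study's printed OR and CI bounds to a
#' log-OR and SE via [seFromCi()], then applies [fixedEffectsMeta()].
#'
#' @param or,ciLo,ciHi equal-length vectors of per-study printed values.
#' @param ... passed to [fixedEffectsMeta()].
#' @return a meta record as from [fixedEffectsMeta()].
#' @examples
#' metaFromCi(or = c(1.71, 1.74), ciLo = c(1.42, 1.42), ciHi = c(2.05, 2.12))
#' @export
metaFromCi <- function(or, ciLo, ciHi, ...) {
  se <- mapply(seFromCi, or, ciLo, ciHi)
  fixedEffectsMeta(beta = log(or), se = se, ...)
}
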