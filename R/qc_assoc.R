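# Genotype/sample QC filters and additive allele-dosage association testing.

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square comparing observed genotype counts with
#' the p^2, 2pq, q^2 expectations at the estimated allele frequency.  A
#' monomorphic variant (one allele absent) is returned with p = 1 and a
#' degenerate flag rather than an error, since the test carries no
#' information there.
#'
#' @param nHomEffect,nHet,nHomOther genotype counts (effect-allele
#'   homozygote, heterozygote, other homozygote).
#' @return list with `chi2`, `p` and logical `degenerate`.
#' @examples
#' hweTest(25, 50, 25)   # exact HWE proportions: chi2 = 0
#' hweTest(30, 30, 40)   # chi2 ~ 15.52, p ~ 8.2e-5
#' @export
hweTest <- function(nHomEffect, nHet, nHomOther) {
  counts <- c(nHomEffect, nHet, nHomOther)
  if (any(counts < 0) || any(counts != round(counts))) {
    .tfStop("genotype counts must be non-negative integers",
            "tagfun_param_error")
  }
  n <- sum(counts)
  if (n < 1) .tfStop("total genotype count must be >= 1", "tagfun_size_error")
  p <- (2 * nHomEffect + nHet) / (2 * n)
  if (p == 0 || p == 1) {
    return(list(chi2 = 0, p = 1, degenerate = TRUE))
  }
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' QC threshold set
#'
#' Default thresholds mirror standard pre-imputation GWAS practice: sample
#' call rate > 0.98, sample inbreeding |F| <= 0.05, SNP missingness <= 0.05,
#' MAF >= 0.01, HWE P >= 1e-4, case/control differential-missingness
#' P >= 0.05.  An `infoMin` of 0.3 is applied as a pass-through filter when
#' the variant metadata carries an imputation `info` column.
#'
#' @param mafMin,snpMissingMax,sampleMissingMax,hwePMin,diffMissingPMin,inbreedingFMax,infoMin
#'   the per-rule thresholds.
#' @return named list of thresholds.
#' @export
qcThresholds <- function(mafMin = 0.01, snpMissingMax = 0.05,
                         sampleMissingMax = 0.02, hwePMin = 1e-4,
                         diffMissingPMin = 0.05, inbreedingFMax = 0.05,
                         infoMin = 0.3) {
  th <- list(mafMin = mafMin, snpMissingMax = snpMissingMax,
             sampleMissingMax = sampleMissingMax, hwePMin = hwePMin,
             diffMissingPMin = diffMissingPMin,
             inbreedingFMax = inbreedingFMax, infoMin = infoMin)
  ok <- vapply(th, function(x) is.numeric(x) && length(x) == 1L &&
                 !is.na(x) && x >= 0, logical(1))
  if (!all(ok)) .tfStop("thresholds must be non-negative numbers",
                        "tagfun_param_error")
  th
}

# hard-call a dosage: 0/1/2 at the conventional 0.5/1.5 cut points
.hardCall <- function(dose) {
  g <- ifelse(dose < 0.5, 0L, ifelse(dose < 1.5, 1L, 2L))
  g[is.na(dose)] <- NA_integer_
  g
}

#' Apply sample and variant QC filters
#'
#' Filters are applied in a fixed order, each rule operating on what the
#' previous rules left: (0) imputation info pass-through (only when an `info`
#' column is present), (1) sample call rate, (2) sample inbreeding |F|,
#' (3) SNP missingness, (4) MAF, (5) HWE, (6) case/control differential
#' missingness.  Each exclusion is attributed to the first rule that
#' triggered it.  HWE is computed on hard-called genotypes of all analysed
#' samples (the filter operates pre-analysis).  Inbreeding F per sample is
#' 1 - observed/expected heterozygosity over the variants in hand.
#'
#' @param geno a [GenotypeData-class].
#' @param pheno data.frame with `sample_id` and `status` ("case"/"control"),
#'   aligned to the genotype samples.
#' @param thresholds a [qcThresholds()] list.
#' @return list with `genotypes` (filtered [GenotypeData-class]) and `report`
#'   (per-rule exclusion counts plus the thresholds used).
#' @export
applyQc <- function(geno, pheno, thresholds = qcThresholds()) {
  stopifnot(is(geno, "GenotypeData"))
  dos <- dosageMatrix(geno)
  variants <- variantInfo(geno)
  if (!all(rownames(dos) %in% pheno$sample_id)) {
    .tfStop("every genotyped sample needs a phenotype row",
            "tagfun_param_error")
  }
  status <- .statusToBinary(pheno$status[match(rownames(dos),
                                               pheno$sample_id)])
  report <- list()

  # 0: imputation info pass-through
  if ("info" %in% names(variants)) {
    drop <- which(!is.na(variants$info) & variants$info < thresholds$infoMin)
    report$info <- length(drop)
    if (length(drop)) {
      dos <- dos[, -drop, drop = FALSE]
      variants <- variants[-drop, , drop = FALSE]
    }
  }

  # 1: sample call rate
  sampleMiss <- rowMeans(is.na(dos))
  dropS <- which(sampleMiss > thresholds$sampleMissingMax)
  report$sample_call_rate <- length(dropS)
  if (length(dropS)) {
    dos <- dos[-dropS, , drop = FALSE]
    status <- status[-dropS]
  }

  # 2: sample inbreeding |F| = |1 - obs het / exp het|
  g <- apply(dos, 2L, .hardCall)
  if (is.null(dim(g))) g <- matrix(g, nrow = nrow(dos))
  freq <- colMeans(dos, na.rm = TRUE) / 2
  expHetPer <- 2 * freq * (1 - freq)
  obsHet <- rowMeans(g == 1L, na.rm = TRUE)
  expHet <- apply(!is.na(g), 1L, function(obs) mean(expHetPer[obs]))
  fhat <- 1 - obsHet / expHet
  fhat[!is.finite(fhat)] <- 0
  dropF <- which(abs(fhat) > thresholds$inbreedingFMax)
  report$inbreeding_f <- length(dropF)
  if (length(dropF)) {
    dos <- dos[-dropF, , drop = FALSE]
    g <- g[-dropF, , drop = FALSE]
    status <- status[-dropF]
  }

  # 3: SNP missingness
  snpMiss <- colMeans(is.na(dos))
  drop <- which(snpMiss > thresholds$snpMissingMax)
  report$snp_missingness <- length(drop)
  if (length(drop)) {
    dos <- dos[, -drop, drop = FALSE]
    g <- g[, -drop, drop = FALSE]
    variants <- variants[-drop, , drop = FALSE]
  }

  # 4: MAF
  freq <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  drop <- which(maf < thresholds$mafMin)
  report$maf <- length(drop)
  if (length(drop)) {
    dos <- dos[, -drop, drop = FALSE]
    g <- g[, -drop, drop = FALSE]
    variants <- variants[-drop, , drop = FALSE]
  }

  # 5: HWE on hard calls, all analysed samples
  if (ncol(dos) && nrow(dos)) {
    hweP <- vapply(seq_len(ncol(g)), function(j) {
      tab <- tabulate(g[, j] + 1L, nbins = 3L)
      if (sum(tab) == 0L) return(1)  # fully missing column: no evidence
      hweTest(tab[3L], tab[2L], tab[1L])$p
    }, numeric(1))
    drop <- which(hweP < thresholds$hwePMin)
  } else drop <- integer()
  report$hwe <- length(drop)
  if (length(drop)) {
    dos <- dos[, -drop, drop = FALSE]
    g <- g[, -drop, drop = FALSE]
    variants <- variants[-drop, , drop = FALSE]
  }

  if (nrow(dos) == 0L) {
    warning("all samples removed by QC", call. = FALSE)
  }
  # 6: differential missingness between cases and controls
  if (ncol(dos) && nrow(dos)) {
    diffP <- vapply(seq_len(ncol(dos)), function(j) {
      miss <- is.na(dos[, j])
      if (!any(miss)) return(1)
      a <- sum(miss & status == 1L); b <- sum(!miss & status == 1L)
      c_ <- sum(miss & status == 0L); d <- sum(!miss & status == 0L)
      stat <- .chisq2x2(a, b, c_, d)
      if (is.na(stat)) 1 else pchisq(stat, df = 1, lower.tail = FALSE)
    }, numeric(1))
    drop <- which(diffP < thresholds$diffMissingPMin)
  } else drop <- integer()
  report$differential_missingness <- length(drop)
  if (length(drop)) {
    dos <- dos[, -drop, drop = FALSE]
    variants <- variants[-drop, , drop = FALSE]
  }

  if (ncol(dos) == 0L) {
    warning("all variants removed by QC", call. = FALSE)
  }
  report$n_samples_kept <- nrow(dos)
  report$n_variants_kept <- ncol(dos)
  report$thresholds <- thresholds
  list(genotypes = GenotypeData(dos, variants, sampleIds = rownames(dos)),
       report = report)
}

#' Additive allele-dosage logistic association test
#'
#' Maximum-likelihood logistic regression of case/control status on
#' effect-allele dose, with optional covariates and conditioning dosages
#' entered as additional covariates.  The Wald test on the dose term supplies
#' beta, SE, OR with 95% CI and the two-sided P; the one-sided P is half the
#' two-sided P when beta matches the prespecified direction, else one minus
#' that half.  Samples with a missing dose, status or covariate are dropped
#' complete-case.  Non-convergence or quasi-complete separation is flagged by
#' returning P = NA rather than an error, mirroring how association software
#' reports unfittable models.
#'
#' @param dose numeric vector of effect-allele dosages in [0, 2].
#' @param status case/control labels ("case"/"control", factor, or 0/1).
#' @param covariates optional data.frame/matrix of numeric covariates.
#' @param conditionOn optional named list (or single vector) of dosage
#'   vectors for conditioning SNPs.
#' @param direction prespecified one-sided direction of effect:
#'   `"positive"` (risk, beta > 0, default) or `"negative"`.
#' @param method `"wald"` (default) or `"score"`; the score variant tests the
#'   dose term by a Rao score test at the null fit (beta/SE/CI still from the
#'   Wald fit).
#' @param snpId,effectAllele labels carried into the result record.
#' @return One-row data.frame (an association record) with columns `snp_id`,
#'   `effect_allele`, `beta`, `se`, `or`, `ci_lo`, `ci_hi`, `p`,
#'   `p_one_sided`, `n_case`, `n_control`, `conditioned_on`.
#' @examples
#' set.seed(1)
#' dose <- rbinom(400, 2, 0.3)
#' y <- rbinom(400, 1, plogis(-1 + 0.4 * dose))
#' logisticAssoc(dose, y)
#' @export
logisticAssoc <- function(dose, status, covariates = NULL, conditionOn = NULL,
                          direction = c("positive", "negative"),
                          method = c("wald", "score"),
                          snpId = "snp", effectAllele = NA_character_) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  y <- .statusToBinary(status)
  X <- cbind(dose = as.numeric(dose))
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    X <- cbind(X, covariates)
  }
  if (!is.null(conditionOn)) {
    if (!is.list(conditionOn)) conditionOn <- list(cond1 = conditionOn)
    if (is.null(names(conditionOn)) || any(names(conditionOn) == "")) {
      names(conditionOn) <- paste0("cond", seq_along(conditionOn))
    }
    X <- cbind(X, do.call(cbind, conditionOn))
  }
  keep <- complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  if (length(unique(X[, "dose"])) < 2L) {
    .tfStop("dose is constant among analysed samples",
            "tagfun_degenerate_error")
  }
  nCase <- sum(y == 1L); nControl <- sum(y == 0L)
  if (nCase < 1L || nControl < 1L) {
    .tfStop("need at least one case and one control", "tagfun_size_error")
  }

  fit <- suppressWarnings(
    glm(y ~ ., data = as.data.frame(X), family = binomial(),
        control = list(epsilon = 1e-8, maxit = 25L)))
  sm <- summary(fit)$coefficients
  beta <- sm["dose", "Estimate"]
  se <- sm["dose", "Std. Error"]
  # quasi-complete separation inflates both wildly; flag instead of reporting
  degenerate <- !fit$converged || !is.finite(se) || se > 50 || abs(beta) > 15

  if (method == "score" && !degenerate) {
    nullX <- X[, -1L, drop = FALSE]
    null <- if (ncol(nullX)) {
      suppressWarnings(glm(y ~ ., data = as.data.frame(nullX),
                           family = binomial()))
    } else {
      suppressWarnings(glm(y ~ 1, family = binomial()))
    }
    phat <- fitted(null)
    w <- phat * (1 - phat)
    d <- X[, 1L]
    Z <- cbind(1, X[, -1L, drop = FALSE])
    u <- sum((y - phat) * d)
    dAdj <- d - Z %*% solve(crossprod(Z * sqrt(w)), crossprod(Z * w, d))
    v <- sum(w * d * dAdj)
    pTwo <- pchisq(u^2 / v, df = 1, lower.tail = FALSE)
    zSigned <- sign(u) * sqrt(u^2 / v)
  } else {
    zSigned <- beta / se
    pTwo <- 2 * pnorm(-abs(zSigned))
  }
  if (degenerate) pTwo <- NA_real_
  dirSign <- if (direction == "positive") 1 else -1
  pOne <- if (is.na(pTwo)) NA_real_
          else if (sign(zSigned) == dirSign || zSigned == 0) pTwo / 2
          else 1 - pTwo / 2
  data.frame(
    snp_id = snpId, effect_allele = effectAllele,
    beta = beta, se = se, or = exp(beta),
    ci_lo = exp(beta - .Z95 * se), ci_hi = exp(beta + .Z95 * se),
    p = pTwo, p_one_sided = pOne,
    n_case = nCase, n_control = nControl,
    conditioned_on = if (is.null(conditionOn)) ""
                     else paste(names(conditionOn), collapse = ","),
    stringsAsFactors = FALSE)
}

#' Chi-square test of homogeneity for a 2 x k count table
#'
#' Pearson chi-square with k - 1 degrees of freedom and no continuity
#' correction; the workhorse of the haplotype-resampling null's replicate
#' tag-SNP test.
#'
#' @param tab 2 x k matrix of non-negative counts with positive margins.
#' @return list with `chi2`, `df` and `p`.
#' @examples
#' chisqHomogeneity(rbind(c(30, 70), c(10, 90)))  # chi2 = 12.5
#' @export
chisqHomogeneity <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2L || ncol(tab) < 2L) {
    .tfStop("tab must be a 2 x k table with k >= 2", "tagfun_param_error")
  }
  if (any(tab < 0)) .tfStop("counts must be non-negative",
                            "tagfun_param_error")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    .tfStop("all table margins must be positive", "tagfun_degenerate_error")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - expected)^2 / expected)
  df <- ncol(tab) - 1L
  list(chi2 = chi2, df = df, p = pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Analytic power of the allelic case-control comparison
#'
#' Normal approximation on the log odds ratio of the allelic 2 x 2 table,
#' with the variance evaluated at the expected allele counts under the
#' alternative: control allele frequency `maf`, case frequency derived from
#' the odds ratio.  At OR = 1 the one-sided power equals the nominal level.
#'
#' @param oddsRatio allelic odds ratio (> 0).
#' @param maf control effect-allele frequency in (0, 1).
#' @param nCase,nControl numbers of cases and controls.
#' @param alpha significance level in (0, 1).
#' @param sided `"one"` or `"two"`.
#' @return power in [0, 1].
#' @examples
#' allelicPower(1.5, maf = 0.2, nCase = 200, nControl = 1400, alpha = 0.05)
#' @export
allelicPower <- function(oddsRatio, maf, nCase, nControl, alpha = 0.05,
                         sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (!is.numeric(oddsRatio) || oddsRatio <= 0) {
    .tfStop("oddsRatio must be positive", "tagfun_param_error")
  }
  .checkProb(maf, "maf")
  .checkProb(alpha, "alpha")
  if (nCase < 1 || nControl < 1) {
    .tfStop("nCase and nControl must be positive", "tagfun_size_error")
  }
  p0 <- maf
  odds1 <- oddsRatio * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  lor <- log(oddsRatio)
  sdAlt <- sqrt(1 / (2 * nCase * p1 * (1 - p1)) +
                1 / (2 * nControl * p0 * (1 - p0)))
  if (sided == "one") {
    pnorm(abs(lor) / sdAlt - qnorm(1 - alpha))
  } else {
    zc <- qnorm(1 - alpha / 2)
    pnorm(abs(lor) / sdAlt - zc) + pnorm(-abs(lor) / sdAlt - zc)
  }
}
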