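# Synthetic-data generators: every input the pipeline assumes can be built
# here, so all downstream stages run without any cohort download.

#' Simulate a two-variant phased haplotype panel with target LD
#'
#' Solves the two-locus haplotype frequencies for given marginal effect-allele
#' frequencies and a target r-squared, then draws haplotypes multinomially.
#' With positive coupling (the default) the effect alleles co-occur:
#' \eqn{p_{AB} = p_A p_B + D} with
#' \eqn{D = \pm\sqrt{r^2 p_A(1-p_A) p_B(1-p_B)}}.
#'
#' @param freqA,freqB effect-allele frequencies of the two variants, in (0,1).
#' @param r2Target target r-squared in [0, 1]; must be attainable for the
#'   marginals (D is bounded by the smaller of the off-coupling products).
#' @param nHap number of haplotypes to draw (>= 4; even for diploids).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param dSign `"positive"` (risk alleles positively coupled, default) or
#'   `"negative"`.
#' @param ids,chrom,pos variant metadata for the two loci.
#' @return A [HaplotypePanel-class] with two variants.
#' @examples
#' panel <- simHaplotypePanel(0.5, 0.5, 1, nHap = 100, seed = 1)
#' unique(apply(alleleMatrix(panel), 1, paste, collapse = ""))  # "11" and "00"
#' @export
simHaplotypePanel <- function(freqA, freqB, r2Target, nHap, seed,
                              dSign = c("positive", "negative"),
                              ids = c("snpA", "snpB"), chrom = "1",
                              pos = c(1000L, 2000L)) {
  dSign <- match.arg(dSign)
  .checkProb(freqA, "freqA")
  .checkProb(freqB, "freqB")
  .checkProb(r2Target, "r2Target", open = FALSE)
  if (nHap < 4) .tfStop("nHap must be at least 4", "tagfun_size_error")

  qA <- 1 - freqA; qB <- 1 - freqB
  denom <- freqA * qA * freqB * qB
  dMax <- if (dSign == "positive") min(freqA * qB, qA * freqB)
          else min(freqA * freqB, qA * qB)
  r2Max <- dMax^2 / denom
  if (r2Target > r2Max + 1e-12) {
    .tfStop(sprintf(
      "r2Target %.3g infeasible for frequencies (%.3g, %.3g): attainable maximum is %.4g",
      r2Target, freqA, freqB, r2Max), "tagfun_feasibility_error")
  }
  d <- sqrt(r2Target * denom) * if (dSign == "positive") 1 else -1
  hfreq <- c(`11` = freqA * freqB + d, `10` = freqA * qB - d,
             `01` = qA * freqB - d, `00` = qA * qB + d)
  hfreq <- pmax(hfreq, 0)  # clip the ~1e-17 negatives at the feasibility edge
  hfreq <- hfreq / sum(hfreq)

  counts <- .withSeed(seed, as.vector(rmultinom(1L, nHap, hfreq)))
  hapTypes <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  alleles <- hapTypes[rep.int(seq_len(4L), counts), , drop = FALSE]
  variants <- data.frame(
    id = ids, chrom = chrom, pos = as.integer(pos),
    effect_allele = c("A", "A"), other_allele = c("G", "G"),
    stringsAsFactors = FALSE)
  HaplotypePanel(alleles, variants)
}

#' Simulate case-control genotypes under an additive log-odds model
#'
#' Retrospective sampling: individuals are formed from two random haplotypes
#' (or from Hardy-Weinberg genotypes when only an allele frequency is given),
#' disease status is drawn from
#' \eqn{\mathrm{logit}\,P(\mathrm{case}) = \alpha + \ln(\mathrm{OR}) \cdot
#' \mathrm{dose}} with \eqn{\alpha} set so the baseline (dose 0) prevalence
#' equals `prevalence`, and sampling continues until the requested case and
#' control counts are reached (rejection sampling from the population model).
#'
#' @param panel a [HaplotypePanel-class]; the `causal` variant carries the
#'   effect.  Alternatively `NULL` with `maf` given for a single-variant
#'   Hardy-Weinberg population.
#' @param oddsRatio per-allele odds ratio (> 0).
#' @param nCase,nControl requested counts; their sum must be positive.
#' @param seed integer seed.
#' @param maf effect-allele frequency when no panel is supplied.
#' @param causal id or index of the causal variant in the panel (default 1).
#' @param prevalence baseline (zero-dose) disease prevalence (default 0.10).
#' @return list with `genotypes` ([GenotypeData-class], cases first) and
#'   `phenotypes` (data.frame of `sample_id`, `status`).
#' @examples
#' cc <- simCaseControl(oddsRatio = 1.5, nCase = 100, nControl = 100,
#'                      seed = 1, maf = 0.3)
#' table(cc$phenotypes$status)
#' @export
simCaseControl <- function(panel = NULL, oddsRatio, nCase, nControl, seed,
                           maf = NULL, causal = 1L, prevalence = 0.10) {
  if (!is.numeric(oddsRatio) || oddsRatio <= 0) {
    .tfStop("oddsRatio must be positive", "tagfun_param_error")
  }
  nCase <- as.integer(nCase); nControl <- as.integer(nControl)
  if (nCase < 0 || nControl < 0 || nCase + nControl == 0) {
    .tfStop("nCase + nControl must be positive", "tagfun_size_error")
  }
  .checkProb(prevalence, "prevalence")
  if (is.null(panel) && is.null(maf)) {
    .tfStop("supply a panel or a maf", "tagfun_param_error")
  }
  if (!is.null(panel)) {
    stopifnot(is(panel, "HaplotypePanel"))
    hap <- alleleMatrix(panel)
    variants <- variantInfo(panel)
    causalIdx <- if (is.character(causal)) match(causal, variants$id)
                 else as.integer(causal)
    if (is.na(causalIdx) || causalIdx < 1 || causalIdx > ncol(hap)) {
      .tfStop("causal variant not found in panel", "tagfun_param_error")
    }
  } else {
    .checkProb(maf, "maf")
    variants <- data.frame(id = "snp1", chrom = "1", pos = 1000L,
                           effect_allele = "A", other_allele = "G",
                           stringsAsFactors = FALSE)
    causalIdx <- 1L
  }
  alpha <- qlogis(prevalence)
  lor <- log(oddsRatio)

  .withSeed(seed, {
    caseRows <- list(); controlRows <- list()
    gotCase <- 0L; gotControl <- 0L
    # expected case fraction governs the batch size needed to fill both quotas
    batch <- max(1000L, 2L * (nCase + nControl))
    for (iter in seq_len(10000L)) {
      if (gotCase >= nCase && gotControl >= nControl) break
      if (!is.null(panel)) {
        i1 <- sample.int(nrow(hap), batch, replace = TRUE)
        i2 <- sample.int(nrow(hap), batch, replace = TRUE)
        g <- hap[i1, , drop = FALSE] + hap[i2, , drop = FALSE]
      } else {
        g <- matrix(rbinom(batch, 2L, maf), ncol = 1L)
      }
      dose <- g[, causalIdx]
      y <- rbinom(batch, 1L, plogis(alpha + lor * dose))
      if (gotCase < nCase) {
        take <- which(y == 1L)[seq_len(min(nCase - gotCase, sum(y == 1L)))]
        if (length(take)) {
          caseRows[[length(caseRows) + 1L]] <- g[take, , drop = FALSE]
          gotCase <- gotCase + length(take)
        }
      }
      if (gotControl < nControl) {
        take <- which(y == 0L)[seq_len(min(nControl - gotControl,
                                           sum(y == 0L)))]
        if (length(take)) {
          controlRows[[length(controlRows) + 1L]] <- g[take, , drop = FALSE]
          gotControl <- gotControl + length(take)
        }
      }
    }
    if (gotCase < nCase || gotControl < nControl) {
      .tfStop("case/control quotas not reached; check parameters",
              "tagfun_size_error")
    }
    dos <- rbind(do.call(rbind, caseRows), do.call(rbind, controlRows))
    status <- c(rep("case", nCase), rep("control", nControl))
    ids <- sprintf("ind%05d", seq_len(nrow(dos)))
    list(
      genotypes = GenotypeData(dos, variants, sampleIds = ids),
      phenotypes = data.frame(sample_id = ids, status = status,
                              stringsAsFactors = FALSE))
  })
}

#' Simulate genotype-class-dependent coexpression data
#'
#' Within each genotype class, draws (TF, target) expression pairs from a
#' bivariate normal with the requested Pearson correlation and unit marginal
#' variances — the structure of a transcription factor whose coupling to its
#' target differs between carriers and non-carriers of a regulatory allele.
#'
#' @param genotypeClass vector of 0/1 class labels, one per sample.
#' @param rClass0,rClass1 target Pearson correlations per class, in [-1, 1].
#' @param seed integer seed.
#' @return list with numeric vectors `tf` and `target` (same order as
#'   `genotypeClass`).
#' @examples
#' cls <- rep(c(0, 1), c(300, 58))
#' xy <- simExpression(cls, rClass0 = 0.24, rClass1 = 0.15, seed = 1)
#' cor(xy$tf[cls == 0], xy$target[cls == 0])
#' @export
simExpression <- function(genotypeClass, rClass0, rClass1, seed) {
  if (any(!genotypeClass %in% c(0, 1))) {
    .tfStop("genotypeClass must contain only 0/1", "tagfun_param_error")
  }
  for (r in c(rClass0, rClass1)) {
    if (!is.numeric(r) || length(r) != 1L || is.na(r) || abs(r) > 1) {
      .tfStop("class correlations must lie in [-1, 1]", "tagfun_param_error")
    }
  }
  n <- length(genotypeClass)
  .withSeed(seed, {
    tf <- numeric(n); target <- numeric(n)
    for (cls in c(0, 1)) {
      idx <- which(genotypeClass == cls)
      if (!length(idx)) next
      r <- if (cls == 0) rClass0 else rClass1
      x <- rnorm(length(idx))
      y <- r * x + sqrt(1 - r^2) * rnorm(length(idx))
      tf[idx] <- x; target[idx] <- y
    }
    list(tf = tf, target = target)
  })
}

#' Simulate null 1-df chi-square association statistics
#'
#' I.i.d. chi-square(1) draws, the null input for genomic-control estimation.
#'
#' @param nSnps number of statistics (>= 1).
#' @param seed integer seed.
#' @return numeric vector of length `nSnps`.
#' @examples
#' lambdaGc(simNullChisq(10000, seed = 1))
#' @export
simNullChisq <- function(nSnps, seed) {
  if (nSnps < 1) .tfStop("nSnps must be at least 1", "tagfun_size_error")
  .withSeed(seed, rchisq(as.integer(nSnps), df = 1))
}
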