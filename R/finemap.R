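# Trans-ethnic fine-mapping utilities: LD statistics, the constrained
# haplotype-resampling null for tag-SNP consistency, and the cross-ancestry
# prioritization filter.

.panelColumn <- function(panel, id) {
  idx <- match(id, variantInfo(panel)$id)
  if (is.na(idx)) {
    .tfStop(sprintf("variant '%s' not in panel", id), "tagfun_param_error")
  }
  alleleMatrix(panel)[, idx]
}

#' Two-locus linkage disequilibrium from phased haplotypes
#'
#' Computes r-squared and D' from the phased haplotype counts of two
#' variants: \eqn{D = p_{AB} - p_A p_B},
#' \eqn{r^2 = D^2 / (p_A(1-p_A) p_B(1-p_B))}, and D' normalised by the
#' allele-frequency bound \eqn{D_{max}}.
#'
#' @param panel a [HaplotypePanel-class].
#' @param snpA,snpB variant ids; both must be polymorphic in the panel.
#' @return list with `r2`, `d_prime`, `d`, `haplotype_counts` (2 x 2 table,
#'   rows = snpA allele 1/0, cols = snpB allele 1/0), `freq_a`, `freq_b`.
#' @examples
#' panel <- simHaplotypePanel(0.3, 0.3, 0.6, nHap = 5000, seed = 2)
#' ldR2(panel, "snpA", "snpB")$r2
#' @export
ldR2 <- function(panel, snpA, snpB) {
  a <- .panelColumn(panel, snpA)
  b <- .panelColumn(panel, snpB)
  pA <- mean(a); pB <- mean(b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    .tfStop("both variants must be polymorphic in the panel",
            "tagfun_degenerate_error")
  }
  counts <- matrix(c(sum(a == 1 & b == 1), sum(a == 1 & b == 0),
                     sum(a == 0 & b == 1), sum(a == 0 & b == 0)),
                   nrow = 2L, byrow = TRUE,
                   dimnames = list(c("a1", "a0"), c("b1", "b0")))
  pAB <- counts[1L, 1L] / length(a)
  d <- pAB - pA * pB
  r2 <- d^2 / (pA * (1 - pA) * pB * (1 - pB))
  dMax <- if (d >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dPrime <- if (dMax == 0) 0 else d / dMax
  list(r2 = r2, d_prime = dPrime, d = d, haplotype_counts = counts,
       freq_a = pA, freq_b = pB)
}

#' Select variants tagged by an index SNP
#'
#' Returns the index SNP plus every polymorphic panel variant whose
#' r-squared with the index exceeds `r2Min` — the LD screen used to define a
#' tagged risk locus.  Monomorphic non-index variants are skipped.
#'
#' @param panel a [HaplotypePanel-class].
#' @param indexSnp id of the index variant (must be polymorphic).
#' @param r2Min strict lower r-squared bound (default 0.6).
#' @return character vector of variant ids (index first).
#' @export
selectTagged <- function(panel, indexSnp, r2Min = 0.6) {
  idx <- .panelColumn(panel, indexSnp)
  if (mean(idx) %in% c(0, 1)) {
    .tfStop("index SNP is monomorphic in the panel",
            "tagfun_degenerate_error")
  }
  others <- setdiff(variantInfo(panel)$id, indexSnp)
  hit <- vapply(others, function(id) {
    f <- mean(.panelColumn(panel, id))
    if (f %in% c(0, 1)) return(FALSE)
    ldR2(panel, indexSnp, id)$r2 > r2Min
  }, logical(1))
  c(indexSnp, others[hit])
}

# replicate tag-SNP P from allele-count 2x2 tables, vectorised; a zero margin
# (e.g. no tag alleles drawn at all) carries no evidence and maps to P = 1
.alleleTableP <- function(caseAlt, nCase, controlAlt, nControl) {
  stat <- .chisq2x2(caseAlt, 2 * nCase - caseAlt,
                    controlAlt, 2 * nControl - controlAlt)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  p[is.na(p)] <- 1
  p
}

# genotype-count 2x3 chi-square per replicate (rows case/control, cols 0/1/2)
.genotypeTableP <- function(caseG, controlG) {
  tab <- rbind(caseG, controlG)
  if (any(colSums(tab) == 0)) {
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
  }
  if (ncol(tab) < 2L) return(1)
  chisqHomogeneity(tab)$p
}

#' Constrained haplotype-resampling null for tag-SNP consistency
#'
#' Tests whether observing a non-significant tag SNP alongside a significant
#' causal candidate is consistent with a panel's LD structure.  Each
#' replicate rebuilds the case-control sample by drawing, for every
#' individual, two haplotypes from the panel conditional on the causal-SNP
#' alleles implied by that individual's assigned causal genotype — so the
#' causal genotype counts match the input exactly in every replicate, and the
#' tag SNP's alleles ride along on the sampled haplotypes.  The replicate tag
#' P comes from the chi-square test of homogeneity on the tag allele-count
#' 2 x 2 table (or the genotype 2 x 3 table with `tagTable = "genotype"`),
#' and the report records the fraction of replicates whose tag P is strictly
#' less significant (greater) than the observed one.
#'
#' Haplotypes are drawn with replacement within each causal-allele stratum by
#' default: strict without-replacement sampling is infeasible whenever the
#' design needs more haplotypes than the panel holds, while conditional
#' sampling preserves the matching constraint that defines the null.  Set
#' `withoutReplacement = TRUE` for small designs.
#'
#' @param panel a [HaplotypePanel-class] containing `causal` and `tag`.
#' @param causal,tag variant ids.
#' @param caseGenotypeCounts,controlGenotypeCounts length-3 integer vectors
#'   (n0, n1, n2) of causal-SNP genotype counts among cases and controls.
#' @param observedTagP observed tag-SNP association P-value.
#' @param b number of replicates (>= 1).
#' @param seed integer seed.
#' @param withoutReplacement draw haplotypes without replacement (errors if
#'   a stratum is exhausted).
#' @param tagTable `"allele"` (2 x 2, default) or `"genotype"` (2 x 3).
#' @return A `SimReport`: list with `b`, `observed_tag_p`,
#'   `frac_less_significant`, `replicate_p`, `seed`.
#' @examples
#' panel <- simHaplotypePanel(0.35, 0.4, 0.6, nHap = 400, seed = 3)
#' constrainedResampleSim(panel, "snpA", "snpB",
#'   caseGenotypeCounts = c(90, 90, 23),
#'   controlGenotypeCounts = c(820, 470, 73),
#'   observedTagP = 0.4, b = 200, seed = 4)
#' @export
constrainedResampleSim <- function(panel, causal, tag,
                                   caseGenotypeCounts, controlGenotypeCounts,
                                   observedTagP, b, seed,
                                   withoutReplacement = FALSE,
                                   tagTable = c("allele", "genotype")) {
  tagTable <- match.arg(tagTable)
  b <- as.integer(b)
  if (b < 1L) .tfStop("b must be at least 1", "tagfun_size_error")
  .checkProb(observedTagP, "observedTagP", open = FALSE)
  cc <- as.integer(caseGenotypeCounts)
  kk <- as.integer(controlGenotypeCounts)
  if (length(cc) != 3L || length(kk) != 3L || any(c(cc, kk) < 0)) {
    .tfStop("genotype counts must be length-3 non-negative (n0, n1, n2)",
            "tagfun_param_error")
  }
  causalAll <- .panelColumn(panel, causal)
  tagAll <- .panelColumn(panel, tag)
  if (mean(causalAll) %in% c(0, 1) || mean(tagAll) %in% c(0, 1)) {
    .tfStop("causal and tag must be polymorphic in the panel",
            "tagfun_degenerate_error")
  }
  # stratify the panel by causal allele; tag alleles ride along
  strat0 <- tagAll[causalAll == 0]
  strat1 <- tagAll[causalAll == 1]
  m0 <- length(strat0); m1 <- length(strat1)
  needs0 <- any(c(cc[1L], cc[2L], kk[1L], kk[2L]) > 0)
  needs1 <- any(c(cc[2L], cc[3L], kk[2L], kk[3L]) > 0)
  if ((needs0 && m0 == 0L) || (needs1 && m1 == 0L)) {
    .tfStop("a required causal-allele stratum is empty in the panel",
            "tagfun_feasibility_error")
  }
  nCase <- sum(cc); nControl <- sum(kk)
  # draws per replicate from each stratum, per group; the causal genotype
  # counts are reproduced exactly by construction — assert the bookkeeping
  caseDraw0 <- 2L * cc[1L] + cc[2L]; caseDraw1 <- cc[2L] + 2L * cc[3L]
  ctrlDraw0 <- 2L * kk[1L] + kk[2L]; ctrlDraw1 <- kk[2L] + 2L * kk[3L]
  stopifnot(caseDraw0 + caseDraw1 == 2L * nCase,
            ctrlDraw0 + ctrlDraw1 == 2L * nControl)
  if (withoutReplacement &&
      (caseDraw0 + ctrlDraw0 > m0 || caseDraw1 + ctrlDraw1 > m1)) {
    .tfStop(paste("without-replacement sampling needs more haplotypes than",
                  "the panel provides in a causal-allele stratum"),
            "tagfun_feasibility_error")
  }
  k0 <- sum(strat0); k1 <- sum(strat1)  # tag effect-allele counts per stratum
  f0 <- if (m0) k0 / m0 else 0
  f1 <- if (m1) k1 / m1 else 0

  repP <- .withSeed(seed, {
    if (tagTable == "allele") {
      if (withoutReplacement) {
        tot0 <- rhyper(b, k0, m0 - k0, caseDraw0 + ctrlDraw0)
        tot1 <- rhyper(b, k1, m1 - k1, caseDraw1 + ctrlDraw1)
        caseAlt0 <- rhyper(b, tot0, caseDraw0 + ctrlDraw0 - tot0, caseDraw0)
        caseAlt1 <- rhyper(b, tot1, caseDraw1 + ctrlDraw1 - tot1, caseDraw1)
        ctrlAlt0 <- tot0 - caseAlt0
        ctrlAlt1 <- tot1 - caseAlt1
      } else {
        caseAlt0 <- rbinom(b, caseDraw0, f0)
        caseAlt1 <- rbinom(b, caseDraw1, f1)
        ctrlAlt0 <- rbinom(b, ctrlDraw0, f0)
        ctrlAlt1 <- rbinom(b, ctrlDraw1, f1)
      }
      .alleleTableP(caseAlt0 + caseAlt1, nCase, ctrlAlt0 + ctrlAlt1, nControl)
    } else {
      # per-individual tag genotype distribution given the causal genotype
      pg <- function(fA, fB) c((1 - fA) * (1 - fB),
                               fA * (1 - fB) + (1 - fA) * fB, fA * fB)
      p00 <- pg(f0, f0); p01 <- pg(f0, f1); p11 <- pg(f1, f1)
      drawG <- function(n0, n1, n2) {
        g <- integer(3L)
        if (n0) g <- g + rmultinom(1L, n0, p00)[, 1L]
        if (n1) g <- g + rmultinom(1L, n1, p01)[, 1L]
        if (n2) g <- g + rmultinom(1L, n2, p11)[, 1L]
        g
      }
      vapply(seq_len(b), function(i) {
        caseG <- drawG(cc[1L], cc[2L], cc[3L])
        ctrlG <- drawG(kk[1L], kk[2L], kk[3L])
        stopifnot(sum(caseG) == nCase, sum(ctrlG) == nControl)
        .genotypeTableP(caseG, ctrlG)
      }, numeric(1))
    }
  })
  out <- list(b = b, observed_tag_p = observedTagP,
              frac_less_significant = mean(repP > observedTagP),
              replicate_p = repP, seed = seed,
              tag_table = tagTable,
              without_replacement = withoutReplacement)
  class(out) <- "SimReport"
  out
}

#' @export
print.SimReport <- function(x, ...) {
  cat(sprintf("Constrained haplotype-resampling null (%d replicates, seed %s)\n",
              x$b, format(x$seed)))
  cat(sprintf("  observed tag P: %.3g\n", x$observed_tag_p))
  cat(sprintf("  replicates with tag P less significant: %.1f%%\n",
              100 * x$frac_less_significant))
  invisible(x)
}

#' Cross-ancestry prioritization of candidate variants
#'
#' Keeps the variants whose one-sided association P falls below `alpha` in
#' every supplied population, optionally also requiring a concordant risk
#' allele (or, when explicit risk-allele columns are absent, a concordant
#' odds-ratio direction) across populations and with the discovery set.
#'
#' @param assocTables named list of per-population data.frames; each needs a
#'   `snp_id` column and a P column (`p_one_sided`, or `p` as fallback);
#'   optional `risk_allele` and `or` columns feed the concordance check.
#' @param alpha significance threshold (default 0.05).
#' @param requireSameRiskAllele enforce allele/direction concordance
#'   (default TRUE).
#' @param discovery optional discovery-set data.frame (same columns) used as
#'   the concordance reference.
#' @return character vector of validated variant ids.
#' @export
prioritizeCrossAncestry <- function(assocTables, alpha = 0.05,
                                    requireSameRiskAllele = TRUE,
                                    discovery = NULL) {
  if (!length(assocTables)) {
    .tfStop("no population tables supplied", "tagfun_size_error")
  }
  getP <- function(df) {
    if ("p_one_sided" %in% names(df)) df$p_one_sided else df$p
  }
  shared <- Reduce(intersect, lapply(assocTables, function(df) df$snp_id))
  pass <- vapply(shared, function(id) {
    all(vapply(assocTables, function(df) {
      p <- getP(df)[match(id, df$snp_id)]
      !is.na(p) && p < alpha
    }, logical(1)))
  }, logical(1))
  ids <- shared[pass]
  if (requireSameRiskAllele && length(ids)) {
    ref <- if (!is.null(discovery)) c(list(discovery = discovery),
                                      assocTables) else assocTables
    conc <- vapply(ids, function(id) {
      alleles <- unlist(lapply(ref, function(df) {
        if ("risk_allele" %in% names(df)) df$risk_allele[match(id, df$snp_id)]
      }))
      if (length(alleles) > 1L && !anyNA(alleles)) {
        return(length(unique(alleles)) == 1L)
      }
      dirs <- unlist(lapply(ref, function(df) {
        if ("or" %in% names(df)) sign(log(df$or[match(id, df$snp_id)]))
      }))
      if (length(dirs) > 1L && !anyNA(dirs)) {
        return(length(unique(dirs)) == 1L)
      }
      TRUE  # nothing to compare against
    }, logical(1))
    ids <- ids[conc]
  }
  ids
}
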