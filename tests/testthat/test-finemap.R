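# LD statistics, tagged-SNP selection, the constrained resampling null,
# and cross-ancestry prioritization.

test_that("r2 and D' from haplotype counts match hand values", {
  # counts (AB, Ab, aB, ab) = (40, 10, 10, 40): D = 0.15, denom 0.25 * 0.25
  ld <- ldR2(panelFromCounts(40, 10, 10, 40), "snpA", "snpB")
  expect_equal(ld$r2, 0.36, tolerance = 1e-12)
  expect_equal(ld$d, 0.15, tolerance = 1e-12)
  perfect <- ldR2(panelFromCounts(50, 0, 0, 50), "snpA", "snpB")
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$d_prime, 1)
  # duplicated variant column: self-LD
  dup <- HaplotypePanel(
    cbind(rep(c(1, 0), c(30, 70)), rep(c(1, 0), c(30, 70))),
    data.frame(id = c("x", "xcopy"), chrom = "1", pos = c(1L, 2L),
               effect_allele = "A", other_allele = "G"))
  self <- ldR2(dup, "x", "xcopy")
  expect_equal(self$r2, 1)
  expect_equal(self$d_prime, 1)
  expect_error(ldR2(panelFromCounts(50, 50, 0, 0), "snpA", "snpB"),
               class = "tagfun_degenerate_error")
})

test_that("r2 equals the squared Pearson correlation of allele columns", {
  set.seed(51)
  for (i in 1:1000) {
    counts <- as.vector(rmultinom(1, sample(20:200, 1), runif(4, 0.05, 1)))
    panel <- panelFromCounts(counts[1], counts[2], counts[3], counts[4])
    a <- alleleMatrix(panel)
    if (length(unique(a[, 1])) < 2 || length(unique(a[, 2])) < 2) next
    expect_equal(ldR2(panel, "snpA", "snpB")$r2,
                 cor(a[, 1], a[, 2])^2, tolerance = 1e-12)
  }
})

test_that("tagged-SNP selection applies the strict r2 threshold", {
  hi <- simHaplotypePanel(0.4, 0.4, 0.70, nHap = 50000, seed = 52)
  lo <- simHaplotypePanel(0.4, 0.4, 0.20, nHap = 50000, seed = 53)
  alleles <- cbind(alleleMatrix(hi),
                   alleleMatrix(lo)[, 2L])
  panel <- HaplotypePanel(alleles, data.frame(
    id = c("index", "tight", "loose"), chrom = "1", pos = c(1L, 2L, 3L),
    effect_allele = "A", other_allele = "G"))
  expect_setequal(selectTagged(panel, "index", r2Min = 0.6),
                  c("index", "tight"))
  expect_setequal(selectTagged(panel, "index", r2Min = 0),
                  c("index", "tight", "loose"))
  mono <- HaplotypePanel(cbind(rep(1, 10), rep(c(0, 1), 5)),
                         data.frame(id = c("m", "x"), chrom = "1",
                                    pos = c(1L, 2L), effect_allele = "A",
                                    other_allele = "G"))
  expect_error(selectTagged(mono, "m"), class = "tagfun_degenerate_error")
})

test_that("perfect LD collapses the resampling null to the causal test", {
  panel <- panelFromCounts(60, 0, 0, 140)
  rep <- constrainedResampleSim(
    panel, "snpA", "snpB",
    caseGenotypeCounts = c(40, 40, 20), controlGenotypeCounts = c(70, 25, 5),
    observedTagP = 0.5, b = 500, seed = 61)
  expect_equal(length(unique(rep$replicate_p)), 1L)
  expect_true(rep$frac_less_significant %in% c(0, 1))
})

test_that("vectorised sampler agrees with a per-individual re-implementation", {
  # independent oracle: draw each individual's two haplotypes explicitly
  oracleSim <- function(panel, cc, kk, obsP, b, seed) {
    a <- alleleMatrix(panel)
    s0 <- a[a[, 1] == 0, 2]; s1 <- a[a[, 1] == 1, 2]
    set.seed(seed)
    fracGreater <- 0L
    for (r in seq_len(b)) {
      drawGroup <- function(g) {
        alt <- sum(sample(s0, 2 * g[1] + g[2], replace = TRUE)) +
               sum(sample(s1, g[2] + 2 * g[3], replace = TRUE))
        alt
      }
      caseAlt <- drawGroup(cc); ctrlAlt <- drawGroup(kk)
      tab <- rbind(c(caseAlt, 2 * sum(cc) - caseAlt),
                   c(ctrlAlt, 2 * sum(kk) - ctrlAlt))
      p <- if (any(colSums(tab) == 0)) 1 else
        suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
      if (p > obsP) fracGreater <- fracGreater + 1L
    }
    fracGreater / b
  }
  panel <- panelFromCounts(6, 3, 4, 7)    # 20-haplotype panel
  cc <- c(15, 10, 5); kk <- c(30, 15, 5)
  b <- 5000
  ours <- constrainedResampleSim(panel, "snpA", "snpB", cc, kk,
                                 observedTagP = 0.3, b = b, seed = 62)
  theirs <- oracleSim(panel, cc, kk, 0.3, b, seed = 63)
  pbar <- (ours$frac_less_significant + theirs) / 2
  tol <- 3 * sqrt(pbar * (1 - pbar) * 2 / b)
  expect_lt(abs(ours$frac_less_significant - theirs), tol)
})

test_that("genotype-table mode and without-replacement bounds behave", {
  panel <- panelFromCounts(30, 10, 10, 50)
  gt <- constrainedResampleSim(panel, "snpA", "snpB",
                               caseGenotypeCounts = c(5, 4, 1),
                               controlGenotypeCounts = c(10, 8, 2),
                               observedTagP = 0.5, b = 50, seed = 64,
                               tagTable = "genotype")
  expect_length(gt$replicate_p, 50)
  expect_true(all(gt$replicate_p > 0 & gt$replicate_p <= 1))
  # without replacement: the design must fit inside the panel strata
  expect_error(constrainedResampleSim(panel, "snpA", "snpB",
                                      caseGenotypeCounts = c(50, 40, 10),
                                      controlGenotypeCounts = c(100, 80, 20),
                                      observedTagP = 0.5, b = 10, seed = 65,
                                      withoutReplacement = TRUE),
               class = "tagfun_feasibility_error")
  small <- constrainedResampleSim(panel, "snpA", "snpB",
                                  caseGenotypeCounts = c(3, 2, 1),
                                  controlGenotypeCounts = c(5, 3, 2),
                                  observedTagP = 0.5, b = 50, seed = 66,
                                  withoutReplacement = TRUE)
  expect_length(small$replicate_p, 50)
})

test_that("cross-ancestry prioritization recovers the single validated SNP", {
  t2 <- loadTable2()
  tables <- list(
    HA = data.frame(snp_id = t2$snp_id, p_one_sided = t2$ha_p, or = t2$ha_or),
    AA = data.frame(snp_id = t2$snp_id, p_one_sided = t2$aa_p, or = t2$aa_or))
  expect_identical(prioritizeCrossAncestry(tables, alpha = 0.05), "rs662463")
  expect_setequal(prioritizeCrossAncestry(tables, alpha = 1), t2$snp_id)
  expect_error(prioritizeCrossAncestry(list()), class = "tagfun_size_error")
})

test_that("discordant risk alleles are excluded when the flag is set", {
  popA <- data.frame(snp_id = c("s1", "s2"), p_one_sided = c(0.01, 0.01),
                     risk_allele = c("A", "A"))
  popB <- data.frame(snp_id = c("s1", "s2"), p_one_sided = c(0.02, 0.02),
                     risk_allele = c("A", "G"))
  expect_identical(prioritizeCrossAncestry(list(a = popA, b = popB)), "s1")
  expect_setequal(prioritizeCrossAncestry(list(a = popA, b = popB),
                                          requireSameRiskAllele = FALSE),
                  c("s1", "s2"))
})
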