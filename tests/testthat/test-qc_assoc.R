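# QC filters, HWE, logistic dosage association, homogeneity test, power.

test_that("HWE chi-square matches hand values and flags monomorphics", {
  exact <- hweTest(25, 50, 25)
  expect_equal(exact$chi2, 0)
  expect_equal(exact$p, 1)
  # hand computation: p-hat = 0.45, expected 20.25 / 49.5 / 30.25
  h <- hweTest(30, 30, 40)
  oracle <- sum((c(30, 30, 40) - 100 * c(0.45^2, 2 * 0.45 * 0.55, 0.55^2))^2 /
                (100 * c(0.45^2, 2 * 0.45 * 0.55, 0.55^2)))
  expect_equal(h$chi2, oracle, tolerance = 1e-12)
  expect_equal(h$chi2, 15.52, tolerance = 1e-3)
  expect_equal(h$p, 8.2e-5, tolerance = 0.01)
  mono <- hweTest(100, 0, 0)
  expect_equal(mono$p, 1)
  expect_true(mono$degenerate)
})

test_that("HWE agrees with the multinomial expected-count oracle", {
  set.seed(42)
  for (i in 1:1000) {
    counts <- as.vector(rmultinom(1, sample(20:500, 1),
                                  prob = runif(3, 0.05, 1)))
    if (sum(counts[1:2]) == 0 || sum(counts[2:3]) == 0) next
    p <- (2 * counts[1] + counts[2]) / (2 * sum(counts))
    ours <- hweTest(counts[1], counts[2], counts[3])
    oracle <- suppressWarnings(
      chisq.test(counts, p = c(p^2, 2 * p * (1 - p), (1 - p)^2)))
    expect_equal(ours$chi2, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(ours$p, pchisq(ours$chi2, 1, lower.tail = FALSE))
  }
})

test_that("QC removes variants rule by rule with first-rule attribution", {
  set.seed(11)
  n <- 400
  common <- function() rbinom(n, 2, 0.3)
  rare <- rbinom(n, 2, 0.005)                      # MAF < 0.01
  # HWE p = 8.2e-5 < 1e-4: genotype counts 40/30/30 (other hom, het, hom eff)
  offHwe <- rep(c(0, 1, 2), times = c(40, 30, 30) * (n / 100))
  fx <- genoFromDosages(ok1 = common(), ok2 = common(), rare = rare,
                        offhwe = offHwe, ok3 = common())
  # per-sample F is only informative genome-wide; relax it for a 5-SNP toy
  res <- applyQc(fx$geno, fx$pheno, qcThresholds(inbreedingFMax = 2))
  kept <- variantInfo(res$genotypes)$id
  expect_setequal(kept, c("ok1", "ok2", "ok3"))
  expect_equal(res$report$maf, 1)
  expect_equal(res$report$hwe, 1)
})

test_that("non-binding thresholds leave the data untouched and QC is idempotent", {
  set.seed(12)
  dosages <- replicate(6, rbinom(300, 2, runif(1, 0.1, 0.5)))
  dosages[sample(length(dosages), 30)] <- NA
  fx <- do.call(genoFromDosages,
                setNames(lapply(seq_len(6), function(j) dosages[, j]),
                         paste0("v", 1:6)))
  slack <- applyQc(fx$geno, fx$pheno, slackThresholds())
  expect_identical(dosageMatrix(slack$genotypes), dosageMatrix(fx$geno))

  th <- qcThresholds(inbreedingFMax = 2)
  once <- applyQc(fx$geno, fx$pheno, th)
  twice <- applyQc(once$genotypes, fx$pheno, th)
  expect_identical(dosageMatrix(twice$genotypes),
                   dosageMatrix(once$genotypes))
})

test_that("logistic dosage test matches the closed-form 2x2 odds ratio", {
  # doses restricted to {0, 2}: cases 30 exposed / 70 not, controls 10 / 90
  dose <- c(rep(2, 30), rep(0, 70), rep(2, 10), rep(0, 90))
  status <- rep(c("case", "control"), each = 100)
  rec <- logisticAssoc(dose, status)
  orExposure <- (30 * 90) / (70 * 10)
  expect_equal(rec$beta, log(orExposure) / 2, tolerance = 1e-6)
  expect_equal(rec$or, exp(log(orExposure) / 2), tolerance = 1e-6)
  expect_equal(rec$n_case, 100)
  expect_equal(rec$n_control, 100)
})

test_that("allele-coding flip negates beta and preserves P", {
  set.seed(13)
  dose <- rbinom(500, 2, 0.3)
  status <- rbinom(500, 1, plogis(-1 + 0.4 * dose))
  a <- logisticAssoc(dose, status)
  b <- logisticAssoc(2 - dose, status)
  expect_equal(b$beta, -a$beta, tolerance = 1e-8)
  expect_equal(b$or, 1 / a$or, tolerance = 1e-8)
  expect_equal(b$p, a$p, tolerance = 1e-10)
  expect_error(logisticAssoc(rep(1, 100), rep(c(0, 1), 50)),
               class = "tagfun_degenerate_error")
})

test_that("conditioning on an independent SNP barely moves the estimate", {
  cc <- simCaseControl(maf = 0.3, oddsRatio = 1.5, nCase = 2500,
                       nControl = 2500, seed = 21)
  dose <- dosageMatrix(cc$genotypes)[, 1L]
  set.seed(22)
  other <- rbinom(length(dose), 2, 0.25)   # r2 = 0 with the causal SNP
  plain <- logisticAssoc(dose, cc$phenotypes$status)
  cond <- logisticAssoc(dose, cc$phenotypes$status,
                        conditionOn = list(other = other))
  expect_lt(abs(cond$beta - plain$beta), 2 * plain$se)
  expect_match(cond$conditioned_on, "other")
})

test_that("score-test variant agrees with Wald asymptotically", {
  set.seed(23)
  dose <- rbinom(2000, 2, 0.3)
  status <- rbinom(2000, 1, plogis(-1 + 0.3 * dose))
  wald <- logisticAssoc(dose, status)
  score <- logisticAssoc(dose, status, method = "score")
  expect_equal(score$p, wald$p, tolerance = 0.15)
  expect_equal(score$beta, wald$beta)  # point estimate still from the fit
})

test_that("homogeneity chi-square matches hand values and rejects zero margins", {
  null <- chisqHomogeneity(rbind(c(50, 50), c(50, 50)))
  expect_equal(null$chi2, 0)
  expect_equal(null$p, 1)
  h <- chisqHomogeneity(rbind(c(30, 70), c(10, 90)))
  # expected counts 20/80/20/80
  expect_equal(h$chi2, 12.5, tolerance = 1e-12)
  expect_equal(h$p, pchisq(12.5, 1, lower.tail = FALSE))
  expect_error(chisqHomogeneity(rbind(c(0, 0), c(10, 90))),
               class = "tagfun_degenerate_error")
})

test_that("analytic allelic power is calibrated and monotone", {
  expect_equal(allelicPower(1, 0.2, 200, 1400, alpha = 0.05, sided = "one"),
               0.05, tolerance = 1e-12)
  pw <- vapply(c(50, 100, 200, 400), function(nc) {
    allelicPower(1.5, 0.2, nc, 1400, alpha = 0.05, sided = "one")
  }, numeric(1))
  expect_true(all(diff(pw) > 0))
  expect_error(allelicPower(1.5, 1.2, 100, 100), class = "tagfun_param_error")
})

test_that("analytic power matches a case-control simulation oracle", {
  nRep <- 3000
  zCrit <- qnorm(0.95)
  rejected <- vapply(seq_len(nRep), function(s) {
    cc <- simCaseControl(maf = 0.2, oddsRatio = 1.5, nCase = 200,
                         nControl = 1400, seed = 30000 + s)
    d <- dosageMatrix(cc$genotypes)[, 1L]
    case <- cc$phenotypes$status == "case"
    tab <- rbind(c(sum(d[case]), 2 * sum(case) - sum(d[case])),
                 c(sum(d[!case]), 2 * sum(!case) - sum(d[!case])))
    h <- chisqHomogeneity(tab)
    z <- sign(mean(d[case]) - mean(d[!case])) * sqrt(h$chi2)
    z > zCrit
  }, logical(1))
  analytic <- allelicPower(1.5, 0.2, 200, 1400, alpha = 0.05, sided = "one")
  expect_lt(abs(mean(rejected) - analytic), 0.02)
})
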