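# Readers, writers, fixtures and the pipeline driver.

test_that("genotype VCF round trip preserves dosages and metadata", {
  cc <- simCaseControl(maf = 0.3, oddsRatio = 1.4, nCase = 25, nControl = 25,
                      seed = 101)
  path <- withr::local_tempfile(fileext = ".vcf")
  writeGenotypesVcf(cc$genotypes, path)
  back <- readGenotypes(path, format = "vcf")
  expect_equal(unname(dosageMatrix(back)),
               unname(dosageMatrix(cc$genotypes)))
  expect_equal(variantInfo(back)$id, variantInfo(cc$genotypes)$id)
})

test_that("DS is preferred over GT and ./. becomes missing", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("9", "22030438", "rsX", "G", "A", ".", "PASS", ".", "GT:DS",
          "0/1:1.3", "0/0:0.1", "./.:.", sep = "\t")), path)
  geno <- readGenotypes(path, format = "vcf")
  expect_equal(unname(dosageMatrix(geno)[, "rsX"]), c(1.3, 0.1, NA))
  # GT-only record falls back to the allele count; ref policy flips it
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("9", "101", "rsY", "G", "A", ".", "PASS", ".", "GT",
          "0/1", "1/1", sep = "\t")), path)
  gt <- readGenotypes(path, format = "vcf")
  expect_equal(unname(dosageMatrix(gt)[, "rsY"]), c(1, 2))
  flipped <- readGenotypes(path, format = "vcf", effectAllelePolicy = "ref")
  expect_equal(unname(dosageMatrix(flipped)[, "rsY"]), c(1, 0))
})

test_that("phased panels survive a VCF round trip", {
  panel <- simHaplotypePanel(0.4, 0.3, 0.5, nHap = 60, seed = 102)
  path <- withr::local_tempfile(fileext = ".vcf")
  writeHaplotypesVcf(panel, path)
  back <- readHaplotypes(path)
  expect_equal(unname(alleleMatrix(back)), unname(alleleMatrix(panel)))
  expect_equal(variantInfo(back)$pos, variantInfo(panel)$pos)
  # unphased input is rejected
  unphased <- withr::local_tempfile(fileext = ".vcf")
  cc <- simCaseControl(maf = 0.3, oddsRatio = 1, nCase = 5, nControl = 5,
                       seed = 103)
  writeGenotypesVcf(cc$genotypes, unphased)
  expect_error(readHaplotypes(unphased), class = "tagfun_parse_error")
})

test_that("dosage TSV round trip preserves missing values", {
  cc <- simCaseControl(maf = 0.25, oddsRatio = 1.2, nCase = 20,
                       nControl = 20, seed = 104)
  dos <- dosageMatrix(cc$genotypes)
  dos[3, 1] <- NA
  geno <- GenotypeData(dos, variantInfo(cc$genotypes))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDosageTsv(geno, path)
  back <- readGenotypes(path, format = "dosage")
  expect_equal(unname(dosageMatrix(back)), unname(dos))
  expect_equal(sampleIds(back), sampleIds(geno))
})

test_that("PWM readers parse both dialects and round-trip probabilities", {
  jaspar <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">MA0001 testmotif",
               "A [ 4 19 0 ]", "C [ 16 0 20 ]",
               "G [ 0 1 0 ]", "T [ 0 0 0 ]"), jaspar)
  pwm <- readPwm(jaspar)
  expect_s4_class(pwm, "PWM")
  expect_equal(motifLength(pwm), 3)
  expect_equal(rowSums(pwmProbs(pwm)), rep(1, 3), tolerance = 1e-12)
  expect_equal(pwm@name, "MA0001")
  # pseudocount arithmetic on the first column: (4 + .25) / (20 + 1)
  expect_equal(unname(pwmProbs(pwm)[1, "A"]), 4.25 / 21, tolerance = 1e-12)

  out <- withr::local_tempfile(fileext = ".jaspar")
  writePwm(pwm, out)
  back <- readPwm(out, pseudocount = 0)
  expect_equal(pwmProbs(back), pwmProbs(pwm), tolerance = 1e-12)

  broken <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c("A [ 1 2 ]", "C [ 1 2 ]", "G [ 1 2 ]"), broken)  # no T row
  expect_error(readPwm(broken), class = "tagfun_parse_error")
  ragged <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c("A [ 1 2 ]", "C [ 1 2 3 ]", "G [ 1 2 ]", "T [ 1 2 ]"), ragged)
  expect_error(readPwm(ragged), class = "tagfun_parse_error")

  transfac <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("ID M00001", "P0 A C G T",
               "01 4 16 0 0 C", "02 19 0 1 0 A", "03 0 20 0 0 C", "XX"),
             transfac)
  tf <- readPwm(transfac, dialect = "transfac")
  expect_equal(motifLength(tf), 3)
  expect_equal(pwmProbs(tf), pwmProbs(pwm), tolerance = 1e-12)
})

test_that("the bundled demo PWM loads", {
  demo <- readPwm(system.file("extdata", "synthetic_gpref.jaspar",
                              package = "tagfun"))
  expect_equal(motifLength(demo), 5)
  expect_equal(unname(colnames(pwmProbs(demo))[max.col(pwmProbs(demo))[3]]),
               "G")
})

test_that("the demo pipeline runs, is reproducible, and validates inputs", {
  cfg <- system.file("extdata", "demo_config.yaml", package = "tagfun")
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  m1 <- suppressMessages(runPipeline(cfg, outputDir = dir1))
  expect_true(all(file.exists(file.path(dir1, m1$output))))
  expect_true(all(file.exists(file.path(dir1,
                                        paste0(m1$output,
                                               ".provenance.json")))))
  rep1 <- jsonlite::read_json(file.path(dir1, "finemap_sim.json"))
  expect_true(rep1$frac_less_significant >= 0 &&
              rep1$frac_less_significant <= 1)
  suppressMessages(runPipeline(cfg, outputDir = dir2))
  for (f in m1$output) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)),
                     label = sprintf("pipeline output %s", f))
  }
  # configs referencing missing inputs fail before any stage runs
  bad <- list(stages = list(list(stage = "qc",
                                 inputs = list(dosage_tsv = "absent.tsv",
                                               phenotype_tsv = "absent2.tsv"),
                                 outputs = list(dosage_tsv = "o.tsv",
                                                report_json = "r.json"))))
  dir3 <- withr::local_tempdir()
  expect_error(runPipeline(bad, outputDir = dir3),
               class = "tagfun_config_error")
  expect_length(list.files(dir3), 0)
  # stochastic stages must declare seeds
  noseed <- list(stages = list(list(stage = "simulate",
                                    params = list(freq_causal = 0.3,
                                                  freq_tag = 0.3,
                                                  r2_target = 0.5,
                                                  n_hap = 100,
                                                  odds_ratio = 1.2,
                                                  n_case = 10,
                                                  n_control = 10),
                                    outputs = list(panel_vcf = "p.vcf",
                                                   dosage_tsv = "d.tsv",
                                                   phenotype_tsv = "ph.tsv"))))
  expect_error(runPipeline(noseed, outputDir = withr::local_tempdir()),
               class = "tagfun_config_error")
})

test_that("fixture tables load with the documented shape", {
  t1 <- loadTable1()
  t2 <- loadTable2()
  expect_equal(nrow(t1), 26)
  expect_equal(nrow(t2), 26)
  expect_true(all(c("disc_or", "rep_or", "comb_or", "p_het", "i2") %in%
                    names(t1)))
  expect_true(all(c("ha_p", "aa_p") %in% names(t2)))
  expect_identical(t1$snp_id, t2$snp_id)
})
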