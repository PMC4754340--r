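# Shared fixture builders: all test data are generated in code.

# panel built from explicit two-locus haplotype counts (AB, Ab, aB, ab)
panelFromCounts <- function(n11, n10, n01, n00, ids = c("snpA", "snpB")) {
  types <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  alleles <- types[rep.int(1:4, c(n11, n10, n01, n00)), , drop = FALSE]
  HaplotypePanel(alleles, data.frame(
    id = ids, chrom = "1", pos = c(100L, 200L),
    effect_allele = "A", other_allele = "G", stringsAsFactors = FALSE))
}

# genotype matrix + phenotype table from explicit dosage columns
genoFromDosages <- function(..., status = NULL) {
  cols <- list(...)
  dos <- do.call(cbind, cols)
  ids <- sprintf("s%03d", seq_len(nrow(dos)))
  variants <- data.frame(
    id = names(cols), chrom = "1", pos = seq_along(cols) * 100L,
    effect_allele = "A", other_allele = "G", stringsAsFactors = FALSE)
  geno <- GenotypeData(dos, variants, sampleIds = ids)
  pheno <- data.frame(sample_id = ids,
                      status = if (is.null(status))
                        rep(c("case", "control"), length.out = nrow(dos))
                      else status,
                      stringsAsFactors = FALSE)
  list(geno = geno, pheno = pheno)
}

# non-binding QC thresholds: nothing should ever trigger
slackThresholds <- function() {
  qcThresholds(mafMin = 0, snpMissingMax = 1, sampleMissingMax = 1,
               hwePMin = 0, diffMissingPMin = 0, inbreedingFMax = 10,
               infoMin = 0)
}
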