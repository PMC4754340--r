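# File I/O: VCF and TSV genotype/phenotype/expression readers and writers,
# JASPAR/TRANSFAC PWM parsing, and the packaged summary-statistic fixtures.
# Conventions: coordinates are 1-based (VCF); TSVs are tab-separated, UTF-8,
# header mandatory, '.' for missing.

.NA_TOKEN <- "."

#' Read genotype dosages from VCF or a dosage TSV
#'
#' For VCF input, the FORMAT `DS` field (imputed posterior-mean dosage) is
#' preferred over `GT` whenever present; otherwise GT is converted to the
#' count of effect alleles.  The effect allele is ALT by default
#' (`effectAllelePolicy = "alt"`); with `"ref"` dosages are flipped to 2 -
#' dose.  `./.` genotypes become NA.  Dosage-TSV input is a samples x
#' variants matrix with a header of variant ids and sample ids in the first
#' column.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage"`.
#' @param effectAllelePolicy `"alt"` (default) or `"ref"`.
#' @return A [GenotypeData-class].
#' @seealso [readHaplotypes()] for phased VCF panels.
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "dosage"),
                          effectAllelePolicy = c("alt", "ref")) {
  format <- match.arg(format)
  effectAllelePolicy <- match.arg(effectAllelePolicy)
  if (!file.exists(path)) {
    .tfStop(sprintf("file not found: %s", path), "tagfun_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  }
  if (format == "dosage") {
    tab <- read.delim(path, check.names = FALSE, na.strings = .NA_TOKEN,
                      stringsAsFactors = FALSE)
    ids <- as.character(tab[[1L]])
    dos <- as.matrix(tab[, -1L, drop = FALSE])
    variants <- data.frame(id = colnames(dos), chrom = NA_character_,
                           pos = NA_integer_, effect_allele = NA_character_,
                           other_allele = NA_character_,
                           stringsAsFactors = FALSE)
    return(GenotypeData(dos, variants, sampleIds = ids))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  variants <- data.frame(
    id = fix[, "ID"], chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    effect_allele = if (effectAllelePolicy == "alt") fix[, "ALT"]
                    else fix[, "REF"],
    other_allele = if (effectAllelePolicy == "alt") fix[, "REF"]
                   else fix[, "ALT"],
    stringsAsFactors = FALSE)
  noId <- is.na(variants$id) | variants$id == "."
  variants$id[noId] <- paste0(variants$chrom[noId], ":", variants$pos[noId])
  hasDs <- "DS" %in% unlist(strsplit(vcf@gt[, "FORMAT"], ":"))
  gtm <- vcfR::extract.gt(vcf, element = "GT")
  doseGt <- apply(gtm, c(1L, 2L), function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(strsplit(g, "[/|]")[[1L]] == "1")
  })
  if (hasDs) {
    ds <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE))
    dose <- ifelse(is.na(ds), doseGt, ds)  # DS preferred over GT
  } else {
    dose <- doseGt
  }
  if (effectAllelePolicy == "ref") dose <- 2 - dose
  GenotypeData(t(dose), variants, sampleIds = colnames(dose))
}

#' Read a phased VCF into a haplotype panel
#'
#' Requires every genotype to be phased (`|` separator, no missing calls);
#' each diploid sample contributes two haplotype rows.  ALT is the effect
#' allele.
#'
#' @param path VCF path.
#' @return A [HaplotypePanel-class].
#' @export
readHaplotypes <- function(path) {
  if (!file.exists(path)) {
    .tfStop(sprintf("file not found: %s", path), "tagfun_io_error")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  gtm <- vcfR::extract.gt(vcf, element = "GT")
  if (any(is.na(gtm)) || any(!grepl("^[01]\\|[01]$", gtm))) {
    .tfStop("panel VCF must be fully phased ('|') with 0/1 alleles",
            "tagfun_parse_error")
  }
  h1 <- apply(gtm, c(1L, 2L), function(g) as.integer(substr(g, 1L, 1L)))
  h2 <- apply(gtm, c(1L, 2L), function(g) as.integer(substr(g, 3L, 3L)))
  alleles <- matrix(0L, nrow = 2L * ncol(gtm), ncol = nrow(gtm))
  alleles[seq(1L, nrow(alleles), by = 2L), ] <- t(h1)
  alleles[seq(2L, nrow(alleles), by = 2L), ] <- t(h2)
  variants <- data.frame(
    id = fix[, "ID"], chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    effect_allele = fix[, "ALT"], other_allele = fix[, "REF"],
    stringsAsFactors = FALSE)
  HaplotypePanel(alleles, variants)
}

.vcfHeader <- function(samples, hasDs = FALSE) {
  c("##fileformat=VCFv4.2",
    "##source=tagfun",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (hasDs)
      "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

#' Write a haplotype panel as a phased plain-text VCF
#'
#' Minimal VCF (CHROM, POS, ID, REF, ALT, GT with `|` separator); pairs of
#' consecutive haplotype rows form one diploid sample, so the panel must
#' hold an even number of haplotypes.
#'
#' @param panel a [HaplotypePanel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHaplotypesVcf <- function(panel, path) {
  a <- alleleMatrix(panel)
  if (nrow(a) %% 2L != 0L) {
    .tfStop("panel must hold an even number of haplotypes to form diploids",
            "tagfun_param_error")
  }
  v <- variantInfo(panel)
  samples <- sprintf("hsample%04d", seq_len(nrow(a) / 2L))
  gt <- matrix(paste0(a[seq(1L, nrow(a), 2L), , drop = FALSE], "|",
                      a[seq(2L, nrow(a), 2L), , drop = FALSE]),
               nrow = nrow(a) / 2L)
  body <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$other_allele[j],
            v$effect_allele[j], ".", "PASS", ".", "GT", gt[, j]),
          collapse = "\t")
  }, character(1))
  writeLines(c(.vcfHeader(samples), body), path)
  invisible(path)
}

#' Write genotype dosages as a plain-text VCF with GT and DS fields
#'
#' Hard calls (0/0, 0/1, 1/1 at the 0.5/1.5 cut points) populate GT and the
#' raw dosage populates DS; missing dosages become `./.` with DS `.`.
#'
#' @param geno a [GenotypeData-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypesVcf <- function(geno, path) {
  dos <- dosageMatrix(geno)
  v <- variantInfo(geno)
  gtOf <- function(d) {
    ifelse(is.na(d), "./.",
           ifelse(d < 0.5, "0/0", ifelse(d < 1.5, "0/1", "1/1")))
  }
  body <- vapply(seq_len(nrow(v)), function(j) {
    d <- dos[, j]
    cells <- paste0(gtOf(d), ":",
                    ifelse(is.na(d), ".", format(d, trim = TRUE)))
    ref <- ifelse(is.na(v$other_allele[j]), "N", v$other_allele[j])
    alt <- ifelse(is.na(v$effect_allele[j]), "N", v$effect_allele[j])
    chrom <- ifelse(is.na(v$chrom[j]), "0", v$chrom[j])
    pos <- ifelse(is.na(v$pos[j]), j, v$pos[j])
    paste(c(chrom, pos, v$id[j], ref, alt, ".", "PASS", ".", "GT:DS", cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(.vcfHeader(rownames(dos), hasDs = TRUE), body), path)
  invisible(path)
}

#' Write/read a samples x variants dosage matrix as TSV
#'
#' Tab-separated with a `sample_id` first column, variant ids as the header,
#' `.` for missing.
#'
#' @param geno a [GenotypeData-class].
#' @param path file path.
#' @return `path` invisibly (writer).
#' @export
writeDosageTsv <- function(geno, path) {
  dos <- dosageMatrix(geno)
  out <- data.frame(sample_id = rownames(dos), dos, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = .NA_TOKEN)
  invisible(path)
}

#' Read a phenotype/covariate TSV
#'
#' Expects `sample_id` and `status` columns; any further numeric columns are
#' covariates.  `.` marks missing.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readPhenotypes <- function(path) {
  tab <- read.delim(path, na.strings = .NA_TOKEN, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(tab))) {
    .tfStop("phenotype TSV needs 'sample_id' and 'status' columns",
            "tagfun_parse_error")
  }
  tab
}

#' Write a table as tagfun-convention TSV
#'
#' Tab separators, mandatory header, `.` for missing, no quoting.
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = .NA_TOKEN)
  invisible(path)
}

#' Read an expression TSV (samples x genes)
#'
#' Header row of gene ids, `sample_id` first column.
#'
#' @param path file path.
#' @return numeric matrix with sample-id rownames.
#' @export
readExpression <- function(path) {
  tab <- read.delim(path, check.names = FALSE, na.strings = .NA_TOKEN,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  m
}

# ---- PWM formats ------------------------------------------------------------

#' Read a PWM in JASPAR or TRANSFAC count format
#'
#' JASPAR: an optional `>name` line then four rows `A [ 4 19 0 ]` (brackets
#' optional).  TRANSFAC: `ID`/`P0` header lines and numbered position rows
#' with columns A C G T.  Counts are converted to probabilities with an
#' additive pseudocount per cell.
#'
#' @param path file path.
#' @param dialect `"jaspar"` (default) or `"transfac"`.
#' @param pseudocount,background passed to [pwmFromCounts()].
#' @return A [PWM-class].
#' @export
readPwm <- function(path, dialect = c("jaspar", "transfac"),
                    pseudocount = 0.25, background = rep(0.25, 4)) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "jaspar") {
    name <- "motif"
    hdr <- grepl("^>", lines)
    if (any(hdr)) {
      name <- sub("^>\\s*", "", lines[which(hdr)[1L]])
      name <- strsplit(name, "\\s+")[[1L]][1L]
      lines <- lines[!hdr]
    }
    rows <- lapply(lines, function(l) {
      base <- sub("^\\s*([ACGTacgt])\\b.*$", "\\1", l)
      nums <- regmatches(l, gregexpr("[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?",
                                     l))[[1L]]
      list(base = toupper(base), counts = as.numeric(nums))
    })
    bases <- vapply(rows, `[[`, character(1), "base")
    if (!setequal(bases, c("A", "C", "G", "T"))) {
      .tfStop("JASPAR matrix needs exactly the rows A, C, G, T",
              "tagfun_parse_error")
    }
    lens <- vapply(rows, function(r) length(r$counts), integer(1))
    if (length(unique(lens)) != 1L || lens[1L] == 0L) {
      .tfStop("JASPAR rows must have equal, positive length",
              "tagfun_parse_error")
    }
    counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
    rownames(counts) <- bases
  } else {
    name <- "motif"
    idLine <- grep("^(ID|NA)\\s", lines, value = TRUE)
    if (length(idLine)) name <- strsplit(idLine[1L], "\\s+")[[1L]][2L]
    p0 <- grep("^P0|^PO", lines)
    if (!length(p0)) {
      .tfStop("TRANSFAC matrix needs a P0 header line", "tagfun_parse_error")
    }
    order0 <- toupper(strsplit(trimws(lines[p0[1L]]), "\\s+")[[1L]][-1L])[1:4]
    if (!setequal(order0, c("A", "C", "G", "T"))) {
      .tfStop("TRANSFAC P0 line must name columns A, C, G, T",
              "tagfun_parse_error")
    }
    posLines <- lines[grepl("^\\s*[0-9]+\\s", lines)]
    if (!length(posLines)) {
      .tfStop("TRANSFAC matrix has no position rows", "tagfun_parse_error")
    }
    vals <- lapply(posLines, function(l) {
      parts <- strsplit(trimws(l), "\\s+")[[1L]]
      as.numeric(parts[2:5])
    })
    if (any(vapply(vals, anyNA, logical(1)))) {
      .tfStop("malformed TRANSFAC position row", "tagfun_parse_error")
    }
    counts <- t(do.call(rbind, vals))
    rownames(counts) <- order0
    name <- if (is.na(name)) "motif" else name
  }
  pwmFromCounts(counts, name = name, pseudocount = pseudocount,
                background = background)
}

#' Write a PWM in JASPAR layout
#'
#' Writes either the probability matrix (default; a read-back with
#' `pseudocount = 0` reproduces the probabilities) or pseudocount-free
#' counts scaled by `nSites`.
#'
#' @param pwm a [PWM-class].
#' @param path output path.
#' @param what `"probs"` (default) or `"counts"`.
#' @param nSites scale factor for `"counts"`.
#' @return `path`, invisibly.
#' @export
writePwm <- function(pwm, path, what = c("probs", "counts"), nSites = 100) {
  what <- match.arg(what)
  m <- t(pwmProbs(pwm))
  if (what == "counts") m <- m * nSites
  lines <- c(paste0(">", pwm@name),
             vapply(c("A", "C", "G", "T"), function(b) {
               paste0(b, " [ ",
                      paste(format(m[b, ], digits = 17, trim = TRUE),
                            collapse = " "), " ]")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

# ---- packaged fixtures ------------------------------------------------------

#' Packaged locus summary-statistic fixtures
#'
#' `loadTable1()` returns the European-ancestry per-study and combined
#' association statistics for the 26 SNPs of the tagged risk locus
#' (discovery meta-analysis, replication, and combined OR/CI/P columns plus
#' heterogeneity statistics).  `loadTable2()` returns the Hispanic-American
#' and African-American association statistics for the same locus, the
#' substrate of the cross-ancestry prioritization filter.
#'
#' @return data.frame of printed summary statistics.
#' @examples
#' t1 <- loadTable1()
#' metaFromCi(or = c(t1$disc_or[1], t1$rep_or[1]),
#'            ciLo = c(t1$disc_lo[1], t1$rep_lo[1]),
#'            ciHi = c(t1$disc_hi[1], t1$rep_hi[1]))
#' @export
loadTable1 <- function() {
  read.delim(system.file("extdata", "table1.tsv", package = "tagfun"),
             stringsAsFactors = FALSE)
}

#' @rdname loadTable1
#' @export
loadTable2 <- function() {
  read.delim(system.file("extdata", "table2.tsv", package = "tagfun"),
             stringsAsFactors = FALSE)
}
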