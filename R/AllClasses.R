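#' Phased haplotype panel for two or more variants
#'
#' Stores phased 0/1 alleles (1 = effect/risk allele) as a haplotypes x
#' variants matrix together with per-variant metadata.  This is the substrate
#' for LD statistics and for the constrained haplotype-resampling null.
#'
#' @slot alleles integer/numeric matrix of 0/1, haplotypes in rows, variants
#'   in columns; column names are variant ids.
#' @slot variants data.frame with columns \code{id}, \code{chrom}, \code{pos}
#'   (1-based), \code{effect_allele}, \code{other_allele}.
#'
#' @examples
#' panel <- simHaplotypePanel(0.3, 0.3, r2Target = 0.6, nHap = 200, seed = 1)
#' panel
#' ldR2(panel, "snpA", "snpB")$r2
#' @export
setClass("HaplotypePanel",
  representation(alleles = "matrix", variants = "data.frame"),
  validity = function(object) {
    msg <- character()
    a <- object@alleles
    v <- object@variants
    if (!all(a %in% c(0, 1))) {
      msg <- c(msg, "alleles must contain only 0/1 (no missing values)")
    }
    need <- c("id", "chrom", "pos", "effect_allele", "other_allele")
    if (!all(need %in% names(v))) {
      msg <- c(msg, paste("variants must have columns:",
                          paste(need, collapse = ", ")))
    } else {
      if (ncol(a) != nrow(v)) {
        msg <- c(msg, "ncol(alleles) must equal nrow(variants)")
      }
      if (anyDuplicated(v$id)) msg <- c(msg, "variant ids must be unique")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a HaplotypePanel
#'
#' @param alleles 0/1 matrix, haplotypes x variants.
#' @param variants data.frame of variant metadata (id, chrom, pos,
#'   effect_allele, other_allele).
#' @return A [HaplotypePanel-class] object.
#' @export
HaplotypePanel <- function(alleles, variants) {
  alleles <- as.matrix(alleles)
  colnames(alleles) <- variants$id
  new("HaplotypePanel", alleles = alleles,
      variants = as.data.frame(variants))
}

#' Genotype dosages with variant metadata
#'
#' Samples x variants matrix of effect-allele dosages in [0, 2] (fractional
#' values allowed for imputed posterior-mean dosages, NA for missing), with
#' the same variant metadata layout as [HaplotypePanel-class].  Sample ids are
#' the row names.
#'
#' @slot dosages numeric matrix, samples x variants; values in [0, 2] or NA.
#' @slot variants data.frame as in [HaplotypePanel-class].
#' @export
setClass("GenotypeData",
  representation(dosages = "matrix", variants = "data.frame"),
  validity = function(object) {
    msg <- character()
    d <- object@dosages
    v <- object@variants
    if (any(d < 0 | d > 2, na.rm = TRUE)) {
      msg <- c(msg, "dosages must lie in [0, 2] or be NA")
    }
    if (is.null(rownames(d)) || anyDuplicated(rownames(d))) {
      msg <- c(msg, "sample ids (rownames of dosages) must exist and be unique")
    }
    if (ncol(d) != nrow(v)) {
      msg <- c(msg, "ncol(dosages) must equal nrow(variants)")
    }
    if (anyDuplicated(v$id)) msg <- c(msg, "variant ids must be unique")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a GenotypeData object
#'
#' @param dosages numeric matrix (samples x variants) of effect-allele doses.
#' @param variants data.frame of variant metadata.
#' @param sampleIds optional sample ids (defaults to existing rownames).
#' @return A [GenotypeData-class] object.
#' @export
GenotypeData <- function(dosages, variants, sampleIds = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(sampleIds)) sampleIds <- paste0("s", seq_len(nrow(dosages)))
  rownames(dosages) <- sampleIds
  colnames(dosages) <- variants$id
  new("GenotypeData", dosages = dosages, variants = as.data.frame(variants))
}

#' Position weight matrix with background frequencies
#'
#' Per-position base probabilities for a transcription-factor binding motif,
#' plus the background base frequencies and the pseudocount used when the
#' matrix was derived from counts.  Basis of LOD scoring in [pwmLodScan()].
#'
#' @slot name motif name.
#' @slot probs positions x 4 matrix with columns A, C, G, T; rows sum to 1.
#' @slot background length-4 base frequencies summing to 1.
#' @slot pseudocount pseudocount added per cell during count conversion.
#' @export
setClass("PWM",
  representation(name = "character", probs = "matrix",
                 background = "numeric", pseudocount = "numeric"),
  validity = function(object) {
    msg <- character()
    p <- object@probs
    if (ncol(p) != 4L || !identical(colnames(p), c("A", "C", "G", "T"))) {
      msg <- c(msg, "probs must have columns A, C, G, T")
    } else if (any(abs(rowSums(p) - 1) > 1e-9)) {
      msg <- c(msg, "each position's probabilities must sum to 1 (tol 1e-9)")
    }
    if (length(object@background) != 4L ||
        abs(sum(object@background) - 1) > 1e-9) {
      msg <- c(msg, "background must be 4 frequencies summing to 1")
    }
    if (any(p < 0) || any(object@background < 0)) {
      msg <- c(msg, "probabilities must be non-negative")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Build a PWM from a count (or probability) matrix
#'
#' Converts a JASPAR-style 4 x L or L x 4 count matrix to per-position
#' probabilities with an additive pseudocount per cell.
#'
#' @param counts numeric matrix of base counts; either 4 rows named
#'   A/C/G/T or 4 such columns.
#' @param name motif name.
#' @param pseudocount additive pseudocount per cell (default 0.25).
#' @param background background base frequencies (default uniform).
#' @return A [PWM-class] object.
#' @examples
#' m <- rbind(A = c(8, 0), C = c(0, 0), G = c(0, 8), T = c(0, 0))
#' pwmFromCounts(m, name = "toy")
#' @export
pwmFromCounts <- function(counts, name = "motif", pseudocount = 0.25,
                          background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  bases <- c("A", "C", "G", "T")
  if (nrow(counts) == 4L && all(bases %in% rownames(counts))) {
    counts <- t(counts[bases, , drop = FALSE])
  } else if (ncol(counts) == 4L && all(bases %in% colnames(counts))) {
    counts <- counts[, bases, drop = FALSE]
  } else {
    .tfStop("counts must have 4 rows or columns named A, C, G, T",
            "tagfun_parse_error")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    .tfStop("counts must be finite and non-negative", "tagfun_param_error")
  }
  probs <- (counts + pseudocount) / (rowSums(counts) + 4 * pseudocount)
  dimnames(probs) <- list(NULL, bases)
  background <- background / sum(background)
  names(background) <- bases
  new("PWM", name = as.character(name), probs = probs,
      background = background, pseudocount = pseudocount)
}

# ---- generics and accessors -------------------------------------------------

#' @describeIn HaplotypePanel-class allele matrix (haplotypes x variants)
#' @param object a HaplotypePanel, GenotypeData or PWM object
#' @export
setGeneric("alleleMatrix", function(object) standardGeneric("alleleMatrix"))
#' @export
setMethod("alleleMatrix", "HaplotypePanel", function(object) object@alleles)

#' @describeIn HaplotypePanel-class variant metadata data.frame
#' @export
setGeneric("variantInfo", function(object) standardGeneric("variantInfo"))
#' @export
setMethod("variantInfo", "HaplotypePanel", function(object) object@variants)
#' @export
setMethod("variantInfo", "GenotypeData", function(object) object@variants)

#' @describeIn HaplotypePanel-class number of haplotypes
#' @export
setGeneric("nHaplotypes", function(object) standardGeneric("nHaplotypes"))
#' @export
setMethod("nHaplotypes", "HaplotypePanel",
          function(object) nrow(object@alleles))

#' @describeIn GenotypeData-class dosage matrix (samples x variants)
#' @export
setGeneric("dosageMatrix", function(object) standardGeneric("dosageMatrix"))
#' @export
setMethod("dosageMatrix", "GenotypeData", function(object) object@dosages)

#' @describeIn GenotypeData-class sample identifiers
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))
#' @export
setMethod("sampleIds", "GenotypeData",
          function(object) rownames(object@dosages))

#' @describeIn PWM-class per-position probability matrix
#' @export
setGeneric("pwmProbs", function(object) standardGeneric("pwmProbs"))
#' @export
setMethod("pwmProbs", "PWM", function(object) object@probs)

#' @describeIn PWM-class background base frequencies
#' @export
setGeneric("pwmBackground", function(object) standardGeneric("pwmBackground"))
#' @export
setMethod("pwmBackground", "PWM", function(object) object@background)

#' @describeIn PWM-class motif length in bases
#' @export
setGeneric("motifLength", function(object) standardGeneric("motifLength"))
#' @export
setMethod("motifLength", "PWM", function(object) nrow(object@probs))

setMethod("show", "HaplotypePanel", function(object) {
  cat(sprintf("HaplotypePanel: %d haplotypes x %d variants\n",
              nrow(object@alleles), ncol(object@alleles)))
  f <- colMeans(object@alleles)
  cat("  effect-allele frequencies:",
      paste(sprintf("%s=%.3f", object@variants$id, f), collapse = ", "), "\n")
})

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d samples x %d variants\n",
              nrow(object@dosages), ncol(object@dosages)))
  nmiss <- sum(is.na(object@dosages))
  if (nmiss > 0) cat(sprintf("  %d missing dosages\n", nmiss))
})

setMethod("show", "PWM", function(object) {
  cat(sprintf("PWM '%s': %d positions (pseudocount %.3g)\n",
              object@name, nrow(object@probs), object@pseudocount))
  cons <- colnames(object@probs)[max.col(object@probs)]
  cat("  consensus:", paste(cons, collapse = ""), "\n")
})
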