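# PWM LOD scoring of reference vs alternate alleles and overlapping
# splice-enhancer motif scanning.

.checkDna <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  if (length(seq) != 1L || is.na(seq) || !grepl("^[ACGT]+$", seq)) {
    .tfStop(sprintf("%s must be a non-empty string over A/C/G/T", what),
            "tagfun_input_error")
  }
  seq
}

.revComp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# LOD of every length-L window of `seq` against the PWM, forward strand
.lodForward <- function(seq, pwm, logBase) {
  lr <- log(pwmProbs(pwm) / matrix(pwmBackground(pwm),
                                   nrow = motifLength(pwm), ncol = 4L,
                                   byrow = TRUE), base = logBase)
  codes <- match(strsplit(seq, "")[[1L]], c("A", "C", "G", "T"))
  L <- motifLength(pwm)
  nOff <- nchar(seq) - L + 1L
  vapply(seq_len(nOff), function(o) {
    sum(lr[cbind(seq_len(L), codes[o:(o + L - 1L)])])
  }, numeric(1))
}

#' Scan a sequence with a PWM and report per-offset LOD scores
#'
#' At every offset, the LOD score is the summed log-ratio of motif versus
#' background base probabilities,
#' \eqn{\sum_j \log_2(p_j(b_j)/bg(b_j))}.  With `bothStrands` the reverse
#' complement is scanned too; a minus-strand hit at offset o means the motif
#' matches the reverse complement of the window starting at o.  All offsets
#' are returned, sorted by decreasing LOD.
#'
#' @param seq DNA string over A/C/G/T.
#' @param pwm a [PWM-class].
#' @param bothStrands scan the reverse complement as well (default TRUE).
#' @param logBase base of the log (default 2; comparisons are sign/rank
#'   based, hence base-invariant).
#' @return data.frame of motif hits: `motif`, `offset` (0-based), `strand`,
#'   `lod`; empty when the sequence is shorter than the motif.
#' @examples
#' pwm <- pwmFromCounts(rbind(A = c(9, 0), C = c(0, 0),
#'                            G = c(0, 9), T = c(0, 0)), name = "AG")
#' pwmLodScan("TTAGTT", pwm)
#' @export
pwmLodScan <- function(seq, pwm, bothStrands = TRUE, logBase = 2) {
  stopifnot(is(pwm, "PWM"))
  seq <- .checkDna(seq)
  L <- motifLength(pwm)
  empty <- data.frame(motif = character(), offset = integer(),
                      strand = character(), lod = numeric(),
                      stringsAsFactors = FALSE)
  if (nchar(seq) < L) return(empty)
  fwd <- .lodForward(seq, pwm, logBase)
  hits <- data.frame(motif = pwm@name,
                     offset = seq_along(fwd) - 1L,
                     strand = "+", lod = fwd, stringsAsFactors = FALSE)
  if (bothStrands) {
    rev <- .lodForward(.revComp(seq), pwm, logBase)
    # offset o' on the reverse complement maps to forward offset n - L - o'
    n <- nchar(seq)
    hits <- rbind(hits, data.frame(
      motif = pwm@name,
      offset = n - L - (seq_along(rev) - 1L),
      strand = "-", lod = rev, stringsAsFactors = FALSE))
  }
  hits[order(-hits$lod, hits$offset, hits$strand), , drop = FALSE]
}

#' Allele-specific motif disruption score
#'
#' Substitutes each allele at the SNP position of a sequence window, takes
#' the best LOD over all offsets and strands for each allele-resolved
#' window, and reports the difference \code{delta = alt_best - ref_best}.
#' A negative delta means the alternate allele weakens the best motif match
#' — the signature of a binding-site-disrupting risk allele.
#'
#' @param seq DNA window containing the SNP.
#' @param snpOffset 0-based offset of the SNP within `seq`.
#' @param ref,alt single bases; `substr(seq, snpOffset + 1, ...)` must equal
#'   `ref`.
#' @param pwm a [PWM-class].
#' @param bothStrands,logBase passed to [pwmLodScan()].
#' @return list with `ref_best_lod`, `alt_best_lod`, `delta`, `snp_offset`.
#' @export
alleleDisruption <- function(seq, snpOffset, ref, alt, pwm,
                             bothStrands = TRUE, logBase = 2) {
  seq <- .checkDna(seq)
  ref <- .checkDna(ref, "ref allele")
  alt <- .checkDna(alt, "alt allele")
  if (nchar(ref) != 1L || nchar(alt) != 1L) {
    .tfStop("ref and alt must be single bases", "tagfun_param_error")
  }
  if (snpOffset < 0 || snpOffset >= nchar(seq)) {
    .tfStop("snpOffset outside the sequence window", "tagfun_coord_error")
  }
  if (substr(seq, snpOffset + 1L, snpOffset + 1L) != ref) {
    .tfStop(sprintf("window base at offset %d is '%s', not the stated ref '%s'",
                    snpOffset,
                    substr(seq, snpOffset + 1L, snpOffset + 1L), ref),
            "tagfun_coord_error")
  }
  if (nchar(seq) < motifLength(pwm)) {
    .tfStop("window shorter than the motif", "tagfun_input_error")
  }
  sub1 <- function(s, base) {
    substr(s, snpOffset + 1L, snpOffset + 1L) <- base
    s
  }
  refHits <- pwmLodScan(sub1(seq, ref), pwm, bothStrands, logBase)
  altHits <- pwmLodScan(sub1(seq, alt), pwm, bothStrands, logBase)
  refBest <- max(refHits$lod)
  altBest <- max(altHits$lod)
  list(ref_best_lod = refBest, alt_best_lod = altBest,
       delta = altBest - refBest, snp_offset = snpOffset)
}

#' Scan both alleles of a template for exact splice-enhancer motifs
#'
#' The template carries exactly one allele slot written `[X/Y]`; the scan
#' resolves the template once per allele and reports every exact (possibly
#' overlapping) match of each motif in each allele-resolved sequence.  The
#' canonical use is showing that the two alleles of an intronic SNP each
#' complete a different overlapping splice-enhancer hexamer.
#'
#' @param seqTemplate DNA string with one `[X/Y]` allele slot.
#' @param motifs character vector of motifs over A/C/G/T (non-empty).
#' @return named list (one element per allele) of hit data.frames with
#'   columns `motif` and `offset` (0-based).
#' @examples
#' spliceHexamerScan("CCCAG[G/T]AC", c("CCCAGG", "CAGTAC"))
#' @export
spliceHexamerScan <- function(seqTemplate, motifs) {
  if (!length(motifs)) .tfStop("motifs must be non-empty",
                               "tagfun_param_error")
  motifs <- vapply(motifs, .checkDna, character(1), what = "motif")
  m <- gregexpr("\\[([ACGTacgt])/([ACGTacgt])\\]", seqTemplate)[[1L]]
  nSlots <- if (m[1L] == -1L) 0L else length(m)
  if (nSlots != 1L) {
    .tfStop(sprintf("template must contain exactly one [X/Y] allele slot (found %d)",
                    nSlots), "tagfun_template_error")
  }
  slot <- regmatches(seqTemplate, m)[[1L]]
  alleles <- toupper(strsplit(gsub("\\[|\\]", "", slot), "/")[[1L]])
  out <- lapply(alleles, function(al) {
    seq <- .checkDna(sub("\\[([ACGTacgt])/([ACGTacgt])\\]", al, seqTemplate),
                     "allele-resolved sequence")
    hits <- lapply(motifs, function(mo) {
      L <- nchar(mo)
      if (L > nchar(seq)) return(integer())
      # exhaustive offset check so self-overlapping occurrences all count
      starts <- 0:(nchar(seq) - L)
      starts[vapply(starts, function(o) {
        substr(seq, o + 1L, o + L) == mo
      }, logical(1))]
    })
    data.frame(
      motif = rep(motifs, lengths(hits)),
      offset = unlist(hits, use.names = FALSE),
      stringsAsFactors = FALSE, row.names = NULL)
  })
  names(out) <- alleles
  out
}
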