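#' Predict the premature termination codon introduced by a variant
#'
#' Maps a VCF-style variant (1-based genomic \code{pos}, \code{ref}/\code{alt}
#' strings, minus-strand transcripts handled by reverse complementing the
#' alleles) into spliced transcript coordinates, applies the edit, and
#' translates the mutated coding sequence from the affected codon onward. A
#' nonsense SNV yields a PTC at its own codon; a frameshift indel yields a PTC
#' at the first stop codon of the shifted reading frame (scanning to the end
#' of the transcript); an in-frame edit yields a PTC only if a new stop
#' appears upstream of the original stop codon. The PTC's genomic location is
#' mapped back through the exon structure (positions inside an inserted block
#' map to the nearest original base).
#'
#' @param variant list or one-row data.frame with \code{chrom}, \code{pos}
#'   (1-based genomic position of the first ref base), \code{ref}, \code{alt}
#'   (genome-strand allele strings), and optionally \code{variant_class}.
#' @param model a \code{\link{TranscriptModel}}.
#' @param genome named \code{DNAStringSet}.
#' @return list of class \code{PTCVariant}: \code{variant_id},
#'   \code{variant_class}, \code{transcript_id}, \code{has_ptc},
#'   \code{ptc_cds_pos_nt} (1-based CDS coordinate of the stop codon's first
#'   nt, NA if none), \code{ptc_tx_pos0} (0-based spliced-transcript
#'   coordinate in the original transcript), \code{ptc_exon_index},
#'   \code{ptc_genomic_pos} (1-based), \code{frameshift} (logical).
#' @export
predictPtc <- function(variant, model, genome) {
  ref <- toupper(as.character(variant$ref))
  alt <- toupper(as.character(variant$alt))
  pos <- as.integer(variant$pos)
  stopifnot(nchar(ref) >= 1L, nchar(alt) >= 1L)

  txSeq <- as.character(splicedSequence(model, genome))
  cdsStart <- model@cdsStart
  cdsEnd <- model@cdsEnd
  cdsLen <- cdsEnd - cdsStart

  # allele strings and anchor position in transcript orientation
  if (model@strand == "+") {
    refT <- ref; altT <- alt
    tStart <- genomicToTranscript(model, pos - 1L)
    tEndBase <- genomicToTranscript(model, pos + nchar(ref) - 2L)
  } else {
    refT <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref)))
    altT <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(alt)))
    tStart <- genomicToTranscript(model, pos + nchar(ref) - 2L)
    tEndBase <- genomicToTranscript(model, pos - 1L)
  }
  if (is.na(tStart) || is.na(tEndBase) || tEndBase - tStart + 1L != nchar(refT))
    stop("variant does not map to a contiguous exonic block of ",
         model@transcriptId)
  if (tStart < cdsStart || tStart >= cdsEnd)
    stop("variant outside the CDS of ", model@transcriptId)
  if (substr(txSeq, tStart + 1L, tStart + nchar(refT)) != refT)
    stop("ref allele mismatch at transcript position ", tStart)

  mutTx <- paste0(substr(txSeq, 1L, tStart), altT,
                  substr(txSeq, tStart + nchar(refT) + 1L, nchar(txSeq)))
  d <- nchar(altT) - nchar(refT)
  frameshift <- (d %% 3L) != 0L

  varCds0 <- tStart - cdsStart
  mutCds <- substr(mutTx, cdsStart + 1L, nchar(mutTx))
  stops <- c("TAA", "TAG", "TGA")
  k <- varCds0 %/% 3L
  stopAt <- NA_integer_                       # 0-based mutated-CDS position
  while (3L * k + 3L <= nchar(mutCds)) {
    codon <- substr(mutCds, 3L * k + 1L, 3L * k + 3L)
    if (codon %in% stops) { stopAt <- 3L * k; break }
    k <- k + 1L
  }
  origStopMut <- cdsLen - 3L + d              # original stop codon, mutated coords
  hasPtc <- !is.na(stopAt) && (frameshift || stopAt < origStopMut)

  vclass <- if (!is.null(variant$variant_class)) as.character(variant$variant_class)
            else if (d != 0L && frameshift) "frameshift_indel"
            else if (d != 0L) "inframe_indel"
            else if (hasPtc) "nonsense" else "missense_or_synonymous"

  out <- list(
    variant_id = paste(variant$chrom, pos, ref, alt, sep = ":"),
    variant_class = vclass,
    transcript_id = model@transcriptId,
    has_ptc = hasPtc,
    ptc_cds_pos_nt = NA_integer_, ptc_tx_pos0 = NA_integer_,
    ptc_exon_index = NA_integer_, ptc_genomic_pos = NA_integer_,
    frameshift = frameshift)
  if (hasPtc) {
    mutT0 <- cdsStart + stopAt
    # mutated -> original transcript coordinate
    origT0 <- if (mutT0 < tStart) mutT0
      else if (mutT0 < tStart + nchar(altT)) tStart
      else mutT0 - d
    origT0 <- min(origT0, transcriptLength(model) - 1L)
    out$ptc_cds_pos_nt <- stopAt + 1L        # 1-based, mutated CDS frame
    out$ptc_tx_pos0 <- origT0
    out$ptc_exon_index <- exonIndexOf(model, origT0)
    out$ptc_genomic_pos <- transcriptToGenomic(model, origT0) + 1L
  }
  class(out) <- "PTCVariant"
  out
}

#' @export
print.PTCVariant <- function(x, ...) {
  cat("PTCVariant", x$variant_id, "on", x$transcript_id, "\n")
  if (x$has_ptc)
    cat("  PTC at CDS nt", x$ptc_cds_pos_nt, "(exon", x$ptc_exon_index,
        "; genomic", x$ptc_genomic_pos, ")\n")
  else cat("  no PTC predicted\n")
  invisible(x)
}

#' Classify a PTC as NMD-triggering or NMD-evading
#'
#' Applies the positional NMD rules to the stop codon's first nt, in spliced
#' transcript coordinates. Under any rule set a PTC evades NMD when it lies in
#' the last exon, within the last \code{penultimateTailNt} (55) nt of the
#' penultimate exon, or within the first \code{startProximalNt} nt of the
#' transcript. When the transcript carries a 3'UTR EJC and
#' \code{utr3EjcOverride} is set, last-exon/55nt evading calls flip to
#' triggering (the start-proximal call does not). Under the dN/dS rule set the
#' long-exon rule additionally applies: a PTC in an exon of length >=
#' \code{evadingMinExonNt} (1000) evades, one in an exon of length in
#' (\code{triggeringMaxExonNt}, \code{evadingMinExonNt}) falls in a buffer
#' zone and is excluded, and triggering requires the exon to be <=
#' \code{triggeringMaxExonNt} (500) nt.
#'
#' @param ptcTxPos0 0-based spliced-transcript coordinate of the first nt of
#'   the (premature) stop codon, or a \code{PTCVariant} from
#'   \code{\link{predictPtc}}.
#' @param model a \code{\link{TranscriptModel}}.
#' @param profile the transcript's \code{NMDFeatureProfile} (or a list with a
#'   \code{has3UtrEjc} element).
#' @param rules an \code{\link{NMDRuleSet-class}} object
#'   (\code{\link{aseRules}} or \code{\link{dndsRules}}).
#' @return one of \code{"triggering"}, \code{"evading"}, \code{"buffer"}.
#' @export
classifyPtcNmd <- function(ptcTxPos0, model, profile, rules = aseRules()) {
  if (inherits(ptcTxPos0, "PTCVariant")) {
    if (!ptcTxPos0$has_ptc) return("none")
    ptcTxPos0 <- ptcTxPos0$ptc_tx_pos0
  }
  pos1 <- as.integer(ptcTxPos0) + 1L          # 1-based transcript coordinate
  lens <- exonLengths(model)
  nEx <- length(lens)
  exIdx <- exonIndexOf(model, ptcTxPos0)
  if (is.na(exIdx)) stop("PTC position outside the transcript")
  hasEjc <- isTRUE(profile$has3UtrEjc) || isTRUE(profile$has_3utr_ejc)

  if (pos1 <= rules@startProximalNt) return("evading")

  lastExon <- exIdx == nEx
  penultTail <- nEx >= 2L && exIdx == nEx - 1L &&
    pos1 >= sum(lens[seq_len(nEx - 1L)]) - rules@penultimateTailNt + 1L
  if (lastExon || penultTail) {
    if (rules@utr3EjcOverride && hasEjc) {
      # fall through to triggering-side rules
    } else return("evading")
  }

  if (!is.na(rules@evadingMinExonNt)) {
    exLen <- lens[exIdx]
    if (exLen >= rules@evadingMinExonNt) return("evading")
    if (exLen > rules@triggeringMaxExonNt) return("buffer")
  }
  "triggering"
}
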