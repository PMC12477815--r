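#' @include AllClasses.R
NULL

#' @describeIn TranscriptModel-class total spliced length (sum of exon
#'   lengths, nt).
#' @param x a \code{TranscriptModel}.
#' @export
transcriptLength <- function(x) {
  stopifnot(is(x, "TranscriptModel"))
  sum(x@exons[, 2L] - x@exons[, 1L])
}

#' @describeIn TranscriptModel-class exon lengths in transcript order (nt).
#' @export
exonLengths <- function(x) {
  stopifnot(is(x, "TranscriptModel"))
  unname(x@exons[, 2L] - x@exons[, 1L])
}

#' @describeIn TranscriptModel-class transcript id accessor.
#' @export
transcriptId <- function(x) { stopifnot(is(x, "TranscriptModel")); x@transcriptId }

#' @describeIn TranscriptModel-class gene id accessor.
#' @export
geneId <- function(x) { stopifnot(is(x, "TranscriptModel")); x@geneId }

#' Convert genomic to spliced-transcript coordinates
#'
#' Both systems are 0-based. Positions falling in introns or outside the
#' transcript return \code{NA}.
#'
#' @param model a \code{TranscriptModel}.
#' @param gpos integer vector of 0-based genomic positions.
#' @return integer vector of 0-based transcript positions (NA where intronic).
#' @export
genomicToTranscript <- function(model, gpos) {
  ex <- model@exons
  lens <- ex[, 2L] - ex[, 1L]
  cum <- c(0L, cumsum(lens))
  vapply(as.integer(gpos), function(g) {
    i <- which(g >= ex[, 1L] & g < ex[, 2L])
    if (length(i) != 1L) return(NA_integer_)
    off <- if (model@strand == "+") g - ex[i, 1L] else ex[i, 2L] - 1L - g
    cum[i] + off
  }, integer(1))
}

#' Convert spliced-transcript to genomic coordinates
#'
#' Inverse of \code{\link{genomicToTranscript}} for exonic positions.
#'
#' @param model a \code{TranscriptModel}.
#' @param tpos integer vector of 0-based transcript positions.
#' @return integer vector of 0-based genomic positions (NA out of range).
#' @export
transcriptToGenomic <- function(model, tpos) {
  ex <- model@exons
  lens <- ex[, 2L] - ex[, 1L]
  cum <- c(0L, cumsum(lens))
  vapply(as.integer(tpos), function(t) {
    if (is.na(t) || t < 0L || t >= cum[length(cum)]) return(NA_integer_)
    i <- findInterval(t, cum, rightmost.closed = FALSE)
    off <- t - cum[i]
    if (model@strand == "+") ex[i, 1L] + off else ex[i, 2L] - 1L - off
  }, integer(1))
}

#' Exon index (transcript order) of a spliced-transcript position
#'
#' @param model a \code{TranscriptModel}.
#' @param tpos 0-based transcript positions.
#' @return 1-based exon indices in transcript orientation.
#' @export
exonIndexOf <- function(model, tpos) {
  cum <- c(0L, cumsum(exonLengths(model)))
  idx <- findInterval(as.integer(tpos), cum, rightmost.closed = FALSE)
  idx[tpos < 0L | tpos >= cum[length(cum)]] <- NA_integer_
  idx
}

#' Spliced transcript sequence
#'
#' @param model a \code{TranscriptModel}.
#' @param genome named \code{DNAStringSet} covering \code{model@chrom}.
#' @return a \code{DNAString} of the spliced transcript (5'->3').
#' @export
splicedSequence <- function(model, genome) {
  chromSeq <- genome[[model@chrom]]
  pieces <- lapply(seq_len(nrow(model@exons)), function(i) {
    s <- Biostrings::subseq(chromSeq,
                            start = model@exons[i, 1L] + 1L,
                            end = model@exons[i, 2L])
    if (model@strand == "-") Biostrings::reverseComplement(s) else s
  })
  do.call(Biostrings::xscat, pieces)
}

#' Parse transcript models from a GTF annotation and genome FASTA
#'
#' Reads exon and CDS records (GTF is 1-based closed; internal storage is
#' 0-based half-open) and returns one \code{\link{TranscriptModel}} per coding
#' transcript. Transcripts without CDS records are skipped with a warning.
#' The CDS stored on the model spans from the first CDS base to the last CDS
#' base present in the annotation (a GTF whose CDS excludes the stop codon
#' yields a model whose \code{cdsEnd} excludes it too).
#'
#' @param annotationFile path to a GTF file with \code{exon} and \code{CDS}
#'   features carrying \code{transcript_id} and \code{gene_id} attributes.
#' @param sequenceFile path to a genome FASTA covering all referenced
#'   chromosomes, or a \code{DNAStringSet}.
#' @return named list of \code{TranscriptModel} (names = transcript ids), with
#'   the genome attached as attribute \code{"genome"}.
#' @export
parseTranscriptModels <- function(annotationFile, sequenceFile) {
  gr <- rtracklayer::import(annotationFile, format = "gtf")
  genome <- if (is(sequenceFile, "DNAStringSet")) sequenceFile
            else Biostrings::readDNAStringSet(sequenceFile)
  names(genome) <- sub("\\s.*$", "", names(genome))

  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  txIds <- as.character(md$transcript_id)

  missingChrom <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                          names(genome))
  if (length(missingChrom))
    stop("chromosome(s) absent from sequence: ",
         paste(missingChrom, collapse = ", "))

  models <- list()
  for (tx in unique(txIds)) {
    sel <- txIds == tx
    sub <- gr[sel]
    subMd <- S4Vectors::mcols(sub)
    isExon <- subMd$type == "exon"
    isCds <- subMd$type == "CDS"
    if (!any(isCds)) {
      warning("transcript ", tx, " has no CDS records; skipped")
      next
    }
    strand <- as.character(GenomicRanges::strand(sub))[1]
    chrom <- as.character(GenomicRanges::seqnames(sub))[1]
    geneId <- as.character(subMd$gene_id)[1]
    biotype <- if ("transcript_biotype" %in% colnames(subMd))
      as.character(subMd$transcript_biotype)[1] else "protein_coding"
    exGr <- sub[isExon]
    # 1-based closed -> 0-based half-open
    ex <- cbind(start = GenomicRanges::start(exGr) - 1L,
                end = GenomicRanges::end(exGr))
    ord <- order(ex[, 1L], decreasing = (strand == "-"))
    ex <- ex[ord, , drop = FALSE]
    cdsGr <- sub[isCds]
    cdsG0 <- GenomicRanges::start(cdsGr) - 1L
    cdsG1 <- GenomicRanges::end(cdsGr) - 1L
    model0 <- TranscriptModel(tx, geneId, chrom, strand, ex,
                              cdsStart = 0L,
                              cdsEnd = sum(ex[, 2L] - ex[, 1L]),
                              biotype = biotype)
    tcoords <- genomicToTranscript(model0, c(cdsG0, cdsG1))
    if (anyNA(tcoords)) {
      warning("transcript ", tx, ": CDS outside exons; skipped")
      next
    }
    models[[tx]] <- TranscriptModel(tx, geneId, chrom, strand, ex,
                                    cdsStart = min(tcoords),
                                    cdsEnd = max(tcoords) + 1L,
                                    biotype = biotype)
  }
  attr(models, "genome") <- genome
  models
}
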