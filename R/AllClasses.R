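#' @import methods
#' @importFrom stats median sd quantile cor var setNames optimize optim
#'   rnbinom rnorm rlnorm runif rbinom lm coef p.adjust as.formula
#'   model.matrix complete.cases dnbinom fitted
#' @importFrom utils head tail write.table read.table modifyList
NULL

#' Transcript model in genomic coordinates
#'
#' Holds the exon/CDS structure of one coding transcript. Exons are stored as
#' 0-based half-open genomic intervals, ordered 5'->3' in transcript
#' orientation (i.e. for minus-strand transcripts the first exon has the
#' largest genomic coordinates). \code{cdsStart}/\code{cdsEnd} are 0-based
#' half-open offsets in spliced transcript coordinates; the CDS includes the
#' stop codon.
#'
#' @slot transcriptId,geneId,chrom,biotype character scalars.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot exons integer matrix with columns \code{start}, \code{end}
#'   (0-based half-open genomic intervals).
#' @slot cdsStart,cdsEnd integer transcript-coordinate offsets.
#'
#' @aliases TranscriptModel-class
#' @exportClass TranscriptModel
setClass("TranscriptModel",
  representation(
    transcriptId = "character",
    geneId = "character",
    chrom = "character",
    strand = "character",
    exons = "matrix",
    cdsStart = "integer",
    cdsEnd = "integer",
    biotype = "character"
  )
)

setValidity("TranscriptModel", function(object) {
  msg <- character()
  ex <- object@exons
  if (ncol(ex) != 2L) msg <- c(msg, "exons must have two columns (start, end)")
  if (!(object@strand %in% c("+", "-")))
    msg <- c(msg, "strand must be '+' or '-'")
  if (any(ex[, 2L] <= ex[, 1L]))
    msg <- c(msg, "exons must be non-empty half-open intervals")
  if (nrow(ex) > 1L) {
    starts <- ex[, 1L]
    ord <- if (object@strand == "+") all(diff(starts) > 0) else all(diff(starts) < 0)
    if (!ord) msg <- c(msg, "exons must be sorted 5'->3' in transcript orientation")
    # non-overlap in genomic space
    g <- ex[order(ex[, 1L]), , drop = FALSE]
    if (any(g[-1L, 1L] < g[-nrow(g), 2L]))
      msg <- c(msg, "exons must not overlap")
  }
  len <- sum(ex[, 2L] - ex[, 1L])
  if (!(object@cdsStart < object@cdsEnd && object@cdsEnd <= len))
    msg <- c(msg, "require cdsStart < cdsEnd <= transcript length")
  if (length(msg)) msg else TRUE
})

#' @describeIn TranscriptModel-class constructor.
#' @param transcriptId,geneId,chrom,strand,exons,cdsStart,cdsEnd,biotype see slots.
#' @export
TranscriptModel <- function(transcriptId, geneId, chrom, strand, exons,
                            cdsStart, cdsEnd, biotype = "protein_coding") {
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  new("TranscriptModel",
      transcriptId = transcriptId, geneId = geneId, chrom = chrom,
      strand = strand, exons = exons,
      cdsStart = as.integer(cdsStart), cdsEnd = as.integer(cdsEnd),
      biotype = biotype)
}

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel", object@transcriptId,
      sprintf("(%s, %s%s)", object@geneId, object@chrom, object@strand), "\n")
  cat("  ", nrow(object@exons), "exons;",
      transcriptLength(object), "nt spliced;",
      "CDS", object@cdsStart, "-", object@cdsEnd,
      sprintf("(%d nt)", object@cdsEnd - object@cdsStart), "\n")
})

#' Rule set for classifying PTCs as NMD-triggering or NMD-evading
#'
#' Two named presets exist: \code{aseRules()} — the canonical rule set used for
#' allele-specific expression variant sets (last exon, last 55 nt of the
#' penultimate exon, start-proximal ~200 nt, all overridden to triggering by a
#' 3'UTR EJC except the start-proximal call) — and \code{dndsRules()}, which
#' additionally applies the long-exon rule with a 500–1000 nt "buffer" zone
#' and uses a 250 nt start-proximal threshold.
#'
#' @slot name character, \code{"ase_default"} or \code{"dnds"}.
#' @slot startProximalNt,penultimateTailNt integer thresholds (nt).
#' @slot triggeringMaxExonNt,evadingMinExonNt integer or NA; the long-exon rule
#'   bounds (dnds only).
#' @slot utr3EjcOverride logical; a 3'UTR EJC flips last-exon/55nt evading
#'   calls to triggering.
#'
#' @aliases NMDRuleSet-class
#' @exportClass NMDRuleSet
setClass("NMDRuleSet",
  representation(
    name = "character",
    startProximalNt = "integer",
    penultimateTailNt = "integer",
    triggeringMaxExonNt = "integer",
    evadingMinExonNt = "integer",
    utr3EjcOverride = "logical"
  )
)

setValidity("NMDRuleSet", function(object) {
  if (!is.na(object@triggeringMaxExonNt) && !is.na(object@evadingMinExonNt) &&
      object@triggeringMaxExonNt >= object@evadingMinExonNt)
    return("triggeringMaxExonNt must be < evadingMinExonNt")
  TRUE
})

#' @describeIn NMDRuleSet-class canonical ASE rule set (200 nt start-proximal,
#'   55 nt penultimate tail, no long-exon rule).
#' @param startProximalNt,penultimateTailNt,utr3EjcOverride overrides.
#' @export
aseRules <- function(startProximalNt = 200L, penultimateTailNt = 55L,
                     utr3EjcOverride = TRUE) {
  new("NMDRuleSet", name = "ase_default",
      startProximalNt = as.integer(startProximalNt),
      penultimateTailNt = as.integer(penultimateTailNt),
      triggeringMaxExonNt = NA_integer_, evadingMinExonNt = NA_integer_,
      utr3EjcOverride = utr3EjcOverride)
}

#' @describeIn NMDRuleSet-class dN/dS-style rule set with the long-exon rule
#'   (triggering requires exon <= 500 nt; exon >= 1000 nt evades; 500-1000 nt
#'   is a buffer zone) and 250 nt start-proximal threshold.
#' @param triggeringMaxExonNt,evadingMinExonNt long-exon rule bounds (nt).
#' @export
dndsRules <- function(startProximalNt = 250L, penultimateTailNt = 55L,
                      triggeringMaxExonNt = 500L, evadingMinExonNt = 1000L,
                      utr3EjcOverride = TRUE) {
  new("NMDRuleSet", name = "dnds",
      startProximalNt = as.integer(startProximalNt),
      penultimateTailNt = as.integer(penultimateTailNt),
      triggeringMaxExonNt = as.integer(triggeringMaxExonNt),
      evadingMinExonNt = as.integer(evadingMinExonNt),
      utr3EjcOverride = utr3EjcOverride)
}

setMethod("show", "NMDRuleSet", function(object) {
  cat("NMDRuleSet <", object@name, ">\n", sep = "")
  cat("  start-proximal:", object@startProximalNt, "nt;",
      "penultimate tail:", object@penultimateTailNt, "nt\n")
  if (!is.na(object@evadingMinExonNt))
    cat("  long-exon rule: triggering <=", object@triggeringMaxExonNt,
        "nt, evading >=", object@evadingMinExonNt, "nt (buffer between)\n")
  cat("  3'UTR EJC override:", object@utr3EjcOverride, "\n")
})

#' Result of a tissue-level randomization test
#'
#' Returned by \code{\link{itnvdTest}} and \code{\link{tndTest}}, and reused by
#' the per-PTC variability tests. \code{deviation} is observed minus the median
#' of the permutation null; \code{pValue} uses the
#' \code{(exceedances + 1) / nIter} formula, so its floor is \code{1/nIter}.
#'
#' @slot statisticName e.g. \code{"ITNVD"} or \code{"TND"}.
#' @slot tissue target tissue for TND, \code{NA} otherwise.
#' @slot observed observed statistic.
#' @slot nullValues numeric vector of permutation statistics.
#' @slot deviation observed - median(null).
#' @slot pValue permutation p-value.
#' @slot nIter,seed integers.
#'
#' @aliases RandomizationResult-class
#' @exportClass RandomizationResult
setClass("RandomizationResult",
  representation(
    statisticName = "character",
    tissue = "character",
    observed = "numeric",
    nullValues = "numeric",
    deviation = "numeric",
    pValue = "numeric",
    nIter = "integer",
    seed = "integer"
  )
)

setValidity("RandomizationResult", function(object) {
  msg <- character()
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (object@pValue * object@nIter < 1 - 1e-9)
    msg <- c(msg, "pValue below the 1/nIter formula floor")
  if (!is.finite(object@deviation)) msg <- c(msg, "deviation must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RandomizationResult", function(object) {
  cat(object@statisticName,
      if (!is.na(object@tissue)) sprintf("[%s]", object@tissue) else "",
      "randomization test\n")
  cat(sprintf("  observed = %.4g; null median = %.4g; deviation = %.4g\n",
              object@observed, median(object@nullValues), object@deviation))
  cat(sprintf("  p = %.3g (%d iterations, seed %d)\n",
              object@pValue, object@nIter, object@seed))
})

#' Summarize the permutation null of a RandomizationResult
#'
#' @param object a \code{RandomizationResult}.
#' @return named numeric vector (median, mean, sd, q2.5, q97.5, nIter).
#' @export
nullSummary <- function(object) {
  stopifnot(is(object, "RandomizationResult"))
  q <- quantile(object@nullValues, c(0.025, 0.975), names = FALSE)
  c(median = median(object@nullValues), mean = mean(object@nullValues),
    sd = sd(object@nullValues), q2.5 = q[1], q97.5 = q[2],
    nIter = object@nIter)
}

#' Duplicated gain/loss copy-number matrix
#'
#' GISTIC-style gene-level dosage scores split into an amplification block
#' (negative scores zeroed) stacked over a deletion block (positive scores
#' zeroed), so that \code{amp + del} reconstructs the original score for every
#' gene and sample. Row metadata keeps the genomic order used for loading
#' autocorrelation.
#'
#' @slot scores numeric matrix, rows = gene x \{amp, del\}, columns = samples.
#' @slot rowInfo data.frame with columns \code{gene}, \code{type}
#'   (\code{"amp"}/\code{"del"}), \code{chrom}, \code{start}, \code{arm}.
#'
#' @aliases GainLossMatrix-class
#' @exportClass GainLossMatrix
setClass("GainLossMatrix",
  representation(scores = "matrix", rowInfo = "data.frame"))

setValidity("GainLossMatrix", function(object) {
  msg <- character()
  if (nrow(object@scores) != nrow(object@rowInfo))
    msg <- c(msg, "rowInfo must describe every score row")
  amp <- object@rowInfo$type == "amp"
  if (any(object@scores[amp, , drop = FALSE] < 0))
    msg <- c(msg, "amplification rows must be >= 0")
  if (any(object@scores[!amp, , drop = FALSE] > 0))
    msg <- c(msg, "deletion rows must be <= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GainLossMatrix", function(object) {
  cat("GainLossMatrix:", nrow(object@scores), "rows (",
      sum(object@rowInfo$type == "amp"), "genes x {amp, del} ) x",
      ncol(object@scores), "samples\n")
})

#' @describeIn GainLossMatrix-class score matrix accessor.
#' @param x a \code{GainLossMatrix}.
#' @export
glScores <- function(x) { stopifnot(is(x, "GainLossMatrix")); x@scores }

#' @describeIn GainLossMatrix-class row metadata accessor.
#' @export
glRowInfo <- function(x) { stopifnot(is(x, "GainLossMatrix")); x@rowInfo }
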