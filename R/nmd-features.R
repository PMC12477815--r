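#' Annotate NMD-triggering features of one transcript
#'
#' Detects (i) qualifying upstream open reading frames (uORFs): AUG-initiated
#' ORFs that start and terminate entirely within the 5'UTR (stop codon before
#' the CDS start, so the uORF does not overlap the CDS) with a minimum length
#' (start through stop codon, default 30 nt); (ii) 3'UTR exon-junction
#' complexes: exon-exon junctions downstream of the stop codon, with
#' \code{has3UtrEjc} true iff some junction lies strictly more than 50 nt
#' downstream of the first nt after the stop codon; (iii) the GC fraction of
#' the 3'UTR. Overlapping uORFs are counted individually (every qualifying AUG
#' opens one uORF).
#'
#' @param model a \code{\link{TranscriptModel}}.
#' @param genome named \code{DNAStringSet}.
#' @param minUorfNt minimum uORF length in nt, start codon through stop codon.
#' @param ejcMinDistanceNt junctions must lie strictly more than this many nt
#'   downstream of the stop to count as a 3'UTR EJC (default 50).
#' @return an object of class \code{NMDFeatureProfile}: a list with elements
#'   \code{transcriptId}, \code{uorfs} (data.frame \code{start}, \code{length},
#'   0-based 5'UTR coordinates), \code{nQualifyingUorfs}, \code{has3UtrEjc},
#'   \code{ejcDistancesNt}, \code{utr3Gc} (NA when the 3'UTR is empty) and
#'   \code{utr3Defined}.
#' @export
annotateNmdFeatures <- function(model, genome, minUorfNt = 30L,
                                ejcMinDistanceNt = 50L) {
  txSeq <- splicedSequence(model, genome)
  seqChar <- as.character(txSeq)
  cdsStart <- model@cdsStart
  cdsEnd <- model@cdsEnd
  txLen <- transcriptLength(model)

  # --- uORFs in the 5'UTR ---------------------------------------------------
  utr5 <- substr(seqChar, 1L, cdsStart)  # may be empty
  uorfStart <- integer(0); uorfLen <- integer(0)
  if (nchar(utr5) >= minUorfNt) {
    atg <- gregexpr("ATG", utr5, fixed = TRUE)[[1]]
    atg <- atg[atg > 0]
    stops <- c("TAA", "TAG", "TGA")
    for (p in atg) {              # p is 1-based position of the A
      pos <- p
      found <- FALSE
      while (pos + 2L <= cdsStart) {   # codon fully within the 5'UTR
        codon <- substr(seqChar, pos, pos + 2L)
        if (pos > p && codon %in% stops) { found <- TRUE; break }
        pos <- pos + 3L
      }
      if (found) {
        len <- pos + 3L - p
        if (len >= minUorfNt) {
          uorfStart <- c(uorfStart, p - 1L)  # 0-based 5'UTR coordinate
          uorfLen <- c(uorfLen, len)
        }
      }
    }
  }

  # --- 3'UTR junctions ------------------------------------------------------
  junctions <- cumsum(exonLengths(model))
  junctions <- junctions[-length(junctions)]        # internal junctions only
  ejcDist <- junctions[junctions >= cdsEnd] - cdsEnd
  has3UtrEjc <- any(ejcDist > ejcMinDistanceNt)

  # --- 3'UTR GC -------------------------------------------------------------
  utr3Len <- txLen - cdsEnd
  if (utr3Len > 0L) {
    utr3 <- Biostrings::subseq(txSeq, start = cdsEnd + 1L, end = txLen)
    gc <- sum(Biostrings::letterFrequency(utr3, c("G", "C"))) / utr3Len
    utr3Defined <- TRUE
  } else {
    gc <- NA_real_
    utr3Defined <- FALSE
  }

  structure(list(
    transcriptId = model@transcriptId,
    uorfs = data.frame(start = uorfStart, length = uorfLen),
    nQualifyingUorfs = length(uorfStart),
    has3UtrEjc = has3UtrEjc,
    ejcDistancesNt = as.integer(ejcDist),
    utr3Gc = gc,
    utr3Defined = utr3Defined
  ), class = "NMDFeatureProfile")
}

#' @export
print.NMDFeatureProfile <- function(x, ...) {
  cat("NMDFeatureProfile", x$transcriptId, "\n")
  cat("  qualifying uORFs:", x$nQualifyingUorfs,
      "| 3'UTR EJC:", x$has3UtrEjc,
      "| 3'UTR GC:", if (is.na(x$utr3Gc)) "undefined" else round(x$utr3Gc, 3),
      "\n")
  invisible(x)
}

#' Annotate NMD features for a list of transcript models
#'
#' @param models list of \code{TranscriptModel} (e.g. from
#'   \code{\link{parseTranscriptModels}}).
#' @param genome named \code{DNAStringSet}; defaults to the genome attached to
#'   \code{models}.
#' @param ... passed to \code{\link{annotateNmdFeatures}}.
#' @return data.frame with one row per transcript: \code{transcript_id},
#'   \code{gene_id}, \code{n_qualifying_uorfs}, \code{has_3utr_ejc},
#'   \code{utr3_gc}, \code{utr3_defined}, \code{n_exons},
#'   \code{transcript_length}.
#' @export
annotateNmdFeatureTable <- function(models, genome = attr(models, "genome"),
                                    ...) {
  rows <- lapply(models, function(m) {
    p <- annotateNmdFeatures(m, genome, ...)
    data.frame(transcript_id = m@transcriptId, gene_id = m@geneId,
               n_qualifying_uorfs = p$nQualifyingUorfs,
               has_3utr_ejc = p$has3UtrEjc,
               utr3_gc = p$utr3Gc, utr3_defined = p$utr3Defined,
               n_exons = nrow(m@exons),
               transcript_length = transcriptLength(m))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build NMD target gene sets from study lists
#'
#' Combines per-study NMD-target gene lists into the derived sets used by the
#' ETG estimator: one set per study, a consensus set (genes reported in at
#' least two independent studies), the union of all studies, and two random
#' negative-control sets drawn from genes absent from every study list — one
#' restricted to genes whose transcripts carry NMD-triggering features, one to
#' genes without any.
#'
#' @param studyGeneLists named list (>= 2 entries) of character vectors of
#'   gene ids, one per study.
#' @param geneFeatureTable data.frame with columns \code{gene_id} and
#'   \code{has_features} (logical: any transcript of the gene carries a
#'   3'UTR EJC or qualifying uORFs), defining the random-control pool.
#' @param nRandom size of each random control set.
#' @param rngSeed integer seed for the random draws.
#' @return named list of character vectors: the study sets, \code{consensus},
#'   \code{all}, \code{random_with_features}, \code{random_without_features}.
#' @export
buildGeneSets <- function(studyGeneLists, geneFeatureTable, nRandom = 50L,
                          rngSeed = 1L) {
  if (length(studyGeneLists) < 2L)
    stop("need at least 2 study gene lists")
  allGenes <- unique(unlist(studyGeneLists, use.names = FALSE))
  counts <- rowSums(vapply(studyGeneLists,
                           function(g) allGenes %in% g,
                           logical(length(allGenes))))
  sets <- studyGeneLists
  sets$consensus <- allGenes[counts >= 2L]
  sets$all <- allGenes

  pool <- geneFeatureTable[!(geneFeatureTable$gene_id %in% allGenes), ]
  withPool <- pool$gene_id[pool$has_features]
  withoutPool <- pool$gene_id[!pool$has_features]
  if (nRandom > length(withPool))
    stop("random control request (", nRandom,
         ") larger than eligible pool with features (", length(withPool), ")")
  if (nRandom > length(withoutPool))
    stop("random control request (", nRandom,
         ") larger than eligible pool without features (",
         length(withoutPool), ")")
  rng <- local({ set.seed(rngSeed); NULL })
  set.seed(rngSeed)
  sets$random_with_features <- sort(sample(withPool, nRandom))
  sets$random_without_features <- sort(sample(withoutPool, nRandom))
  sets
}

#' Select the NMD target / control transcript pair of one gene
#'
#' Targets must carry start and stop codons, reach a median expression of
#' \code{log(TPM) >= 1} over the reference cohort, and carry either a 3'UTR
#' EJC or at least two qualifying uORFs; among qualifying targets the one with
#' the highest 3'UTR GC content wins (ties broken by lexicographic transcript
#' id). Controls need start and stop codons, \code{log(TPM) >= 3}, and no
#' NMD-triggering features; the most expressed qualifying control is paired.
#' The pair is emitted only when the target/control TPM ratio is <= 0.9 and,
#' when a wild-type cell-line expression ratio is supplied for the target,
#' that ratio is also <= 0.9.
#'
#' @param geneTable data.frame of the gene's transcripts with columns
#'   \code{transcript_id}, \code{gene_id}, \code{median_log_tpm},
#'   \code{has_3utr_ejc}, \code{n_qualifying_uorfs}, \code{utr3_gc}, and
#'   optionally \code{has_start_stop} (default TRUE).
#' @param thresholds list overriding \code{targetMinLogTpm} (1),
#'   \code{controlMinLogTpm} (3), \code{maxRatio} (0.9), \code{minUorfs} (2).
#' @param wildtypeCelllineRatios optional named numeric vector of mean
#'   wild-type cell-line target/control expression ratios, keyed by target
#'   transcript id.
#' @param logBase base of \code{median_log_tpm} (default natural log).
#' @return one-row data.frame (gene_id, target_id, control_id,
#'   target_median_logtpm, control_median_logtpm, expression_ratio,
#'   target_utr3_gc, wildtype_cellline_ratio) or \code{NULL} when no valid
#'   pair exists.
#' @export
selectTargetControlPairs <- function(geneTable, thresholds = list(),
                                     wildtypeCelllineRatios = NULL,
                                     logBase = exp(1)) {
  th <- modifyList(list(targetMinLogTpm = 1, controlMinLogTpm = 3,
                        maxRatio = 0.9, minUorfs = 2L), thresholds)
  if (is.null(geneTable$has_start_stop))
    geneTable$has_start_stop <- TRUE

  isTarget <- geneTable$has_start_stop &
    geneTable$median_log_tpm >= th$targetMinLogTpm &
    (geneTable$has_3utr_ejc | geneTable$n_qualifying_uorfs >= th$minUorfs)
  isControl <- geneTable$has_start_stop &
    geneTable$median_log_tpm >= th$controlMinLogTpm &
    !geneTable$has_3utr_ejc & geneTable$n_qualifying_uorfs == 0L
  if (!any(isTarget) || !any(isControl)) return(NULL)

  tg <- geneTable[isTarget, , drop = FALSE]
  tg <- tg[order(-tg$utr3_gc, tg$transcript_id), , drop = FALSE]
  target <- tg[1L, ]
  ct <- geneTable[isControl & geneTable$transcript_id != target$transcript_id,
                  , drop = FALSE]
  if (!nrow(ct)) return(NULL)
  ct <- ct[order(-ct$median_log_tpm, ct$transcript_id), , drop = FALSE]
  control <- ct[1L, ]

  ratio <- logBase^(target$median_log_tpm - control$median_log_tpm)
  if (ratio > th$maxRatio) return(NULL)
  wtRatio <- NA_real_
  if (!is.null(wildtypeCelllineRatios) &&
      target$transcript_id %in% names(wildtypeCelllineRatios)) {
    wtRatio <- unname(wildtypeCelllineRatios[[target$transcript_id]])
    if (wtRatio > th$maxRatio) return(NULL)
  }
  data.frame(gene_id = target$gene_id,
             target_id = target$transcript_id,
             control_id = control$transcript_id,
             target_median_logtpm = target$median_log_tpm,
             control_median_logtpm = control$median_log_tpm,
             expression_ratio = ratio,
             target_utr3_gc = target$utr3_gc,
             wildtype_cellline_ratio = wtRatio)
}

#' Select target/control pairs for every gene of a transcript table
#'
#' @param transcriptTable a feature/expression table covering many genes (the
#'   column contract of \code{\link{selectTargetControlPairs}}).
#' @param ... passed to \code{\link{selectTargetControlPairs}}.
#' @return data.frame of pairs (possibly 0 rows).
#' @export
selectPairsForGenes <- function(transcriptTable, ...) {
  pairs <- lapply(split(transcriptTable, transcriptTable$gene_id),
                  selectTargetControlPairs, ...)
  pairs <- pairs[!vapply(pairs, is.null, logical(1))]
  if (!length(pairs))
    return(data.frame(gene_id = character(), target_id = character(),
                      control_id = character()))
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  out
}
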