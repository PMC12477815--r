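#' Per-individual filtering cascade of the ETG method
#'
#' Applies, for one individual and one NMD gene set, the endogenous
#' target-gene filters: a cohort prevalence filter (a pair is dropped when
#' both of its transcripts fail \code{log2(raw count) >= 1} in at least 50\%
#' of the individuals of the same tissue cohort), removal of non-coding
#' transcripts, removal of transcripts overlapping the individual's truncating
#' mutation / CNA exclusion intervals, removal of pairs whose two members are
#' both zero in this individual, a minimum of 2 surviving pairs (otherwise no
#' estimate), and a seeded subsampling cap of 50 pairs for every set except
#' the consensus set.
#'
#' @param pairs data.frame of target/control pairs with columns
#'   \code{gene_id}, \code{target_id}, \code{control_id}.
#' @param counts integer matrix of raw transcript counts, transcripts x
#'   samples (rownames = transcript ids, colnames = sample ids).
#' @param individualId sample to build design rows for (must be a column of
#'   \code{counts}).
#' @param sampleTissues optional named character vector mapping sample id to
#'   tissue/cancer type; the prevalence filter then uses only samples of the
#'   individual's tissue (whole-cohort fallback when NULL).
#' @param transcriptInfo optional data.frame (\code{transcript_id},
#'   \code{is_coding}, \code{transcript_length}, and \code{chrom},
#'   \code{start}, \code{end} genomic span for exclusion overlap).
#' @param exclusions optional data.frame of per-individual exclusion intervals
#'   (\code{individual_id}, \code{chrom}, \code{start}, \code{end}; 0-based
#'   half-open).
#' @param nmdSet name of the gene set (the \code{"consensus"} set is exempt
#'   from the 50-pair cap).
#' @param config list overriding \code{prevalenceFraction} (0.5),
#'   \code{minLog2Count} (1), \code{minPairs} (2), \code{maxPairs} (50).
#' @param rngSeed global seed; the subsampling uses a per-individual child
#'   seed derived from it (recorded as attribute \code{"seed"}).
#' @return design-row data.frame (\code{raw_count}, \code{is_nmd_target},
#'   \code{gene_label}, \code{transcript_id}, \code{transcript_length}), with
#'   0 rows when fewer than \code{minPairs} pairs survive.
#' @export
filterEtgPairs <- function(pairs, counts, individualId, sampleTissues = NULL,
                           transcriptInfo = NULL, exclusions = NULL,
                           nmdSet = "consensus", config = list(),
                           rngSeed = 1L) {
  cfg <- modifyList(list(prevalenceFraction = 0.5, minLog2Count = 1,
                         minPairs = 2L, maxPairs = 50L), config)
  if (!(individualId %in% colnames(counts)))
    stop("unknown individual: ", individualId)

  cohort <- colnames(counts)
  if (!is.null(sampleTissues) && individualId %in% names(sampleTissues)) {
    tis <- sampleTissues[[individualId]]
    cohort <- intersect(cohort, names(sampleTissues)[sampleTissues == tis])
  }

  empty <- data.frame(raw_count = integer(), is_nmd_target = integer(),
                      gene_label = character(), transcript_id = character(),
                      transcript_length = integer())

  known <- pairs$target_id %in% rownames(counts) &
    pairs$control_id %in% rownames(counts)
  pairs <- pairs[known, , drop = FALSE]
  if (!nrow(pairs)) return(empty)

  # cohort prevalence: log2(count) >= minLog2Count in >= 50% of cohort
  passFrac <- function(tx) {
    mean(log2(pmax(counts[tx, cohort], 0) + 0) >= cfg$minLog2Count)
  }
  tFrac <- vapply(pairs$target_id, passFrac, numeric(1))
  cFrac <- vapply(pairs$control_id, passFrac, numeric(1))
  pairs <- pairs[!(tFrac < cfg$prevalenceFraction &
                   cFrac < cfg$prevalenceFraction), , drop = FALSE]

  if (!is.null(transcriptInfo)) {
    info <- transcriptInfo[match(c(pairs$target_id, pairs$control_id),
                                 transcriptInfo$transcript_id), ]
    if (!is.null(transcriptInfo$is_coding)) {
      nonCoding <- matrix(!info$is_coding, ncol = 2)
      pairs <- pairs[!(nonCoding[, 1] | nonCoding[, 2]), , drop = FALSE]
    }
    if (!is.null(exclusions) && nrow(pairs)) {
      ex <- exclusions[exclusions$individual_id == individualId, , drop = FALSE]
      if (nrow(ex)) {
        overlaps <- function(tx) {
          ti <- transcriptInfo[transcriptInfo$transcript_id == tx, ]
          if (!nrow(ti) || is.null(ti$chrom)) return(FALSE)
          any(ex$chrom == ti$chrom & ex$start < ti$end & ex$end > ti$start)
        }
        hit <- vapply(pairs$target_id, overlaps, logical(1)) |
          vapply(pairs$control_id, overlaps, logical(1))
        pairs <- pairs[!hit, , drop = FALSE]
      }
    }
  }

  if (nrow(pairs)) {
    bothZero <- counts[pairs$target_id, individualId] == 0 &
      counts[pairs$control_id, individualId] == 0
    pairs <- pairs[!bothZero, , drop = FALSE]
  }
  if (nrow(pairs) < cfg$minPairs) return(empty)

  seedUsed <- .individualSeed(rngSeed, individualId)
  if (nmdSet != "consensus" && nrow(pairs) > cfg$maxPairs) {
    set.seed(seedUsed)
    pairs <- pairs[sort(sample.int(nrow(pairs), cfg$maxPairs)), , drop = FALSE]
  }

  txLen <- function(tx) {
    if (is.null(transcriptInfo) ||
        !tx %in% transcriptInfo$transcript_id) return(NA_integer_)
    transcriptInfo$transcript_length[match(tx, transcriptInfo$transcript_id)]
  }
  rows <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    data.frame(
      raw_count = as.integer(counts[c(p$target_id, p$control_id), individualId]),
      is_nmd_target = c(1L, 0L),
      gene_label = p$gene_id,
      transcript_id = c(p$target_id, p$control_id),
      transcript_length = c(txLen(p$target_id), txLen(p$control_id)))
  }))
  if (all(is.na(rows$transcript_length))) rows$transcript_length <- NULL
  attr(rows, "seed") <- seedUsed
  rows
}

#' Estimate ETG iNMDeff for one individual
#'
#' Fits the pooled negative-binomial regression on the filtered target/control
#' design rows and returns the sign-flipped NMD-target coefficient:
#' \code{inmdeff = -beta1}, so that \code{exp(-inmdeff)} is the modeled
#' target/control expression ratio and higher values mean more efficient NMD.
#'
#' @param individualId,nmdSet identifiers carried into the output.
#' @param rows design rows from \code{\link{filterEtgPairs}} (non-empty).
#' @param logLength passed to \code{\link{fitNbGlm}}.
#' @return one-row data.frame: \code{individual_id}, \code{nmd_set},
#'   \code{inmdeff}, \code{standard_error}, \code{n_units} (pairs),
#'   \code{dispersion}, \code{converged}, \code{seed}.
#' @export
estimateInmdeffEtg <- function(individualId, nmdSet, rows, logLength = FALSE) {
  if (!nrow(rows)) stop("no design rows; individual was filtered out")
  fit <- fitNbGlm(rows, logLength = logLength)
  .inmdeffRecord(individualId, nmdSet, fit, nUnits = nrow(rows) / 2L,
                 seedUsed = attr(rows, "seed") %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the ETG estimator over every sample of a count matrix
#'
#' Convenience cohort driver: filter + fit per individual.
#'
#' @inheritParams filterEtgPairs
#' @param ... passed to \code{\link{filterEtgPairs}}.
#' @return data.frame of estimates, one row per estimable individual.
#' @export
estimateCohortEtg <- function(pairs, counts, nmdSet = "consensus", ...) {
  out <- lapply(colnames(counts), function(ind) {
    rows <- filterEtgPairs(pairs, counts, ind, nmdSet = nmdSet, ...)
    if (!nrow(rows)) return(NULL)
    estimateInmdeffEtg(ind, nmdSet, rows)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}
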