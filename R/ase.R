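#' Per-individual filtering cascade of the ASE method
#'
#' Applies, for one individual and one NMD variant set, the allele-specific
#' expression filters: PASS heterozygous germline variants only; minimum total
#' read coverage (WT + MUT) of 5 for nonsense/synonymous/missense SNVs and 2
#' for indels; population MAF <= 20\% (strictly greater is excluded);
#' removal of variants in non-coding or single-exon transcripts, in genes
#' under positive selection, or in the most constrained LOEUF bin (default:
#' lowest 10\%); removal of variants co-occurring with somatic truncating
#' events or CNAs (when flagged); set-specific rules (the triggering set drops
#' NMD-evading PTCs and frameshifts without a predicted PTC, and vice versa;
#' the synonymous set drops variants in any NMD-All gene); in GTex mode,
#' removal of variants observed in a single tissue; a minimum of 3 surviving
#' variants (otherwise no estimate); and a seeded cap of 100 variants.
#'
#' @param variants data.frame with columns \code{variant_id}, \code{gene_id},
#'   \code{variant_class} (\code{nonsense}, \code{frameshift_indel},
#'   \code{inframe_indel}, \code{synonymous}, \code{missense}),
#'   \code{nmd_class} (\code{triggering}/\code{evading}/\code{buffer}/
#'   \code{none}), \code{filter_status}, \code{genotype}
#'   (\code{het}/\code{hom}), \code{population_maf},
#'   \code{gene_loeuf_percentile} (fraction, low = constrained),
#'   \code{wt_count}, \code{mut_count}; optional \code{n_exons},
#'   \code{is_coding}, \code{somatic_overlap}, \code{n_tissues}.
#' @param individualId identifier used only to derive the subsampling seed.
#' @param variantSet one of \code{"triggering"}, \code{"evading"},
#'   \code{"synonymous"}.
#' @param config list overriding \code{minCoverageSnv} (5),
#'   \code{minCoverageIndel} (2), \code{maxMaf} (0.2),
#'   \code{loeufConstrainedFraction} (0.1), \code{minVariants} (3),
#'   \code{maxVariants} (100), \code{gtexMode} (FALSE).
#' @param auxiliaryLists list with optional character vectors
#'   \code{positiveSelection} and \code{nmdAllGenes}.
#' @param rngSeed global seed for the variant cap.
#' @return design-row data.frame (\code{raw_count}, \code{is_mut_allele},
#'   \code{gene_label}, \code{variant_id}), two rows per variant, 0 rows when
#'   fewer than \code{minVariants} survive.
#' @export
filterAseVariants <- function(variants, individualId = "sample",
                              variantSet = c("triggering", "evading",
                                             "synonymous"),
                              config = list(), auxiliaryLists = list(),
                              rngSeed = 1L) {
  if (!is.character(variantSet) ||
      !(variantSet[1] %in% c("triggering", "evading", "synonymous")))
    stop("unknown variant set: ", variantSet[1])
  variantSet <- variantSet[1]
  cfg <- modifyList(list(minCoverageSnv = 5L, minCoverageIndel = 2L,
                         maxMaf = 0.2, loeufConstrainedFraction = 0.1,
                         minVariants = 3L, maxVariants = 100L,
                         gtexMode = FALSE), config)
  v <- variants
  empty <- data.frame(raw_count = integer(), is_mut_allele = integer(),
                      gene_label = character(), variant_id = character())

  keep <- v$filter_status == "PASS" & v$genotype == "het"
  cov <- v$wt_count + v$mut_count
  isIndel <- v$variant_class %in% c("frameshift_indel", "inframe_indel")
  keep <- keep & ifelse(isIndel, cov >= cfg$minCoverageIndel,
                        cov >= cfg$minCoverageSnv)
  keep <- keep & v$population_maf <= cfg$maxMaf
  if (!is.null(v$is_coding)) keep <- keep & v$is_coding
  if (!is.null(v$n_exons)) keep <- keep & v$n_exons >= 2L
  if (!is.null(auxiliaryLists$positiveSelection))
    keep <- keep & !(v$gene_id %in% auxiliaryLists$positiveSelection)
  if (!is.null(v$gene_loeuf_percentile))
    keep <- keep & v$gene_loeuf_percentile > cfg$loeufConstrainedFraction
  if (!is.null(v$somatic_overlap))
    keep <- keep & !v$somatic_overlap
  if (cfg$gtexMode && !is.null(v$n_tissues))
    keep <- keep & v$n_tissues > 1L

  keep <- keep & switch(variantSet,
    triggering = v$variant_class %in% c("nonsense", "frameshift_indel") &
      v$nmd_class == "triggering",
    evading = v$variant_class %in% c("nonsense", "frameshift_indel") &
      v$nmd_class == "evading",
    synonymous = {
      s <- v$variant_class == "synonymous"
      if (!is.null(auxiliaryLists$nmdAllGenes))
        s <- s & !(v$gene_id %in% auxiliaryLists$nmdAllGenes)
      s
    })

  v <- v[keep & !is.na(keep), , drop = FALSE]
  if (nrow(v) < cfg$minVariants) return(empty)

  seedUsed <- .individualSeed(rngSeed, individualId)
  if (nrow(v) > cfg$maxVariants) {
    set.seed(seedUsed)
    v <- v[sort(sample.int(nrow(v), cfg$maxVariants)), , drop = FALSE]
  }

  rows <- data.frame(
    raw_count = as.integer(rbind(v$wt_count, v$mut_count)),
    is_mut_allele = rep(c(0L, 1L), nrow(v)),
    gene_label = rep(v$gene_id, each = 2L),
    variant_id = rep(v$variant_id, each = 2L))
  attr(rows, "seed") <- seedUsed
  rows
}

#' Estimate ASE iNMDeff for one individual
#'
#' Negative-binomial regression of allele counts on the mutant-allele
#' indicator with gene fixed effects (one row per allele):
#' \code{log(mu) = b0 + b1 * NMDtarget + geneID}. The estimate is
#' \code{inmdeff = -b1}; \code{exp(-inmdeff)} is the modeled MUT/WT allele
#' expression ratio.
#'
#' @param individualId,variantSet identifiers carried into the output.
#' @param rows design rows from \code{\link{filterAseVariants}} (>= 3
#'   variants, both alleles each).
#' @return one-row estimate data.frame shaped as in
#'   \code{\link{estimateInmdeffEtg}} (\code{n_units} = variants).
#' @export
estimateInmdeffAse <- function(individualId, variantSet, rows) {
  if (!nrow(rows)) stop("no design rows; individual was filtered out")
  fit <- fitNbGlm(data.frame(raw_count = rows$raw_count,
                             is_nmd_target = rows$is_mut_allele,
                             gene_label = rows$gene_label))
  .inmdeffRecord(individualId, variantSet, fit, nUnits = nrow(rows) / 2L,
                 seedUsed = attr(rows, "seed") %||% NA_integer_)
}
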