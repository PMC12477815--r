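#' Per-PTC NMD efficiency score
#'
#' \code{pNMDeff = -log2(MUT / WT)} over the RNA allele counts at one
#' heterozygous PTC locus. A score of 0 means no allele-specific degradation,
#' 1 means the mutant allele is expressed at half the wild-type level, and
#' complete degradation of the mutant allele gives \code{+Inf}. A wild-type
#' count of zero leaves the score undefined and is an error (callers exclude
#' the locus).
#'
#' @param wtCount,mutCount nonnegative allele read counts (vectorized).
#' @return numeric pNMDeff values.
#' @export
computePnmdeff <- function(wtCount, mutCount) {
  if (any(wtCount < 0 | mutCount < 0)) stop("counts must be nonnegative")
  if (any(wtCount == 0))
    stop("pNMDeff undefined for wt_count = 0; exclude the locus")
  res <- -log2(mutCount / wtCount)
  res + 0          # map IEEE -0 (balanced counts) to plain 0
}

#' Exclusion filters for pNMDeff records
#'
#' Applies the per-PTC exclusions: indels without a predicted downstream PTC;
#' co-occurring truncating variants or CNA overlap; single-exon transcripts
#' without additional 3'UTR splice sites; genes in the most constrained LOEUF
#' decile or under positive selection; homozygous variants; somatic DNA
#' variant allele frequency > 20\%; and low or unstable transcript expression
#' (median TPM < 5 or coefficient of variation > 0.5).
#'
#' @param records data.frame with \code{individual_id}, \code{variant_id},
#'   \code{wt_count}, \code{mut_count} and the annotation columns referenced
#'   by the filters (any of \code{variant_class}, \code{has_ptc},
#'   \code{somatic_overlap}, \code{n_exons}, \code{has_3utr_ejc},
#'   \code{gene_loeuf_percentile}, \code{positive_selection},
#'   \code{genotype}, \code{somatic_vaf}, \code{median_tpm},
#'   \code{expression_cv}; absent columns skip that filter).
#' @param config list overriding \code{minMedianTpm} (5), \code{maxCv} (0.5),
#'   \code{maxVaf} (0.2), \code{loeufConstrainedFraction} (0.1).
#' @return filtered records with a \code{pnmdeff} column added (records with
#'   \code{wt_count == 0} are excluded as undefined).
#' @export
applyPnmdeffFilters <- function(records, config = list()) {
  cfg <- modifyList(list(minMedianTpm = 5, maxCv = 0.5, maxVaf = 0.2,
                         loeufConstrainedFraction = 0.1), config)
  r <- records
  keep <- rep(TRUE, nrow(r))
  if (!is.null(r$variant_class) && !is.null(r$has_ptc))
    keep <- keep & !(r$variant_class %in%
                       c("frameshift_indel", "inframe_indel") & !r$has_ptc)
  if (!is.null(r$somatic_overlap)) keep <- keep & !r$somatic_overlap
  if (!is.null(r$n_exons)) {
    singleExon <- r$n_exons == 1L
    if (!is.null(r$has_3utr_ejc)) singleExon <- singleExon & !r$has_3utr_ejc
    keep <- keep & !singleExon
  }
  if (!is.null(r$gene_loeuf_percentile))
    keep <- keep & r$gene_loeuf_percentile > cfg$loeufConstrainedFraction
  if (!is.null(r$positive_selection)) keep <- keep & !r$positive_selection
  if (!is.null(r$genotype)) keep <- keep & r$genotype == "het"
  if (!is.null(r$somatic_vaf)) keep <- keep & r$somatic_vaf <= cfg$maxVaf
  if (!is.null(r$median_tpm)) keep <- keep & r$median_tpm >= cfg$minMedianTpm
  if (!is.null(r$expression_cv)) keep <- keep & r$expression_cv <= cfg$maxCv
  keep <- keep & r$wt_count > 0
  r <- r[keep & !is.na(keep), , drop = FALSE]
  if (nrow(r)) r$pnmdeff <- computePnmdeff(r$wt_count, r$mut_count)
  r
}

#' Inter-/intra-individual pNMDeff variability test
#'
#' Measures whether pNMDeff values are structured by individual (intra mode:
#' PTCs within one individual resemble each other) or by PTC (inter mode:
#' individuals sharing one common PTC resemble each other), against a
#' randomized baseline obtained by permuting pNMDeff values over the whole
#' record table.
#'
#' With \code{metric = "spearman"}, each iteration samples two PTCs per
#' individual (intra) or two individuals per shared PTC (inter) and computes
#' the Spearman correlation of the two sampled score vectors; the observed
#' statistic is the mean correlation over iterations and the upper permutation
#' tail gives the p-value. With \code{metric = "variance"}, the observed
#' statistic is the mean within-group variance (groups = individuals with >= 3
#' PTCs, or PTCs shared by >= 3 individuals); structure shows as a variance
#' deficit, so \code{excessVariance = mean(randomized) - observed} and the
#' lower tail gives the p-value. Non-finite pNMDeff values (\code{+Inf}) are
#' excluded.
#'
#' @param records data.frame with \code{individual_id}, \code{variant_id},
#'   \code{pnmdeff}.
#' @param mode \code{"intra"} or \code{"inter"}.
#' @param metric \code{"spearman"} or \code{"variance"}.
#' @param nIter iterations (default 1000).
#' @param seed RNG seed.
#' @return list of class \code{VariabilityResult}: \code{mode}, \code{metric},
#'   \code{observed}, \code{randomized} (vector), \code{randomizedSummary},
#'   \code{excessVariance} (variance metric only), \code{pValue},
#'   \code{nIterations}, \code{testable} (FALSE with a \code{reason} when the
#'   sharing structure is insufficient).
#' @export
variabilityTest <- function(records, mode = c("intra", "inter"),
                            metric = c("spearman", "variance"),
                            nIter = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  r <- records[is.finite(records$pnmdeff), , drop = FALSE]
  groupCol <- if (mode == "intra") "individual_id" else "variant_id"
  minPer <- if (metric == "spearman") 2L else 3L
  sizes <- table(r[[groupCol]])
  groups <- names(sizes)[sizes >= minPer]
  notTestable <- function(reason)
    structure(list(mode = mode, metric = metric, observed = NA_real_,
                   randomized = numeric(0), randomizedSummary = NULL,
                   excessVariance = NA_real_, pValue = NA_real_,
                   nIterations = as.integer(nIter), testable = FALSE,
                   reason = reason), class = "VariabilityResult")
  if (metric == "spearman" && length(groups) < 3L)
    return(notTestable("need >= 3 groups with >= 2 finite scores each"))
  if (metric == "variance" && length(groups) < 2L)
    return(notTestable("need >= 2 groups with >= 3 finite scores each"))
  r <- r[r[[groupCol]] %in% groups, , drop = FALSE]
  idx <- split(seq_len(nrow(r)), r[[groupCol]])

  statOnce <- function(values) {
    if (metric == "spearman") {
      picks <- vapply(idx, function(i) sample(i, 2L), integer(2))
      suppressWarnings(cor(values[picks[1L, ]], values[picks[2L, ]],
                           method = "spearman"))
    } else {
      mean(vapply(idx, function(i) var(values[i]), numeric(1)))
    }
  }

  set.seed(as.integer(seed))
  n <- nrow(r)
  if (metric == "spearman") {
    obs <- numeric(nIter); rand <- numeric(nIter)
    for (b in seq_len(nIter)) {
      obs[b] <- statOnce(r$pnmdeff)
      rand[b] <- statOnce(r$pnmdeff[sample.int(n)])
    }
    observed <- mean(obs, na.rm = TRUE)
    p <- (sum(rand >= observed, na.rm = TRUE) + 1) / nIter
    excess <- NA_real_
  } else {
    observed <- statOnce(r$pnmdeff)
    rand <- vapply(seq_len(nIter), function(b)
      statOnce(r$pnmdeff[sample.int(n)]), numeric(1))
    excess <- mean(rand) - observed
    p <- (sum(rand <= observed) + 1) / nIter
  }
  q <- quantile(rand, c(0.025, 0.5, 0.975), names = FALSE, na.rm = TRUE)
  structure(list(
    mode = mode, metric = metric, observed = observed, randomized = rand,
    randomizedSummary = c(mean = mean(rand, na.rm = TRUE),
                          sd = sd(rand), q2.5 = q[1], median = q[2],
                          q97.5 = q[3]),
    excessVariance = excess, pValue = min(p, 1),
    nIterations = as.integer(nIter), testable = TRUE, reason = NA_character_),
    class = "VariabilityResult")
}

#' @export
print.VariabilityResult <- function(x, ...) {
  cat("pNMDeff variability test:", x$mode, "/", x$metric, "\n")
  if (!x$testable) {
    cat("  not testable:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  observed = %.4g; randomized mean = %.4g\n",
              x$observed, x$randomizedSummary["mean"]))
  if (x$metric == "variance")
    cat(sprintf("  excess variance = %.4g\n", x$excessVariance))
  cat(sprintf("  p = %.3g (%d iterations)\n", x$pValue, x$nIterations))
  invisible(x)
}
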