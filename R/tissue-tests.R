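#' Inter-tissue iNMDeff variability deviation (ITNVD) test
#'
#' Observed statistic: the standard deviation, over tissues, of the
#' tissue-specific median iNMDeff. The null is built by permuting the
#' sample-to-tissue assignment (tissue sizes preserved) \code{nIter} times.
#' \code{ITNVD = observed - median(null)}; under exchangeability it is close
#' to 0. The p-value follows
#' \code{(sum(null > observed) + 1) / nIter} (strict inequality; ties do not
#' count as exceedances), so its floor is \code{1/nIter} — 5e-4 at the default
#' 2000 iterations.
#'
#' @param inmdeff numeric vector of per-sample iNMDeff estimates.
#' @param tissue character/factor vector of tissue labels, same length.
#' @param nIter permutation iterations (default 2000).
#' @param seed RNG seed.
#' @param donor optional vector of donor ids; when given, permutation is
#'   blocked so that all samples of one donor move together (off by default).
#' @return a \code{\link{RandomizationResult-class}} with
#'   \code{statisticName = "ITNVD"}.
#' @export
itnvdTest <- function(inmdeff, tissue, nIter = 2000L, seed = 1L,
                      donor = NULL) {
  ok <- is.finite(inmdeff) & !is.na(tissue)
  x <- inmdeff[ok]; g <- as.character(tissue)[ok]
  if (length(unique(g)) < 2L) stop("ITNVD needs at least 2 tissues")
  observed <- sd(vapply(split(x, g), median, numeric(1)))
  nullStat <- .permuteTissueStat(x, g, nIter, seed, donor = donor,
                                 statistic = function(xx, gg)
                                   sd(vapply(split(xx, gg), median, numeric(1))))
  p <- (sum(nullStat > observed) + 1) / nIter
  new("RandomizationResult", statisticName = "ITNVD", tissue = NA_character_,
      observed = observed, nullValues = nullStat,
      deviation = observed - median(nullStat),
      pValue = min(p, 1), nIter = as.integer(nIter), seed = as.integer(seed))
}

#' Tissue iNMDeff deviation (TND) test
#'
#' Compares one tissue's observed median iNMDeff against the distribution of
#' its median under permuted sample-to-tissue labels (size preserved).
#' \code{TND = observed median - median(randomized medians)}: positive means
#' the tissue runs a higher NMD efficiency than expected by chance. The
#' p-value is one-sided in the direction of the deviation — upper tail
#' \code{(sum(null > observed) + 1)/nIter} for TND > 0, lower tail for
#' TND < 0.
#'
#' @inheritParams itnvdTest
#' @param targetTissue the tissue to test (must be present).
#' @return a \code{\link{RandomizationResult-class}} with
#'   \code{statisticName = "TND"}.
#' @export
tndTest <- function(inmdeff, tissue, targetTissue, nIter = 2000L, seed = 1L,
                    donor = NULL) {
  ok <- is.finite(inmdeff) & !is.na(tissue)
  x <- inmdeff[ok]; g <- as.character(tissue)[ok]
  if (!(targetTissue %in% g)) stop("tissue absent: ", targetTissue)
  observed <- median(x[g == targetTissue])
  nullStat <- .permuteTissueStat(x, g, nIter, seed, donor = donor,
                                 statistic = function(xx, gg)
                                   median(xx[gg == targetTissue]))
  dev <- observed - median(nullStat)
  p <- if (dev >= 0) (sum(nullStat > observed) + 1) / nIter
       else (sum(nullStat < observed) + 1) / nIter
  new("RandomizationResult", statisticName = "TND", tissue = targetTissue,
      observed = observed, nullValues = nullStat, deviation = dev,
      pValue = min(p, 1), nIter = as.integer(nIter), seed = as.integer(seed))
}

# shared permutation engine: shuffle labels (optionally donor-blocked),
# conserving tissue sizes and the multiset of values
.permuteTissueStat <- function(x, g, nIter, seed, donor = NULL, statistic) {
  set.seed(as.integer(seed))
  n <- length(x)
  vapply(seq_len(nIter), function(b) {
    perm <- if (is.null(donor)) sample.int(n) else {
      blocks <- split(seq_len(n), donor)
      unlist(blocks[sample.int(length(blocks))], use.names = FALSE)[seq_len(n)]
    }
    statistic(x[perm], g)
  }, numeric(1))
}

#' Per-tissue TND table
#'
#' Runs \code{\link{tndTest}} for every tissue and collects a tidy table with
#' Benjamini-Hochberg adjusted p-values.
#'
#' @inheritParams itnvdTest
#' @return data.frame: \code{tissue}, \code{n_samples}, \code{tnd},
#'   \code{observed_median}, \code{p_value}, \code{fdr}.
#' @export
tndTable <- function(inmdeff, tissue, nIter = 2000L, seed = 1L) {
  tissues <- sort(unique(as.character(tissue)))
  rows <- lapply(tissues, function(tt) {
    res <- tndTest(inmdeff, tissue, tt, nIter = nIter, seed = seed)
    data.frame(tissue = tt, n_samples = sum(tissue == tt),
               tnd = res@deviation, observed_median = res@observed,
               p_value = res@pValue)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out
}

#' Empirical false discovery rate from a randomization control
#'
#' Contrasts the rate of significant hits under randomized phenotype values
#' with the observed rate:
#' \code{(randomizedHits/randomizedTests) / (observedHits/observedTests)}.
#' With equal test totals, 3 randomized versus 10 observed hits gives 0.30.
#'
#' @param observedHits,observedTests,randomizedHits,randomizedTests counts.
#' @return the empirical FDR fraction, with the inverse (observed rate over
#'   randomized rate) attached as attribute \code{"inverseRatio"} for audit.
#' @export
empiricalFdr <- function(observedHits, observedTests, randomizedHits,
                         randomizedTests) {
  if (observedTests <= 0 || randomizedTests <= 0)
    stop("test totals must be positive")
  if (observedHits <= 0)
    stop("empirical FDR undefined with zero observed hits")
  obsRate <- observedHits / observedTests
  randRate <- randomizedHits / randomizedTests
  structure(randRate / obsRate,
            inverseRatio = if (randRate > 0) obsRate / randRate else Inf)
}

#' Leave-one-out variance decomposition of a linear iNMDeff model
#'
#' Fits the full linear model of iNMDeff on the supplied covariates, then
#' refits dropping each covariate in turn; each covariate's contribution is
#' the drop in total variance explained, \code{deltaR2 = R2(full) -
#' R2(without)}.
#'
#' @param inmdeff numeric response.
#' @param covariates data.frame of explanatory variables (tissue label among
#'   them, factors allowed).
#' @return list: \code{fullR2} and \code{deltaR2} (named numeric per
#'   covariate). Collinear covariates raise an error naming the pair.
#' @export
varianceDecomposition <- function(inmdeff, covariates) {
  stopifnot(nrow(covariates) == length(inmdeff))
  covariates <- as.data.frame(covariates)
  # collinearity check on the encoded design
  mm <- model.matrix(~ ., data = covariates)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    aliasIdx <- qr_$pivot[(qr_$rank + 1L):ncol(mm)]
    bad <- colnames(mm)[aliasIdx]
    asg <- attr(mm, "assign")[aliasIdx]
    partner <- vapply(aliasIdx, function(j) {
      cors <- abs(suppressWarnings(cor(mm[, j], mm[, -j, drop = FALSE])))
      colnames(mm)[-j][which.max(cors)]
    }, character(1))
    stop("collinear covariates: ",
         paste(paste(bad, "~", partner), collapse = "; "))
  }
  dat <- cbind(data.frame(.y = inmdeff), covariates)
  full <- lm(.y ~ ., data = dat)
  fullR2 <- summary(full)$r.squared
  delta <- vapply(names(covariates), function(v) {
    red <- lm(.y ~ ., data = dat[, setdiff(names(dat), v), drop = FALSE])
    fullR2 - summary(red)$r.squared
  }, numeric(1))
  list(fullR2 = fullR2, deltaR2 = delta)
}
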