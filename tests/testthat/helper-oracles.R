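# Independent oracles and fixture builders used across the suite.

# Toy transcript with explicit exon lengths on a fabricated chromosome.
# utr5/cds/utr3 are nt lengths; cds includes the stop codon.
makeToyModel <- function(exonLens, cdsStartNt, cdsLenNt, strand = "+",
                         chrom = "chrT", intronLen = 80L, offset = 100L) {
  txLen <- sum(exonLens)
  stopifnot(cdsStartNt + cdsLenNt <= txLen)
  bounds <- c(0L, cumsum(exonLens))
  ex <- matrix(0L, length(exonLens), 2L)
  cum <- offset
  for (i in seq_along(exonLens)) {
    ex[i, ] <- c(cum, cum + exonLens[i])
    cum <- cum + exonLens[i] + intronLen
  }
  if (strand == "-") {
    total <- cum - intronLen          # absolute end of the gene span
    ex <- cbind(offset + total - ex[, 2L], offset + total - ex[, 1L])
  }
  TranscriptModel(
    transcriptId = "TOY.T1", geneId = "TOY", chrom = chrom, strand = strand,
    exons = ex, cdsStart = cdsStartNt, cdsEnd = cdsStartNt + cdsLenNt)
}

# Brute-force positional NMD rule classifier: direct arithmetic over the
# 1-based transcript coordinate of the stop codon's first nt.
bruteClassify <- function(pos1, exonLens, hasEjc, rules) {
  cum <- cumsum(exonLens)
  nEx <- length(exonLens)
  exIdx <- which(pos1 <= cum)[1]
  if (pos1 <= rules@startProximalNt) return("evading")
  lastExon <- exIdx == nEx
  tail55 <- nEx >= 2 && exIdx == nEx - 1 &&
    (cum[nEx - 1] - pos1 + 1) <= rules@penultimateTailNt
  overridden <- rules@utr3EjcOverride && hasEjc
  if ((lastExon || tail55) && !overridden) return("evading")
  if (!is.na(rules@evadingMinExonNt)) {
    len <- exonLens[exIdx]
    if (len >= rules@evadingMinExonNt) return("evading")
    if (len > rules@triggeringMaxExonNt && len < rules@evadingMinExonNt)
      return("buffer")
  }
  "triggering"
}

# Naive mutate-and-translate PTC oracle on a spliced transcript string.
# Returns the 1-based mutated-CDS position of the first premature stop, or NA.
bruteMutateTranslate <- function(txSeq, cdsStart0, cdsLen, tStart0, refT, altT) {
  mutTx <- paste0(substr(txSeq, 1, tStart0), altT,
                  substr(txSeq, tStart0 + nchar(refT) + 1, nchar(txSeq)))
  d <- nchar(altT) - nchar(refT)
  mutCds <- substr(mutTx, cdsStart0 + 1, nchar(mutTx))
  stops <- c("TAA", "TAG", "TGA")
  frameshift <- (d %% 3) != 0
  k <- 0
  while (3 * k + 3 <= nchar(mutCds)) {
    if (substr(mutCds, 3 * k + 1, 3 * k + 3) %in% stops) {
      if (frameshift || 3 * k < cdsLen - 3 + d) return(as.integer(3 * k + 1))
      return(NA_integer_)
    }
    k <- k + 1
  }
  NA_integer_
}

# 1-D grid-search / profile-likelihood oracle for the NB-GLM NMD coefficient:
# for fixed beta1 the remaining coefficients and log(theta) are optimized
# directly on the negative-binomial log-likelihood; the profile is then
# minimized over beta1. Entirely independent of MASS::glm.nb.
profileBeta1 <- function(rows, interval = c(-4, 4)) {
  rows$gene_label <- factor(rows$gene_label)
  X <- if (nlevels(rows$gene_label) > 1)
    model.matrix(~ gene_label, rows) else matrix(1, nrow(rows), 1)
  y <- rows$raw_count
  z <- rows$is_nmd_target
  start <- c(log(mean(y) + 0.5), rep(0, ncol(X) - 1), log(10))
  nll <- function(beta1) {
    f <- function(par) {
      mu <- exp(drop(X %*% par[seq_len(ncol(X))]) + beta1 * z)
      -sum(dnbinom(y, mu = mu, size = exp(par[ncol(X) + 1]), log = TRUE))
    }
    o <- optim(start, f, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
    start <<- o$par
    o$value
  }
  optimize(nll, interval, tol = 1e-6)$minimum
}
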