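#' Build the duplicated gain/loss CNA matrix
#'
#' Splits a gene-level GISTIC-style dosage table into an amplification block
#' (negative scores zeroed) stacked over a deletion block (positive scores
#' zeroed), so that for every gene and sample \code{amp + del} reconstructs
#' the original score. Rows carry genomic order metadata (chrom, start, arm)
#' used by the loading autocorrelation.
#'
#' @param gisticTable data.frame with columns \code{gene}, \code{chrom},
#'   \code{start}, optionally \code{arm}, and one numeric column per sample.
#' @return a \code{\link{GainLossMatrix-class}}. Genes without coordinates are
#'   dropped with a warning.
#' @export
buildGainLossMatrix <- function(gisticTable) {
  meta <- c("gene", "chrom", "start", "arm")
  sampleCols <- setdiff(names(gisticTable), meta)
  bad <- is.na(gisticTable$chrom) | is.na(gisticTable$start)
  if (any(bad)) {
    warning(sum(bad), " gene(s) without coordinates dropped")
    gisticTable <- gisticTable[!bad, , drop = FALSE]
  }
  ord <- order(gisticTable$chrom, gisticTable$start)
  gisticTable <- gisticTable[ord, , drop = FALSE]
  raw <- as.matrix(gisticTable[, sampleCols, drop = FALSE])
  rownames(raw) <- gisticTable$gene
  amp <- pmax(raw, 0)
  del <- pmin(raw, 0)
  arm <- if ("arm" %in% names(gisticTable)) gisticTable$arm
         else gisticTable$chrom
  info <- data.frame(
    gene = rep(gisticTable$gene, 2L),
    type = rep(c("amp", "del"), each = nrow(gisticTable)),
    chrom = rep(gisticTable$chrom, 2L),
    start = rep(gisticTable$start, 2L),
    arm = rep(arm, 2L))
  scores <- rbind(amp, del)
  rownames(scores) <- paste(info$gene, info$type, sep = "_")
  new("GainLossMatrix", scores = scores, rowInfo = info)
}

#' Genomic lag-1 autocorrelation of a loading vector
#'
#' Pearson correlation between the genomically ordered loadings and a copy of
#' themselves lagged by one gene position. Arm-scale events produce blocks of
#' similar weights and autocorrelation near 1; unstructured loadings give
#' values near 0. A constant vector has no defined correlation and returns 0
#' with attribute \code{"constant" = TRUE}.
#'
#' @param loadings numeric loading vector.
#' @param genomicOrder permutation arranging loadings by genomic location
#'   (default: already ordered).
#' @return numeric scalar in [-1, 1].
#' @export
autocorrelationScore <- function(loadings, genomicOrder = seq_along(loadings)) {
  v <- loadings[genomicOrder]
  if (length(v) < 3L) stop("need at least 3 loadings")
  if (sd(v) == 0) return(structure(0, constant = TRUE))
  n <- length(v)
  a <- v[-n]; b <- v[-1L]
  if (sd(a) == 0 || sd(b) == 0) return(structure(0, constant = TRUE))
  cor(a, b)
}

#' Sparse principal component analysis by soft-thresholded power iteration
#'
#' Deflation-based rank-one sparse PCA: each component is obtained by
#' alternating power iterations between sample scores and feature loadings,
#' soft-thresholding the unnormalized loadings at \code{alpha} times the
#' largest absolute loading magnitude of the leading component (one global
#' penalty scale: \code{alpha = 0} is ordinary PCA, while trailing
#' low-variance components fall entirely below the threshold and become
#' ineffective), with a deterministic SVD warm start and a fixed
#' iteration cap — no RNG is involved, so loadings are reproducible.
#' Components whose loadings are thresholded to all-zero are kept as
#' ineffective placeholders.
#'
#' @param x numeric matrix, features x samples.
#' @param k number of components.
#' @param alpha sparsity level in [0, 1).
#' @param maxIter,tol iteration cap and convergence tolerance.
#' @param center center each feature across samples (default TRUE).
#' @return list with \code{loadings} (features x k), \code{scores}
#'   (samples x k), \code{sdev} (component scale), \code{effective} (logical
#'   per component).
#' @export
sparsePca <- function(x, k, alpha = 0, maxIter = 200L, tol = 1e-7,
                      center = TRUE) {
  stopifnot(alpha >= 0, alpha < 1)
  xc <- if (center) x - rowMeans(x) else x
  nF <- nrow(xc); nS <- ncol(xc)
  k <- min(k, nS, nF)
  loadings <- matrix(0, nF, k, dimnames = list(rownames(x), NULL))
  scores <- matrix(0, nS, k, dimnames = list(colnames(x), NULL))
  sdev <- numeric(k)
  effective <- logical(k)
  sv <- svd(xc, nu = k, nv = 0)
  globalScale <- NA_real_   # |w| scale of the leading component
  for (j in seq_len(k)) {
    v <- if (j <= ncol(sv$u)) sv$u[, j] else next       # warm start
    nv <- sqrt(sum(v^2)); if (nv == 0) next
    v <- v / nv
    for (it in seq_len(maxIter)) {
      s <- drop(crossprod(xc, v))
      ns <- sqrt(sum(s^2)); if (ns == 0) { v <- v * 0; break }
      s <- s / ns
      w <- drop(xc %*% s)
      if (is.na(globalScale)) globalScale <- max(abs(w))
      thr <- alpha * globalScale
      vNew <- sign(w) * pmax(abs(w) - thr, 0)
      nvNew <- sqrt(sum(vNew^2))
      if (nvNew == 0) { v <- vNew; break }
      vNew <- vNew / nvNew
      if (sum((vNew - v)^2) < tol) { v <- vNew; break }
      v <- vNew
    }
    if (sum(abs(v)) == 0) next
    effective[j] <- TRUE
    if (sum(v) < 0) v <- -v            # deterministic sign orientation
    s <- drop(crossprod(xc, v))
    loadings[, j] <- v
    scores[, j] <- s
    sdev[j] <- sqrt(sum(s^2) / max(1, nS - 1))
    xc <- xc - v %*% crossprod(v, xc)          # projection deflation
    if (j < k) sv <- svd(xc, nu = min(k, nS, nF), nv = 0)
  }
  list(loadings = loadings, scores = scores, sdev = sdev,
       effective = effective)
}

#' Tune and extract sparse-PCA CNA signatures by genomic autocorrelation
#'
#' For every (alpha, k) grid point, fits \code{\link{sparsePca}} to the
#' gain/loss matrix and scores the fit by the median genomic lag-1
#' autocorrelation of the leading 1\% (at least one) of effective components —
#' arm-scale signatures should push this toward 1. The grid point with the
#' highest score is selected, provided it reaches
#' \code{closenessThreshold}; otherwise the best available point is returned
#' with a warning.
#'
#' @param glMatrix a \code{\link{GainLossMatrix-class}}.
#' @param alphaGrid,kGrid numeric/integer grids (non-empty).
#' @param closenessThreshold required closeness of the tuning score to 1
#'   (default 0.9).
#' @param leadingFraction fraction of effective PCs scored (default 0.01;
#'   \code{"leading"} highest-variance components, configurable to
#'   \code{"trailing"}).
#' @param subset \code{"leading"} or \code{"trailing"}.
#' @return list: \code{alpha}, \code{k}, \code{tuningScore}, \code{grid}
#'   (data.frame of all scores), and \code{signatures} — a list of
#'   \code{CnaPcSignature} entries (\code{pcIndex}, \code{loadings},
#'   \code{sampleScores}, \code{effective}, \code{autocorrelation}).
#' @export
tuneSparsePca <- function(glMatrix, alphaGrid, kGrid,
                          closenessThreshold = 0.9, leadingFraction = 0.01,
                          subset = c("leading", "trailing")) {
  stopifnot(length(alphaGrid) > 0, length(kGrid) > 0)
  subset <- match.arg(subset)
  x <- glScores(glMatrix)
  grid <- expand.grid(alpha = alphaGrid, k = kGrid)
  fits <- vector("list", nrow(grid))
  scoreOf <- function(fit) {
    eff <- which(fit$effective)
    if (!length(eff)) return(NA_real_)
    m <- max(1L, ceiling(leadingFraction * length(eff)))
    pick <- if (subset == "leading") head(eff, m) else tail(eff, m)
    median(vapply(pick, function(j)
      as.numeric(autocorrelationScore(fit$loadings[, j])), numeric(1)))
  }
  grid$score <- NA_real_
  grid$nEffective <- 0L
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- sparsePca(x, k = grid$k[i], alpha = grid$alpha[i])
    grid$score[i] <- scoreOf(fits[[i]])
    grid$nEffective[i] <- sum(fits[[i]]$effective)
  }
  cand <- which(!is.na(grid$score) & grid$score >= closenessThreshold)
  if (length(cand)) {
    best <- cand[which.max(grid$score[cand])]
  } else {
    best <- which.max(grid$score)
    warning("no (alpha, k) grid point reached the autocorrelation threshold ",
            closenessThreshold, "; returning the best available (score = ",
            signif(grid$score[best], 3), ")")
  }
  fit <- fits[[best]]
  sigs <- lapply(seq_len(ncol(fit$loadings)), function(j) {
    structure(list(
      pcIndex = j,
      loadings = fit$loadings[, j],
      sampleScores = fit$scores[, j],
      effective = fit$effective[j],
      autocorrelation = if (fit$effective[j])
        as.numeric(autocorrelationScore(fit$loadings[, j])) else NA_real_),
      class = "CnaPcSignature")
  })
  list(alpha = grid$alpha[best], k = grid$k[best],
       tuningScore = grid$score[best], grid = grid, signatures = sigs)
}

#' @export
print.CnaPcSignature <- function(x, ...) {
  cat("CnaPcSignature PC", x$pcIndex,
      if (x$effective) sprintf("(%d nonzero loadings, autocorrelation %.3f)",
                               sum(x$loadings != 0), x$autocorrelation)
      else "(ineffective: all-zero loadings)", "\n")
  invisible(x)
}

#' Discovery/validation association of CNA signatures with iNMDeff
#'
#' Linear model of iNMDeff on each signature's sample scores (plus optional
#' covariates), run first on the ASE estimates (discovery) and, for
#' signatures passing the discovery FDR, on the ETG estimates (validation).
#' A signature is replicated iff both phases pass the FDR threshold and the
#' effect signs agree.
#'
#' @param sampleScores numeric matrix, samples x signatures (rownames =
#'   sample ids).
#' @param aseEstimates,etgEstimates estimate data.frames with
#'   \code{individual_id} and \code{inmdeff} columns.
#' @param covariates optional data.frame of per-sample covariates (rownames =
#'   sample ids).
#' @param fdrThreshold FDR cutoff for both phases (default 0.1).
#' @return data.frame per signature: betas, p-values, FDRs for both phases
#'   and a \code{replicated} flag. Signatures with fewer usable samples than
#'   parameters are skipped with \code{NA} and reason.
#' @export
associateSignatures <- function(sampleScores, aseEstimates, etgEstimates,
                                covariates = NULL, fdrThreshold = 0.1) {
  phase <- function(est, sig) {
    ids <- intersect(rownames(sampleScores), est$individual_id)
    y <- est$inmdeff[match(ids, est$individual_id)]
    dat <- data.frame(.y = y, .score = sampleScores[ids, sig])
    if (!is.null(covariates)) dat <- cbind(dat, covariates[ids, , drop = FALSE])
    if (nrow(dat) <= ncol(dat) + 1L)
      return(c(beta = NA_real_, p = NA_real_))
    fit <- lm(.y ~ ., data = dat)
    cf <- summary(fit)$coefficients
    if (!(".score" %in% rownames(cf))) return(c(beta = NA_real_, p = NA_real_))
    c(beta = cf[".score", "Estimate"], p = cf[".score", "Pr(>|t|)"])
  }
  k <- ncol(sampleScores)
  disc <- t(vapply(seq_len(k), function(j) phase(aseEstimates, j), numeric(2)))
  out <- data.frame(signature = seq_len(k),
                    beta_ase = disc[, "beta"], p_ase = disc[, "p"])
  out$fdr_ase <- p.adjust(out$p_ase, method = "BH")
  out$beta_etg <- NA_real_; out$p_etg <- NA_real_; out$fdr_etg <- NA_real_
  sel <- which(!is.na(out$fdr_ase) & out$fdr_ase <= fdrThreshold)
  if (length(sel)) {
    val <- t(vapply(sel, function(j) phase(etgEstimates, j), numeric(2)))
    out$beta_etg[sel] <- val[, "beta"]
    out$p_etg[sel] <- val[, "p"]
    out$fdr_etg[sel] <- p.adjust(val[, "p"], method = "BH")
  }
  out$replicated <- !is.na(out$fdr_ase) & out$fdr_ase <= fdrThreshold &
    !is.na(out$fdr_etg) & out$fdr_etg <= fdrThreshold &
    sign(out$beta_ase) == sign(out$beta_etg)
  out
}

#' Gene-wise iNMDeff among focal amplification carriers
#'
#' For each gene, the median iNMDeff of samples carrying a focal copy-number
#' amplification of that gene. A sample's amplified genes are grouped into
#' contiguous runs along each chromosome arm (genomic order); a run is focal
#' when it spans less than a configured fraction of the arm's genes
#' (arm-level otherwise).
#'
#' @param cnaTable data.frame: \code{gene}, \code{chrom}, \code{start},
#'   optional \code{arm}, plus per-sample score columns.
#' @param inmdeff named numeric vector of per-sample iNMDeff.
#' @param focality list overriding \code{scoreThreshold} (0.3: minimum dosage
#'   score calling a gene amplified) and \code{maxArmFraction} (0.25: runs
#'   spanning at least this fraction of the arm count as arm-level).
#' @return data.frame in genomic order: \code{gene}, \code{chrom},
#'   \code{start}, \code{n_focal_carriers}, \code{median_inmdeff} (NA when no
#'   focal carrier exists).
#' @export
genewiseFocalInmdeff <- function(cnaTable, inmdeff, focality = list()) {
  cfg <- modifyList(list(scoreThreshold = 0.3, maxArmFraction = 0.25),
                    focality)
  meta <- c("gene", "chrom", "start", "arm")
  sampleCols <- intersect(setdiff(names(cnaTable), meta), names(inmdeff))
  ord <- order(cnaTable$chrom, cnaTable$start)
  tab <- cnaTable[ord, , drop = FALSE]
  arm <- if ("arm" %in% names(tab)) tab$arm else tab$chrom
  nGenes <- nrow(tab)
  carriers <- matrix(FALSE, nGenes, length(sampleCols),
                     dimnames = list(tab$gene, sampleCols))
  for (s in sampleCols) {
    amp <- tab[[s]] >= cfg$scoreThreshold
    for (a in unique(arm)) {
      inArm <- which(arm == a)
      r <- rle(amp[inArm])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (i in which(r$values)) {
        if (r$lengths[i] < cfg$maxArmFraction * length(inArm))
          carriers[inArm[starts[i]:ends[i]], s] <- TRUE
      }
    }
  }
  med <- vapply(seq_len(nGenes), function(g) {
    ids <- sampleCols[carriers[g, ]]
    if (!length(ids)) NA_real_ else median(inmdeff[ids])
  }, numeric(1))
  data.frame(gene = tab$gene, chrom = tab$chrom, start = tab$start,
             n_focal_carriers = rowSums(carriers),
             median_inmdeff = med)
}

#' Prioritize candidate dosage-sensitive NMD genes
#'
#' Candidates are genes whose expression correlates negatively with iNMDeff
#' (the presumed downstream effect on the phenotype) and positively with
#' their own copy-number dosage (the presumed cause of the expression
#' change).
#'
#' @param expression numeric matrix genes x samples.
#' @param inmdeff named numeric vector of per-sample iNMDeff.
#' @param cna numeric matrix genes x samples of dosage scores (same genes).
#' @param thresholds list overriding \code{exprInmdeffMax} (-0.2: the
#'   expression-iNMDeff correlation must be below this) and \code{exprCnaMin}
#'   (0.2: the expression-CNA correlation must exceed this).
#' @return data.frame: \code{gene}, \code{cor_expr_inmdeff},
#'   \code{cor_expr_cna}, \code{candidate}.
#' @export
prioritizeCandidates <- function(expression, inmdeff, cna,
                                 thresholds = list()) {
  th <- modifyList(list(exprInmdeffMax = -0.2, exprCnaMin = 0.2), thresholds)
  ids <- Reduce(intersect, list(colnames(expression), names(inmdeff),
                                colnames(cna)))
  genes <- intersect(rownames(expression), rownames(cna))
  c1 <- vapply(genes, function(g)
    suppressWarnings(cor(expression[g, ids], inmdeff[ids])), numeric(1))
  c2 <- vapply(genes, function(g)
    suppressWarnings(cor(expression[g, ids], cna[g, ids])), numeric(1))
  data.frame(gene = genes,
             cor_expr_inmdeff = c1,
             cor_expr_cna = c2,
             candidate = !is.na(c1) & !is.na(c2) &
               c1 < th$exprInmdeffMax & c2 > th$exprCnaMin)
}
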